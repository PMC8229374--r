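test_that("the toy model is viable, flux-consistent and Warburg-capable", {
  m <- make_toy_model()
  expect_true(all(reserved_reactions() %in% reaction_ids(m)))
  expect_gte(nrow(m$reactions), 40)
  expect_gte(length(unique(m$reactions$subsystem)), 6)
  s <- fba(m)
  expect_gt(s$objective_value, 0)
  expect_length(fastcc(m)$removed_reactions, 0)
  # overflow signature: both ATP routes run, lactate secreted, oxygen taken up
  expect_gt(s$flux[["GAPD"]], 0)
  expect_gt(s$flux[["ATPS4mi"]], 0)
  expect_lt(s$flux[["D_LACt2"]], 0)
  expect_gt(s$flux[["O2t"]], 0)
})

test_that("closing glucose reduces the biomass optimum", {
  m <- make_toy_model()
  z0 <- fba(m)$objective_value
  m$reactions$lower_bound[reaction_ids(m) == "EX_glc_e"] <- 0
  z1 <- fba(m)$objective_value
  expect_lt(z1, z0)
})

test_that("without the oxygen cap the optimum abandons overflow", {
  m <- make_toy_model(toy_model_spec(include_warburg_core = FALSE))
  s <- fba(m)
  # oxidative ATP is cheaper per carbon: no lactate overflow at the optimum
  expect_gte(s$flux[["D_LACt2"]], -1e-6)
})

test_that("toy model construction is deterministic given the seed", {
  m1 <- make_toy_model(toy_model_spec(seed = 4))
  m2 <- make_toy_model(toy_model_spec(seed = 4))
  expect_identical(m1$reactions, m2$reactions)
  expect_identical(vapply(m1$gpr, format_gpr, ""), vapply(m2$gpr, format_gpr, ""))
  m3 <- make_toy_model(toy_model_spec(seed = 5))
  expect_false(identical(vapply(m1$gpr, format_gpr, ""),
                         vapply(m3$gpr, format_gpr, "")))
})

test_that("expression simulation is byte-deterministic and honors the design", {
  m <- make_toy_model()
  d <- simulation_design(n_groups = 2, n_samples_per_group = 2, seed = 12)
  s1 <- simulate_expression(m, d)
  s2 <- simulate_expression(m, d)
  expect_identical(s1$matrix, s2$matrix)
  expect_equal(ncol(s1$matrix), 2 * 2 * d$n_replicates)
  expect_equal(length(unique(s1$replicate_groups)), 4)
  expect_error(simulate_expression(m, simulation_design(missing_fraction = 1)),
               "missing_fraction")
})

test_that("a null design produces identical profiles within and between groups", {
  m <- make_toy_model()
  d <- simulation_design(n_groups = 2, n_samples_per_group = 2,
                         effect_size = 1, noise_sd = 0, missing_fraction = 0,
                         seed = 9)
  s <- simulate_expression(m, d)
  expect_true(all(apply(s$matrix, 1, function(x) diff(range(x)) == 0)))
})

test_that("planted effects shift exactly the planted subsystem's genes", {
  m <- make_toy_model()
  d <- simulation_design(n_groups = 2, n_samples_per_group = 1,
                         n_replicates = 1, noise_sd = 0, missing_fraction = 0,
                         effect_size = 4, seed = 21)
  s <- simulate_expression(m, d)
  planted_genes <- s$ground_truth$planted_genes
  ref <- s$matrix[, "grp1_s01_r1"]
  alt <- s$matrix[, "grp2_s01_r1"]
  changed <- rownames(s$matrix)[abs(ref - alt) > 1e-12]
  expect_setequal(changed, planted_genes)
  # down-regulation by the declared fold
  expect_equal(alt[planted_genes], ref[planted_genes] / 4,
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("proteome designs cover fewer genes, varying between samples", {
  m <- make_toy_model()
  sp <- simulate_expression(m, simulation_design(platform = "proteome",
                                                 n_groups = 1,
                                                 n_samples_per_group = 4,
                                                 seed = 31))
  sr <- simulate_expression(m, simulation_design(platform = "rnaseq",
                                                 n_groups = 1,
                                                 n_samples_per_group = 4,
                                                 seed = 32))
  miss_p <- mean(is.na(sp$matrix))
  miss_r <- mean(is.na(sr$matrix))
  expect_gt(miss_p, 0.3)
  expect_lt(miss_r, 0.1)
  # per-sample coverage differs across proteome samples
  um <- sp$ground_truth$unmeasured_genes
  expect_gt(length(unique(vapply(um, paste, "", collapse = ","))), 1)
})

test_that("each planted group's extracted models lose their silenced pathway", {
  m <- make_toy_model()
  prot <- protect_reactions(m, reserved_reactions())
  sim <- simulate_expression(m, simulation_design(n_samples_per_group = 1,
                                                  seed = 41))
  profs <- preprocess_expression(sim$matrix, sim$replicate_groups)
  sub <- setNames(m$reactions$subsystem, reaction_ids(m))
  ok <- 0; total <- 0
  for (g in 2:4) {
    planted_sub <- sim$ground_truth$planted[[g]]$subsystem
    planted_rxn <- names(sub)[sub == planted_sub]
    act_ref <- map_expression(m, profs[[sprintf("grp%d_s01", 1)]])
    act_g <- map_expression(m, profs[[sprintf("grp%d_s01", g)]])
    r_ref <- extract_context(m, act_ref, extraction_config("init", protected = prot))
    r_g <- extract_context(m, act_g, extraction_config("init", protected = prot))
    total <- total + 1
    # the silenced pathway is (at least partly) dropped in its own group
    # while the reference group keeps it intact
    if (all(planted_rxn %in% r_ref$kept_reactions) &&
        !all(planted_rxn %in% r_g$kept_reactions)) ok <- ok + 1
  }
  expect_gte(ok, 2)
})

test_that("the flux-level generator plants exactly one subsystem's reactions", {
  m <- make_toy_model()
  s <- simulate_flux_matrix(m, seed = 51)
  expect_equal(unique(m$reactions$subsystem[match(s$planted_reactions,
                                                  reaction_ids(m))]),
               s$planted_subsystem)
  expect_identical(simulate_flux_matrix(m, seed = 51)$matrix, s$matrix)
  # group means differ on planted reactions only (beyond the noise floor)
  g1 <- colMeans(s$matrix[s$labels == "group1", ])
  g4 <- colMeans(s$matrix[s$labels == "group4", ])
  big <- names(which(abs(g1 - g4) > 1))
  expect_setequal(big, s$planted_reactions)
})
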