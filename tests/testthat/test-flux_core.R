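test_that("FBA saturates a linear chain and respects bottlenecks", {
  m <- chain_model()
  s <- fba(m)
  expect_equal(s$status, "optimal")
  expect_equal(s$objective_value, 10, tolerance = 1e-6)
  expect_equal(unname(s$flux[c("r1", "r2")]), c(10, 10), tolerance = 1e-6)

  s3 <- fba(chain_model(ub1 = 3))
  expect_equal(s3$objective_value, 3, tolerance = 1e-6)
})

test_that("FBA on the Warburg toy model matches an independent LP solve", {
  skip_if_not(has_python_scipy(), "python/scipy not available")
  m <- make_toy_model()
  s <- fba(m, parsimonious = FALSE)
  cs <- list(obj = as.numeric(reaction_ids(m) == m$objective),
             mat = as.matrix(m$S),
             dir = rep("=", length(m$metabolites)),
             rhs = numeric(length(m$metabolites)),
             lower = m$reactions$lower_bound,
             upper = m$reactions$upper_bound, sense = "max")
  ref <- scipy_lp_batch(list(cs))[[1]]
  expect_equal(ref$status, "optimal")
  expect_equal(s$objective_value, ref$objective, tolerance = 1e-6)
})

test_that("infeasible and unbounded problems are reported, not thrown", {
  # demand with no producer: infeasible
  m <- metabolic_model(
    "bad", data.frame(reaction_id = "DM", lower_bound = 1, upper_bound = 2),
    list(c(a = -1)), objective = "DM")
  s <- fba(m)
  expect_equal(s$status, "infeasible")
  expect_true(all(is.na(s$flux)))

  # free exchange pair with unbounded objective
  m2 <- metabolic_model(
    "unb", data.frame(reaction_id = c("in", "out"),
                      lower_bound = c(-Inf, -Inf), upper_bound = c(Inf, Inf)),
    list(c(a = 1), c(a = -1)), objective = "out")
  expect_equal(fba(m2)$status, "unbounded")
})

test_that("flux states satisfy steady state and bounds within tolerance", {
  for (seed in 1:8) {
    m <- random_net(18, seed = seed)
    s <- fba(m, objective = sample(reaction_ids(m), 1))
    expect_equal(s$status, "optimal")
    viol <- fluxprint:::flux_violations(m, s$flux)
    expect_lt(viol$steady, 1e-6)
    expect_lt(viol$bounds, 1e-6)
  }
})

test_that("the parsimonious tie-break never shrinks the optimum and reduces total flux", {
  m <- make_toy_model()
  plain <- fba(m, parsimonious = FALSE)
  pars <- fba(m, parsimonious = TRUE)
  expect_equal(pars$objective_value, plain$objective_value, tolerance = 1e-6)
  expect_lte(sum(abs(pars$flux)), sum(abs(plain$flux)) + 1e-6)
})

test_that("FVA brackets every reaction, matching brute-force per-reaction LPs", {
  m <- chain_model()
  vv <- fva(m)
  expect_equal(vv$min[vv$reaction_id == "r1"], 0, tolerance = 1e-6)
  expect_equal(vv$max[vv$reaction_id == "r1"], 10, tolerance = 1e-6)

  # pinned reaction yields the degenerate interval
  mp <- metabolic_model(
    "pin", data.frame(reaction_id = c("EX_a", "r1", "EX_b"),
                      lower_bound = c(-10, 0, 0), upper_bound = c(10, 0, 10)),
    list(c(a = -1), c(a = -1, b = 1), c(b = -1)), objective = "EX_b")
  vvp <- fva(mp, "r1")
  expect_equal(c(vvp$min, vvp$max), c(0, 0), tolerance = 1e-9)

  for (seed in 1:6) {
    mr <- random_net(15, seed = 100 + seed)
    mine <- fva(mr)
    ref <- brute_fva(mr)
    expect_equal(mine$min, ref$min, tolerance = 1e-6)
    expect_equal(mine$max, ref$max, tolerance = 1e-6)
  }
})

test_that("FVA at a positive optimum fraction constrains the objective", {
  m <- make_toy_model()
  z <- fba(m, parsimonious = FALSE)$objective_value
  vv <- fva(m, "biomass_reaction", fraction_of_optimum = 0.9)
  expect_gte(vv$min + 1e-6, 0.9 * z)
  expect_lte(vv$max, z + 1e-6)
})

test_that("fastcc removes dead-end producers and keeps coupled cycles", {
  # b is produced but never consumed: r1 is blocked
  m <- metabolic_model(
    "dead", data.frame(reaction_id = c("EX_a", "r1", "r2", "EX_c"),
                       lower_bound = c(-10, 0, 0, 0),
                       upper_bound = c(10, 10, 10, 10)),
    list(c(a = -1), c(a = -1, b = 1), c(a = -1, c = 1), c(c = -1)),
    objective = "EX_c")
  cr <- fastcc(m)
  expect_true("r1" %in% cr$removed_reactions)
  expect_true(all(c("EX_a", "r2", "EX_c") %in% cr$consistent_reactions))

  # fully coupled chain with exchanges: nothing removed
  cr2 <- fastcc(chain_model())
  expect_length(cr2$removed_reactions, 0)
})

test_that("fastcc equals the FVA-derived consistent set on random networks", {
  eps <- 1e-4
  for (seed in 1:10) {
    m <- random_net(sample(12:25, 1), seed = 200 + seed)
    cr <- fastcc(m, eps)
    ref <- brute_fva(m)
    ref_ok <- ref$reaction_id[pmax(abs(ref$min), abs(ref$max)) >= eps * 0.999]
    expect_setequal(cr$consistent_reactions, ref_ok)
    expect_setequal(c(cr$consistent_reactions, cr$removed_reactions),
                    reaction_ids(m))
  }
})

test_that("fastcc is idempotent and preserves the FBA optimum", {
  for (seed in 1:5) {
    m <- random_net(20, seed = 300 + seed)
    cr <- fastcc(m)
    if (!length(cr$consistent_reactions)) next
    red <- cr$consistent_model
    cr2 <- fastcc(red)
    expect_length(cr2$removed_reactions, 0)
    if (m$objective %in% reaction_ids(red)) {
      expect_equal(fba(red, parsimonious = FALSE)$objective_value,
                   fba(m, parsimonious = FALSE)$objective_value,
                   tolerance = 1e-6)
    }
  }
})

test_that("epsilon below the solver floor is clamped with a warning", {
  m <- chain_model()
  expect_warning(cr <- fastcc(m, 1e-10), "clamped")
  expect_length(cr$removed_reactions, 0)
})
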