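# a small parallel-pathway network: substrate -> x, then either pA or pB
# -> y, exported by OUT (the objective)
parallel_model <- function() {
  metabolic_model(
    "parallel",
    data.frame(reaction_id = c("EX_s", "T", "pA", "pB", "OUT"),
               lower_bound = c(-10, 0, 0, 0, 0),
               upper_bound = c(0, 10, 10, 10, 10)),
    list(c(s = -1), c(s = -1, x = 1), c(x = -1, y = 1), c(x = -1, y = 1),
         c(y = -1)),
    objective = "OUT")
}

act_for <- function(model, ...) {
  v <- setNames(rep(NA_real_, nrow(model$reactions)),
                model$reactions$reaction_id)
  over <- c(...)
  v[names(over)] <- over
  structure(list(sample_id = "t", values = v), class = "reaction_activity")
}

test_that("GIMME keeps everything when nothing is penalized", {
  m <- chain_model()
  act <- act_for(m, r1 = 1, r2 = 1)
  r <- extract_gimme(m, act)
  expect_setequal(r$kept_reactions, reaction_ids(m))
})

test_that("GIMME drops a penalized parallel pathway while holding biomass", {
  m <- parallel_model()
  act <- act_for(m, pA = 0.05, pB = 0.9)
  r <- extract_gimme(m, act, extraction_config("gimme"))
  expect_false("pA" %in% r$kept_reactions)
  expect_true(all(c("EX_s", "T", "pB", "OUT") %in% r$kept_reactions))
  s <- fba(r$context_model)
  expect_gte(s$objective_value,
             0.9 * r$diagnostics$biomass_optimum - 1e-6)
})

test_that("GIMME stage-2 optimum matches an independently formulated LP", {
  skip_if_not(has_python_scipy(), "python/scipy not available")
  m <- make_toy_model()
  set.seed(61)
  rid <- reaction_ids(m)
  act_v <- setNames(runif(length(rid)), rid)
  act_v[startsWith(rid, "EX_")] <- NA
  act <- structure(list(sample_id = "t", values = act_v),
                   class = "reaction_activity")
  cfg <- extraction_config("gimme")
  r <- extract_gimme(m, act, cfg)

  # independent formulation: split variables, biomass row, scipy solve
  thr <- quantile(act_v[!is.na(act_v)], cfg$expression_threshold)
  w <- pmax(0, thr - act_v); w[is.na(w)] <- 0
  A <- as.matrix(m$S)
  n <- ncol(A)
  lb <- m$reactions$lower_bound; ub <- m$reactions$upper_bound
  bio <- as.numeric(rid == m$objective)
  zstar <- r$diagnostics$biomass_optimum
  cs <- list(obj = c(w, w),
             mat = rbind(cbind(A, -A), c(bio, -bio)),
             dir = c(rep("=", nrow(A)), ">="),
             rhs = c(numeric(nrow(A)), cfg$biomass_fraction * zstar),
             lower = c(pmax(lb, 0), pmax(-ub, 0)),
             upper = c(pmax(ub, 0), pmax(-lb, 0)),
             sense = "min")
  ref <- scipy_lp_batch(list(cs))[[1]]
  expect_equal(ref$status, "optimal")
  expect_equal(r$diagnostics$stage2_objective, ref$objective, tolerance = 1e-6)
})

test_that("iMAT satisfies a conflict-free classification completely", {
  m <- chain_model()
  act <- act_for(m, r1 = 1, r2 = 1)
  r <- extract_imat(m, act)
  expect_equal(r$diagnostics$agreement,
               length(r$diagnostics$high_set) + length(r$diagnostics$low_set))
  expect_true(all(c("r1", "r2") %in% r$kept_reactions))
})

test_that("iMAT resolves a stoichiometric high/low conflict optimally", {
  m <- chain_model()
  act <- act_for(m, r1 = 1, r2 = 0)  # coupled reactions, opposite classes
  r <- extract_imat(m, act)
  expect_equal(length(r$diagnostics$high_set) + length(r$diagnostics$low_set), 2)
  expect_equal(r$diagnostics$agreement, 1)  # total - 1
})

test_that("iMAT with no classified reactions leaves the model unchanged", {
  m <- chain_model()
  act <- act_for(m)  # all missing
  r <- extract_imat(m, act)
  expect_equal(r$diagnostics$agreement, 0L)
  expect_setequal(r$kept_reactions, reaction_ids(m))
})

test_that("iMAT agreement matches exhaustive enumeration on small nets", {
  eps <- 1e-4
  for (seed in 1:6) {
    m <- random_net(9, seed = 400 + seed, p_rev = 0, p_deadend = 0.1)
    m <- fastcc(m)$consistent_model
    internal <- reaction_ids(m)[!startsWith(reaction_ids(m), "EX_") &
                                  m$reactions$lower_bound >= 0]
    if (length(internal) < 3) next
    set.seed(seed)
    hi <- sample(internal, min(2, length(internal)))
    lo <- sample(setdiff(internal, hi), min(2, length(internal) - length(hi)))
    act_v <- setNames(rep(NA_real_, length(reaction_ids(m))), reaction_ids(m))
    act_v[hi] <- 1; act_v[lo] <- 0
    act <- structure(list(sample_id = "t", values = act_v),
                     class = "reaction_activity")
    r <- extract_imat(m, act, extraction_config("imat", high_quantile = 0.7,
                                                low_quantile = 0.3))
    H <- r$diagnostics$high_set; L <- r$diagnostics$low_set
    # enumerate which subsets of the classification are simultaneously
    # satisfiable; the best total is the iMAT optimum
    A <- as.matrix(m$S)
    lb <- m$reactions$lower_bound; ub <- m$reactions$upper_bound
    best <- 0
    items <- c(H, L)
    for (mask in 0:(2^length(items) - 1)) {
      pick <- items[bitwAnd(mask, 2^(seq_along(items) - 1)) > 0]
      lo2 <- lb; hi2 <- ub
      for (x in intersect(pick, H)) lo2[match(x, reaction_ids(m))] <-
          max(lo2[match(x, reaction_ids(m))], eps)
      for (x in intersect(pick, L)) {
        j <- match(x, reaction_ids(m))
        # the low reward is strict (|v| < eps); mirror the implementation's
        # eps-halved window
        lo2[j] <- max(lo2[j], -eps / 2); hi2[j] <- min(hi2[j], eps / 2)
      }
      sub <- solve_lp(numeric(ncol(A)), A, rep("=", nrow(A)), numeric(nrow(A)),
                      lo2, hi2, "min")
      if (sub$status == "optimal") best <- max(best, length(pick))
    }
    expect_equal(r$diagnostics$milp_objective, best, tolerance = 1e-6,
                 info = paste("net", seed))
    expect_equal(r$diagnostics$agreement, best, info = paste("net", seed))
  }
})

test_that("INIT keeps positively weighted reactions and drops negative bypasses", {
  m <- parallel_model()
  act <- act_for(m, pA = 0.1, pB = 0.9, T = 0.8, OUT = 0.9)
  r <- extract_init(m, act, extraction_config("init", expression_threshold = 0.5))
  w <- r$diagnostics$weights
  expect_true(all(names(w)[!is.na(w) & w > 0] %in% r$kept_reactions))
  expect_false("pA" %in% r$kept_reactions)
})

test_that("INIT with no informative weights returns the protected closure", {
  m <- chain_model()
  act <- act_for(m)  # all missing: every weight zero
  r <- extract_init(m, act)
  # the objective is implicitly protected; its minimal support is the chain
  expect_setequal(r$kept_reactions, reaction_ids(m))
  expect_equal(r$diagnostics$milp_status, "trivial")
})

test_that("INIT optimum matches exhaustive subset enumeration on small nets", {
  eps <- 1e-4
  for (seed in 1:5) {
    m <- random_net(8, seed = 500 + seed, p_rev = 0, p_deadend = 0.1)
    m <- fastcc(m)$consistent_model
    internal <- reaction_ids(m)[m$reactions$lower_bound >= 0 &
                                  !startsWith(reaction_ids(m), "EX_")]
    if (length(internal) < 2) next
    set.seed(seed)
    act_v <- setNames(rep(NA_real_, length(reaction_ids(m))), reaction_ids(m))
    act_v[internal] <- runif(length(internal))
    act <- structure(list(sample_id = "t", values = act_v),
                     class = "reaction_activity")
    cfg <- extraction_config("init", expression_threshold = 0.5)
    r <- extract_init(m, act, cfg)
    thr <- quantile(act_v[!is.na(act_v)], 0.5)
    w <- act_v - thr; w[is.na(w)] <- 0
    pos <- names(w)[w > 0]
    A <- as.matrix(m$S)
    lb <- m$reactions$lower_bound; ub <- m$reactions$upper_bound
    best <- 0
    for (mask in 0:(2^length(pos) - 1)) {
      pick <- pos[bitwAnd(mask, 2^(seq_along(pos) - 1)) > 0]
      lo2 <- lb
      for (x in pick) lo2[match(x, reaction_ids(m))] <-
          max(lo2[match(x, reaction_ids(m))], eps)
      sub <- solve_lp(numeric(ncol(A)), A, rep("=", nrow(A)), numeric(nrow(A)),
                      lo2, ub, "min")
      if (sub$status == "optimal") best <- max(best, sum(w[pick]))
    }
    expect_equal(r$diagnostics$milp_objective, best, tolerance = 1e-5,
                 info = paste("net", seed))
  }
})

test_that("FASTCORE returns the whole model for a full core and grows chains", {
  m <- chain_model()
  r <- extract_fastcore(m, reaction_ids(m))
  expect_setequal(r$kept_reactions, reaction_ids(m))

  # a single middle reaction forces the whole chain as support
  r2 <- extract_fastcore(m, "r1", extraction_config("fastcore"))
  expect_setequal(r2$kept_reactions, reaction_ids(m))
})

test_that("FASTCORE rejects unknown and blocked core reactions by name", {
  m <- chain_model()
  expect_error(extract_fastcore(m, "nope"), "not in model: nope")
  # dead-end producer cannot carry flux
  md <- metabolic_model(
    "dead", data.frame(reaction_id = c("EX_a", "r1", "rblock"),
                       lower_bound = c(-10, 0, 0), upper_bound = c(10, 10, 10)),
    list(c(a = -1), c(a = -1), c(a = -1, dead = 1)),
    objective = "r1")
  expect_error(
    extract_fastcore(md, "rblock", extraction_config("fastcore")),
    "cannot carry flux.*rblock")
})

test_that("FASTCORE output is consistent, contains the core, and is near-minimal", {
  eps <- 1e-4
  checked <- 0
  for (seed in 1:8) {
    m <- random_net(sample(8:12, 1), seed = 600 + seed)
    cons <- fastcc(m, eps)$consistent_reactions
    if (length(cons) < 3) next
    set.seed(seed)
    core <- sample(cons, min(3, length(cons)))
    cfg <- extraction_config("fastcore")
    cfg$protected <- character(0)
    kept <- fluxprint:::fastcore_support(m, core, eps)
    expect_true(all(core %in% kept))
    expect_true(submodel_consistent(m, kept, eps))
    best <- brute_min_consistent_superset(m, core, eps)
    expect_lte(length(kept), best + 2)
    checked <- checked + 1
  }
  expect_gte(checked, 4)
})

test_that("an enlarged FASTCORE core stays fully contained in the result", {
  for (seed in 1:4) {
    m <- random_net(12, seed = 700 + seed)
    cons <- fastcc(m)$consistent_reactions
    if (length(cons) < 4) next
    set.seed(seed)
    core1 <- sample(cons, 2)
    core2 <- union(core1, sample(cons, 2))
    k1 <- fluxprint:::fastcore_support(m, core1, 1e-4)
    k2 <- fluxprint:::fastcore_support(m, core2, 1e-4)
    expect_true(all(core1 %in% k1))
    expect_true(all(core2 %in% k2))
    expect_true(submodel_consistent(m, k2, 1e-4))
  }
})

test_that("every algorithm keeps the protected set and yields consistent, viable models", {
  m <- make_toy_model()
  prot <- protect_reactions(m, reserved_reactions())
  sim <- simulate_expression(m, simulation_design(n_groups = 2,
                                                  n_samples_per_group = 1,
                                                  seed = 77))
  profs <- preprocess_expression(sim$matrix, sim$replicate_groups)
  act <- map_expression(m, profs[[2]])
  for (alg in c("gimme", "imat", "init", "fastcore")) {
    r <- extract_context(m, act, extraction_config(alg, protected = prot))
    expect_true(all(prot %in% r$kept_reactions), info = alg)
    expect_true(all(r$kept_reactions %in% reaction_ids(m)), info = alg)
    # flux-consistent: a second consistency pass removes nothing
    cr <- fastcc(r$context_model)
    expect_length(cr$removed_reactions, 0)
    # biomass stays attainable
    expect_gt(fba(r$context_model)$objective_value, 0)
  }
})

test_that("GIMME/INIT produce larger submodels than iMAT/FASTCORE on average", {
  m <- make_toy_model()
  prot <- protect_reactions(m, reserved_reactions())
  sizes <- c(gimme = 0, imat = 0, init = 0, fastcore = 0)
  n <- 0
  for (seed in 1:2) {
    sim <- simulate_expression(m, simulation_design(n_samples_per_group = 1,
                                                    seed = 800 + seed))
    profs <- preprocess_expression(sim$matrix, sim$replicate_groups)
    for (p in profs) {
      act <- map_expression(m, p)
      for (alg in names(sizes)) {
        r <- extract_context(m, act, extraction_config(alg, protected = prot))
        sizes[alg] <- sizes[alg] + length(r$kept_reactions)
      }
      n <- n + 1
    }
  }
  sizes <- sizes / n
  expect_gte(mean(sizes[c("gimme", "init")]),
             mean(sizes[c("imat", "fastcore")]))
})
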