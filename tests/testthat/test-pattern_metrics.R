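mk_result <- function(model, kept, id) {
  structure(list(sample_id = id, algorithm = "manual",
                 parent_model_id = model$model_id,
                 kept_reactions = kept,
                 context_model = fluxprint:::induced_submodel(model, kept)),
            class = "extraction_result")
}

# two-subsystem fixture model with free reaction names
fixture_model <- function() {
  ids <- c("a", "b", "c", "d", "x")
  metabolic_model(
    "fix",
    data.frame(reaction_id = ids, lower_bound = -10, upper_bound = 10,
               subsystem = c("s1", "s1", "s1", "s1", "s2")),
    lapply(seq_along(ids), function(i) setNames(1, paste0("m", i))),
    objective = "a")
}

test_that("subsystem Jaccard handles identity, disjointness and hand values", {
  m <- fixture_model()
  r1 <- mk_result(m, c("a", "b", "c", "x"), "s1")
  expect_equal(jaccard_subsystem(r1, r1, m)$mean_index, 1)

  r2 <- mk_result(m, c("d"), "s2")
  expect_equal(jaccard_subsystem(r1, r2, m)$mean_index, 0)

  # s1: {a,b,c} vs {b,c,d} -> 2/4 = 0.5; s2: {x} vs {x} -> 1; mean 0.75
  ra <- mk_result(m, c("a", "b", "c", "x"), "A")
  rb <- mk_result(m, c("b", "c", "d", "x"), "B")
  jr <- jaccard_subsystem(ra, rb, m)
  expect_equal(unname(jr$per_subsystem["s1"]), 0.5)
  expect_equal(unname(jr$per_subsystem["s2"]), 1)
  expect_equal(jr$mean_index, 0.75)
})

test_that("Jaccard is symmetric, bounded, and refuses different parents", {
  m <- fixture_model()
  set.seed(9)
  for (i in 1:20) {
    ka <- sample(reaction_ids(m), sample(1:5, 1))
    kb <- sample(reaction_ids(m), sample(1:5, 1))
    ra <- mk_result(m, ka, "a"); rb <- mk_result(m, kb, "b")
    jab <- jaccard_subsystem(ra, rb, m)$mean_index
    jba <- jaccard_subsystem(rb, ra, m)$mean_index
    expect_equal(jab, jba)
    expect_true(jab >= 0 && jab <= 1)
    expect_equal(jaccard_subsystem(ra, ra, m)$mean_index, 1)
  }
  other <- mk_result(fixture_model(), "a", "x")
  other$parent_model_id <- "different"
  expect_error(jaccard_subsystem(mk_result(m, "a", "y"), other, m),
               "different parent models")
})

test_that("Bland-Altman recovers textbook mean, SD, LoA and p-values", {
  # identical vectors
  v <- setNames(rnorm(50), paste0("r", 1:50))
  ba <- bland_altman(v, v)
  expect_equal(ba$mean_difference, 0)
  expect_equal(ba$sd_difference, 0)
  expect_equal(c(ba$loa_low, ba$loa_high), c(0, 0))
  expect_equal(ba$p_value, 1)

  # constant shift of +1 across 100 reactions
  a <- setNames(rnorm(100), paste0("r", 1:100))
  ba2 <- bland_altman(a + 1, a)
  expect_equal(ba2$mean_difference, 1)
  expect_equal(ba2$sd_difference, 0)
  expect_equal(ba2$p_value, 0)

  # gaussian differences: compare against the direct formulas
  set.seed(77)
  base <- setNames(rnorm(1000), paste0("r", 1:1000))
  d <- rnorm(1000, 0.5, 1)
  ba3 <- bland_altman(base + d, base)
  expect_equal(ba3$mean_difference, mean(d), tolerance = 1e-12)
  expect_equal(ba3$sd_difference, sd(d), tolerance = 1e-12)
  expect_equal(ba3$loa_low, mean(d) - 1.96 * sd(d), tolerance = 1e-12)
  expect_equal(ba3$loa_high, mean(d) + 1.96 * sd(d), tolerance = 1e-12)
  expect_equal(ba3$p_value, t.test(d, mu = 0)$p.value, tolerance = 1e-12)
})

test_that("Bland-Altman is antisymmetric and aligns over the reaction union", {
  set.seed(13)
  a <- setNames(rnorm(30), paste0("r", 1:30))
  b <- setNames(rnorm(25), paste0("r", 6:30))  # partial overlap
  ab <- bland_altman(a, b)
  ba <- bland_altman(b, a)
  expect_equal(ab$mean_difference, -ba$mean_difference)
  expect_equal(ab$sd_difference, ba$sd_difference)
  expect_equal(ab$loa_low, -ba$loa_high)
  expect_equal(ab$p_value, ba$p_value)
  expect_equal(ab$n_pairs, 30)  # union, absent entries imputed 0
})

test_that("percent mode drops zero-mean pairs and errors below 3 pairs", {
  a <- c(r1 = 1, r2 = 2, r3 = 0, r4 = 4)
  b <- c(r1 = 2, r2 = 1, r3 = 0, r4 = 2)
  ba <- bland_altman(a, b, mode = "percent")
  expect_equal(ba$n_dropped, 1)  # r3 has mean 0
  expect_equal(ba$n_pairs, 3)
  # d = 100 * (a - b) / mean
  expect_equal(sort(unname(ba$differences)),
               sort(100 * c(-1 / 1.5, 1 / 1.5, 2 / 3)))
  expect_error(bland_altman(c(r1 = 1, r2 = 1), c(r1 = 2, r2 = 0)),
               "fewer than 3")
})

test_that("disagreement fractions cover the degenerate pair counts", {
  v <- setNames(rnorm(20), paste0("r", 1:20))
  same <- list(a = v, b = v, c = v)
  dm <- disagreement_matrix(same)
  expect_equal(dm$percent_disagreement, 0)
  expect_equal(nrow(dm$table), 3)

  two <- list(a = v, b = v + 1)
  dm2 <- disagreement_matrix(two)
  expect_true(dm2$percent_disagreement %in% c(0, 100))
  expect_equal(dm2$percent_disagreement, 100)  # constant shift: p = 0
})

test_that("planted group shifts produce detectable pairwise disagreement", {
  # two groups of flux states with a systematic offset on many reactions
  set.seed(55)
  base <- setNames(rnorm(60), paste0("r", 1:60))
  states <- c(
    lapply(1:4, function(i) base + rnorm(60, 0, 0.05)),
    lapply(1:4, function(i) base + 0.5 + rnorm(60, 0, 0.05)))
  names(states) <- paste0("s", 1:8)
  dm <- disagreement_matrix(states)
  cross <- with(dm$table, xor(sample_i %in% paste0("s", 1:4),
                              sample_j %in% paste0("s", 1:4)))
  expect_true(all(dm$table$significant[cross]))
  expect_false(any(dm$table$significant[!cross]))
})
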