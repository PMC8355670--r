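# Synthetic-data generator: locations, entropy control, generative law,
# experiment presets, round-trips.

test_that("locations are uniform in the region and reproducible", {
  set.seed(1)
  loc <- simulate_locations(500, c(0, 2, -1, 1))
  expect_true(all(loc$x >= 0 & loc$x <= 2))
  expect_true(all(loc$y >= -1 & loc$y <= 1))
  expect_lt(abs(mean(loc$x) - 1), 3 * 2 / sqrt(12 * 500)) # 3 MC sigmas
  set.seed(9)
  l1 <- simulate_locations(50)
  set.seed(9)
  l2 <- simulate_locations(50)
  expect_identical(l1, l2)
})

test_that("lower concentration yields lower expected entropy", {
  set.seed(2)
  h_low <- mean(apply(simulate_probability_vectors(3, 0.1, n = 1000), 1,
                      sprachbund:::shannon_entropy))
  h_high <- mean(apply(simulate_probability_vectors(3, 10, n = 1000), 1,
                       sprachbund:::shannon_entropy))
  expect_lt(h_low, h_high)
  v <- simulate_probability_vectors(4, 100)
  expect_equal(sum(v), 1, tolerance = 1e-12)
  expect_true(all(v > 0))
})

test_that("all-universal weights reproduce alpha in the long run", {
  rz <- list(n_entities = 3000, n_states = 3L, families = list(),
             areas = list(), w = matrix(c(1, 0, 0), 1, 3),
             alpha = list(c(0.2, 0.3, 0.5)), beta = list(), gamma = list())
  set.seed(3)
  X <- simulate_features(rz)
  freq <- tabulate(X[, 1], 3) / 3000
  expect_lt(max(abs(freq - c(0.2, 0.3, 0.5))), 3 * sqrt(0.25 / 3000))
})

test_that("a deterministic contact vector forces a constant column in-area", {
  rz <- list(n_entities = 10, n_states = 2L, families = list(),
             areas = list(1:4), w = matrix(c(0, 0, 1), 1, 3),
             alpha = list(c(0.5, 0.5)), beta = list(),
             gamma = list(list(c(0, 1))))
  set.seed(4)
  X <- simulate_features(rz)
  expect_true(all(X[1:4, 1] == 2L))
})

test_that("component-then-state sampling matches the marginal mixture law", {
  # one in-family, in-area entity; mixture probabilities from the cell formula
  w <- c(0.2, 0.3, 0.5)
  alpha <- c(0.1, 0.6, 0.3)
  beta <- c(0.7, 0.2, 0.1)
  gamma <- c(0.05, 0.05, 0.9)
  p_marg <- w[1] * alpha + w[2] * beta + w[3] * gamma
  rz <- list(n_entities = 1, n_states = 3L, families = list(1L),
             areas = list(1L), w = matrix(w, 1, 3), alpha = list(alpha),
             beta = list(list(beta)), gamma = list(list(gamma)))
  set.seed(5)
  draws <- vapply(1:10000, function(i) simulate_features(rz)[1, 1], 0L)
  tab <- tabulate(draws, 3)
  expect_gt(chisq.test(tab, p = p_marg)$p.value, 1e-3)
})

test_that("simulated datasets regenerate bit-identically from their seed", {
  spec <- scenario_spec(n_entities = 40, n_features = 6, families = list(8),
                        areas = list(6), seed = 11)
  s1 <- simulate_dataset(spec)
  s2 <- simulate_dataset(spec)
  expect_identical(s1$dataset$X, s2$dataset$X)
  expect_identical(s1$truth, s2$truth)
})

test_that("synthetic datasets round-trip through the writers and readers", {
  spec <- scenario_spec(n_entities = 30, n_features = 5, families = list(6),
                        areas = list(5), missing_rate = 0.1, seed = 12)
  synth <- simulate_dataset(spec)
  dir <- withr::local_tempdir()
  write_synth(synth, dir)
  ft <- read_feature_table(file.path(dir, "features.csv"),
                           states = synth$dataset$states)
  loc <- read_locations(file.path(dir, "locations.csv"))
  d2 <- sb_dataset(ft, loc, coord = "planar")
  expect_identical(unname(d2$X), unname(synth$dataset$X))
  expect_identical(d2$states, synth$dataset$states)
  expect_identical(d2$entities$family, synth$dataset$entities$family)
  expect_equal(d2$entities$x, synth$dataset$entities$x, tolerance = 1e-12)
})

test_that("experiment presets realize their planted structure", {
  e3 <- make_experiment("exp3", scale = 0.1, seed = 3)
  expect_length(e3$truth$areas, 2)
  expect_length(intersect(e3$truth$areas[[1]], e3$truth$areas[[2]]), 0)
  expect_length(e3$truth$families, 0)

  e1 <- make_experiment("exp1", scale = 0.1, seed = 4)
  expect_equal(nrow(e1$dataset$X), 95) # ~0.1 * 951
  expect_equal(ncol(e1$dataset$X), 30) # features preserved
  expect_length(e1$truth$areas, 3)

  e2 <- make_experiment("exp2", scale = 0.1, seed = 5)
  expect_length(intersect(e2$truth$families[[1]], e2$truth$areas[[1]]), 0)
  expect_false(setequal(e2$truth$families[[1]], e2$truth$areas[[1]]))

  e4 <- make_experiment("exp4", scale = 0.1, seed = 6)
  expect_true(all(e4$truth$areas[[1]] %in% e4$subsample))
  expect_length(e4$prior_counts, 30)

  expect_error(make_experiment("exp1", scale = 0.004, seed = 1),
               "below 2 members")
})

test_that("requested entropy ordering is realized in the drawn vectors", {
  e2 <- make_experiment("exp2", scale = 0.1, seed = 7)
  h_beta <- mean(vapply(e2$truth$beta[[1]], sprachbund:::shannon_entropy, 0))
  h_gamma <- mean(vapply(e2$truth$gamma[[1]], sprachbund:::shannon_entropy, 0))
  expect_lt(h_beta, h_gamma) # inheritance stronger than contact
})
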