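# Mixture likelihood: effective weights, per-cell probabilities, joint
# log-likelihood, and its invariants.

test_that("effective weights zero inapplicable components and re-normalize", {
  expect_equal(effective_weights(c(0.2, 0.3, 0.5), TRUE, FALSE),
               c(0.4, 0.6, 0))
  expect_equal(effective_weights(c(0.2, 0.3, 0.5), TRUE, TRUE),
               c(0.2, 0.3, 0.5))
  expect_equal(effective_weights(c(0.2, 0.3, 0.5), FALSE, FALSE),
               c(1, 0, 0))
  # all applicable mass zero -> universal fallback
  expect_equal(effective_weights(c(0, 0, 1), TRUE, FALSE), c(1, 0, 0))
  expect_error(effective_weights(c(-0.1, 0.6, 0.5), TRUE, TRUE),
               "non-negative")
})

test_that("cell likelihood evaluates the three-component mixture", {
  expect_equal(cell_likelihood(1, alpha = c(0.3, 0.7),
                               weights = c(1, 0, 0)), 0.3)
  expect_equal(cell_likelihood(1, alpha = c(0.1, 0.9), beta = c(0.4, 0.6),
                               gamma = c(0.8, 0.2),
                               weights = c(0.2, 0.3, 0.5)), 0.54)
  expect_equal(cell_likelihood(1, alpha = c(0.5, 0.5), beta = c(0.5, 0.5),
                               gamma = c(0.5, 0.5),
                               weights = c(0.1, 0.2, 0.7)), 0.5)
  expect_error(cell_likelihood(3, alpha = c(0.5, 0.5),
                               weights = c(1, 0, 0)),
               "out of range")
})

test_that("uniform all-universal model has closed-form log-likelihood", {
  d <- fixture_dataset(L = 10, F_ = 4, n_states = 2, n_fam = 0, seed = 1)
  st <- random_state(d, K = 0, seed = 1)
  for (f in 1:4) st$alpha[[f]] <- c(0.5, 0.5)
  st$w <- matrix(rep(c(1, 0, 0), each = 4), 4, 3)
  expect_equal(data_log_likelihood(d, st), -40 * log(2))
})

test_that("log-likelihood equals the per-cell product oracle", {
  for (i in 1:8) {
    d <- fixture_dataset(L = 10, F_ = 4, seed = i, n_fam = 2,
                         missing_rate = 0.1)
    st <- random_state(d, K = 1, area_size = 3, seed = i + 50)
    expect_equal(data_log_likelihood(d, st), naive_loglik(d, st),
                 tolerance = 1e-12)
  }
})

test_that("an all-missing dataset has log-likelihood 0", {
  d <- fixture_dataset(L = 5, F_ = 3, seed = 2, n_fam = 1)
  st <- random_state(d, K = 0, seed = 3)
  d$X[] <- NA_integer_
  expect_equal(data_log_likelihood(d, st), 0)
})

test_that("cell mixture is normalized over states for random parameters", {
  set.seed(11)
  for (i in 1:20) {
    n <- sample(2:4, 1)
    rdir <- function(k) {
      x <- rgamma(k, 1)
      x / sum(x)
    }
    a <- rdir(n); b <- rdir(n); g <- rdir(n); w <- rdir(3)
    tot <- sum(vapply(seq_len(n), function(s) {
      cell_likelihood(s, a, b, g, w)
    }, 0))
    expect_equal(tot, 1, tolerance = 1e-12)
  }
})

test_that("log-likelihood is invariant to entity and feature ordering", {
  d <- fixture_dataset(L = 8, F_ = 4, seed = 5, n_fam = 2)
  st <- random_state(d, K = 1, area_size = 3, seed = 6)
  base <- data_log_likelihood(d, st)
  set.seed(8)
  perm_e <- sample(8)
  perm_f <- sample(4)
  d2 <- d
  d2$X <- d$X[perm_e, perm_f]
  d2$entities <- d$entities[perm_e, ]
  d2$states <- d$states[perm_f]
  st2 <- st
  st2$areas <- lapply(st$areas, function(a) match(a, perm_e))
  st2$w <- st$w[perm_f, ]
  st2$alpha <- st$alpha[perm_f]
  st2$beta <- lapply(st$beta, function(b) b[perm_f])
  st2$gamma <- lapply(st$gamma, function(g) g[perm_f])
  expect_equal(data_log_likelihood(d2, st2), base, tolerance = 1e-10)
})

test_that("likelihood is non-decreasing as the contact vector sharpens", {
  # one feature, planted area whose members all share state 1
  d <- fixture_dataset(L = 6, F_ = 1, n_states = 2, n_fam = 0, seed = 9)
  d$X[, 1] <- c(1L, 1L, 1L, 2L, 2L, 1L)
  st <- random_state(d, K = 0, seed = 4)
  st$areas <- list(1:3)
  st$gamma <- list(list(c(0.5, 0.5)))
  st$w <- matrix(c(0.3, 0, 0.7), 1, 3)
  lls <- vapply(c(0.5, 0.7, 0.9, 0.99, 0.999), function(p) {
    st$gamma[[1]][[1]] <- c(p, 1 - p)
    data_log_likelihood(d, st)
  }, 0)
  expect_true(all(diff(lls) >= 0))
})

test_that("zero-probability cells flag -Inf", {
  d <- fixture_dataset(L = 4, F_ = 2, n_states = 2, n_fam = 0, seed = 3)
  d$X[1, 1] <- 1L
  st <- random_state(d, K = 0, seed = 2)
  st$w <- matrix(rep(c(1, 0, 0), each = 2), 2, 3)
  st$alpha[[1]] <- c(0, 1)
  ll <- data_log_likelihood(d, st)
  expect_identical(as.numeric(ll), -Inf)
  expect_true(isTRUE(attr(ll, "zero_cell")))
})
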