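# Proposals, initialization, caches, reproducibility, and a detailed-balance
# smoke test on an enumerable state space.

test_that("simplex proposals stay on the simplex and target correctly", {
  set.seed(4)
  for (i in 1:50) {
    cur <- sprachbund:::rdirichlet1(c(2, 2, 2))
    pr <- propose_simplex(cur, kappa = 30)
    expect_equal(sum(pr$value), 1, tolerance = 1e-12)
    expect_true(all(pr$value >= 0))
  }
  # MH chain targeting Dir(3, 1) with this proposal: E[x1] = 0.75
  set.seed(5)
  x <- c(0.5, 0.5)
  target <- function(v) sprachbund:::ddirichlet_log(v, c(3, 1))
  acc <- 0
  sums <- 0
  n <- 20000
  for (i in seq_len(n)) {
    pr <- propose_simplex(x, kappa = 10)
    logr <- target(pr$value) - target(x) + pr$log_hastings
    if (is.finite(logr) && log(runif(1)) < logr) {
      x <- pr$value
      acc <- acc + 1
    }
    sums <- sums + x[1]
  }
  expect_gt(acc / n, 0.1)
  expect_lt(abs(sums / n - 0.75), 0.02)
})

test_that("initial states are reproducible and respect structure", {
  d <- fixture_dataset(L = 100, F_ = 5, seed = 1, n_fam = 2)
  pr <- prior_spec(d)
  set.seed(7)
  s1 <- init_state(d, pr, K = 2)
  set.seed(7)
  s2 <- init_state(d, pr, K = 2)
  expect_identical(s1, s2)
  expect_length(s1$areas, 2)
  expect_equal(lengths(s1$areas), c(3L, 3L)) # m_init = m_min
  expect_length(intersect(s1$areas[[1]], s1$areas[[2]]), 0)
  s0 <- init_state(d, pr, K = 0)
  expect_length(s0$areas, 0)
  d_small <- fixture_dataset(L = 5, F_ = 3, seed = 2, n_fam = 0)
  expect_error(init_state(d_small, prior_spec(d_small, m_max = 4), K = 2),
               "exceeds the number of entities")
})

test_that("the legal move menu respects the size bounds", {
  legal <- sprachbund:::legal_area_moves
  expect_false("grow" %in% legal(m = 10, n_un = 5, m_min = 3, m_max = 10))
  expect_false("shrink" %in% legal(m = 3, n_un = 5, m_min = 3, m_max = 10))
  expect_false("grow" %in% legal(m = 5, n_un = 0, m_min = 3, m_max = 10))
  expect_setequal(legal(m = 5, n_un = 5, m_min = 3, m_max = 10),
                  c("grow", "shrink", "swap"))
})

test_that("sampled areas always satisfy disjointness and size bounds", {
  d <- fixture_dataset(L = 30, F_ = 4, seed = 3, n_fam = 1)
  pr <- prior_spec(d, m_min = 3, m_max = 8)
  cfg <- sampler_config(n_steps = 4000, n_retained = 200, seed = 2,
                        anneal_T0 = 2)
  tr <- run_chain(d, pr, K = 2, config = cfg)
  for (st in tr$samples) {
    sizes <- lengths(st$areas)
    expect_true(all(sizes >= 3 & sizes <= 8))
    expect_equal(anyDuplicated(unlist(st$areas)), 0L)
    for (k in 1:2) {
      for (f in seq_along(st$gamma[[k]])) {
        expect_true(all(st$gamma[[k]][[f]] > 0))
        expect_equal(sum(st$gamma[[k]][[f]]), 1, tolerance = 1e-9)
      }
    }
  }
})

test_that("incremental caches agree with full recomputation after many steps", {
  d <- fixture_dataset(L = 40, F_ = 6, seed = 5, n_fam = 2,
                       missing_rate = 0.1)
  pr <- prior_spec(d)
  cfg <- sampler_config(n_steps = 2000, n_retained = 100, seed = 9)
  set.seed(9)
  ctx <- sampler_context(d, pr, K = 1, cfg)
  for (i in 1:2000) mh_step(ctx)
  parts <- ctx_log_posterior_parts(ctx)
  st <- ctx_state(ctx)
  expect_equal(unname(parts["log_likelihood"]), data_log_likelihood(d, st),
               tolerance = 1e-9)
  expect_equal(unname(parts["log_prior"]), log_prior(st, pr, d),
               tolerance = 1e-9)
})

test_that("chains are bit-reproducible from the seed", {
  d <- fixture_dataset(L = 25, F_ = 4, seed = 6, n_fam = 1)
  pr <- prior_spec(d)
  cfg <- sampler_config(n_steps = 3000, n_retained = 150, seed = 123)
  t1 <- run_chain(d, pr, K = 1, config = cfg)
  t2 <- run_chain(d, pr, K = 1, config = cfg)
  expect_identical(t1$ll, t2$ll)
  expect_identical(t1$samples[[150]], t2$samples[[150]])
  expect_equal(length(t1$ll), 150)
  expect_equal(t1$deviance, -2 * t1$ll)
})

test_that("a K = 0 chain runs the pure confounder model", {
  d <- fixture_dataset(L = 20, F_ = 3, seed = 7, n_fam = 0)
  pr <- prior_spec(d)
  cfg <- sampler_config(n_steps = 2000, n_retained = 100, seed = 4)
  tr <- run_chain(d, pr, K = 0, config = cfg)
  expect_length(tr$samples[[1]]$areas, 0)
  expect_false("area" %in% tr$accept$op)
  expect_false("gamma" %in% tr$accept$op)
})

test_that("area chain with fixed tables matches exhaustive enumeration", {
  # 4 entities, 2 binary features, K = 1, sizes in [2, 3]: 10 legal states.
  d <- fixture_dataset(L = 4, F_ = 2, n_states = 2, n_fam = 0, seed = 8)
  d$X[, 1] <- c(1L, 1L, 2L, 2L)
  d$X[, 2] <- c(1L, 2L, 1L, 2L)
  pr <- prior_spec(d, m_min = 2, m_max = 3)
  st <- random_state(d, K = 1, area_size = 2, seed = 10)
  st$w <- matrix(rep(c(0.3, 0, 0.7), each = 2), 2, 3)
  st$alpha <- list(c(0.4, 0.6), c(0.7, 0.3))
  st$gamma <- list(list(c(0.9, 0.1), c(0.2, 0.8)))

  legal <- c(utils::combn(4, 2, simplify = FALSE),
             utils::combn(4, 3, simplify = FALSE))
  log_post <- vapply(legal, function(a) {
    s <- st
    s$areas <- list(a)
    data_log_likelihood(d, s) + size_prior_log(length(a), pr)
  }, 0)
  post <- exp(log_post - max(log_post))
  post <- post / sum(post)

  cfg <- sampler_config(n_steps = 100000, n_retained = 45000, seed = 3,
                        burn_in = 0.1, anneal_T0 = 1, p_relocate = 0,
                        fix = c("weights", "alpha", "gamma"))
  tr <- run_chain(d, pr, K = 1, config = cfg, init = st)
  key <- vapply(legal, function(a) paste(a, collapse = "-"), "")
  got <- vapply(tr$samples,
                function(s) paste(sort(s$areas[[1]]), collapse = "-"), "")
  freq <- as.vector(table(factor(got, levels = key))) / length(got)
  expect_lt(max(abs(freq - post)), 0.05) # total-variation smoke bound
})
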