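# Dirichlet pseudocounts, empirical priors, geo-prior, size prior.

test_that("pseudocounts follow 1 + mu * rho", {
  expect_equal(pseudocounts_from_prior(c(0.5, 0.5), 0), c(1, 1))
  expect_equal(pseudocounts_from_prior(c(0.2, 0.8), 10), c(3, 9))
  expect_equal(pseudocounts_from_prior(rep(1 / 3, 3), 30), c(11, 11, 11))
  expect_error(pseudocounts_from_prior(c(0.5, 0.6), 1), "sum to 1")
  expect_error(pseudocounts_from_prior(c(0.5, 0.5), -1), ">= 0")
})

test_that("empirical priors use sample frequencies, with uniform fallback", {
  psi <- empirical_prior_from_sample(list(f1 = c(8, 2)), rho = 10)
  expect_equal(psi$f1, c(9, 3))
  psi2 <- empirical_prior_from_sample(list(f1 = c(5, 5)), rho = 7)
  expect_equal(psi2$f1[1], psi2$f1[2])
  expect_warning(psi3 <- empirical_prior_from_sample(list(f1 = c(0, 0, 0))),
                 "absent from prior sample")
  expect_equal(psi3$f1, c(1, 1, 1))
})

test_that("area cost: MST of collinear points and the single-edge case", {
  cost <- as.matrix(dist(cbind(c(0, 1, 3), 0)))
  expect_equal(area_cost(1:3, cost, "mst"), 1.5) # edges 1 and 2
  expect_equal(area_cost(1:2, cost, "mst"), 1)
  expect_equal(area_cost(1:2, cost, "complete"), 1)
  expect_equal(area_cost(2, cost, "mst"), 0) # singleton
})

test_that("MST mean cost matches brute-force spanning-tree enumeration", {
  set.seed(21)
  for (i in 1:10) {
    n <- sample(4:6, 1)
    pts <- cbind(runif(n), runif(n))
    cost <- as.matrix(dist(pts))
    expect_equal(area_cost(seq_len(n), cost, "mst"),
                 brute_force_mst_mean(cost), tolerance = 1e-12)
  }
})

test_that("MST mean cost agrees with igraph on larger instances", {
  skip_if_not_installed("igraph")
  set.seed(31)
  pts <- cbind(runif(12), runif(12))
  cost <- as.matrix(dist(pts))
  g <- igraph::graph_from_adjacency_matrix(cost, mode = "undirected",
                                           weighted = TRUE)
  mst <- igraph::mst(g)
  expect_equal(area_cost(1:12, cost, "mst"),
               sum(igraph::E(mst)$weight) / 11, tolerance = 1e-12)
})

test_that("MST linkage never exceeds complete linkage", {
  set.seed(13)
  for (i in 1:10) {
    n <- sample(3:8, 1)
    cost <- as.matrix(dist(cbind(runif(n), runif(n))))
    expect_lte(area_cost(seq_len(n), cost, "mst"),
               area_cost(seq_len(n), cost, "complete") + 1e-12)
  }
})

test_that("delaunay linkage works and falls back to MST when collinear", {
  loc <- data.frame(x = c(0, 1, 0, 1), y = c(0, 0, 1, 1))
  cost <- as.matrix(dist(loc))
  dl <- area_cost(1:4, cost, "delaunay", locations = loc)
  expect_true(is.finite(dl) && dl > 0)
  col <- data.frame(x = c(0, 1, 3), y = c(0, 0, 0))
  cost_c <- as.matrix(dist(col))
  expect_warning(dc <- area_cost(1:3, cost_c, "delaunay", locations = col),
                 "collinear")
  expect_equal(dc, 1.5)
})

test_that("geo-prior log follows the exponential-decay and overlap rules", {
  cost <- as.matrix(dist(cbind(c(0, 1, 3, 7), 0)))
  spec0 <- geo_prior_spec("cost_based", lambda = 0, cost = cost)
  expect_equal(geo_prior_log(list(1:2, 3:4), spec0), 0)
  # one area with mean MST edge cost 1.5 at lambda 2 -> -3
  spec2 <- geo_prior_spec("cost_based", lambda = 2, cost = cost)
  expect_equal(geo_prior_log(list(1:3), spec2), -3)
  expect_identical(geo_prior_log(list(1:3, 3:4), spec2), -Inf)
  expect_identical(geo_prior_log(list(1:2, 2:3),
                                 geo_prior_spec("uniform")), -Inf)
  expect_equal(geo_prior_log(list(1:2), geo_prior_spec("uniform")), 0)
})

test_that("cost-based geo-prior is strictly decreasing in lambda", {
  cost <- as.matrix(dist(cbind(runif(6), runif(6))))
  lps <- vapply(c(0.5, 1, 2, 4), function(l) {
    geo_prior_log(list(1:4), geo_prior_spec("cost_based", l, cost = cost))
  }, 0)
  expect_true(all(diff(lps) < 0))
})

test_that("adding a distant entity cannot raise the cost-based geo-prior", {
  set.seed(3)
  pts <- cbind(runif(8, 0, 0.2), runif(8, 0, 0.2))
  pts <- rbind(pts, c(5, 5)) # far-away entity 9
  cost <- as.matrix(dist(pts))
  spec <- geo_prior_spec("cost_based", lambda = 1, cost = cost)
  expect_lt(geo_prior_log(list(c(1:8, 9L)), spec),
            geo_prior_log(list(1:8), spec))
})

test_that("prior is invariant to entity relabeling", {
  set.seed(17)
  pts <- cbind(runif(10), runif(10))
  cost <- as.matrix(dist(pts))
  spec <- geo_prior_spec("cost_based", lambda = 1.3, cost = cost)
  perm <- sample(10)
  cost_p <- cost[perm, perm]
  spec_p <- geo_prior_spec("cost_based", lambda = 1.3, cost = cost_p)
  area <- c(2L, 5L, 9L)
  expect_equal(geo_prior_log(list(area), spec),
               geo_prior_log(list(match(area, perm)), spec_p),
               tolerance = 1e-12)
})

test_that("joint log-prior combines Dirichlet terms, geo and size priors", {
  d <- fixture_dataset(L = 10, F_ = 3, n_states = 2, n_fam = 0, seed = 2)
  pr <- prior_spec(d, m_min = 3, size_prior = "uniform_configs")
  st <- random_state(d, K = 0, seed = 5)
  # uniform psi everywhere: each vector contributes log Gamma(N)
  expected <- 3 * (lgamma(3) + lgamma(2)) # weights Dir(1,1,1) + alpha Dir(1,1)
  expect_equal(log_prior(st, pr, d), expected, tolerance = 1e-12)
  # one Dir(2,2) alpha at (0.5, 0.5) contributes log 1.5
  pr2 <- prior_spec(d, psi_alpha = 2, size_prior = "uniform_configs")
  st2 <- st
  for (f in 1:3) st2$alpha[[f]] <- c(0.5, 0.5)
  expect_equal(log_prior(st2, pr2, d), 3 * lgamma(3) + 3 * log(1.5),
               tolerance = 1e-12)
  # size bound violation
  st3 <- random_state(d, K = 1, area_size = 2, seed = 6) # below m_min = 3
  expect_identical(log_prior(st3, pr, d), -Inf)
})

test_that("uniform-size prior charges -log choose(L, m) per area", {
  d <- fixture_dataset(L = 10, F_ = 3, n_states = 2, n_fam = 0, seed = 2)
  pr_u <- prior_spec(d, m_min = 3, size_prior = "uniform_size")
  pr_c <- prior_spec(d, m_min = 3, size_prior = "uniform_configs")
  st <- random_state(d, K = 1, area_size = 4, seed = 5)
  expect_equal(log_prior(st, pr_u, d),
               log_prior(st, pr_c, d) - lchoose(10, 4), tolerance = 1e-12)
  expect_equal(size_prior_log(4, pr_u), -lchoose(10, 4))
  expect_identical(size_prior_log(2, pr_u), -Inf)
})
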