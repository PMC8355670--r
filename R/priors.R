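# Priors: Dirichlet priors on weights and probability vectors (with optional
# empirical pseudocounts), cost-based geo-prior on area configurations, and a
# uniform-in-bounds prior on area sizes.

#' Dirichlet pseudocounts from a prior mean and precision
#'
#' Converts a prior mean `mu` (probability vector over the states of a
#' feature) and a precision `rho` into Dirichlet pseudocounts
#' `psi_n = 1 + mu_n * rho`. With `rho = 0` this is the uniform prior
#' `(1, ..., 1)`; larger `rho` concentrates the prior around `mu`.
#'
#' @param mu probability vector (prior mean).
#' @param rho non-negative precision.
#' @return Pseudocount vector of the same length as `mu`.
#' @export
#' @examples
#' pseudocounts_from_prior(c(0.2, 0.8), rho = 10) # c(3, 9)
pseudocounts_from_prior <- function(mu, rho) {
  check_simplex(mu, "prior mean mu")
  if (!is_number(rho) || rho < 0) stop("precision rho must be >= 0")
  1 + mu * rho
}

#' Empirical Dirichlet prior from a sample of state counts
#'
#' Sets the prior mean of each feature to the relative state frequencies in
#' an external sample (e.g. a stratified global sample of languages) and
#' converts it to pseudocounts with [pseudocounts_from_prior()]. Features
#' with no observations in the sample fall back to the uniform prior with a
#' warning.
#'
#' @param counts named list: feature -> non-negative count vector over that
#'   feature's states.
#' @param rho precision (default 10, a weakly informative prior).
#' @return Named list of pseudocount vectors.
#' @export
empirical_prior_from_sample <- function(counts, rho = 10) {
  out <- vector("list", length(counts))
  names(out) <- names(counts)
  for (f in names(counts)) {
    cts <- counts[[f]]
    if (any(cts < 0)) stop("negative counts for feature '", f, "'")
    tot <- sum(cts)
    if (tot == 0) {
      warning("feature '", f,
              "' absent from prior sample; using uniform prior")
      out[[f]] <- rep(1, length(cts))
    } else {
      out[[f]] <- pseudocounts_from_prior(cts / tot, rho)
    }
  }
  out
}

#' Specify the geographic prior on areas
#'
#' The cost-based geo-prior makes the prior probability of an area decay
#' exponentially with its average linkage cost `c_k`:
#' `P(Z_k) propto exp(-lambda * c_k)`, and truncates the product over areas
#' to disjoint configurations. With `lambda = 0` (or `type = "uniform"`) it
#' is uniform over disjoint configurations.
#'
#' @param type `"uniform"` or `"cost_based"`.
#' @param lambda non-negative decay rate (per cost unit).
#' @param linkage `"mst"` (mean edge cost of the minimum spanning tree,
#'   default), `"delaunay"` (mean cost of Delaunay-triangulation edges among
#'   the members) or `"complete"` (mean cost over all member pairs).
#' @param cost optional cost matrix (see [build_cost_matrix()]); if omitted
#'   it is built from the dataset when sampling starts.
#' @return An object of class `sb_geo_prior`.
#' @export
geo_prior_spec <- function(type = c("uniform", "cost_based"), lambda = 0,
                           linkage = c("mst", "delaunay", "complete"),
                           cost = NULL) {
  type <- match.arg(type)
  linkage <- match.arg(linkage)
  if (!is_number(lambda) || lambda < 0) stop("lambda must be finite and >= 0")
  if (!is.null(cost) && !isTRUE(all.equal(cost, t(cost)))) {
    stop("cost matrix must be symmetric")
  }
  structure(list(type = type, lambda = lambda, linkage = linkage,
                 cost = cost),
            class = "sb_geo_prior")
}

#' Average linkage cost of an area
#'
#' @param members integer indices of the area's entities.
#' @param cost symmetric cost matrix over all entities.
#' @param linkage see [geo_prior_spec()].
#' @param locations data frame with `x`/`y` columns; required for
#'   `linkage = "delaunay"`.
#' @return Mean edge cost (0 for a singleton area). For `"delaunay"` with
#'   collinear member locations the MST linkage is used instead, with a
#'   warning.
#' @export
area_cost <- function(members, cost, linkage = c("mst", "delaunay",
                                                 "complete"),
                      locations = NULL) {
  linkage <- match.arg(linkage)
  m <- length(members)
  if (m <= 1L) {
    return(0)
  }
  cm <- cost[members, members, drop = FALSE]
  switch(linkage,
    mst = mst_total_cost(cm) / (m - 1L),
    complete = sum(cm[upper.tri(cm)]) / (m * (m - 1L) / 2L),
    delaunay = {
      if (is.null(locations)) {
        stop("delaunay linkage needs entity locations")
      }
      pts <- cbind(locations$x[members], locations$y[members])
      edges <- delaunay_edges(pts)
      if (is.null(edges)) {
        warning("degenerate (collinear) locations; falling back to MST linkage")
        return(mst_total_cost(cm) / (m - 1L))
      }
      mean(cm[edges])
    })
}

#' Log geo-prior of an area configuration (unnormalized)
#'
#' @param areas list of integer membership vectors.
#' @param spec an `sb_geo_prior` with its `cost` matrix set (a cost matrix is
#'   required for the cost-based type).
#' @param locations locations data frame (only for Delaunay linkage).
#' @return 0 or `-lambda * sum(c_k)` for disjoint configurations, `-Inf`
#'   when any two areas overlap.
#' @export
geo_prior_log <- function(areas, spec, locations = NULL) {
  all_members <- unlist(areas, use.names = FALSE)
  if (anyDuplicated(all_members)) {
    return(-Inf)
  }
  if (spec$type == "uniform" || spec$lambda == 0) {
    return(0)
  }
  if (is.null(spec$cost)) stop("cost-based geo-prior needs a cost matrix")
  lp <- 0
  for (k in seq_along(areas)) {
    lp <- lp - spec$lambda * area_cost(areas[[k]], spec$cost, spec$linkage,
                                       locations)
  }
  lp
}

#' Assemble the full prior specification
#'
#' Bundles Dirichlet pseudocounts for every probability vector, the geo-prior
#' and the bounds of the (uniform-in-bounds) area-size prior. Defaults are
#' the uniform prior `psi = (1, ..., 1)` everywhere, a uniform geo-prior and
#' size bounds `[3, min(50, L - 1)]`.
#'
#' @param dataset an `sb_dataset` (supplies feature state counts and family
#'   labels).
#' @param psi_weights pseudocount triple for every per-feature weight vector
#'   (length 3), or a features x 3 matrix.
#' @param psi_alpha named list of pseudocount vectors per feature (e.g. from
#'   [empirical_prior_from_sample()]); a single number means symmetric
#'   pseudocounts.
#' @param psi_beta either a named list per family of per-feature pseudocount
#'   lists, a single per-feature list applied to all families, or a number.
#' @param psi_gamma per-feature pseudocounts for the contact vectors (same
#'   slot is used for every area), or a number.
#' @param geo an `sb_geo_prior` from [geo_prior_spec()].
#' @param m_min,m_max integer bounds on area size, `2 <= m_min <= m_max <= L`.
#' @param size_prior `"uniform_size"` (default): every area size in
#'   `[m_min, m_max]` is equally likely a priori and membership is uniform
#'   given the size, so an area of size `m` contributes
#'   `-log choose(L, m)`. `"uniform_configs"` instead makes every
#'   membership configuration equally likely (contributing 0 within
#'   bounds); note that this implicitly concentrates prior mass on large
#'   areas, since there are vastly more of them, and lets a cluster absorb
#'   weakly-fitting languages essentially for free.
#' @return An object of class `sb_priors`.
#' @export
prior_spec <- function(dataset, psi_weights = c(1, 1, 1), psi_alpha = 1,
                       psi_beta = 1, psi_gamma = 1,
                       geo = geo_prior_spec("uniform"),
                       m_min = 3L, m_max = NULL,
                       size_prior = c("uniform_size", "uniform_configs")) {
  size_prior <- match.arg(size_prior)
  nst <- lengths(dataset$states)
  F_ <- length(nst)
  L <- nrow(dataset$X)
  if (is.null(m_max)) m_max <- min(50L, L - 1L)
  m_min <- as.integer(m_min)
  m_max <- as.integer(m_max)
  if (m_min < 2L || m_min > m_max || m_max > L) {
    stop("size bounds must satisfy 2 <= m_min <= m_max <= number of entities")
  }

  expand_per_feature <- function(psi, what) {
    if (is.numeric(psi) && length(psi) == 1L) {
      psi <- lapply(nst, function(n) rep(psi, n))
      names(psi) <- names(dataset$states)
    }
    if (!is.list(psi) || length(psi) != F_) {
      stop(what, " must be one number or a list with one vector per feature")
    }
    if (is.null(names(psi))) names(psi) <- names(dataset$states)
    psi <- psi[names(dataset$states)]
    for (f in seq_len(F_)) {
      if (length(psi[[f]]) != nst[f] || any(psi[[f]] <= 0)) {
        stop(what, ": pseudocounts for feature '", names(nst)[f],
             "' must be ", nst[f], " positive values")
      }
    }
    psi
  }

  if (is.matrix(psi_weights)) {
    if (nrow(psi_weights) != F_ || ncol(psi_weights) != 3L) {
      stop("psi_weights matrix must be features x 3")
    }
    w_psi <- psi_weights
  } else {
    if (length(psi_weights) != 3L || any(psi_weights <= 0)) {
      stop("psi_weights must be 3 positive values")
    }
    w_psi <- matrix(psi_weights, nrow = F_, ncol = 3L, byrow = TRUE)
  }

  a_psi <- expand_per_feature(psi_alpha, "psi_alpha")
  g_psi <- expand_per_feature(psi_gamma, "psi_gamma")
  n_fam <- length(dataset$families)
  if (is.list(psi_beta) && n_fam > 0 &&
      !is.null(names(psi_beta)) &&
      all(names(psi_beta) %in% dataset$families)) {
    b_psi <- lapply(dataset$families, function(phi) {
      if (!is.null(psi_beta[[phi]])) {
        expand_per_feature(psi_beta[[phi]], paste0("psi_beta[", phi, "]"))
      } else {
        expand_per_feature(1, "psi_beta")
      }
    })
  } else {
    one <- expand_per_feature(psi_beta, "psi_beta")
    b_psi <- rep(list(one), n_fam)
  }
  names(b_psi) <- dataset$families

  structure(list(psi_weights = w_psi, psi_alpha = a_psi, psi_beta = b_psi,
                 psi_gamma = g_psi, geo = geo,
                 m_min = m_min, m_max = m_max, size_prior = size_prior,
                 n_entities = L),
            class = "sb_priors")
}

#' Log size prior of one area
#'
#' @param m area size.
#' @param priors an `sb_priors`.
#' @return `-Inf` outside `[m_min, m_max]`; within bounds,
#'   `-log choose(L, m)` for the `"uniform_size"` prior and 0 for
#'   `"uniform_configs"` (both unnormalized).
#' @export
size_prior_log <- function(m, priors) {
  if (m < priors$m_min || m > priors$m_max) {
    return(-Inf)
  }
  if (priors$size_prior == "uniform_size") {
    -lchoose(priors$n_entities, m)
  } else {
    0
  }
}

#' Joint log-prior of a model state
#'
#' Sum of the Dirichlet log-densities of every weight and probability vector,
#' the geo-prior, and the size prior (0 within `[m_min, m_max]`, `-Inf`
#' outside).
#'
#' @param state model state (see [data_log_likelihood()]).
#' @param priors an `sb_priors`.
#' @param dataset the dataset (locations for Delaunay linkage).
#' @return Log-prior; `-Inf` for out-of-bound sizes, overlapping areas or
#'   off-simplex vectors.
#' @export
log_prior <- function(state, priors, dataset = NULL) {
  sizes <- lengths(state$areas)
  if (any(sizes < priors$m_min | sizes > priors$m_max)) {
    return(-Inf)
  }
  locations <- if (!is.null(dataset)) dataset$entities else NULL
  lp <- geo_prior_log(state$areas, priors$geo, locations) +
    sum(vapply(sizes, size_prior_log, 0, priors = priors))
  if (!is.finite(lp)) {
    return(-Inf)
  }
  F_ <- nrow(priors$psi_weights)
  for (f in seq_len(F_)) {
    lp <- lp + ddirichlet_log(state$w[f, ], priors$psi_weights[f, ]) +
      ddirichlet_log(state$alpha[[f]], priors$psi_alpha[[f]])
  }
  for (phi in seq_along(state$beta)) {
    for (f in seq_len(F_)) {
      lp <- lp + ddirichlet_log(state$beta[[phi]][[f]],
                                priors$psi_beta[[phi]][[f]])
    }
  }
  for (k in seq_along(state$gamma)) {
    for (f in seq_len(F_)) {
      lp <- lp + ddirichlet_log(state$gamma[[k]][[f]], priors$psi_gamma[[f]])
    }
  }
  lp
}
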