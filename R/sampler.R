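# Metropolis-Hastings sampler over the full parameter vector
# Theta = {areas Z, weights w, alpha, beta, gamma}. Probability vectors move
# by Dirichlet proposals centred on the current value; areas move by
# spatially informed discrete grow/shrink/swap proposals whose grow
# candidates are the g nearest unassigned languages (by cost) of the area.
# All proposals carry full Hastings corrections, so the stationary
# distribution does not depend on the proposal tuning.

#' Sampler configuration
#'
#' @param n_steps total MCMC steps.
#' @param burn_in fraction of steps discarded from the start, in `[0, 1)`.
#' @param n_retained number of (evenly thinned) samples kept after burn-in.
#' @param kappa concentration of the Dirichlet proposal: larger values make
#'   smaller steps. Default 30.
#' @param eps small constant added to every Dirichlet proposal parameter so
#'   the proposal keeps full support. Default `1e-4`.
#' @param g size of the spatial candidate neighbourhood for area grow moves.
#'   Default 10.
#' @param op_weights named relative weights of the operators `area`,
#'   `weights`, `alpha`, `beta`, `gamma`. Inapplicable operators (e.g.
#'   `area`/`gamma` when `K = 0`, `beta` without families) are dropped and
#'   the rest re-normalized.
#' @param p_joint_gamma probability that an area move also redraws the
#'   area's contact vectors from the Hastings-corrected pseudo-conditional
#'   `Dir(psi + member state counts)`. These joint moves let membership and
#'   contact vectors cross likelihood valleys together; 0 disables them.
#' @param p_conditional probability that a contact-vector update uses the
#'   pseudo-conditional independence proposal instead of the local Dirichlet
#'   random walk.
#' @param fix character vector of parameter blocks to hold fixed (no
#'   operator): any of `"weights"`, `"alpha"`, `"beta"`, `"gamma"`. Useful
#'   for validation runs with known tables.
#' @param seed integer seed; every stochastic draw of the chain flows through
#'   it.
#' @param p_relocate probability that an area move during burn-in teleports
#'   the whole area to a random spatial ball of the same size (with contact
#'   vectors redrawn conditionally). Relocations are a warmup search device
#'   and are never used after burn-in, so the retained samples come from the
#'   exact kernel.
#' @param anneal_T0 initial likelihood temperature of the annealed burn-in.
#'   During burn-in the data log-likelihood enters the acceptance ratio
#'   divided by a temperature that decreases from `anneal_T0` to 1, so weak
#'   self-reinforcing pseudo-clusters dissolve before the chain commits to a
#'   basin; after burn-in the kernel targets the exact posterior. 1 disables
#'   annealing. Retained samples are never tempered.
#' @param refresh_every steps between full cache recomputations that squash
#'   accumulated floating-point drift.
#' @param log_every emit a progress message (step, phase, log-posterior,
#'   per-operator acceptance rates) every this many steps; 0 (the default)
#'   is silent.
#' @return A list of class `sb_sampler_config`.
#' @export
sampler_config <- function(n_steps = 100000L, burn_in = 0.2,
                           n_retained = 1000L, kappa = 30, eps = 1e-4,
                           g = 10L,
                           op_weights = c(area = 0.4, weights = 0.2,
                                          alpha = 0.1, beta = 0.15,
                                          gamma = 0.15),
                           p_joint_gamma = 0.5, p_conditional = 0.5,
                           fix = character(), seed = 1L, anneal_T0 = 5,
                           p_relocate = 0.15, refresh_every = 10000L,
                           log_every = 0L) {
  n_steps <- as.integer(n_steps)
  if (n_steps <= 0L) stop("n_steps must be positive")
  if (!is_number(burn_in) || burn_in < 0 || burn_in >= 1) {
    stop("burn_in must be in [0, 1)")
  }
  if (n_retained < 1L) stop("n_retained must be >= 1")
  if (n_retained > n_steps - floor(burn_in * n_steps)) {
    stop("n_retained exceeds the number of post-burn-in steps")
  }
  if (!is_number(kappa) || kappa <= 0) stop("kappa must be > 0")
  stopifnot(all(fix %in% c("weights", "alpha", "beta", "gamma")))
  ops <- c("area", "weights", "alpha", "beta", "gamma")
  if (is.null(names(op_weights)) || !all(names(op_weights) %in% ops)) {
    stop("op_weights must be named with: ", paste(ops, collapse = ", "))
  }
  if (!is_number(p_joint_gamma) || p_joint_gamma < 0 || p_joint_gamma > 1 ||
      !is_number(p_conditional) || p_conditional < 0 || p_conditional > 1) {
    stop("p_joint_gamma and p_conditional must be in [0, 1]")
  }
  if (!is_number(anneal_T0) || anneal_T0 < 1) {
    stop("anneal_T0 must be >= 1")
  }
  structure(list(n_steps = n_steps, burn_in = burn_in,
                 n_retained = as.integer(n_retained), kappa = kappa,
                 eps = eps, g = as.integer(g), op_weights = op_weights,
                 p_joint_gamma = p_joint_gamma,
                 p_conditional = p_conditional, anneal_T0 = anneal_T0,
                 p_relocate = p_relocate,
                 fix = fix, seed = as.integer(seed),
                 refresh_every = as.integer(refresh_every),
                 log_every = as.integer(log_every)),
            class = "sb_sampler_config")
}

#' Draw an initial model state from the priors
#'
#' Weights and probability vectors are drawn from their Dirichlet priors.
#' Each area is seeded from a random entity together with its `m_min - 1`
#' nearest unassigned neighbours by cost, so initial areas are disjoint and
#' within the size bounds.
#'
#' @param dataset an `sb_dataset`.
#' @param priors an `sb_priors`.
#' @param K number of areas (`K = 0` gives the pure confounder model).
#' @param cost cost matrix (built from the dataset when omitted and
#'   `K > 0`).
#' @return A model state (class `sb_state`): list with `areas`, `w`,
#'   `alpha`, `beta`, `gamma`.
#' @export
init_state <- function(dataset, priors, K, cost = NULL) {
  L <- nrow(dataset$X)
  F_ <- ncol(dataset$X)
  K <- as.integer(K)
  if (K < 0L) stop("K must be >= 0")
  if (K * priors$m_min > L) {
    stop("K * m_min exceeds the number of entities")
  }
  if (K > 0L && is.null(cost)) cost <- build_cost_matrix(dataset)
  w <- t(vapply(seq_len(F_),
                function(f) rdirichlet1(priors$psi_weights[f, ]),
                numeric(3L)))
  alpha <- lapply(seq_len(F_), function(f) rdirichlet1(priors$psi_alpha[[f]]))
  names(alpha) <- names(dataset$states)
  beta <- lapply(priors$psi_beta, function(psi_phi) {
    b <- lapply(psi_phi, rdirichlet1)
    names(b) <- names(dataset$states)
    b
  })
  gamma <- lapply(seq_len(K), function(k) {
    g <- lapply(priors$psi_gamma, rdirichlet1)
    names(g) <- names(dataset$states)
    g
  })
  areas <- vector("list", K)
  unassigned <- seq_len(L)
  for (k in seq_len(K)) {
    seed_ent <- unassigned[sample.int(length(unassigned), 1L)]
    ord <- order(cost[unassigned, seed_ent])
    members <- unassigned[ord[seq_len(priors$m_min)]]
    areas[[k]] <- members
    unassigned <- setdiff(unassigned, members)
  }
  structure(list(areas = areas, w = w, alpha = alpha, beta = beta,
                 gamma = gamma),
            class = "sb_state")
}

#' Dirichlet proposal on the probability simplex
#'
#' Proposes `x' ~ Dirichlet(kappa * x + eps)` and returns the Hastings
#' log-ratio `log q(x | x') - log q(x' | x)`. Proposals with a coordinate
#' that underflowed to 0 carry a `-Inf` log-ratio (the caller auto-rejects),
#' which keeps the chain in the open simplex.
#'
#' @param current strictly positive probability vector.
#' @param kappa proposal concentration (> 0).
#' @param eps support-widening constant added to each proposal parameter.
#' @return List with `value` (the proposal) and `log_hastings`.
#' @export
propose_simplex <- function(current, kappa, eps = 1e-4) {
  if (!is_number(kappa) || kappa <= 0) stop("kappa must be > 0")
  shape_fwd <- kappa * current + eps
  prop <- rdirichlet1(shape_fwd)
  if (any(prop <= 0) || any(current <= 0)) {
    return(list(value = prop, log_hastings = -Inf))
  }
  shape_rev <- kappa * prop + eps
  lh <- ddirichlet_log(current, shape_rev) - ddirichlet_log(prop, shape_fwd)
  list(value = prop, log_hastings = lh)
}

# ---------------------------------------------------------------------------
# Sampler context: an environment holding the model state plus incremental
# caches. Layout:
#   X (L x F int), obs (logical), nst, fam (0 = none), fam_members,
#   areas / area_of / group (1 neither, 2 family, 3 area, 4 both),
#   w, alpha, beta, gamma (+ gflat: per-area flattened gamma for O(F) row
#   lookups), WU/WI/WC (4 x F effective-weight triples by group),
#   A/B/G (L x F component probabilities at the observed states; 0 at
#   missing cells), P (cell mixture probabilities; 1 at missing cells),
#   loglik, lp_dir (sum of Dirichlet log-densities), lp_geo (per area).
# ---------------------------------------------------------------------------

#' Create a sampler context
#'
#' A mutable context holding the model state and its likelihood/prior
#' caches. [mh_step()] advances it by one step; [run_chain()] wraps the full
#' loop. Note the context does not seed the RNG; `run_chain` does.
#'
#' @inheritParams init_state
#' @param config an `sb_sampler_config`.
#' @param init optional starting `sb_state` (default: drawn via
#'   [init_state()]).
#' @return An environment of class `sb_context`.
#' @export
sampler_context <- function(dataset, priors, K, config = sampler_config(),
                            init = NULL, cost = NULL) {
  K <- as.integer(K)
  ctx <- new.env(parent = emptyenv())
  ctx$dataset <- dataset
  ctx$priors <- priors
  ctx$config <- config
  ctx$K <- K
  ctx$X <- unname(dataset$X) # dimnames stripped: hot-loop indexing stays cheap
  ctx$obs <- unname(!is.na(dataset$X))
  ctx$L <- nrow(dataset$X)
  ctx$F <- ncol(dataset$X)
  ctx$nst <- lengths(dataset$states)
  ctx$off <- c(0L, cumsum(ctx$nst))[seq_len(ctx$F)] # per-feature offsets
  ctx$fam <- family_index(dataset)
  ctx$n_fam <- length(dataset$families)
  ctx$fam_members <- lapply(seq_len(ctx$n_fam), function(p) which(ctx$fam == p))
  if (K > 0L) {
    cm <- if (!is.null(cost)) cost
      else if (!is.null(priors$geo$cost)) priors$geo$cost
      else build_cost_matrix(dataset)
    attributes(cm) <- list(dim = dim(cm))
    ctx$cost <- cm
  }
  state <- if (is.null(init)) init_state(dataset, priors, K, ctx$cost)
           else init
  if (length(state$areas) != K) stop("init state has wrong number of areas")
  ctx_load_state(ctx, state)
  # operator menu
  opw <- config$op_weights
  drop <- character()
  if (K == 0L) drop <- c(drop, "area", "gamma")
  if (ctx$n_fam == 0L) drop <- c(drop, "beta")
  drop <- union(drop, config$fix)
  opw <- opw[setdiff(names(opw), drop)]
  opw <- opw[opw > 0]
  if (!length(opw)) stop("no applicable operators left")
  ctx$ops <- names(opw)
  ctx$op_cum <- cumsum(opw / sum(opw))
  # joint and relocation moves redraw contact vectors, so they are disabled
  # when gamma is held fixed
  gamma_fixed <- "gamma" %in% config$fix
  ctx$p_joint <- if (gamma_fixed) 0 else config$p_joint_gamma
  ctx$p_reloc <- if (gamma_fixed) 0 else config$p_relocate
  ctx$acc_prop <- ctx$acc_acc <- setNames(numeric(length(ctx$ops)), ctx$ops)
  ctx$invT <- 1 # inverse likelihood temperature (1 = exact posterior)
  ctx$in_burn <- FALSE
  ctx$step_count <- 0L
  class(ctx) <- c("sb_context", class(ctx))
  ctx
}

# Load a state into the context and rebuild every cache from scratch.
ctx_load_state <- function(ctx, state) {
  L <- ctx$L; F_ <- ctx$F
  ctx$areas <- state$areas
  ctx$area_of <- integer(L)
  for (k in seq_along(state$areas)) ctx$area_of[state$areas[[k]]] <- k
  ctx$w <- state$w
  ctx$alpha <- state$alpha
  ctx$beta <- state$beta
  ctx$gamma <- state$gamma
  ctx$gflat <- lapply(state$gamma, function(g) unlist(g, use.names = FALSE))
  ctx$group <- 1L + (ctx$fam > 0L) + 2L * (ctx$area_of > 0L)

  wg <- weight_groups_all(state$w)
  ctx$WU <- wg$WU; ctx$WI <- wg$WI; ctx$WC <- wg$WC

  A <- matrix(0, L, F_); B <- matrix(0, L, F_); G <- matrix(0, L, F_)
  for (f in seq_len(F_)) {
    xf <- ctx$X[, f]
    av <- state$alpha[[f]][xf]
    av[is.na(av)] <- 0
    A[, f] <- av
    for (phi in seq_along(state$beta)) {
      rows <- ctx$fam_members[[phi]]
      if (length(rows)) {
        bv <- state$beta[[phi]][[f]][xf[rows]]
        bv[is.na(bv)] <- 0
        B[rows, f] <- bv
      }
    }
    for (k in seq_along(state$areas)) {
      rows <- state$areas[[k]]
      if (length(rows)) {
        gv <- state$gamma[[k]][[f]][xf[rows]]
        gv[is.na(gv)] <- 0
        G[rows, f] <- gv
      }
    }
  }
  ctx$A <- A; ctx$B <- B; ctx$G <- G
  ctx$Eu <- ctx$WU[ctx$group, , drop = FALSE]
  ctx$Ei <- ctx$WI[ctx$group, , drop = FALSE]
  ctx$Ec <- ctx$WC[ctx$group, , drop = FALSE]
  P <- ctx$Eu * A + ctx$Ei * B + ctx$Ec * G
  P[!ctx$obs] <- 1
  ctx$P <- P
  ctx$loglik <- sum(log(P))
  ctx_refresh_lp_dir(ctx)
  ctx$lp_size <- vapply(state$areas,
                        function(a) size_prior_log(length(a), ctx$priors), 0)
  ctx$lp_geo <- vapply(seq_along(state$areas), function(k) {
    if (ctx$priors$geo$type == "uniform" || ctx$priors$geo$lambda == 0) 0
    else -ctx$priors$geo$lambda *
      area_cost(state$areas[[k]], ctx$cost, ctx$priors$geo$linkage,
                ctx$dataset$entities)
  }, 0)
  invisible(ctx)
}

ctx_refresh_lp_dir <- function(ctx) {
  lp <- 0
  for (f in seq_len(ctx$F)) {
    lp <- lp + ddirichlet_log(ctx$w[f, ], ctx$priors$psi_weights[f, ]) +
      ddirichlet_log(ctx$alpha[[f]], ctx$priors$psi_alpha[[f]])
  }
  for (phi in seq_along(ctx$beta)) {
    for (f in seq_len(ctx$F)) {
      lp <- lp + ddirichlet_log(ctx$beta[[phi]][[f]],
                                ctx$priors$psi_beta[[phi]][[f]])
    }
  }
  for (k in seq_along(ctx$gamma)) {
    for (f in seq_len(ctx$F)) {
      lp <- lp + ddirichlet_log(ctx$gamma[[k]][[f]], ctx$priors$psi_gamma[[f]])
    }
  }
  ctx$lp_dir <- lp
  invisible(ctx)
}

# Effective-weight triples of all 4 groups for every feature; 4 x F each.
weight_groups_all <- function(w) {
  s12 <- w[, 1L] + w[, 2L]
  s13 <- w[, 1L] + w[, 3L]
  wu2 <- ifelse(s12 > 0, w[, 1L] / s12, 1)
  wi2 <- ifelse(s12 > 0, w[, 2L] / s12, 0)
  wu3 <- ifelse(s13 > 0, w[, 1L] / s13, 1)
  wc3 <- ifelse(s13 > 0, w[, 3L] / s13, 0)
  list(WU = rbind(1, wu2, wu3, w[, 1L], deparse.level = 0L),
       WI = rbind(0, wi2, 0, w[, 2L], deparse.level = 0L),
       WC = rbind(0, 0, wc3, w[, 3L], deparse.level = 0L))
}

#' Extract the current model state from a context
#' @param ctx an `sb_context`.
#' @return An `sb_state` list.
#' @export
ctx_state <- function(ctx) {
  structure(list(areas = ctx$areas, w = ctx$w, alpha = ctx$alpha,
                 beta = ctx$beta, gamma = ctx$gamma),
            class = "sb_state")
}

#' Cached log-likelihood and log-prior of a context
#' @param ctx an `sb_context`.
#' @return Named numeric vector `c(log_likelihood, log_prior)`.
#' @export
ctx_log_posterior_parts <- function(ctx) {
  c(log_likelihood = ctx$loglik,
    log_prior = ctx$lp_dir + sum(ctx$lp_geo) + sum(ctx$lp_size))
}

#' Advance the sampler by one Metropolis-Hastings step
#'
#' Picks one operator by the configured operator weights, proposes, and
#' accepts with probability `min(1, exp(delta log-posterior + Hastings
#' log-ratio))`. Proposals that violate hard constraints (area overlap, size
#' bounds, zero-probability cells) are always rejected.
#'
#' @param ctx an `sb_context`; modified in place.
#' @return Invisibly, `TRUE` if the proposal was accepted.
#' @export
mh_step <- function(ctx) {
  u <- runif(1L)
  op <- ctx$ops[findInterval(u, ctx$op_cum) + 1L]
  ctx$acc_prop[[op]] <- ctx$acc_prop[[op]] + 1
  accepted <- switch(op,
    area = step_area(ctx),
    weights = step_weights(ctx),
    alpha = step_alpha(ctx),
    beta = step_beta(ctx),
    gamma = step_gamma(ctx))
  if (accepted) ctx$acc_acc[[op]] <- ctx$acc_acc[[op]] + 1
  ctx$step_count <- ctx$step_count + 1L
  if (ctx$step_count %% ctx$config$refresh_every == 0L) {
    ctx$loglik <- sum(log(ctx$P))
    ctx_refresh_lp_dir(ctx)
  }
  invisible(accepted)
}

accept_log_ratio <- function(logr) {
  is.finite(logr) && (logr >= 0 || log(runif(1L)) < logr) ||
    identical(logr, Inf)
}

# --- operator: per-feature mixture weights ---------------------------------

step_weights <- function(ctx) {
  f <- sample.int(ctx$F, 1L)
  cur <- ctx$w[f, ]
  pr <- propose_simplex(cur, ctx$config$kappa, ctx$config$eps)
  if (!is.finite(pr$log_hastings)) return(FALSE)
  wg <- effective_weight_groups(pr$value)
  eu <- wg[ctx$group, 1L]; ei <- wg[ctx$group, 2L]; ec <- wg[ctx$group, 3L]
  pnew <- eu * ctx$A[, f] + ei * ctx$B[, f] + ec * ctx$G[, f]
  pnew[!ctx$obs[, f]] <- 1
  dll <- sum(log(pnew)) - sum(log(ctx$P[, f]))
  dlp <- ddirichlet_log(pr$value, ctx$priors$psi_weights[f, ]) -
    ddirichlet_log(cur, ctx$priors$psi_weights[f, ])
  if (!accept_log_ratio(dll * ctx$invT + dlp + pr$log_hastings)) return(FALSE)
  ctx$w[f, ] <- pr$value
  ctx$WU[, f] <- wg[, 1L]; ctx$WI[, f] <- wg[, 2L]; ctx$WC[, f] <- wg[, 3L]
  ctx$Eu[, f] <- eu; ctx$Ei[, f] <- ei; ctx$Ec[, f] <- ec
  ctx$P[, f] <- pnew
  ctx$loglik <- ctx$loglik + dll
  ctx$lp_dir <- ctx$lp_dir + dlp
  TRUE
}

# --- operator: universal preference vectors --------------------------------

step_alpha <- function(ctx) {
  f <- sample.int(ctx$F, 1L)
  cur <- ctx$alpha[[f]]
  pr <- propose_simplex(cur, ctx$config$kappa, ctx$config$eps)
  if (!is.finite(pr$log_hastings)) return(FALSE)
  av <- pr$value[ctx$X[, f]]
  av[is.na(av)] <- 0
  pnew <- ctx$Eu[, f] * av + ctx$Ei[, f] * ctx$B[, f] +
    ctx$Ec[, f] * ctx$G[, f]
  pnew[!ctx$obs[, f]] <- 1
  dll <- sum(log(pnew)) - sum(log(ctx$P[, f]))
  dlp <- ddirichlet_log(pr$value, ctx$priors$psi_alpha[[f]]) -
    ddirichlet_log(cur, ctx$priors$psi_alpha[[f]])
  if (!accept_log_ratio(dll * ctx$invT + dlp + pr$log_hastings)) return(FALSE)
  ctx$alpha[[f]] <- pr$value
  ctx$A[, f] <- av
  ctx$P[, f] <- pnew
  ctx$loglik <- ctx$loglik + dll
  ctx$lp_dir <- ctx$lp_dir + dlp
  TRUE
}

# --- operator: inheritance vectors (one family, one feature) ---------------

step_beta <- function(ctx) {
  phi <- sample.int(ctx$n_fam, 1L)
  f <- sample.int(ctx$F, 1L)
  rows <- ctx$fam_members[[phi]]
  cur <- ctx$beta[[phi]][[f]]
  pr <- propose_simplex(cur, ctx$config$kappa, ctx$config$eps)
  if (!is.finite(pr$log_hastings)) return(FALSE)
  bv <- pr$value[ctx$X[rows, f]]
  bv[is.na(bv)] <- 0
  pnew <- ctx$Eu[rows, f] * ctx$A[rows, f] + ctx$Ei[rows, f] * bv +
    ctx$Ec[rows, f] * ctx$G[rows, f]
  pnew[!ctx$obs[rows, f]] <- 1
  dll <- sum(log(pnew)) - sum(log(ctx$P[rows, f]))
  dlp <- ddirichlet_log(pr$value, ctx$priors$psi_beta[[phi]][[f]]) -
    ddirichlet_log(cur, ctx$priors$psi_beta[[phi]][[f]])
  if (!accept_log_ratio(dll * ctx$invT + dlp + pr$log_hastings)) return(FALSE)
  ctx$beta[[phi]][[f]] <- pr$value
  ctx$B[rows, f] <- bv
  ctx$P[rows, f] <- pnew
  ctx$loglik <- ctx$loglik + dll
  ctx$lp_dir <- ctx$lp_dir + dlp
  TRUE
}

# --- operator: contact vectors (one area, one feature) ---------------------

# State counts of feature f among `members` (missing cells ignored).
area_state_counts <- function(ctx, members, f) {
  xf <- ctx$X[members, f]
  tabulate(xf[!is.na(xf)], nbins = ctx$nst[f])
}

step_gamma <- function(ctx) {
  k <- sample.int(ctx$K, 1L)
  f <- sample.int(ctx$F, 1L)
  rows <- ctx$areas[[k]]
  cur <- ctx$gamma[[k]][[f]]
  if (runif(1L) < ctx$config$p_conditional) {
    # independence proposal from the pseudo-conditional
    # Dir(psi + state counts in the area); counts over-weight the contact
    # component (cells are mixtures), which the Hastings ratio corrects.
    shape <- ctx$priors$psi_gamma[[f]] + area_state_counts(ctx, rows, f)
    val <- rdirichlet1(shape)
    pr <- if (any(val <= 0)) {
      list(value = val, log_hastings = -Inf)
    } else {
      list(value = val,
           log_hastings = ddirichlet_log(cur, shape) -
             ddirichlet_log(val, shape))
    }
  } else {
    pr <- propose_simplex(cur, ctx$config$kappa, ctx$config$eps)
  }
  if (!is.finite(pr$log_hastings)) return(FALSE)
  gv <- pr$value[ctx$X[rows, f]]
  gv[is.na(gv)] <- 0
  pnew <- ctx$Eu[rows, f] * ctx$A[rows, f] + ctx$Ei[rows, f] * ctx$B[rows, f] +
    ctx$Ec[rows, f] * gv
  pnew[!ctx$obs[rows, f]] <- 1
  dll <- sum(log(pnew)) - sum(log(ctx$P[rows, f]))
  dlp <- ddirichlet_log(pr$value, ctx$priors$psi_gamma[[f]]) -
    ddirichlet_log(cur, ctx$priors$psi_gamma[[f]])
  if (!accept_log_ratio(dll * ctx$invT + dlp + pr$log_hastings)) return(FALSE)
  ctx$gamma[[k]][[f]] <- pr$value
  ctx$gflat[[k]][ctx$off[f] + seq_len(ctx$nst[f])] <- pr$value
  ctx$G[rows, f] <- gv
  ctx$P[rows, f] <- pnew
  ctx$loglik <- ctx$loglik + dll
  ctx$lp_dir <- ctx$lp_dir + dlp
  TRUE
}

# --- operator: discrete area moves -----------------------------------------

# g nearest unassigned entities to an area (distance = min cost to any
# member); ties broken by entity index for reproducibility.
nearest_unassigned <- function(ctx, members, unassigned) {
  cm <- ctx$cost[unassigned, members, drop = FALSE]
  # row minima via max.col (C-level), ties by first column
  jm <- max.col(-cm, ties.method = "first")
  d <- cm[cbind(seq_along(unassigned), jm)]
  ord <- order(d)
  unassigned[ord[seq_len(min(ctx$config$g, length(unassigned)))]]
}

# Legal moves for an area of size m with n_un unassigned entities.
legal_area_moves <- function(m, n_un, m_min, m_max) {
  c(if (m < m_max && n_un > 0L) "grow",
    if (m > m_min) "shrink",
    if (m >= 1L) "swap")
}

# Draw one membership move for area k. Returns NULL for auto-rejects
# (no legal move, irreversible proposal), else a list with the new member
# vector, the Hastings log-ratio of the discrete move, and the entities
# whose membership changed.
propose_membership <- function(ctx, k) {
  members <- ctx$areas[[k]]
  m <- length(members)
  unassigned <- which(ctx$area_of == 0L)
  m_min <- ctx$priors$m_min
  m_max <- ctx$priors$m_max
  moves <- legal_area_moves(m, length(unassigned), m_min, m_max)
  if (!length(moves)) return(NULL) # auto-reject: no legal move
  mv <- moves[sample.int(length(moves), 1L)]

  if (mv == "grow") {
    cand <- nearest_unassigned(ctx, members, unassigned)
    j <- cand[sample.int(length(cand), 1L)]
    new_members <- c(members, j)
    n_rev <- length(legal_area_moves(m + 1L, length(unassigned) - 1L,
                                     m_min, m_max))
    lh <- (-log(n_rev) - log(m + 1L)) - (-log(length(moves)) -
                                           log(length(cand)))
    changed <- list(list(ent = j, new_k = k))
  } else if (mv == "shrink") {
    i <- members[sample.int(m, 1L)]
    new_members <- members[members != i]
    cand_rev <- nearest_unassigned(ctx, new_members, c(unassigned, i))
    if (!(i %in% cand_rev)) return(NULL) # irreversible; auto-reject
    n_rev <- length(legal_area_moves(m - 1L, length(unassigned) + 1L,
                                     m_min, m_max))
    lh <- (-log(n_rev) - log(length(cand_rev))) - (-log(length(moves)) -
                                                     log(m))
    changed <- list(list(ent = i, new_k = 0L))
  } else { # swap: shrink then grow, size preserved
    i <- members[sample.int(m, 1L)]
    reduced <- members[members != i]
    cand <- nearest_unassigned(ctx, reduced, c(unassigned, i))
    j <- cand[sample.int(length(cand), 1L)]
    if (!(i %in% cand)) return(NULL) # reverse swap impossible
    if (j == i) { # identity proposal, trivially accepted
      return(list(identity = TRUE))
    }
    new_members <- c(reduced, j)
    lh <- 0 # same menu, same candidate set in both directions
    changed <- list(list(ent = i, new_k = 0L), list(ent = j, new_k = k))
  }
  list(identity = FALSE, new_members = new_members, lh = lh,
       changed = changed)
}

# Geo-prior log term of one area under the current spec.
area_geo_log <- function(ctx, members) {
  geo <- ctx$priors$geo
  if (geo$type == "uniform" || geo$lambda == 0) {
    return(0)
  }
  -geo$lambda * area_cost(members, ctx$cost, geo$linkage,
                          ctx$dataset$entities)
}

step_area <- function(ctx) {
  k <- sample.int(ctx$K, 1L)
  if (ctx$in_burn && runif(1L) < ctx$p_reloc) {
    return(step_area_relocate(ctx, k))
  }
  mp <- propose_membership(ctx, k)
  if (is.null(mp)) return(FALSE)
  if (mp$identity) return(TRUE)
  if (runif(1L) < ctx$p_joint) {
    return(step_area_joint(ctx, k, mp))
  }

  # plain move: membership changes, contact vectors stay
  dll <- 0
  rowinfo <- vector("list", length(mp$changed))
  for (ci in seq_along(mp$changed)) {
    l <- mp$changed[[ci]]$ent
    new_k <- mp$changed[[ci]]$new_k
    xl <- ctx$X[l, ]
    if (new_k > 0L) {
      gv <- ctx$gflat[[new_k]][ctx$off + xl]
      gv[is.na(gv)] <- 0
    } else {
      gv <- numeric(ctx$F)
    }
    grp <- 1L + (ctx$fam[l] > 0L) + 2L * (new_k > 0L)
    eu <- ctx$WU[grp, ]; ei <- ctx$WI[grp, ]; ec <- ctx$WC[grp, ]
    pnew <- eu * ctx$A[l, ] + ei * ctx$B[l, ] + ec * gv
    pnew[!ctx$obs[l, ]] <- 1
    dll <- dll + sum(log(pnew)) - sum(log(ctx$P[l, ]))
    rowinfo[[ci]] <- list(l = l, new_k = new_k, grp = grp, gv = gv,
                          eu = eu, ei = ei, ec = ec, pnew = pnew)
  }
  lp_geo_new <- area_geo_log(ctx, mp$new_members)
  dgeo <- lp_geo_new - ctx$lp_geo[k]
  lp_size_new <- size_prior_log(length(mp$new_members), ctx$priors)
  dsize <- lp_size_new - ctx$lp_size[k]
  if (!accept_log_ratio(dll * ctx$invT + dgeo + dsize + mp$lh)) return(FALSE)

  ctx$areas[[k]] <- mp$new_members
  ctx$lp_geo[k] <- lp_geo_new
  ctx$lp_size[k] <- lp_size_new
  ctx$loglik <- ctx$loglik + dll
  for (ri in rowinfo) {
    l <- ri$l
    ctx$area_of[l] <- ri$new_k
    ctx$group[l] <- ri$grp
    ctx$G[l, ] <- ri$gv
    ctx$Eu[l, ] <- ri$eu; ctx$Ei[l, ] <- ri$ei; ctx$Ec[l, ] <- ri$ec
    ctx$P[l, ] <- ri$pnew
  }
  TRUE
}

# Burn-in-only exploration move: teleport the whole area to a random
# spatial ball (random seed entity plus its nearest unassigned neighbours,
# same size) with contact vectors redrawn conditionally, accepted by the
# tempered posterior ratio. The move is not reversible, so it runs only
# during burn-in, where it lets the chain compare distant basins; every
# retained sample comes from the exact Metropolis-Hastings kernel.
step_area_relocate <- function(ctx, k) {
  members <- ctx$areas[[k]]
  m <- length(members)
  free <- which(ctx$area_of == 0L | ctx$area_of == k)
  if (length(free) < m) return(FALSE)
  seed_ent <- free[sample.int(length(free), 1L)]
  ord <- order(ctx$cost[free, seed_ent])
  new_members <- free[ord[seq_len(m)]]
  mp <- list(identity = FALSE, new_members = new_members, lh = 0,
             changed = NULL)
  # greedy: accepted on the tempered fit + geo-prior improvement alone,
  # a profile-posterior hill-climbing step (burn-in only)
  step_area_joint(ctx, k, mp, greedy = TRUE)
}

# Joint move: membership change plus a redraw of all the area's contact
# vectors from the pseudo-conditional Dir(psi + new member state counts).
# Letting gamma re-adapt within the same proposal lets the chain cross the
# likelihood valleys that separate membership modes (a plain one-entity move
# must keep the old, mis-adapted contact vectors).
step_area_joint <- function(ctx, k, mp, greedy = FALSE) {
  members <- ctx$areas[[k]]
  new_members <- mp$new_members
  psi <- ctx$priors$psi_gamma
  gnew <- vector("list", ctx$F)
  q_fwd <- q_rev <- dlp_dir <- 0
  for (f in seq_len(ctx$F)) {
    shape_new <- psi[[f]] + area_state_counts(ctx, new_members, f)
    gf <- rdirichlet1(shape_new)
    if (any(gf <= 0)) return(FALSE)
    gnew[[f]] <- gf
    q_fwd <- q_fwd + ddirichlet_log(gf, shape_new)
    shape_old <- psi[[f]] + area_state_counts(ctx, members, f)
    cur <- ctx$gamma[[k]][[f]]
    q_rev <- q_rev + ddirichlet_log(cur, shape_old)
    dlp_dir <- dlp_dir + ddirichlet_log(gf, psi[[f]]) -
      ddirichlet_log(cur, psi[[f]])
  }
  names(gnew) <- names(ctx$gamma[[k]])

  rows <- sort(unique(c(members, new_members)))
  in_new <- rows %in% new_members
  gflat_new <- unlist(gnew, use.names = FALSE)
  Xb <- ctx$X[rows, , drop = FALSE]
  idx <- sweep(Xb, 2L, ctx$off, "+")
  Gb <- matrix(gflat_new[idx], nrow = length(rows))
  Gb[is.na(Gb)] <- 0
  Gb[!in_new, ] <- 0
  grp <- 1L + (ctx$fam[rows] > 0L) + 2L * in_new
  Eu_b <- ctx$WU[grp, , drop = FALSE]
  Ei_b <- ctx$WI[grp, , drop = FALSE]
  Ec_b <- ctx$WC[grp, , drop = FALSE]
  Pb <- Eu_b * ctx$A[rows, , drop = FALSE] +
    Ei_b * ctx$B[rows, , drop = FALSE] + Ec_b * Gb
  obs_b <- ctx$obs[rows, , drop = FALSE]
  Pb[!obs_b] <- 1
  dll <- sum(log(Pb)) - sum(log(ctx$P[rows, , drop = FALSE]))

  lp_geo_new <- area_geo_log(ctx, new_members)
  dgeo <- lp_geo_new - ctx$lp_geo[k]
  lp_size_new <- size_prior_log(length(new_members), ctx$priors)
  dsize <- lp_size_new - ctx$lp_size[k]
  logr <- if (greedy) {
    dll * ctx$invT + dgeo + dsize
  } else {
    dll * ctx$invT + dgeo + dsize + dlp_dir + mp$lh + (q_rev - q_fwd)
  }
  if (!accept_log_ratio(logr)) {
    return(FALSE)
  }

  ctx$areas[[k]] <- new_members
  ctx$gamma[[k]] <- gnew
  ctx$gflat[[k]] <- gflat_new
  ctx$lp_geo[k] <- lp_geo_new
  ctx$lp_size[k] <- lp_size_new
  ctx$loglik <- ctx$loglik + dll
  ctx$lp_dir <- ctx$lp_dir + dlp_dir
  ctx$area_of[rows] <- ifelse(in_new, k, 0L)
  ctx$group[rows] <- grp
  ctx$G[rows, ] <- Gb
  ctx$Eu[rows, ] <- Eu_b
  ctx$Ei[rows, ] <- Ei_b
  ctx$Ec[rows, ] <- Ec_b
  ctx$P[rows, ] <- Pb
  TRUE
}

# ---------------------------------------------------------------------------

#' Run a Markov chain and collect a posterior trace
#'
#' Executes `config$n_steps` Metropolis-Hastings steps, discards the burn-in
#' fraction, and retains `config$n_retained` evenly thinned samples. Fully
#' reproducible from `config$seed`.
#'
#' @inheritParams sampler_context
#' @return An object of class `sb_trace`: list with `K`, `ll`, `lp`,
#'   `deviance` (numeric vectors over retained samples, `deviance = -2 * ll`),
#'   `samples` (list of model states), `accept` (per-operator proposal and
#'   acceptance counts), `entity_ids`, `retained_steps` and the `config`.
#' @export
run_chain <- function(dataset, priors, K, config = sampler_config(),
                      init = NULL, cost = NULL) {
  set.seed(config$seed)
  ctx <- sampler_context(dataset, priors, K, config, init = init, cost = cost)
  n <- config$n_steps
  burn <- floor(config$burn_in * n)
  ret_steps <- unique(round(seq(burn + 1L, n,
                                length.out = min(config$n_retained,
                                                 n - burn))))
  n_ret <- length(ret_steps)
  ll <- lp <- numeric(n_ret)
  samples <- vector("list", n_ret)
  r <- 1L
  # annealed burn-in: inverse temperature rises linearly to 1
  invT_sched <- if (burn > 0L && config$anneal_T0 > 1) {
    seq(1 / config$anneal_T0, 1, length.out = burn)
  } else {
    rep(1, burn)
  }
  # During burn-in, remember the best state by untempered log-posterior and
  # restart from it when burn-in ends, so the exact sampling phase starts in
  # the deepest basin the warmup explored.
  best_lp <- -Inf
  best_state <- NULL
  for (step in seq_len(n)) {
    if (step <= burn) {
      ctx$in_burn <- TRUE
      ctx$invT <- invT_sched[step]
    } else if (ctx$in_burn) {
      ctx$in_burn <- FALSE
      ctx$invT <- 1
      if (!is.null(best_state) &&
          best_lp > ctx$loglik + ctx$lp_dir + sum(ctx$lp_geo) +
            sum(ctx$lp_size)) {
        ctx_load_state(ctx, best_state)
      }
    }
    mh_step(ctx)
    if (ctx$in_burn) {
      cur_lp <- ctx$loglik + ctx$lp_dir + sum(ctx$lp_geo) + sum(ctx$lp_size)
      if (cur_lp > best_lp) {
        best_lp <- cur_lp
        best_state <- ctx_state(ctx)
      }
    }
    if (config$log_every > 0L && step %% config$log_every == 0L) {
      rates <- ifelse(ctx$acc_prop > 0, ctx$acc_acc / ctx$acc_prop, NA)
      message(sprintf(
        "step %d/%d [%s] log-posterior %.2f | acceptance %s",
        step, n, if (ctx$in_burn) "burn-in" else "sampling",
        ctx$loglik + ctx$lp_dir + sum(ctx$lp_geo) + sum(ctx$lp_size),
        paste(sprintf("%s %.2f", names(rates), rates), collapse = ", ")))
    }
    if (r <= n_ret && step == ret_steps[r]) {
      ll[r] <- ctx$loglik
      lp[r] <- ctx$lp_dir + sum(ctx$lp_geo) + sum(ctx$lp_size)
      samples[[r]] <- ctx_state(ctx)
      r <- r + 1L
    }
  }
  structure(list(K = K, ll = ll, lp = lp, deviance = -2 * ll,
                 samples = samples,
                 accept = data.frame(op = names(ctx$acc_prop),
                                     proposed = as.numeric(ctx$acc_prop),
                                     accepted = as.numeric(ctx$acc_acc),
                                     row.names = NULL),
                 entity_ids = dataset$entities$id,
                 n_entities = nrow(dataset$X),
                 retained_steps = ret_steps, config = config),
            class = "sb_trace")
}

#' @export
print.sb_trace <- function(x, ...) {
  cat("<sb_trace> K = ", x$K, ", ", length(x$ll), " retained samples (",
      x$config$n_steps, " steps, burn-in ", 100 * x$config$burn_in,
      "%)\n", sep = "")
  rates <- ifelse(x$accept$proposed > 0,
                  x$accept$accepted / x$accept$proposed, NA)
  cat("  acceptance:",
      paste(sprintf("%s %.2f", x$accept$op, rates), collapse = ", "), "\n")
  cat("  mean log-likelihood:", mean(x$ll), "\n")
  invisible(x)
}

#' Write a trace to line-oriented files
#'
#' Writes `samples.tsv` (one row per retained sample: step, log-likelihood,
#' log-prior, deviance, flattened weights and probability vectors) and
#' `areas.txt` (per sample, one line per area listing member entity ids), so
#' external diagnostic tools can ingest the scalar columns.
#'
#' @param trace an `sb_trace`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_trace <- function(trace, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  flat <- function(st) {
    c(as.vector(t(st$w)),
      unlist(st$alpha, use.names = FALSE),
      unlist(st$beta, use.names = FALSE),
      unlist(st$gamma, use.names = FALSE))
  }
  first <- trace$samples[[1L]]
  hdr_w <- paste0("w_", rep(seq_len(nrow(first$w)), each = 3L), "_",
                  c("universal", "inherit", "contact"))
  hdr_a <- paste0("alpha_", rep(names(first$alpha), lengths(first$alpha)),
                  "_", unlist(lapply(first$alpha, seq_along)))
  hdr_b <- if (length(first$beta)) {
    unlist(lapply(names(first$beta), function(phi) {
      paste0("beta_", phi, "_", rep(names(first$beta[[phi]]),
                                    lengths(first$beta[[phi]])), "_",
             unlist(lapply(first$beta[[phi]], seq_along)))
    }))
  } else character()
  hdr_g <- if (length(first$gamma)) {
    unlist(lapply(seq_along(first$gamma), function(k) {
      paste0("gamma_", k, "_", rep(names(first$gamma[[k]]),
                                   lengths(first$gamma[[k]])), "_",
             unlist(lapply(first$gamma[[k]], seq_along)))
    }))
  } else character()
  mat <- t(vapply(trace$samples, flat,
                  numeric(length(flat(first)))))
  out <- data.frame(step = trace$retained_steps,
                    log_likelihood = trace$ll, log_prior = trace$lp,
                    deviance = trace$deviance, mat, check.names = FALSE)
  colnames(out) <- c("step", "log_likelihood", "log_prior", "deviance",
                     hdr_w, hdr_a, hdr_b, hdr_g)
  write.table(out, file.path(dir, "samples.tsv"), sep = "\t",
              row.names = FALSE, quote = FALSE)
  con <- file(file.path(dir, "areas.txt"), "w")
  on.exit(close(con))
  for (r in seq_along(trace$samples)) {
    for (k in seq_along(trace$samples[[r]]$areas)) {
      ids <- trace$entity_ids[trace$samples[[r]]$areas[[k]]]
      writeLines(paste(c(sprintf("sample=%d area=%d", r, k), ids),
                       collapse = "\t"), con)
    }
  }
  invisible(dir)
}
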