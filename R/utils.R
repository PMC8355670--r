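# Small numeric helpers shared across modules.

#' Draw one Dirichlet random vector
#'
#' @param shape positive concentration (shape) parameters.
#' @return A probability vector of `length(shape)`. Coordinates can underflow
#'   to exactly 0 for very small shapes; callers that require interior points
#'   must check (the sampler auto-rejects such proposals).
#' @keywords internal
rdirichlet1 <- function(shape) {
  x <- rgamma(length(shape), shape = shape, rate = 1)
  s <- sum(x)
  if (!is.finite(s) || s <= 0) {
    return(rep(1 / length(shape), length(shape)))
  }
  x / s
}

#' Log-density of a Dirichlet distribution
#'
#' @param x probability vector (strictly positive, sums to 1).
#' @param alpha positive parameters of the same length.
#' @return Log-density; `-Inf` when `x` leaves the open simplex.
#' @keywords internal
ddirichlet_log <- function(x, alpha) {
  if (length(x) == 1L) {
    # degenerate one-state simplex: point mass at 1
    return(if (isTRUE(all.equal(x, 1))) 0 else -Inf)
  }
  if (any(x <= 0) || any(x >= 1)) {
    return(-Inf)
  }
  sum((alpha - 1) * log(x)) - sum(lgamma(alpha)) + lgamma(sum(alpha))
}

#' Shannon entropy of a probability vector (nats)
#' @param p probability vector.
#' @keywords internal
shannon_entropy <- function(p) {
  p <- p[p > 0]
  -sum(p * log(p))
}

# Total cost of a minimum spanning tree over a symmetric cost matrix
# (Prim's algorithm; ties broken by smallest vertex index, which makes
# degenerate inputs reproducible). O(n^2), suited to the small member sets
# touched inside the sampler loop.
mst_total_cost <- function(cm) {
  n <- nrow(cm)
  if (n < 2L) {
    return(0)
  }
  in_tree <- logical(n)
  in_tree[1L] <- TRUE
  d <- cm[1L, ]
  d[1L] <- Inf
  total <- 0
  for (i in seq_len(n - 1L)) {
    j <- which.min(d)
    total <- total + d[j]
    in_tree[j] <- TRUE
    d[j] <- Inf
    nd <- cm[j, ]
    upd <- !in_tree & nd < d
    d[upd] <- nd[upd]
  }
  unname(total)
}

# Is x a single finite number?
is_number <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x)
}

# Validate that x lies on the probability simplex.
check_simplex <- function(x, what = "vector", tol = 1e-8) {
  if (any(!is.finite(x)) || any(x < 0)) {
    stop(what, " must be non-negative and finite", call. = FALSE)
  }
  if (abs(sum(x) - 1) > tol) {
    stop(what, " must sum to 1 (got ", format(sum(x)), ")", call. = FALSE)
  }
  invisible(x)
}
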