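# Three-component mixture likelihood: universal preference, inheritance,
# contact. Each cell X[l, f] = s has probability
#   w_u * alpha[f][s] + w_i * beta[f, family(l)][s] + w_c * gamma[f, area(l)][s]
# with the per-feature weight triple w on the simplex. For a language outside
# any area the contact weight is zeroed and the remaining weights are
# re-normalized; a language outside any family is treated symmetrically for
# the inheritance weight.

#' Effective mixture weights for one language
#'
#' Zeroes the weights of inapplicable components (inheritance for a language
#' in no family, contact for a language in no area) and re-normalizes the
#' rest to sum to one. If every applicable weight is zero, all mass goes to
#' the universal component.
#'
#' @param weights numeric triple `(universal, inheritance, contact)` on the
#'   simplex.
#' @param in_family,in_area logical flags for the language.
#' @return A numeric triple summing to 1.
#' @export
#' @examples
#' effective_weights(c(0.2, 0.3, 0.5), in_family = TRUE, in_area = FALSE)
effective_weights <- function(weights, in_family, in_area) {
  if (any(weights < 0)) stop("mixture weights must be non-negative")
  w <- weights
  if (!in_family) w[2L] <- 0
  if (!in_area) w[3L] <- 0
  s <- sum(w)
  if (s <= 0) {
    return(c(1, 0, 0))
  }
  w / s
}

#' Mixture probability of one observed state
#'
#' @param state 1-based state index.
#' @param alpha universal probability vector for the feature.
#' @param beta inheritance probability vector for the language's family
#'   (ignored when its effective weight is 0; may be `NULL` then).
#' @param gamma contact probability vector for the language's area (same).
#' @param weights effective weight triple (see [effective_weights()]).
#' @return Probability in `[0, 1]`.
#' @export
cell_likelihood <- function(state, alpha, beta = NULL, gamma = NULL, weights) {
  if (state < 1L || state > length(alpha)) stop("state index out of range")
  p <- weights[1L] * alpha[state]
  if (weights[2L] > 0) p <- p + weights[2L] * beta[state]
  if (weights[3L] > 0) p <- p + weights[3L] * gamma[state]
  p
}

#' Joint data log-likelihood of a model state
#'
#' Sums the log mixture probability over every non-missing cell. Missing
#' cells contribute a factor of 1 (the mixture factorizes over cells).
#'
#' @param dataset an `sb_dataset`.
#' @param state a model state as produced by [init_state()] or stored in a
#'   trace: a list with `areas` (list of integer entity-index vectors), `w`
#'   (features x 3 weight matrix), `alpha` (list of vectors per feature),
#'   `beta` (list per family of lists per feature; may be `NULL`), `gamma`
#'   (list per area of lists per feature; may be `NULL` when there are no
#'   areas).
#' @return Log-likelihood; `-Inf` (with attribute `zero_cell = TRUE`) when
#'   some observed cell has probability 0 under all applicable components.
#' @export
data_log_likelihood <- function(dataset, state) {
  X <- dataset$X
  L <- nrow(X)
  F_ <- ncol(X)
  fam <- family_index(dataset)
  area_of <- integer(L)
  for (k in seq_along(state$areas)) area_of[state$areas[[k]]] <- k
  has_fam <- fam > 0L
  has_area <- area_of > 0L

  total <- 0
  zero <- FALSE
  for (f in seq_len(F_)) {
    xf <- X[, f]
    obs <- !is.na(xf)
    a <- state$alpha[[f]][xf]
    b <- numeric(L)
    if (!is.null(state$beta)) {
      for (phi in seq_along(state$beta)) {
        rows <- which(fam == phi)
        if (length(rows)) b[rows] <- state$beta[[phi]][[f]][xf[rows]]
      }
    }
    g <- numeric(L)
    for (k in seq_along(state$areas)) {
      rows <- state$areas[[k]]
      if (length(rows)) g[rows] <- state$gamma[[k]][[f]][xf[rows]]
    }
    ew <- effective_weight_matrix(state$w[f, ], has_fam, has_area)
    p <- ew[, 1L] * a + ew[, 2L] * b + ew[, 3L] * g
    p <- p[obs]
    if (any(p <= 0, na.rm = TRUE)) zero <- TRUE
    total <- total + sum(log(p))
  }
  if (zero || is.nan(total)) {
    total <- -Inf
    attr(total, "zero_cell") <- TRUE
  }
  total
}

# L x 3 matrix of effective weights for one feature, rows = entities.
effective_weight_matrix <- function(w_f, has_fam, has_area) {
  tr <- effective_weight_groups(w_f)
  grp <- 1L + has_fam + 2L * has_area
  tr[grp, , drop = FALSE]
}

# 4 x 3 matrix of effective weight triples by group:
# row 1 = neither family nor area, 2 = family only, 3 = area only, 4 = both.
effective_weight_groups <- function(w_f) {
  s12 <- w_f[1L] + w_f[2L]
  s13 <- w_f[1L] + w_f[3L]
  g2 <- if (s12 > 0) c(w_f[1L] / s12, w_f[2L] / s12, 0) else c(1, 0, 0)
  g3 <- if (s13 > 0) c(w_f[1L] / s13, 0, w_f[3L] / s13) else c(1, 0, 0)
  rbind(c(1, 0, 0), g2, g3, w_f, deparse.level = 0L)
}
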