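# Model selection and posterior summaries: DIC over K, label matching across
# samples, membership frequencies, area ranking, Gabriel edge frequencies,
# and effective sample sizes.

#' Deviance information criterion of a trace
#'
#' `DIC = mean deviance + p_D` with the effective number of parameters
#' estimated from the posterior uncertainty as `p_D = var(deviance) / 2`
#' (the Gelman variant; the plug-in variant is unavailable here because the
#' posterior mean of a discrete area configuration is undefined).
#'
#' @param x an `sb_trace` or a numeric vector of per-sample deviances.
#' @return List with `mean_deviance`, `p_d`, `dic`.
#' @export
#' @examples
#' dic(c(10, 12, 14)) # mean 12, p_D 2, DIC 14
dic <- function(x) {
  dev <- if (inherits(x, "sb_trace")) x$deviance else as.numeric(x)
  if (length(dev) < 2L) {
    stop("p_D is undefined for a single-sample trace")
  }
  dbar <- mean(dev)
  pd <- var(dev) / 2
  list(mean_deviance = dbar, p_d = pd, dic = dbar + pd)
}

#' Scan the number of areas and select K by DIC levelling
#'
#' Runs one chain per candidate `K` and reports the DIC table. More areas
#' always fit at least as well, so the chosen `K` is where the DIC levels
#' off: the smallest `K` such that
#' `DIC(K_next) >= DIC(K) - tau * |DIC(K)|`. If the DIC is still improving
#' at the end of the list, the largest `K` is returned with a warning.
#'
#' @param dataset an `sb_dataset`.
#' @param priors an `sb_priors`.
#' @param K_list ascending candidate numbers of areas.
#' @param config an `sb_sampler_config`; run `i` uses seed
#'   `config$seed + K_list[i]`.
#' @param tau relative levelling threshold (default 0.02).
#' @param keep_traces keep the per-K traces in the result (default `TRUE`).
#' @return An object of class `sb_scan`: list with `table` (data frame `K`,
#'   `mean_deviance`, `p_d`, `dic`), `selected_k`, `tau` and optionally
#'   `traces`.
#' @export
scan_k <- function(dataset, priors, K_list, config = sampler_config(),
                   tau = 0.02, keep_traces = TRUE) {
  K_list <- as.integer(K_list)
  if (!length(K_list)) stop("K_list must be non-empty")
  if (is.unsorted(K_list, strictly = TRUE)) {
    stop("K_list must be strictly ascending")
  }
  traces <- vector("list", length(K_list))
  tab <- data.frame(K = K_list, mean_deviance = NA_real_, p_d = NA_real_,
                    dic = NA_real_)
  for (i in seq_along(K_list)) {
    cfg <- config
    cfg$seed <- config$seed + K_list[i]
    tr <- run_chain(dataset, priors, K_list[i], cfg)
    d <- dic(tr)
    tab$mean_deviance[i] <- d$mean_deviance
    tab$p_d[i] <- d$p_d
    tab$dic[i] <- d$dic
    traces[[i]] <- tr
  }
  selected <- NA_integer_
  if (length(K_list) == 1L) {
    selected <- K_list[1L]
  } else {
    for (i in seq_len(length(K_list) - 1L)) {
      if (tab$dic[i + 1L] >= tab$dic[i] - tau * abs(tab$dic[i])) {
        selected <- K_list[i]
        break
      }
    }
    if (is.na(selected)) {
      selected <- K_list[length(K_list)]
      warning("DIC still decreasing at the largest K scanned; ",
              "consider extending K_list")
    }
  }
  structure(list(table = tab, selected_k = selected, tau = tau,
                 traces = if (keep_traces) traces),
            class = "sb_scan")
}

#' @export
print.sb_scan <- function(x, ...) {
  cat("<sb_scan> selected K =", x$selected_k, "\n")
  print(x$table, row.names = FALSE)
  invisible(x)
}

jaccard <- function(a, b) {
  u <- length(union(a, b))
  if (u == 0L) return(0)
  length(intersect(a, b)) / u
}

#' Resolve label switching across posterior samples
#'
#' Area labels are exchangeable, so slot `k` can mean different areas in
#' different samples. Each sample's areas are greedily matched to a running
#' reference (initialized from the first retained sample) by maximum
#' Jaccard overlap, and the sample's area and contact-vector slots are
#' permuted accordingly. Contents are unchanged; only labels move.
#'
#' @param trace an `sb_trace`.
#' @return The relabelled `sb_trace`.
#' @export
match_area_labels <- function(trace) {
  K <- trace$K
  if (K <= 1L) {
    return(trace)
  }
  if (all(lengths(trace$samples[[1L]]$areas) == 0L)) {
    warning("all areas empty; labels left unchanged")
    return(trace)
  }
  ref <- trace$samples[[1L]]$areas
  for (t in seq_along(trace$samples)) {
    st <- trace$samples[[t]]
    J <- matrix(0, K, K)
    for (i in seq_len(K)) {
      for (j in seq_len(K)) J[i, j] <- jaccard(st$areas[[i]], ref[[j]])
    }
    perm <- integer(K) # perm[j] = which sample-area goes to slot j
    free_i <- rep(TRUE, K)
    free_j <- rep(TRUE, K)
    for (r in seq_len(K)) {
      Jm <- J
      Jm[!free_i, ] <- -1
      Jm[, !free_j] <- -1
      best <- arrayInd(which.max(Jm), dim(Jm))
      perm[best[2L]] <- best[1L]
      free_i[best[1L]] <- FALSE
      free_j[best[2L]] <- FALSE
    }
    if (!all(perm == seq_len(K))) {
      st$areas <- st$areas[perm]
      st$gamma <- st$gamma[perm]
      trace$samples[[t]] <- st
    }
    ref <- st$areas
  }
  trace
}

#' Posterior membership frequencies
#'
#' Fraction of retained samples in which each entity belongs to each area
#' slot. Rows need not sum to 1: an entity can sit outside every area.
#' Labels should be matched first (see [match_area_labels()]).
#'
#' @param trace an `sb_trace` (ideally relabelled).
#' @return `L x K` numeric matrix with entity ids as row names.
#' @export
membership_frequencies <- function(trace) {
  K <- trace$K
  L <- trace$n_entities
  out <- matrix(0, L, K, dimnames = list(trace$entity_ids,
                                         paste0("area_", seq_len(K))))
  if (K == 0L) {
    return(out)
  }
  for (st in trace$samples) {
    for (k in seq_len(K)) out[st$areas[[k]], k] <- out[st$areas[[k]], k] + 1
  }
  out / length(trace$samples)
}

#' Posterior mean of the per-feature mixture weights
#' @param trace an `sb_trace`.
#' @return Features x 3 matrix (columns universal, inheritance, contact).
#' @export
posterior_mean_weights <- function(trace) {
  acc <- trace$samples[[1L]]$w * 0
  for (st in trace$samples) acc <- acc + st$w
  out <- acc / length(trace$samples)
  colnames(out) <- c("universal", "inherit", "contact")
  out
}

#' Posterior mean of the universal preference vectors
#' @param trace an `sb_trace`.
#' @return Named list of mean probability vectors, one per feature.
#' @export
posterior_mean_alpha <- function(trace) {
  acc <- lapply(trace$samples[[1L]]$alpha, function(v) v * 0)
  for (st in trace$samples) {
    for (f in seq_along(acc)) acc[[f]] <- acc[[f]] + st$alpha[[f]]
  }
  lapply(acc, function(v) v / length(trace$samples))
}

#' Posterior mean of an area's contact vectors
#' @param trace an `sb_trace` (relabel first for K > 1).
#' @param k area slot.
#' @return Named list of mean probability vectors, one per feature.
#' @export
posterior_mean_gamma <- function(trace, k) {
  acc <- lapply(trace$samples[[1L]]$gamma[[k]], function(v) v * 0)
  for (st in trace$samples) {
    for (f in seq_along(acc)) acc[[f]] <- acc[[f]] + st$gamma[[k]][[f]]
  }
  lapply(acc, function(v) v / length(trace$samples))
}

#' Summarize posterior areas
#'
#' Matches labels, computes per-entity membership frequencies, ranks the
#' area slots, and accumulates Gabriel-graph edge frequencies (how often two
#' adjacent languages sit in the same area across the posterior). Areas are
#' ranked by their mean per-sample log-likelihood contribution -- the drop
#' in data log-likelihood when the slot is removed from the state -- with
#' mean size as tie-break.
#'
#' @param trace an `sb_trace`.
#' @param dataset the `sb_dataset` the trace was sampled from.
#' @param n_eval number of (evenly spaced) samples used for the likelihood
#'   contributions and Gabriel edge counts; these are the expensive parts.
#' @return An object of class `sb_area_summary`: list with `membership`
#'   (L x K), `rank` (per slot, 1 = strongest), `contribution`, `mean_size`,
#'   `weights_mean`, `gamma_mean` (list per slot), `gabriel` (list per slot
#'   of data frames `from`, `to`, `freq` in entity ids).
#' @export
area_summary <- function(trace, dataset, n_eval = 200L) {
  trace <- match_area_labels(trace)
  K <- trace$K
  membership <- membership_frequencies(trace)
  n <- length(trace$samples)
  eval_idx <- unique(round(seq(1L, n, length.out = min(n_eval, n))))

  contribution <- numeric(K)
  gabriel_counts <- vector("list", K)
  for (k in seq_len(K)) gabriel_counts[[k]] <- list()
  for (t in eval_idx) {
    st <- trace$samples[[t]]
    ll_full <- data_log_likelihood(dataset, st)
    for (k in seq_len(K)) {
      reduced <- st
      reduced$areas <- st$areas[-k]
      reduced$gamma <- st$gamma[-k]
      contribution[k] <- contribution[k] +
        (ll_full - data_log_likelihood(dataset, reduced))
      members <- st$areas[[k]]
      if (length(members) >= 2L) {
        ed <- gabriel_graph(dataset$entities[members, , drop = FALSE])
        for (r in seq_len(nrow(ed))) {
          key <- paste(sort(members[ed[r, ]]), collapse = "-")
          gabriel_counts[[k]][[key]] <-
            (gabriel_counts[[k]][[key]] %||% 0) + 1
        }
      }
    }
  }
  contribution <- contribution / length(eval_idx)
  mean_size <- vapply(seq_len(K), function(k) {
    mean(vapply(trace$samples, function(st) length(st$areas[[k]]), 0))
  }, 0)
  rank_k <- integer(K)
  rank_k[order(-contribution, -mean_size)] <- seq_len(K)

  gabriel <- lapply(seq_len(K), function(k) {
    cts <- gabriel_counts[[k]]
    if (!length(cts)) {
      return(data.frame(from = character(), to = character(),
                        freq = numeric()))
    }
    pairs <- do.call(rbind, strsplit(names(cts), "-", fixed = TRUE))
    data.frame(from = trace$entity_ids[as.integer(pairs[, 1L])],
               to = trace$entity_ids[as.integer(pairs[, 2L])],
               freq = unlist(cts, use.names = FALSE) / length(eval_idx),
               stringsAsFactors = FALSE)
  })
  structure(list(membership = membership, rank = rank_k,
                 contribution = contribution, mean_size = mean_size,
                 weights_mean = posterior_mean_weights(trace),
                 gamma_mean = lapply(seq_len(K),
                                     function(k) posterior_mean_gamma(trace,
                                                                      k)),
                 gabriel = gabriel),
            class = "sb_area_summary")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Effective sample size of a scalar chain
#'
#' `n / (1 + 2 * sum(rho))` with the autocorrelation sum truncated by the
#' initial-positive-sequence rule: consecutive lag pairs
#' `rho(2t-1) + rho(2t)` are accumulated until the first non-positive pair.
#'
#' @param x numeric chain of length >= 2.
#' @return Effective sample size. A constant chain is reported as `n` with a
#'   degenerate-chain warning.
#' @export
ess <- function(x) {
  n <- length(x)
  if (n < 2L) stop("chain must have length >= 2")
  if (var(x) == 0) {
    warning("degenerate (constant) chain; reporting ESS = n")
    return(n)
  }
  lag_max <- min(n - 1L, 2000L)
  rho <- as.vector(acf(x, lag.max = lag_max, plot = FALSE,
                       demean = TRUE)$acf)[-1L]
  s <- 0
  t <- 1L
  while (t <= length(rho)) {
    pair <- rho[t] + if (t + 1L <= length(rho)) rho[t + 1L] else 0
    if (!is.finite(pair) || pair <= 0) break
    s <- s + pair
    t <- t + 2L
  }
  n / (1 + 2 * s)
}

#' Export a posterior area summary to JSON and delimited tables
#'
#' Writes `summary.json` (ranks, contributions, mean sizes, metadata),
#' `membership.tsv` (per-entity frequencies) and `gabriel_edges.geojson`
#' (Gabriel edges with a `freq` attribute, as GeoJSON LineStrings) for
#' external map rendering.
#'
#' @param summary an `sb_area_summary`.
#' @param dataset the dataset (for coordinates).
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_area_summary <- function(summary, dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  meta <- list(
    rank = summary$rank,
    contribution = summary$contribution,
    mean_size = summary$mean_size,
    ranking_statistic = paste(
      "mean per-sample log-likelihood contribution of the area slot",
      "(tie-break: mean size); a heuristic stand-in for relative posterior",
      "probability"))
  jsonlite::write_json(meta, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  mem <- data.frame(id = rownames(summary$membership), summary$membership,
                    check.names = FALSE, row.names = NULL)
  write.table(mem, file.path(dir, "membership.tsv"), sep = "\t",
              row.names = FALSE, quote = FALSE)
  feats <- list()
  for (k in seq_along(summary$gabriel)) {
    ed <- summary$gabriel[[k]]
    for (r in seq_len(nrow(ed))) {
      i <- match(ed$from[r], dataset$entities$id)
      j <- match(ed$to[r], dataset$entities$id)
      feats[[length(feats) + 1L]] <- list(
        type = "Feature",
        properties = list(area = k, freq = ed$freq[r],
                          from = ed$from[r], to = ed$to[r]),
        geometry = list(
          type = "LineString",
          coordinates = list(
            c(dataset$entities$x[i], dataset$entities$y[i]),
            c(dataset$entities$x[j], dataset$entities$y[j]))))
    }
  }
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       file.path(dir, "gabriel_edges.geojson"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
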