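# Fixture builders and independent oracles. Oracles deliberately re-derive
# quantities with their own arithmetic instead of calling the code paths
# they check.

# Small random dataset built in code.
fixture_dataset <- function(L = 10L, F_ = 4L, n_states = NULL, n_fam = 2L,
                            seed = 1L, missing_rate = 0) {
  set.seed(seed)
  if (is.null(n_states)) n_states <- sample(2:4, F_, replace = TRUE)
  n_states <- rep_len(n_states, F_)
  X <- vapply(seq_len(F_),
              function(f) sample.int(n_states[f], L, replace = TRUE),
              integer(L))
  if (missing_rate > 0) X[runif(length(X)) < missing_rate] <- NA_integer_
  ids <- sprintf("l%d", seq_len(L))
  fnames <- sprintf("f%d", seq_len(F_))
  dimnames(X) <- list(ids, fnames)
  states <- lapply(n_states, function(n) sprintf("s%d", seq_len(n)))
  names(states) <- fnames
  fam <- rep(NA_character_, L)
  if (n_fam > 0L) {
    # first 2/3 of entities split round-robin over families
    head_n <- floor(2 * L / 3)
    fam[seq_len(head_n)] <- sprintf("fam%d",
                                    rep_len(seq_len(n_fam), head_n))
  }
  entities <- data.frame(id = ids, x = runif(L), y = runif(L), family = fam,
                         stringsAsFactors = FALSE)
  sprachbund:::new_sb_dataset(entities, X, states, "planar")
}

# Random valid model state for a dataset.
random_state <- function(dataset, K = 0L, area_size = 3L, seed = 1L) {
  set.seed(seed)
  rdir <- function(a) {
    x <- rgamma(length(a), a)
    x / sum(x)
  }
  F_ <- ncol(dataset$X)
  nst <- lengths(dataset$states)
  L <- nrow(dataset$X)
  areas <- list()
  free <- seq_len(L)
  for (k in seq_len(K)) {
    members <- sample(free, area_size)
    areas[[k]] <- members
    free <- setdiff(free, members)
  }
  list(
    areas = areas,
    w = t(vapply(seq_len(F_), function(f) rdir(c(1, 1, 1)), numeric(3))),
    alpha = lapply(nst, function(n) rdir(rep(1, n))),
    beta = lapply(dataset$families, function(phi) {
      lapply(nst, function(n) rdir(rep(1, n)))
    }),
    gamma = lapply(seq_len(K), function(k) {
      lapply(nst, function(n) rdir(rep(1, n)))
    }))
}

# Oracle: per-cell product of the mixture, plain double loop.
naive_loglik <- function(dataset, state) {
  L <- nrow(dataset$X)
  F_ <- ncol(dataset$X)
  total <- 0
  for (l in seq_len(L)) {
    famlab <- dataset$entities$family[l]
    phi <- if (is.na(famlab)) 0L else match(famlab, dataset$families)
    k <- 0L
    for (kk in seq_along(state$areas)) {
      if (l %in% state$areas[[kk]]) k <- kk
    }
    for (f in seq_len(F_)) {
      s <- dataset$X[l, f]
      if (is.na(s)) next
      w <- state$w[f, ]
      if (phi == 0L) w[2] <- 0
      if (k == 0L) w[3] <- 0
      w <- if (sum(w) > 0) w / sum(w) else c(1, 0, 0)
      p <- w[1] * state$alpha[[f]][s]
      if (phi > 0L) p <- p + w[2] * state$beta[[phi]][[f]][s]
      if (k > 0L) p <- p + w[3] * state$gamma[[k]][[f]][s]
      total <- total + log(p)
    }
  }
  total
}

# Oracle: minimum mean spanning-tree edge cost by enumerating all labelled
# spanning trees via Pruefer sequences (n^(n-2) trees).
prufer_decode <- function(pr, n) {
  deg <- tabulate(pr, n) + 1L
  edges <- matrix(0L, n - 1L, 2L)
  for (i in seq_along(pr)) {
    leaf <- which(deg == 1L)[1L]
    edges[i, ] <- c(leaf, pr[i])
    deg[leaf] <- deg[leaf] - 1L
    deg[pr[i]] <- deg[pr[i]] - 1L
  }
  edges[n - 1L, ] <- which(deg == 1L)
  edges
}

brute_force_mst_mean <- function(cm) {
  n <- nrow(cm)
  if (n == 2L) return(cm[1L, 2L])
  seqs <- as.matrix(expand.grid(rep(list(seq_len(n)), n - 2L)))
  best <- Inf
  for (r in seq_len(nrow(seqs))) {
    edges <- prufer_decode(as.integer(seqs[r, ]), n)
    best <- min(best, sum(cm[edges]))
  }
  best / (n - 1L)
}

# Write a small feature/locations file pair, returning the two paths.
write_fixture_files <- function(dir, rows, locations_rows,
                                header = "id,f1,f2") {
  fp <- file.path(dir, "features.csv")
  lp <- file.path(dir, "locations.csv")
  writeLines(c(header, rows), fp)
  writeLines(c("id,x,y,family", locations_rows), lp)
  list(features = fp, locations = lp)
}
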