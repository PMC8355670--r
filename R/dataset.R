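# Domain types and readers/writers: feature tables, locations, families,
# cost matrices.

#' Read a categorical feature table
#'
#' Reads a delimited text file with one row per language (entity) and one
#' column per feature. The first column holds the unique entity id. Cells
#' equal to `missing_token` become missing values. State inventories are
#' inferred from the observed labels (stable alphabetical order) unless an
#' explicit inventory is supplied, in which case the declared order is kept
#' and unknown labels are an error.
#'
#' @param path path to a CSV (`.csv`) or TSV (anything else) file.
#' @param missing_token string marking a missing cell. Default `"?"`.
#' @param states optional state inventories: a named list mapping feature
#'   names to ordered character vectors of state labels, or a path to a
#'   YAML/JSON file holding such a mapping.
#' @return An object of class `sb_features`: a list with `ids` (character),
#'   `data` (integer matrix of 1-based state indices, `NA` = missing) and
#'   `states` (named list of ordered state labels, one per feature; every
#'   feature has at least two states).
#' @export
#' @examples
#' tf <- tempfile(fileext = ".csv")
#' writeLines(c("id,base", "l1,decimal", "l2,vigesimal", "l3,hybrid"), tf)
#' ft <- read_feature_table(tf)
#' ft$states$base # alphabetical: decimal, hybrid, vigesimal
read_feature_table <- function(path, missing_token = "?", states = NULL) {
  raw <- read_delim_auto(path)
  if (ncol(raw) < 2L) {
    stop("feature table needs an id column plus at least one feature column")
  }
  ids <- as.character(raw[[1L]])
  if (anyDuplicated(ids)) {
    stop("duplicate entity ids in feature table: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  cells <- as.matrix(raw[, -1L, drop = FALSE])
  storage.mode(cells) <- "character"
  cells[cells == missing_token | is.na(cells)] <- NA_character_
  feature_names <- colnames(raw)[-1L]
  colnames(cells) <- feature_names
  rownames(cells) <- ids

  inventories <- resolve_state_inventories(states)
  states_out <- vector("list", length(feature_names))
  names(states_out) <- feature_names
  data <- matrix(NA_integer_, nrow = length(ids), ncol = length(feature_names),
                 dimnames = list(ids, feature_names))
  for (j in seq_along(feature_names)) {
    f <- feature_names[j]
    observed <- unique(cells[!is.na(cells[, j]), j])
    if (!is.null(inventories[[f]])) {
      sf <- as.character(inventories[[f]])
      unknown <- setdiff(observed, sf)
      if (length(unknown)) {
        stop("feature '", f, "': state label(s) not in declared inventory: ",
             paste(unknown, collapse = ", "))
      }
    } else {
      sf <- sort(observed, method = "radix")
      if (length(sf) < 2L) {
        stop("feature '", f, "' has fewer than two observed states and no ",
             "declared inventory")
      }
    }
    if (anyDuplicated(sf)) {
      stop("feature '", f, "': duplicate state labels in inventory")
    }
    if (length(sf) < 2L) {
      stop("feature '", f, "': a feature needs at least two states")
    }
    states_out[[j]] <- sf
    data[, j] <- match(cells[, j], sf)
  }
  structure(list(ids = ids, data = data, states = states_out),
            class = "sb_features")
}

#' Write a feature table
#'
#' Inverse of [read_feature_table()]: writes state labels (not indices) with
#' `missing_token` for missing cells, so reading the file back reproduces the
#' cell values exactly.
#'
#' @param x an `sb_dataset` or `sb_features` object.
#' @param path output path (`.csv` for comma-separated, else tab).
#' @param missing_token token for missing cells.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(x, path, missing_token = "?") {
  if (inherits(x, "sb_dataset")) {
    feats <- list(ids = x$entities$id, data = x$X, states = x$states)
  } else {
    feats <- x
  }
  lab <- matrix(missing_token, nrow = nrow(feats$data), ncol = ncol(feats$data))
  for (j in seq_len(ncol(feats$data))) {
    obs <- !is.na(feats$data[, j])
    lab[obs, j] <- feats$states[[j]][feats$data[obs, j]]
  }
  out <- data.frame(id = feats$ids, lab, check.names = FALSE,
                    stringsAsFactors = FALSE)
  colnames(out) <- c("id", names(feats$states))
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  write.table(out, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read entity locations and family labels
#'
#' @param path delimited text with columns `id`, `x` (or `lon`), `y` (or
#'   `lat`) and optionally `family`. Empty family cells mean the entity
#'   belongs to no family.
#' @return A data frame with columns `id`, `x`, `y`, `family` (`NA` = none)
#'   and an attribute `coord_hint` (`"planar"` or `"spherical"`) recording
#'   whether the coordinate columns were named `lon`/`lat`.
#' @export
read_locations <- function(path) {
  raw <- read_delim_auto(path)
  nm <- tolower(colnames(raw))
  id_col <- match("id", nm)
  if (is.na(id_col)) id_col <- 1L
  x_col <- match(c("x", "lon", "longitude"), nm)
  y_col <- match(c("y", "lat", "latitude"), nm)
  xi <- x_col[!is.na(x_col)][1L]
  yi <- y_col[!is.na(y_col)][1L]
  if (is.na(xi) || is.na(yi)) {
    stop("locations file must have columns x/y or lon/lat")
  }
  hint <- if (nm[xi] %in% c("lon", "longitude")) "spherical" else "planar"
  fam <- if ("family" %in% nm) as.character(raw[[match("family", nm)]])
         else rep(NA_character_, nrow(raw))
  fam[!is.na(fam) & fam == ""] <- NA_character_
  out <- data.frame(id = as.character(raw[[id_col]]),
                    x = as.numeric(raw[[xi]]), y = as.numeric(raw[[yi]]),
                    family = fam, stringsAsFactors = FALSE)
  if (anyDuplicated(out$id)) stop("duplicate entity ids in locations file")
  if (any(!is.finite(out$x)) || any(!is.finite(out$y))) {
    stop("non-finite coordinates in locations file")
  }
  attr(out, "coord_hint") <- hint
  out
}

#' Assemble a dataset of languages, features and locations
#'
#' @param features an `sb_features` object from [read_feature_table()].
#' @param locations a data frame from [read_locations()] (or with the same
#'   columns). Must contain every id in `features`.
#' @param coord `"auto"`, `"planar"` or `"spherical"`. With `"auto"`,
#'   coordinates are treated as degrees lon/lat when the columns were named
#'   that way or when every point satisfies |x| <= 180 and |y| <= 90;
#'   override explicitly if planar coordinates happen to fall in that box.
#' @return An object of class `sb_dataset`: list with `entities` (data frame
#'   id/x/y/family), `X` (integer matrix of state indices, `NA` = missing),
#'   `states` (named list), `families` (sorted unique family labels) and
#'   `coord_type`.
#' @export
sb_dataset <- function(features, locations,
                       coord = c("auto", "planar", "spherical")) {
  coord <- match.arg(coord)
  stopifnot(inherits(features, "sb_features"))
  idx <- match(features$ids, locations$id)
  if (anyNA(idx)) {
    stop("locations missing for entities: ",
         paste(features$ids[is.na(idx)], collapse = ", "))
  }
  loc <- locations[idx, , drop = FALSE]
  if (is.null(loc$family)) loc$family <- NA_character_
  coord_type <- switch(coord,
    planar = "planar",
    spherical = "spherical",
    auto = {
      hint <- attr(locations, "coord_hint")
      if (identical(hint, "spherical") ||
          (all(abs(loc$x) <= 180) && all(abs(loc$y) <= 90))) {
        "spherical"
      } else {
        "planar"
      }
    })
  entities <- data.frame(id = loc$id, x = loc$x, y = loc$y,
                         family = as.character(loc$family),
                         stringsAsFactors = FALSE)
  rownames(entities) <- NULL
  new_sb_dataset(entities, features$data, features$states, coord_type)
}

# Internal constructor; also used by the simulator.
new_sb_dataset <- function(entities, X, states, coord_type) {
  fams <- sort(unique(entities$family[!is.na(entities$family)]))
  n_missing_feat <- colSums(!is.na(X)) == 0L
  if (any(n_missing_feat)) {
    stop("feature(s) with no observed value: ",
         paste(colnames(X)[n_missing_feat], collapse = ", "))
  }
  structure(
    list(entities = entities, X = X, states = states,
         families = fams, coord_type = coord_type),
    class = "sb_dataset")
}

#' @export
print.sb_dataset <- function(x, ...) {
  nst <- lengths(x$states)
  cat("<sb_dataset> ", nrow(x$X), " entities x ", ncol(x$X), " features (",
      min(nst), "-", max(nst), " states, ",
      sum(is.na(x$X)), " missing cells), ",
      length(x$families), " families, ", x$coord_type, " coordinates\n",
      sep = "")
  invisible(x)
}

# Integer family ids: 0 = no family, 1..n index into dataset$families.
family_index <- function(dataset) {
  f <- match(dataset$entities$family, dataset$families)
  f[is.na(f)] <- 0L
  f
}

#' Build a pairwise cost matrix between entity locations
#'
#' Costs quantify the effort to traverse the space between two languages and
#' drive both the geo-prior and the spatially informed area proposals.
#'
#' @param x an `sb_dataset` or a locations data frame with `x`/`y` columns.
#' @param metric `"auto"` (follow the dataset's coordinate type),
#'   `"euclidean"`, or `"great_circle"` (haversine on a sphere of radius
#'   6371 km; result in km).
#' @param custom optional user-supplied square matrix of non-negative costs;
#'   asymmetric matrices are symmetrized by averaging `(C + t(C)) / 2`.
#' @return Symmetric non-negative matrix with zero diagonal and attribute
#'   `"metric"`.
#' @export
build_cost_matrix <- function(x, metric = c("auto", "euclidean",
                                            "great_circle"),
                              custom = NULL) {
  metric <- match.arg(metric)
  if (!is.null(custom)) {
    cm <- as.matrix(custom)
    if (nrow(cm) != ncol(cm)) stop("custom cost matrix must be square")
    if (any(!is.finite(cm))) stop("custom cost matrix has non-finite entries")
    if (any(cm < 0)) stop("custom cost matrix has negative entries")
    cm <- (cm + t(cm)) / 2
    diag(cm) <- 0
    attr(cm, "metric") <- "custom"
    return(cm)
  }
  loc <- if (inherits(x, "sb_dataset")) x$entities else x
  if (any(!is.finite(loc$x)) || any(!is.finite(loc$y))) {
    stop("non-finite coordinates")
  }
  if (metric == "auto") {
    metric <- if (inherits(x, "sb_dataset") && x$coord_type == "spherical") {
      "great_circle"
    } else {
      "euclidean"
    }
  }
  cm <- if (metric == "euclidean") {
    as.matrix(dist(cbind(loc$x, loc$y)))
  } else {
    geosphere::distm(cbind(loc$x, loc$y),
                     fun = function(a, b) geosphere::distHaversine(a, b,
                                                                   r = 6371))
  }
  dimnames(cm) <- list(loc$id, loc$id)
  diag(cm) <- 0
  attr(cm, "metric") <- metric
  cm
}

#' Validate a dataset (report, do not stop)
#'
#' Produces a validation report: per-family membership counts, features with
#' low coverage, and structural problems. Families with fewer than
#' `min_family_size` members get a warning entry, because probability vectors
#' estimated from very few languages are not robust.
#'
#' @param dataset an `sb_dataset`.
#' @param cost_matrix optional cost matrix to check for symmetry.
#' @param min_family_size smallest family size considered robust (default 5).
#' @return An object of class `sb_validation` with elements `errors`,
#'   `warnings`, `families` (named counts) and `feature_coverage` (fraction
#'   of non-missing cells per feature).
#' @export
validate_dataset <- function(dataset, cost_matrix = NULL,
                             min_family_size = 5L) {
  errors <- character()
  warnings <- character()
  fam <- dataset$entities$family
  fam_tab <- table(fam[!is.na(fam)])
  small <- fam_tab[fam_tab < min_family_size]
  for (nm in names(small)) {
    warnings <- c(warnings, sprintf(
      "family '%s' has only %d member(s); fewer than %d makes its probability vectors hard to estimate",
      nm, small[[nm]], min_family_size))
  }
  coverage <- colSums(!is.na(dataset$X)) / nrow(dataset$X)
  for (f in names(coverage)[coverage == 0]) {
    errors <- c(errors, sprintf("feature '%s' is missing in all entities", f))
  }
  for (f in names(coverage)[coverage > 0 & coverage < 0.5]) {
    warnings <- c(warnings,
                  sprintf("feature '%s' observed in only %.0f%% of entities",
                          f, 100 * coverage[[f]]))
  }
  if (any(!is.finite(dataset$entities$x)) ||
      any(!is.finite(dataset$entities$y))) {
    errors <- c(errors, "non-finite coordinates")
  }
  if (!is.null(cost_matrix)) {
    if (!isTRUE(all.equal(cost_matrix, t(cost_matrix)))) {
      errors <- c(errors, "cost matrix is not symmetric")
    }
    if (any(diag(cost_matrix) != 0)) {
      errors <- c(errors, "cost matrix has non-zero diagonal")
    }
    if (any(cost_matrix < 0)) {
      errors <- c(errors, "cost matrix has negative entries")
    }
  }
  structure(list(errors = errors, warnings = warnings,
                 families = as.list(fam_tab),
                 feature_coverage = coverage),
            class = "sb_validation")
}

#' @export
print.sb_validation <- function(x, ...) {
  cat("<sb_validation> ", length(x$errors), " error(s), ",
      length(x$warnings), " warning(s)\n", sep = "")
  for (e in x$errors) cat("  error:   ", e, "\n", sep = "")
  for (w in x$warnings) cat("  warning: ", w, "\n", sep = "")
  invisible(x)
}

# --- helpers -----------------------------------------------------------------

read_delim_auto <- function(path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  read.table(path, header = TRUE, sep = sep, stringsAsFactors = FALSE,
             check.names = FALSE, colClasses = "character",
             na.strings = character(), quote = "\"", comment.char = "")
}

resolve_state_inventories <- function(states) {
  if (is.null(states)) {
    return(list())
  }
  if (is.character(states) && length(states) == 1L) {
    states <- if (grepl("\\.json$", states, ignore.case = TRUE)) {
      jsonlite::read_json(states, simplifyVector = TRUE)
    } else {
      yaml::read_yaml(states)
    }
  }
  if (!is.list(states) || is.null(names(states))) {
    stop("state inventories must be a named list (feature -> state labels)")
  }
  lapply(states, as.character)
}

#' Read a user-supplied cost matrix
#'
#' Square delimited text with a header row and a leading id column; row and
#' column ids must agree. The matrix is passed through [build_cost_matrix()]
#' (symmetrization, validation).
#'
#' @param path file path.
#' @param ids optional character vector: reorder/subset to these ids.
#' @return A symmetric cost matrix.
#' @export
read_cost_matrix <- function(path, ids = NULL) {
  raw <- read_delim_auto(path)
  rn <- as.character(raw[[1L]])
  m <- as.matrix(raw[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- rn
  if (!setequal(rownames(m), colnames(m))) {
    stop("cost matrix row and column ids differ")
  }
  m <- m[, rownames(m), drop = FALSE]
  if (!is.null(ids)) {
    missing_ids <- setdiff(ids, rownames(m))
    if (length(missing_ids)) {
      stop("cost matrix missing ids: ", paste(missing_ids, collapse = ", "))
    }
    m <- m[ids, ids, drop = FALSE]
  }
  build_cost_matrix(NULL, custom = m)
}
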