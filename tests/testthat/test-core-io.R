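# Readers/writers, cost matrices and dataset validation.

test_that("feature tables are read with inferred alphabetical state order", {
  tf <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("id,f1", "a,present", "b,absent"), tf)
  ft <- read_feature_table(tf)
  expect_equal(ft$states$f1, c("absent", "present"))
  expect_equal(unname(ft$data[, 1]), c(2L, 1L)) # present, absent
})

test_that("a three-state feature gets alphabetical indices", {
  tf <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("id,base", "a,decimal", "b,hybrid", "c,vigesimal"), tf)
  ft <- read_feature_table(tf)
  expect_equal(ft$states$base, c("decimal", "hybrid", "vigesimal"))
  expect_equal(unname(ft$data[, 1]), 1:3)
})

test_that("the missing token becomes a missing cell", {
  tf <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("id,f1", "a,x", "b,?", "c,y"), tf)
  ft <- read_feature_table(tf)
  expect_true(is.na(ft$data["b", 1]))
  tf2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("id,f1", "a,x", "b,NA", "c,y"), tf2)
  ft2 <- read_feature_table(tf2, missing_token = "NA")
  expect_true(is.na(ft2$data["b", 1]))
})

test_that("declared inventories keep file order and reject unknown labels", {
  tf <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("id,f1", "a,x", "b,y"), tf)
  ft <- read_feature_table(tf, states = list(f1 = c("y", "x", "z")))
  expect_equal(ft$states$f1, c("y", "x", "z"))
  expect_equal(unname(ft$data[, 1]), c(2L, 1L))
  expect_error(read_feature_table(tf, states = list(f1 = c("x", "z"))),
               "not in declared inventory")
})

test_that("degenerate feature tables are rejected", {
  tf <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("id,f1", "a,x", "a,y"), tf)
  expect_error(read_feature_table(tf), "duplicate entity ids")
  tf2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("id,f1", "a,x", "b,x"), tf2)
  expect_error(read_feature_table(tf2), "fewer than two observed states")
})

test_that("write/read round-trips cell values and state inventories", {
  d <- fixture_dataset(L = 12, F_ = 5, seed = 3, missing_rate = 0.15)
  tf <- withr::local_tempfile(fileext = ".csv")
  write_feature_table(d, tf)
  ft <- read_feature_table(tf, states = d$states)
  expect_identical(unname(ft$data), unname(d$X))
  expect_identical(ft$states, d$states)
  # and with inferred inventories the labels still round-trip
  ft2 <- read_feature_table(tf)
  lab <- function(data, states) {
    vapply(seq_len(ncol(data)),
           function(j) paste(states[[j]][data[, j]], collapse = "|"),
           "")
  }
  expect_identical(lab(ft2$data, ft2$states), lab(d$X, d$states))
})

test_that("euclidean costs: 3-4-5 triangle and metric properties", {
  loc <- data.frame(id = c("a", "b"), x = c(0, 3), y = c(0, 4))
  cm <- build_cost_matrix(loc, metric = "euclidean")
  expect_equal(cm["a", "b"], 5)
  set.seed(7)
  loc2 <- data.frame(id = sprintf("p%d", 1:8), x = runif(8), y = runif(8))
  cm2 <- build_cost_matrix(loc2, metric = "euclidean")
  expect_equal(cm2, t(cm2))
  expect_true(all(diag(cm2) == 0))
  for (i in 1:8) for (j in 1:8) for (k in 1:8) {
    expect_lte(cm2[i, j], cm2[i, k] + cm2[k, j] + 1e-12)
  }
})

test_that("great-circle costs: a quarter circle is pi * R / 2 km", {
  loc <- data.frame(id = c("a", "b"), x = c(0, 90), y = c(0, 0))
  cm <- build_cost_matrix(loc, metric = "great_circle")
  expect_equal(cm["a", "b"], 6371 * pi / 2, tolerance = 1e-6)
  same <- data.frame(id = c("a", "b"), x = c(10, 10), y = c(20, 20))
  cms <- build_cost_matrix(same, metric = "great_circle")
  expect_equal(cms["a", "b"], 0)
})

test_that("user cost matrices are symmetrized by averaging", {
  m <- matrix(c(0, 2, 4, 0), 2, 2) # c12 = 4, c21 = 2 (column-major)
  cm <- build_cost_matrix(NULL, custom = m)
  expect_equal(cm[1, 2], 3)
  expect_equal(cm[2, 1], 3)
  expect_error(build_cost_matrix(NULL, custom = matrix(c(0, -1, -1, 0), 2)),
               "negative")
})

test_that("coordinate auto-detection and override work", {
  tf <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("id,f1", "a,x", "b,y"), tf)
  ft <- read_feature_table(tf)
  loc_deg <- data.frame(id = c("a", "b"), x = c(10, 20), y = c(0, 5),
                        family = NA_character_)
  d1 <- sb_dataset(ft, loc_deg)
  expect_equal(d1$coord_type, "spherical")
  d2 <- sb_dataset(ft, loc_deg, coord = "planar")
  expect_equal(d2$coord_type, "planar")
  loc_pl <- data.frame(id = c("a", "b"), x = c(1000, 2000), y = c(0, 5))
  expect_equal(sb_dataset(ft, loc_pl)$coord_type, "planar")
})

test_that("validation reports small families and low coverage", {
  d <- fixture_dataset(L = 9, F_ = 3, n_fam = 3, seed = 2)
  rep1 <- validate_dataset(d)
  expect_length(rep1$errors, 0)
  expect_true(any(grepl("family", rep1$warnings)))
  # a fully consistent dataset: one family of 6
  d2 <- fixture_dataset(L = 9, F_ = 3, n_fam = 1, seed = 2)
  expect_length(validate_dataset(d2)$errors, 0)
  expect_length(validate_dataset(d2)$warnings, 0)
  # feature missing everywhere is a hard error in the report
  d3 <- fixture_dataset(L = 6, F_ = 2, n_fam = 1, seed = 4)
  d3$X[, 2] <- NA_integer_
  rep3 <- validate_dataset(d3)
  expect_true(any(grepl("missing in all entities", rep3$errors)))
})
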