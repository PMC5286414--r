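test_that("community CSV ingest validates and preserves axis order", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("taxon,d13C,d15N", "a,0,0", "b,1,0", "c,0,1"), path)
  cm <- read_community(path)
  expect_s3_class(cm, "community_matrix")
  expect_equal(n_taxa(cm), 3L)
  expect_equal(n_axes(cm), 2L)
  expect_identical(axis_names(cm), c("d13C", "d15N"))
  expect_equal(unname(cm$values), rbind(c(0, 0), c(1, 0), c(0, 1)))

  writeLines(c("taxon,x,y", "Lepomis,0,0", "Lepomis,1,1"), path)
  expect_error(read_community(path), class = "nichehull_duplicate_taxon_error")

  writeLines(c("taxon,x,y", "a,0,0", "b,,1"), path)
  err <- tryCatch(read_community(path), error = identity)
  expect_s3_class(err, "nichehull_missing_value_error")
  expect_match(conditionMessage(err), "row 2, column 'x'")

  writeLines(c("taxon,x,y", "a,0,zebra"), path)
  err <- tryCatch(read_community(path), error = identity)
  expect_s3_class(err, "nichehull_parse_error")
  expect_match(conditionMessage(err), "row 1, column 'y'")
})

test_that("drop_incomplete drops rows with a report instead of imputing", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("taxon,x,y", "a,0,0", "b,,1", "c,2,2"), path)
  expect_message(cm <- read_community(path, drop_incomplete = TRUE),
                 "dropped 1 incomplete row")
  expect_identical(taxa(cm), c("a", "c"))
})

test_that("individuals ingest groups by taxon and flags boundary cases", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("taxon,x,y", "A,0,0", "A,2,2", "A,1,1",
               "B,5,5", "B,6,6", "B,7,7"), path)
  obs <- read_individuals(path)
  expect_equal(nrow(obs$values), 6L)
  expect_equal(taxon_counts(obs), c(A = 3L, B = 3L))

  writeLines(c("taxon,x,y", "A,0,0", "B,1,1"), path)
  expect_warning(obs1 <- read_individuals(path), class = "nichehull_warning")
  expect_equal(unname(taxon_counts(obs1)), c(1L, 1L))

  writeLines("taxon,x,y", path)
  expect_error(read_individuals(path), class = "nichehull_empty_taxon_error")
})

test_that("taxon_means averages per taxon and is idempotent", {
  obs <- suppressWarnings(individual_observations(
    c("A", "A", "B"), rbind(c(0, 0), c(2, 2), c(4, 6)),
    axes = axis_descriptor(c("x", "y"))))
  cm <- taxon_means(obs)
  expect_equal(unname(cm$values), rbind(c(1, 1), c(4, 6)))

  obs3 <- individual_observations(
    rep("A", 3), rbind(c(0, 0), c(0, 3), c(3, 0)))
  expect_equal(unname(taxon_means(obs3)$values), rbind(c(1, 1)))

  # one individual per taxon: means reproduce the table exactly
  single <- suppressWarnings(individual_observations(
    c("A", "B"), rbind(c(0.1, 0.2), c(0.3, 0.4))))
  expect_equal(unname(taxon_means(single)$values),
               rbind(c(0.1, 0.2), c(0.3, 0.4)))
})

test_that("estimate table enforces completeness, sd >= 0 and bounds", {
  axes <- axis_descriptor(c("algae", "TP"), unit = c("fraction", "TP"),
                          lower = c(0, -Inf), upper = c(1, Inf))
  est <- estimate_table(rep(c("A", "B"), each = 2),
                        rep(c("algae", "TP"), 2),
                        mean = c(0.4, 2.1, 0.6, 3.0),
                        sd = c(0.1, 0.2, 0.1, 0.2), axes = axes)
  expect_equal(unname(estimate_means(est)["A", ]), c(0.4, 2.1))

  expect_error(
    estimate_table("A", "algae", mean = 0.4, sd = -1, axes = axes),
    class = "nichehull_validation_error")
  expect_error(  # mean outside declared bounds
    estimate_table(rep("A", 2), c("algae", "TP"), mean = c(1.4, 2),
                   sd = c(0.1, 0.1), axes = axes),
    class = "nichehull_validation_error")
  expect_error(  # missing cell
    estimate_table(c("A", "A", "B"), c("algae", "TP", "algae"),
                   mean = c(0.4, 2, 0.5), sd = c(0, 0, 0), axes = axes),
    class = "nichehull_missing_value_error")
})

test_that("all three table kinds round-trip through CSV at full precision", {
  dir <- withr::local_tempdir()
  set.seed(11)
  X <- random_community_matrix(6, 3)
  cm <- community_matrix(X)
  p1 <- file.path(dir, "cm.csv")
  write_community(cm, p1)
  expect_equal(read_community(p1)$values, cm$values)

  obs <- generate_individuals(cm, k = 4, sd = 0.5, seed = 9)
  p2 <- file.path(dir, "obs.csv")
  write_individuals(obs, p2)
  back <- read_individuals(p2)
  expect_equal(back$values, obs$values)
  expect_identical(back$taxon, obs$taxon)

  est <- generate_estimate_table(cm, sd_map = 0.25)
  p3 <- file.path(dir, "est.csv")
  write_estimates(est, p3)
  back <- read_estimates(p3, axes = cm$axes)
  expect_equal(back$table, est$table)
})

test_that("metric CSV writes one row per metric and round-trips", {
  ms <- compute_all_metrics(triangle_cm())
  path <- withr::local_tempfile(fileext = ".csv")
  write_metrics(ms, path)
  back <- read_metrics(path)
  expect_equal(nrow(back), 6L)  # 2 ranges + cd, nnd, sdnnd, chv
  expect_equal(back$point, as.numeric(ms))
  expect_true(all(is.na(back$lower)))

  cis <- metric_ci_set(names(ms), as.numeric(ms), as.numeric(ms) - 0.1,
                       as.numeric(ms) + 0.1, replicates = 100L, level = 0.9,
                       seed = 7L)
  write_metrics(cis, path)
  header <- grep("^#", readLines(path), value = TRUE)
  expect_true(any(grepl("level=0.9", header)))
  expect_true(any(grepl("replicates=100", header)))
  back <- read_metrics(path)
  expect_equal(back$lower, cis$lower)
  expect_equal(attr(back, "seed"), 7L)
})

test_that("axis config sidecar parses bounds and run settings", {
  path <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(list(
    axes = list(list(name = "algae", unit = "fraction", lower = 0, upper = 1),
                list(name = "TP", unit = "TP")),
    ci_level = 0.9, replicates = 500, seed = 3), path, auto_unbox = TRUE)
  cfg <- read_axes_config(path)
  expect_equal(cfg$axes$lower, c(0, -Inf))
  expect_equal(cfg$axes$upper, c(1, Inf))
  expect_equal(cfg$replicates, 500L)
  expect_equal(cfg$ci_level, 0.9)
})

test_that("constructors reject inverted bounds and bad axis sets", {
  expect_error(axis_descriptor("x", lower = 2, upper = 1),
               class = "nichehull_validation_error")
  expect_error(axis_descriptor(c("x", "x")),
               class = "nichehull_validation_error")
  expect_error(
    community_matrix(rbind(c(0, 0), c(1, NA)), taxa = c("a", "b")),
    class = "nichehull_missing_value_error")
})
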