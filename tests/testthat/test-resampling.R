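make_obs <- function(S = 4, k = 6, sd = 0.3, seed = 21) {
  set.seed(seed)
  cm <- community_matrix(random_community_matrix(S, 2))
  generate_individuals(cm, k = k, sd = sd, seed = seed)
}

test_that("percentile_ci follows the documented type-7 quantile rule", {
  ci <- percentile_ci(1:100, level = 0.95)
  expect_equal(unname(ci), c(3.475, 97.525))
  expect_equal(unname(percentile_ci(rep(5, 10), 0.95)), c(5, 5))
  expect_error(percentile_ci(1:10, level = 0), class = "nichehull_validation_error")
  expect_error(percentile_ci(1:10, level = 1.5), class = "nichehull_validation_error")
  expect_error(percentile_ci(c(NA_real_, NA_real_)),
               class = "nichehull_undefined_ci_error")
})

test_that("nonparametric bootstrap is bit-reproducible under a fixed seed", {
  obs <- make_obs()
  cfg <- resampling_config(replicates = 200L, seed = 42L)
  a <- suppressWarnings(nonparametric_bootstrap(obs, cfg))
  b <- suppressWarnings(nonparametric_bootstrap(obs, cfg))
  expect_identical(a, b)
  c2 <- suppressWarnings(nonparametric_bootstrap(
    obs, resampling_config(replicates = 200L, seed = 43L)))
  expect_false(identical(a$lower, c2$lower))
})

test_that("zero within-taxon variance yields zero-width CIs at the point estimate", {
  cm <- community_matrix(random_community_matrix(5, 2))
  obs <- generate_individuals(cm, k = 5, sd = 0, seed = 1)
  cis <- nonparametric_bootstrap(obs, resampling_config(replicates = 100L, seed = 1L))
  expect_equal(cis$lower, cis$point)
  expect_equal(cis$upper, cis$point)
})

test_that("per-taxon substreams: adding a taxon leaves other taxa's draws alone", {
  cm <- community_matrix(random_community_matrix(4, 2))
  obs4 <- generate_individuals(cm, k = 8, sd = 0.5, seed = 7)
  cm5 <- community_matrix(rbind(cm$values, extra = c(50, 50)),
                          taxa = c(taxa(cm), "extra"))
  obs5 <- generate_individuals(cm5, k = 8, sd = 0.5, seed = 7)
  shared <- obs5$taxon %in% taxa(cm)
  expect_identical(obs5$values[shared, ], obs4$values)
})

test_that("bootstrap CIs from two seeds agree within Monte-Carlo tolerance", {
  set.seed(33)
  base <- community_matrix(random_community_matrix(8, 2, scale = 8))
  # enforce taxon separation >= 2 so the bias-negligible regime holds
  while (min(stats::dist(base$values)) < 2) {
    base <- community_matrix(random_community_matrix(8, 2, scale = 8))
  }
  obs <- generate_individuals(base, k = 10, sd = 0.1, seed = 5)
  B <- 1000L
  a <- suppressWarnings(nonparametric_bootstrap(
    obs, resampling_config(replicates = B, seed = 1L), metrics = "cd"))
  b <- suppressWarnings(nonparametric_bootstrap(
    obs, resampling_config(replicates = B, seed = 2L), metrics = "cd"))
  se <- a$boot_sd / sqrt(B)
  expect_lt(abs(a$lower - b$lower), 3 * se + 3 * b$boot_sd / sqrt(B))
  expect_lt(abs(a$upper - b$upper), 3 * se + 3 * b$boot_sd / sqrt(B))
})

test_that("CI width shrinks toward zero as within-taxon noise vanishes", {
  cm <- community_matrix(random_community_matrix(6, 2))
  widths <- vapply(c(1, 0.3, 0.05, 0.005), function(s) {
    obs <- generate_individuals(cm, k = 8, sd = s, seed = 3)
    cis <- suppressWarnings(nonparametric_bootstrap(
      obs, resampling_config(replicates = 300L, seed = 4L), metrics = "cd"))
    cis$upper - cis$lower
  }, numeric(1))
  expect_true(all(diff(widths) < 0))
  expect_lt(widths[4], 0.02)
})

test_that("rtruncnorm respects bounds and matches half-normal moments", {
  set.seed(61)
  x <- rtruncnorm(1e5, mean = 0, sd = 1, lower = 0)
  expect_true(all(x >= 0))
  # half-normal mean sqrt(2/pi); MC standard error of the mean ~ sd/sqrt(n)
  expect_lt(abs(mean(x) - sqrt(2 / pi)), 4 * stats::sd(x) / sqrt(length(x)))
  expect_lt(abs(stats::var(x) - (1 - 2 / pi)), 0.01)

  y <- rtruncnorm(1e4, mean = 0.5, sd = 2, lower = 0, upper = 1)
  expect_true(all(y >= 0 & y <= 1))
  expect_equal(rtruncnorm(5, mean = 3, sd = 0, lower = 0, upper = 10),
               rep(3, 5))
  expect_error(rtruncnorm(1, mean = 0, sd = -1),
               class = "nichehull_validation_error")
  expect_error(rtruncnorm(1, mean = 0, sd = 0, lower = 1, upper = 2),
               class = "nichehull_validation_error")
})

test_that("parametric resampling truncates to axis bounds and hits sd = 0 exactly", {
  axes <- axis_descriptor(c("algae", "c3"), unit = "fraction",
                          lower = 0, upper = 1)
  cm <- community_matrix(rbind(a = c(0.1, 0.8), b = c(0.5, 0.3),
                               c = c(0.9, 0.1)), axes = axes)
  est <- generate_estimate_table(cm, sd_map = 0.4)
  cfg <- resampling_config(replicates = 400L, seed = 11L, scheme = "parametric")
  cis <- suppressWarnings(parametric_resample(est, cfg))
  for (ax in c("algae", "c3")) {
    row <- cis[cis$metric == paste0("range_", ax), ]
    expect_lte(row$upper, 1)  # a range of [0,1]-bounded draws is at most 1
  }
  expect_identical(suppressWarnings(parametric_resample(est, cfg)), cis)

  est0 <- generate_estimate_table(cm, sd_map = 0)
  cis0 <- parametric_resample(est0, cfg)
  expect_equal(cis0$lower, cis0$point)
  expect_equal(cis0$upper, cis0$point)
})

test_that("degenerate CHV replicates are dropped from the CHV distribution only", {
  # 3 taxa in 2-D with k = 1: every bootstrap replicate reproduces the same
  # 3 points, so CHV stays defined; contrast with a 2-axis community whose
  # resampled points can collapse. Build collapse deliberately: two taxa
  # share identical individuals, so many replicates are collinear.
  obs <- suppressWarnings(individual_observations(
    rep(c("a", "b", "c"), each = 2),
    rbind(c(0, 0), c(1, 1), c(0, 0), c(1, 1), c(5, 0), c(5, 0))))
  cis <- suppressWarnings(nonparametric_bootstrap(
    obs, resampling_config(replicates = 200L, seed = 2L)))
  chv_row <- cis[cis$metric == "chv", ]
  other <- cis[cis$metric != "chv", ]
  expect_true(all(other$n_used == 200L))
  expect_lte(chv_row$n_used, 200L)
})

test_that("community comparison flags exactly the non-overlapping CIs", {
  mk <- function(lower, upper) {
    metric_ci_set(c("cd", "nnd"), point = (lower + upper) / 2,
                  lower = lower, upper = upper,
                  replicates = 10L, level = 0.95, seed = 1L)
  }
  rep1 <- compare_communities(mk(c(0, 0), c(1, 1)), mk(c(2, 1), c(3, 3)))
  expect_identical(rep1$flagged_different, c(TRUE, FALSE))  # touching overlaps
  expect_identical(rep1$overlap, !rep1$flagged_different)
  rep2 <- compare_communities(mk(c(0, 0), c(2, 2)), mk(c(1, 1), c(3, 3)))
  expect_false(any(rep2$flagged_different))
  expect_error(
    compare_communities(mk(c(0, 0), c(1, 1)),
                        metric_ci_set("cd", 1, 0, 2, replicates = 10L,
                                      level = 0.95, seed = 1L)),
    class = "nichehull_validation_error")
})

test_that("resampling_config validates its domain", {
  expect_error(resampling_config(level = 1.5), class = "nichehull_validation_error")
  expect_error(resampling_config(replicates = 0), class = "nichehull_validation_error")
  cfg <- resampling_config()
  expect_equal(cfg$replicates, 10000L)
  expect_equal(cfg$level, 0.95)
  obs <- make_obs()
  expect_error(nonparametric_bootstrap(obs, resampling_config(scheme = "parametric")),
               class = "nichehull_validation_error")
})
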