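# Resampling-based confidence intervals for the metric set. Two schemes:
# non-parametric (bootstrap individuals within each taxon, recompute taxon
# means, recompute metrics) and parametric (draw every taxon x axis value
# from a truncated normal with the supplied mean/SD). Both use one root seed
# with per-taxon substreams derived from a hash of the taxon name, so adding
# or removing a taxon leaves the other taxa's draws untouched.

#' Resampling configuration
#'
#' @param replicates number of resampling replicates (default 10000).
#' @param level confidence level in (0, 1) (default 0.95).
#' @param seed integer root seed; every random draw derives from it, so a
#'   fixed seed gives bit-identical output.
#' @param scheme `"nonparametric"` (individual-level bootstrap) or
#'   `"parametric"` (truncated-normal draws from an estimate table).
#' @return a list of class `resampling_config`.
#' @export
resampling_config <- function(replicates = 10000L, level = 0.95, seed = 1L,
                              scheme = c("nonparametric", "parametric")) {
  scheme <- match.arg(scheme)
  if (!(is.numeric(replicates) && length(replicates) == 1L && replicates >= 1)) {
    stop_validation("replicates must be a single integer >= 1")
  }
  if (!(is.numeric(level) && length(level) == 1L && level > 0 && level < 1)) {
    stop_validation("confidence level must lie strictly in (0, 1)")
  }
  if (!(is.numeric(seed) && length(seed) == 1L && is.finite(seed))) {
    stop_validation("seed must be a single integer")
  }
  structure(list(replicates = as.integer(replicates), level = as.numeric(level),
                 seed = as.integer(seed), scheme = scheme),
            class = "resampling_config")
}

# Deterministic 31-adic string hash folded into [0, 2^31 - 2]; combined with
# the root seed it keys a taxon's private RNG substream.
taxon_seed <- function(root, name) {
  h <- 0
  for (b in utf8ToInt(enc2utf8(name))) h <- (h * 31 + b) %% 2147483647
  as.integer((abs(as.numeric(root)) + h) %% 2147483647)
}

with_preserved_rng <- function(code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  force(code)
}

#' Truncated normal draws (inverse-CDF)
#'
#' Samples `normal(mean, sd)` conditioned on `[lower, upper]` by mapping
#' uniform draws through the normal quantile function — a deterministic one
#' draw per value, so resampling streams are seed-stable. `sd = 0` returns
#' `mean` (which must lie inside the bounds).
#'
#' @param n number of draws.
#' @param mean,sd distribution parameters (`sd >= 0`).
#' @param lower,upper truncation bounds (may be infinite).
#' @return numeric vector of `n` draws, all within `[lower, upper]`.
#' @export
rtruncnorm <- function(n, mean = 0, sd = 1, lower = -Inf, upper = Inf) {
  if (sd < 0) stop_validation("sd must be >= 0")
  if (lower >= upper) stop_validation("lower bound must be < upper bound")
  u <- stats::runif(n)
  if (sd == 0) {
    if (mean < lower || mean > upper) {
      stop_validation("sd = 0 with mean outside the truncation bounds")
    }
    return(rep(mean, n))
  }
  plo <- stats::pnorm(lower, mean, sd)
  phi <- stats::pnorm(upper, mean, sd)
  if (phi - plo <= 0) {
    stop_validation(sprintf(
      "truncation interval [%g, %g] has zero admissible mass under normal(%g, %g)",
      lower, upper, mean, sd))
  }
  pmin(pmax(stats::qnorm(plo + u * (phi - plo), mean, sd), lower), upper)
}

#' Percentile confidence interval
#'
#' Equal-tailed empirical quantiles of a resampling distribution at
#' probabilities `(1 - level)/2` and `1 - (1 - level)/2`. Quantile rule:
#' linear interpolation between order statistics (R's default type 7), so
#' e.g. samples `1:100` at level 0.95 give (3.475, 97.525). `NA` replicates
#' are ignored; if no finite replicate remains the CI is undefined.
#'
#' @param samples numeric vector of replicate statistic values.
#' @param level confidence level in (0, 1).
#' @return named numeric vector `c(lower, upper)`.
#' @export
percentile_ci <- function(samples, level = 0.95) {
  if (!(is.numeric(level) && length(level) == 1L && level > 0 && level < 1)) {
    stop_validation("confidence level must lie strictly in (0, 1)")
  }
  s <- samples[is.finite(samples)]
  if (length(s) == 0L) stop_undefined_ci("all replicate values are undefined")
  alpha <- (1 - level) / 2
  q <- stats::quantile(s, probs = c(alpha, 1 - alpha), names = FALSE, type = 7)
  c(lower = q[1L], upper = q[2L])
}

# Shared back half of both resamplers: replicate metric matrix -> CI set.
# reps: B x n_metric matrix; point: named point-estimate vector.
ci_set_from_replicates <- function(point, reps, cfg) {
  B <- nrow(reps)
  nm <- colnames(reps)
  lower <- upper <- bmean <- bsd <- rep(NA_real_, length(nm))
  n_used <- rep(B, length(nm))
  for (j in seq_along(nm)) {
    v <- reps[, j]
    finite <- is.finite(v)
    n_used[j] <- sum(finite)
    if (nm[j] == "chv" && n_used[j] < B) {
      dropped <- B - n_used[j]
      if (dropped > B / 2) {
        nh_warn(sprintf(
          "CHV undefined in %d of %d replicates (> 50%%); CHV CI reported as undefined",
          dropped, B))
        n_used[j] <- 0L
        next
      }
      nh_warn(sprintf(
        "CHV undefined in %d of %d replicates; those replicates were dropped from the CHV distribution only",
        dropped, B))
    }
    ci <- tryCatch(percentile_ci(v, cfg$level),
                   nichehull_undefined_ci_error = function(e) NULL)
    if (is.null(ci)) { n_used[j] <- 0L; next }
    lower[j] <- ci[["lower"]]; upper[j] <- ci[["upper"]]
    bmean[j] <- mean(v[finite]); bsd[j] <- stats::sd(v[finite])
  }
  metric_ci_set(metric = nm, point = as.numeric(point[nm]),
                lower = lower, upper = upper, boot_mean = bmean, boot_sd = bsd,
                n_used = n_used, replicates = B, level = cfg$level,
                seed = cfg$seed, scheme = cfg$scheme)
}

metric_selection <- function(metrics, axis_names) {
  all_kinds <- c("ranges", "cd", "nnd", "sdnnd", "chv")
  if (is.null(metrics)) return(all_kinds)
  bad <- setdiff(metrics, all_kinds)
  if (length(bad)) {
    stop_validation(sprintf("unknown metric selection: %s (choose from %s)",
                            paste(bad, collapse = ", "),
                            paste(all_kinds, collapse = ", ")))
  }
  all_kinds[all_kinds %in% metrics]
}

replicate_metrics <- function(arr, axis_names, which_metrics) {
  S <- dim(arr)[1L]; n <- dim(arr)[2L]; B <- dim(arr)[3L]
  first <- metrics_from_matrix(matrix(arr[, , 1L], S, n), axis_names, which_metrics)
  reps <- matrix(NA_real_, B, length(first),
                 dimnames = list(NULL, names(first)))
  reps[1L, ] <- first
  if (B > 1L) {
    for (b in 2L:B) {
      reps[b, ] <- metrics_from_matrix(matrix(arr[, , b], S, n),
                                       axis_names, which_metrics)
    }
  }
  reps
}

#' Non-parametric bootstrap confidence intervals
#'
#' For each replicate, the `k_t` individuals of every taxon are redrawn with
#' replacement from that taxon's own `k_t` records (resampling is independent
#' across taxa), taxon means are recomputed, and the full metric set is
#' recalculated; percentile CIs are then read off the replicate
#' distributions. The point estimate is computed from the original taxon
#' means. Replicates in which the resampled points are degenerate contribute
#' `NA` to the CHV distribution only and are dropped from it (with a warning;
#' if more than half the replicates are degenerate the CHV CI itself is
#' reported undefined).
#'
#' @param obs an [individual_observations()] object covering at least 2 taxa.
#' @param cfg a [resampling_config()] with `scheme = "nonparametric"`.
#' @param metrics optional subset of `c("ranges","cd","nnd","sdnnd","chv")`
#'   to restrict computation (e.g. `"cd"` alone for large simulation
#'   studies); default computes everything.
#' @return a [metric_ci_set()].
#' @export
nonparametric_bootstrap <- function(obs, cfg = resampling_config(), metrics = NULL) {
  stopifnot(inherits(obs, "individual_observations"))
  if (!identical(cfg$scheme, "nonparametric")) {
    stop_validation("cfg$scheme must be 'nonparametric' for nonparametric_bootstrap()")
  }
  k <- taxon_counts(obs)
  if (length(k) < 2L) stop_insufficient_taxa("bootstrap needs at least 2 taxa")
  if (any(k == 0L)) stop_empty_taxon("a taxon has no records")
  which_metrics <- metric_selection(metrics, obs$axes$name)
  tx <- names(k)
  S <- length(tx); n <- ncol(obs$values); B <- cfg$replicates

  cm0 <- suppressWarnings(taxon_means(obs))
  point <- suppressWarnings(metrics_from_matrix(cm0$values, obs$axes$name,
                                                which_metrics))

  arr <- array(NA_real_, c(S, n, B))
  with_preserved_rng({
    for (ti in seq_along(tx)) {
      rows <- which(obs$taxon == tx[ti])
      kt <- length(rows)
      set.seed(taxon_seed(cfg$seed, tx[ti]))
      idx <- sample.int(kt, kt * B, replace = TRUE)
      for (j in seq_len(n)) {
        v <- obs$values[rows, j]
        arr[ti, j, ] <- .colMeans(v[idx], kt, B)
      }
    }
  })
  reps <- replicate_metrics(arr, obs$axes$name, which_metrics)
  ci_set_from_replicates(point, reps, cfg)
}

#' Parametric (truncated-normal) resampling confidence intervals
#'
#' For each replicate, every (taxon, axis) value is drawn independently from
#' a normal distribution with that cell's mean and SD, truncated to the
#' axis's declared mathematically admissible range (e.g. diet fractions to
#' \[0, 1\]); the metric set is recomputed per replicate and percentile CIs
#' are read off. Axes without declared bounds are untruncated.
#'
#' @param est an [estimate_table()] (means, SDs, axis bounds).
#' @param cfg a [resampling_config()] with `scheme = "parametric"`.
#' @inheritParams nonparametric_bootstrap
#' @return a [metric_ci_set()].
#' @export
parametric_resample <- function(est, cfg = resampling_config(scheme = "parametric"),
                                metrics = NULL) {
  stopifnot(inherits(est, "estimate_table"))
  if (!identical(cfg$scheme, "parametric")) {
    stop_validation("cfg$scheme must be 'parametric' for parametric_resample()")
  }
  M0 <- estimate_means(est)
  SD <- estimate_sds(est)
  if (nrow(M0) < 2L) stop_insufficient_taxa("resampling needs at least 2 taxa")
  which_metrics <- metric_selection(metrics, est$axes$name)
  S <- nrow(M0); n <- ncol(M0); B <- cfg$replicates
  lo <- est$axes$lower; hi <- est$axes$upper

  point <- suppressWarnings(metrics_from_matrix(M0, est$axes$name, which_metrics))

  arr <- array(NA_real_, c(S, n, B))
  with_preserved_rng({
    for (ti in seq_len(S)) {
      set.seed(taxon_seed(cfg$seed, rownames(M0)[ti]))
      for (j in seq_len(n)) {
        arr[ti, j, ] <- rtruncnorm(B, M0[ti, j], SD[ti, j], lo[j], hi[j])
      }
    }
  })
  reps <- replicate_metrics(arr, est$axes$name, which_metrics)
  ci_set_from_replicates(point, reps, cfg)
}

#' Compare two communities by confidence-interval overlap
#'
#' The inferential device is deliberately minimal: two communities are
#' flagged as differing on a metric exactly when their resampling CIs fail to
#' intersect. Intervals are closed — a shared endpoint counts as overlap.
#' Metrics whose CI is undefined in either set yield `NA` flags.
#'
#' @param a,b [metric_ci_set()] objects over the same metric names.
#' @return a data.frame of class `comparison_report`: per metric both CIs,
#'   `overlap`, and `flagged_different` (`= !overlap`).
#' @export
compare_communities <- function(a, b) {
  stopifnot(inherits(a, "metric_ci_set"), inherits(b, "metric_ci_set"))
  if (!setequal(a$metric, b$metric) || anyDuplicated(a$metric)) {
    stop_validation("the two CI sets must cover the same metric names")
  }
  bb <- b[match(a$metric, b$metric), , drop = FALSE]
  overlap <- a$lower <= bb$upper & bb$lower <= a$upper
  structure(data.frame(
    metric = a$metric,
    a_point = a$point, a_lower = a$lower, a_upper = a$upper,
    b_point = bb$point, b_lower = bb$lower, b_upper = bb$upper,
    overlap = overlap, flagged_different = !overlap,
    stringsAsFactors = FALSE
  ), class = c("comparison_report", "data.frame"))
}

#' @export
print.comparison_report <- function(x, ...) {
  cat("<comparison_report> flagged metrics:",
      if (any(x$flagged_different, na.rm = TRUE))
        paste(x$metric[which(x$flagged_different)], collapse = ", ")
      else "none", "\n")
  print.data.frame(x)
  invisible(x)
}
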