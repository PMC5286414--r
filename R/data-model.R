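#' Axis descriptor table
#'
#' Builds the axis metadata table used by [community_matrix()] and friends.
#' Each niche axis has a name, a unit label (e.g. `"permil"`, `"fraction"`,
#' `"TP"`) and optional numeric bounds. Bounds matter only for parametric
#' resampling, where draws are truncated to the mathematically admissible
#' range of the axis (a diet fraction lives in \[0, 1\]); axes without a
#' stated physical range are unbounded by default.
#'
#' @param name character vector of axis names (unique, non-empty).
#' @param unit character vector of unit labels, recycled to length of `name`.
#' @param lower,upper numeric vectors of bounds, recycled; use `-Inf`/`Inf`
#'   for unbounded axes.
#' @return a `data.frame` with columns `name`, `unit`, `lower`, `upper`.
#' @export
#' @examples
#' axis_descriptor(c("d13C", "d15N"), unit = "permil")
axis_descriptor <- function(name, unit = "", lower = -Inf, upper = Inf) {
  name <- as.character(name)
  if (length(name) == 0L) stop_validation("at least one axis is required")
  if (anyNA(name) || any(!nzchar(name))) {
    stop_validation("axis names must be non-empty")
  }
  if (anyDuplicated(name)) {
    stop_validation(sprintf("duplicate axis name: '%s'",
                            name[duplicated(name)][1L]))
  }
  out <- data.frame(
    name = name,
    unit = rep_len(as.character(unit), length(name)),
    lower = rep_len(as.numeric(lower), length(name)),
    upper = rep_len(as.numeric(upper), length(name)),
    stringsAsFactors = FALSE
  )
  bad <- is.finite(out$lower) & is.finite(out$upper) & !(out$lower < out$upper)
  if (any(bad)) {
    stop_validation(sprintf("axis '%s': lower bound must be < upper bound",
                            out$name[which(bad)[1L]]))
  }
  out
}

default_axes <- function(names) axis_descriptor(names)

#' Community matrix of taxon-mean niche coordinates
#'
#' The central container: S taxa by n niche axes of taxon-mean coordinates
#' (isotope ratios, trophic position, diet fractions, traits ... on their raw
#' scales). All dispersion metrics ([compute_all_metrics()]) operate on this
#' object.
#'
#' @param values numeric matrix (or data.frame) S x n; rownames are taxon ids
#'   unless `taxa` is given.
#' @param taxa character vector of taxon identifiers (unique, non-empty).
#' @param axes an axis table from [axis_descriptor()], or `NULL` to derive
#'   unbounded axes from the column names of `values`.
#' @return an object of class `community_matrix`: a list with elements
#'   `values` (named numeric matrix) and `axes` (axis table).
#' @seealso [read_community()], [taxon_means()], [compute_all_metrics()]
#' @export
#' @examples
#' cm <- community_matrix(rbind(a = c(0, 0), b = c(1, 0), c = c(0, 1)),
#'                        axes = axis_descriptor(c("d13C", "d15N")))
#' n_taxa(cm)
community_matrix <- function(values, taxa = rownames(values), axes = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(axes)) {
    cn <- colnames(values)
    if (is.null(cn)) cn <- paste0("axis", seq_len(ncol(values)))
    axes <- default_axes(cn)
  }
  if (!is.data.frame(axes) || !all(c("name", "unit", "lower", "upper") %in% names(axes))) {
    stop_validation("'axes' must be an axis_descriptor() table")
  }
  if (ncol(values) != nrow(axes)) {
    stop_dimension(sprintf("values has %d columns but %d axes are declared",
                           ncol(values), nrow(axes)))
  }
  if (is.null(taxa)) stop_validation("taxon identifiers are required")
  taxa <- as.character(taxa)
  if (length(taxa) != nrow(values)) {
    stop_dimension("length of 'taxa' does not match rows of 'values'")
  }
  if (anyNA(taxa) || any(!nzchar(taxa))) {
    stop_validation("taxon identifiers must be non-empty")
  }
  if (anyDuplicated(taxa)) {
    stop_duplicate_taxon(sprintf("duplicate taxon identifier: '%s'",
                                 taxa[duplicated(taxa)][1L]))
  }
  if (anyNA(values) || any(!is.finite(values))) {
    idx <- which(!is.finite(values), arr.ind = TRUE)[1L, ]
    stop_missing_value(sprintf(
      "missing or non-finite value for taxon '%s', axis '%s'",
      taxa[idx[1L]], axes$name[idx[2L]]))
  }
  dimnames(values) <- list(taxa, axes$name)
  structure(list(values = values, axes = axes), class = "community_matrix")
}

#' @rdname community_matrix
#' @param x a `community_matrix`.
#' @export
n_taxa <- function(x) nrow(x$values)

#' @rdname community_matrix
#' @export
n_axes <- function(x) ncol(x$values)

#' @rdname community_matrix
#' @export
taxa <- function(x) rownames(x$values)

#' @rdname community_matrix
#' @export
axis_names <- function(x) x$axes$name

#' @export
print.community_matrix <- function(x, ...) {
  cat(sprintf("<community_matrix> %d taxa x %d axes (%s)\n",
              n_taxa(x), n_axes(x), paste(axis_names(x), collapse = ", ")))
  print(utils::head(x$values, 10L))
  if (n_taxa(x) > 10L) cat(sprintf("... and %d more taxa\n", n_taxa(x) - 10L))
  invisible(x)
}

#' Individual-level observations
#'
#' Replicate measurements per taxon, the input to the non-parametric
#' bootstrap: one row per captured individual, a taxon label plus one value
#' per axis. Per-taxon sample sizes `k_t` are recoverable with
#' [taxon_counts()].
#'
#' @param taxon character vector of taxon labels, one per record.
#' @param values numeric matrix of measurements, rows aligned with `taxon`.
#' @param axes axis table, or `NULL` to derive from column names.
#' @return an object of class `individual_observations`.
#' @export
individual_observations <- function(taxon, values, axes = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  taxon <- as.character(taxon)
  if (length(taxon) != nrow(values)) {
    stop_dimension("one taxon label per record is required")
  }
  if (length(taxon) == 0L) stop_empty_taxon("no records supplied")
  if (anyNA(taxon) || any(!nzchar(taxon))) {
    stop_validation("taxon labels must be non-empty")
  }
  if (is.null(axes)) {
    cn <- colnames(values)
    if (is.null(cn)) cn <- paste0("axis", seq_len(ncol(values)))
    axes <- default_axes(cn)
  }
  if (ncol(values) != nrow(axes)) {
    stop_dimension("record width does not match declared axes")
  }
  if (anyNA(values) || any(!is.finite(values))) {
    idx <- which(!is.finite(values), arr.ind = TRUE)[1L, ]
    stop_missing_value(sprintf(
      "missing or non-finite value in record %d (taxon '%s'), axis '%s'",
      idx[1L], taxon[idx[1L]], axes$name[idx[2L]]))
  }
  colnames(values) <- axes$name
  k <- table(taxon)
  if (any(k == 1L)) {
    nh_warn(sprintf(
      "taxa with a single individual (k = 1): %s; their bootstrap draws are degenerate",
      paste(names(k)[k == 1L], collapse = ", ")))
  }
  structure(list(taxon = taxon, values = values, axes = axes),
            class = "individual_observations")
}

#' @rdname individual_observations
#' @param x an `individual_observations` object.
#' @return `taxon_counts()`: named integer vector of per-taxon sample sizes.
#' @export
taxon_counts <- function(x) {
  tab <- table(x$taxon)
  out <- as.integer(tab)
  names(out) <- names(tab)
  out[unique(x$taxon)]
}

#' @export
print.individual_observations <- function(x, ...) {
  k <- taxon_counts(x)
  cat(sprintf("<individual_observations> %d records, %d taxa, %d axes; k = %s\n",
              nrow(x$values), length(k), ncol(x$values),
              paste(sprintf("%s:%d", names(k), k), collapse = " ")))
  invisible(x)
}

#' Per-taxon, per-axis estimate table (mean and SD)
#'
#' The shape of Bayesian mixing-model output: for every taxon and axis a
#' point estimate and a standard deviation, used by [parametric_resample()].
#' Truncation bounds are carried on the axis table.
#'
#' @param taxon,axis character vectors (one entry per taxon x axis cell).
#' @param mean,sd numeric vectors; `sd` must be non-negative.
#' @param axes axis table carrying truncation bounds; `NULL` derives
#'   unbounded axes from the `axis` values in order of appearance.
#' @return an object of class `estimate_table`.
#' @export
estimate_table <- function(taxon, axis, mean, sd, axes = NULL) {
  taxon <- as.character(taxon); axis <- as.character(axis)
  mean <- as.numeric(mean); sd <- as.numeric(sd)
  nrec <- length(taxon)
  if (!all(lengths(list(axis, mean, sd)) == nrec)) {
    stop_dimension("taxon, axis, mean and sd must have equal length")
  }
  if (nrec == 0L) stop_validation("estimate table is empty")
  if (anyNA(mean) || anyNA(sd)) stop_missing_value("estimate table contains missing values")
  if (any(sd < 0)) stop_validation("standard deviations must be >= 0")
  if (is.null(axes)) axes <- default_axes(unique(axis))
  if (!all(axis %in% axes$name)) {
    stop_axis_not_found(sprintf("axis '%s' is not declared",
                                setdiff(axis, axes$name)[1L]))
  }
  if (anyDuplicated(paste(taxon, axis, sep = "\r"))) {
    stop_validation("duplicate (taxon, axis) cell in estimate table")
  }
  tx <- unique(taxon)
  full <- expand.grid(taxon = tx, axis = axes$name, stringsAsFactors = FALSE)
  have <- paste(taxon, axis, sep = "\r")
  need <- paste(full$taxon, full$axis, sep = "\r")
  if (!setequal(have, need)) {
    miss <- full[!(need %in% have), , drop = FALSE]
    stop_missing_value(sprintf("estimate table lacks cell (taxon '%s', axis '%s')",
                               miss$taxon[1L], miss$axis[1L]))
  }
  lo <- axes$lower[match(axis, axes$name)]
  hi <- axes$upper[match(axis, axes$name)]
  out_of_bounds <- (is.finite(lo) & mean < lo) | (is.finite(hi) & mean > hi)
  if (any(out_of_bounds)) {
    i <- which(out_of_bounds)[1L]
    stop_validation(sprintf(
      "mean %.6g for (taxon '%s', axis '%s') lies outside declared bounds [%g, %g]",
      mean[i], taxon[i], axis[i], lo[i], hi[i]))
  }
  structure(list(
    table = data.frame(taxon = taxon, axis = axis, mean = mean, sd = sd,
                       stringsAsFactors = FALSE),
    axes = axes
  ), class = "estimate_table")
}

#' @export
print.estimate_table <- function(x, ...) {
  cat(sprintf("<estimate_table> %d taxa x %d axes\n",
              length(unique(x$table$taxon)), nrow(x$axes)))
  print(utils::head(x$table, 10L))
  invisible(x)
}

# Mean matrix (taxa x axes) implied by an estimate table, in declared axis order.
estimate_means <- function(est) {
  tx <- unique(est$table$taxon)
  ax <- est$axes$name
  m <- matrix(NA_real_, length(tx), length(ax), dimnames = list(tx, ax))
  m[cbind(match(est$table$taxon, tx), match(est$table$axis, ax))] <- est$table$mean
  m
}

estimate_sds <- function(est) {
  tx <- unique(est$table$taxon)
  ax <- est$axes$name
  m <- matrix(NA_real_, length(tx), length(ax), dimnames = list(tx, ax))
  m[cbind(match(est$table$taxon, tx), match(est$table$axis, ax))] <- est$table$sd
  m
}

#' Metric set
#'
#' Named collection of the generalized Layman metrics for one community:
#' one range per axis plus CD (mean distance to centroid), NND (mean nearest
#' neighbor distance), SDNND (its standard deviation) and CHV (convex hull
#' area/volume). CHV is `NA` when undefined (S <= n, or degenerate geometry).
#'
#' @param values named numeric vector: `range_<axis>` entries followed by
#'   `cd`, `nnd`, `sdnnd`, `chv`.
#' @param dimension niche-space dimension n.
#' @param taxon_count number of taxa S.
#' @return an object of class `metric_set` (a named numeric vector with
#'   attributes `dimension` and `taxon_count`).
#' @export
metric_set <- function(values, dimension, taxon_count) {
  stopifnot(is.numeric(values), !is.null(names(values)))
  defined <- values[!is.na(values)]
  if (any(defined < 0) || any(!is.finite(defined))) {
    stop_validation("metric values must be finite and non-negative")
  }
  structure(values, dimension = as.integer(dimension),
            taxon_count = as.integer(taxon_count), class = "metric_set")
}

metric_names_for <- function(axis_names) {
  c(paste0("range_", axis_names), "cd", "nnd", "sdnnd", "chv")
}

#' @export
print.metric_set <- function(x, ...) {
  cat(sprintf("<metric_set> S = %d taxa, n = %d axes\n",
              attr(x, "taxon_count"), attr(x, "dimension")))
  print(stats::setNames(as.numeric(x), names(x)))
  invisible(x)
}

#' Metric confidence-interval set
#'
#' Per-metric point estimate and resampling confidence interval, with the
#' resampling distribution summarized (mean, SD of replicate values, number
#' of replicates retained).
#'
#' @param metric character vector of metric names.
#' @param point,lower,upper numeric vectors.
#' @param boot_mean,boot_sd numeric summaries of the resampling distribution.
#' @param n_used integer vector: replicates retained per metric.
#' @param replicates,level,seed,scheme scalars recorded as attributes.
#' @return an object of class `metric_ci_set` (a data.frame).
#' @export
metric_ci_set <- function(metric, point, lower, upper,
                          boot_mean = NA_real_, boot_sd = NA_real_,
                          n_used = NA_integer_,
                          replicates, level, seed, scheme = "nonparametric") {
  if (!(is.numeric(level) && length(level) == 1L && level > 0 && level < 1)) {
    stop_validation("confidence level must lie strictly in (0, 1)")
  }
  if (!(is.numeric(replicates) && replicates >= 1)) {
    stop_validation("replicates must be >= 1")
  }
  ok <- !is.na(lower) & !is.na(upper)
  if (any(lower[ok] > upper[ok] + 1e-12)) {
    stop_validation("CI lower bound exceeds upper bound")
  }
  structure(data.frame(metric = metric, point = point, lower = lower,
                       upper = upper, boot_mean = boot_mean, boot_sd = boot_sd,
                       n_used = as.integer(n_used), stringsAsFactors = FALSE),
            replicates = as.integer(replicates), level = as.numeric(level),
            seed = as.integer(seed), scheme = scheme,
            class = c("metric_ci_set", "data.frame"))
}

#' @export
print.metric_ci_set <- function(x, ...) {
  cat(sprintf("<metric_ci_set> %s scheme, B = %d, level = %.3g, seed = %d\n",
              attr(x, "scheme"), attr(x, "replicates"), attr(x, "level"),
              attr(x, "seed")))
  print.data.frame(x)
  invisible(x)
}
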