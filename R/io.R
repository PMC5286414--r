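# CSV ingest/egress for the three table dialects plus the JSON sidecar
# config. Dialect is fixed: comma separator, "." decimal, UTF-8, mandatory
# header, first column = taxon id. No locale inference, no imputation.

read_csv_strict <- function(path) {
  if (!file.exists(path)) stop_io(sprintf("file not found: '%s'", path))
  df <- tryCatch(
    utils::read.csv(path, header = TRUE, stringsAsFactors = FALSE,
                    check.names = FALSE, colClasses = "character",
                    fileEncoding = "UTF-8", comment.char = "#"),
    error = function(e) stop_parse(sprintf("cannot parse '%s': %s", path,
                                           conditionMessage(e))))
  if (ncol(df) < 2L) stop_parse(sprintf("'%s': need a taxon column plus at least one axis", path))
  df
}

# Convert character columns to numeric, reporting the first offending cell.
# Returns list(values = matrix, dropped = integer row indices).
numeric_matrix_from <- function(df, cols, path, drop_incomplete = FALSE) {
  if (nrow(df) == 0L) {
    return(list(values = matrix(numeric(0), 0L, length(cols),
                                dimnames = list(NULL, cols)),
                dropped = integer(0)))
  }
  raw <- as.matrix(df[, cols, drop = FALSE])
  trimmed <- trimws(raw)
  blank <- is.na(trimmed) | trimmed == "" | toupper(trimmed) %in% c("NA", "NAN")
  suppressWarnings(num <- array(as.numeric(trimmed), dim = dim(trimmed),
                                dimnames = dimnames(trimmed)))
  malformed <- !blank & is.na(num)
  if (any(malformed)) {
    idx <- which(malformed, arr.ind = TRUE)[1L, ]
    stop_parse(sprintf("'%s': non-numeric value '%s' at data row %d, column '%s'",
                       path, trimmed[idx[1L], idx[2L]], idx[1L], cols[idx[2L]]))
  }
  dropped <- integer(0)
  if (any(blank)) {
    if (drop_incomplete) {
      dropped <- sort(unique(which(blank, arr.ind = TRUE)[, 1L]))
      message(sprintf("'%s': dropped %d incomplete row(s): %s", path,
                      length(dropped), paste(dropped, collapse = ", ")))
      num <- num[-dropped, , drop = FALSE]
    } else {
      idx <- which(blank, arr.ind = TRUE)[1L, ]
      stop_missing_value(sprintf("'%s': missing value at data row %d, column '%s'",
                                 path, idx[1L], cols[idx[2L]]))
    }
  }
  list(values = num, dropped = dropped)
}

#' Read a community table
#'
#' Reads a CSV of taxon-mean niche coordinates: header row, first column the
#' taxon identifier, remaining columns one niche axis each
#' (`taxon,axis1,axis2,...`). Missing values are an error unless
#' `drop_incomplete = TRUE`, which drops offending rows with a logged report
#' (values are never imputed).
#'
#' @param path path to the CSV file.
#' @param axes optional [axis_descriptor()] table declaring units/bounds; axis
#'   names must match the file header. Default: unbounded axes from header.
#' @param drop_incomplete drop rows with missing cells instead of erroring.
#' @return a [community_matrix()].
#' @export
read_community <- function(path, axes = NULL, drop_incomplete = FALSE) {
  df <- read_csv_strict(path)
  axis_cols <- names(df)[-1L]
  got <- numeric_matrix_from(df, axis_cols, path, drop_incomplete)
  taxa <- trimws(df[[1L]])
  if (length(got$dropped)) taxa <- taxa[-got$dropped]
  if (length(taxa) == 0L) stop_empty_taxon(sprintf("'%s': no data rows", path))
  if (anyDuplicated(taxa)) {
    stop_duplicate_taxon(sprintf("'%s': duplicate taxon id '%s'",
                                 path, taxa[duplicated(taxa)][1L]))
  }
  if (!is.null(axes)) {
    if (!setequal(axes$name, axis_cols)) {
      stop_axis_not_found(sprintf(
        "declared axes (%s) do not match file columns (%s)",
        paste(axes$name, collapse = ", "), paste(axis_cols, collapse = ", ")))
    }
    axes <- axes[match(axis_cols, axes$name), , drop = FALSE]
    rownames(axes) <- NULL
  }
  community_matrix(got$values, taxa = taxa, axes = axes)
}

#' Read individual-level observations
#'
#' Long-format CSV: a taxon column followed by one numeric column per axis,
#' one row per captured individual (taxon labels repeat).
#'
#' @inheritParams read_community
#' @return an [individual_observations()] object.
#' @export
read_individuals <- function(path, axes = NULL, drop_incomplete = FALSE) {
  df <- read_csv_strict(path)
  axis_cols <- names(df)[-1L]
  got <- numeric_matrix_from(df, axis_cols, path, drop_incomplete)
  taxon <- trimws(df[[1L]])
  if (length(got$dropped)) taxon <- taxon[-got$dropped]
  if (length(taxon) == 0L) stop_empty_taxon(sprintf("'%s': no observation rows", path))
  if (!is.null(axes)) {
    if (!setequal(axes$name, axis_cols)) {
      stop_axis_not_found("declared axes do not match file columns")
    }
    axes <- axes[match(axis_cols, axes$name), , drop = FALSE]
    rownames(axes) <- NULL
  }
  individual_observations(taxon, got$values, axes = axes)
}

#' Read a per-taxon, per-axis estimate table
#'
#' CSV with columns `taxon,axis,mean,sd` — the shape of mixing-model output.
#'
#' @inheritParams read_community
#' @return an [estimate_table()].
#' @export
read_estimates <- function(path, axes = NULL) {
  df <- read_csv_strict(path)
  need <- c("taxon", "axis", "mean", "sd")
  if (!all(need %in% names(df))) {
    stop_parse(sprintf("'%s': estimate CSV needs columns %s", path,
                       paste(need, collapse = ", ")))
  }
  got <- numeric_matrix_from(df, c("mean", "sd"), path, drop_incomplete = FALSE)
  estimate_table(trimws(df$taxon), trimws(df$axis),
                 got$values[, "mean"], got$values[, "sd"], axes = axes)
}

#' Per-taxon means of individual observations
#'
#' Collapses replicate measurements to one row per taxon (the arithmetic mean
#' per axis), yielding the community matrix the dispersion metrics act on.
#' Taxa appear in order of first occurrence. Idempotent: applied to a table
#' with one individual per taxon it reproduces the table.
#'
#' @param obs an [individual_observations()] object.
#' @return a [community_matrix()].
#' @export
taxon_means <- function(obs) {
  stopifnot(inherits(obs, "individual_observations"))
  tx <- unique(obs$taxon)
  m <- rowsum(obs$values, group = factor(obs$taxon, levels = tx)) /
    as.vector(table(factor(obs$taxon, levels = tx)))
  community_matrix(m, taxa = tx, axes = obs$axes)
}

#' Write (and read back) a metrics table
#'
#' One row per metric: `metric,point,lower,upper`. For a bare [metric_set()]
#' the CI columns are blank; for a [metric_ci_set()] the confidence level,
#' replicate count, seed and scheme are recorded as `#`-comment header lines
#' so a run is self-describing. Values round-trip at full double precision.
#'
#' @param ms a `metric_set` or `metric_ci_set`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_metrics <- function(ms, path) {
  con <- tryCatch(file(path, open = "wt", encoding = "UTF-8"),
                  error = function(e) stop_io(sprintf("cannot write '%s'", path)))
  on.exit(close(con))
  fmt <- function(x) ifelse(is.na(x), "", sprintf("%.17g", x))
  if (inherits(ms, "metric_ci_set")) {
    writeLines(c(
      sprintf("# level=%.17g", attr(ms, "level")),
      sprintf("# replicates=%d", attr(ms, "replicates")),
      sprintf("# seed=%d", attr(ms, "seed")),
      sprintf("# scheme=%s", attr(ms, "scheme"))
    ), con)
    df <- data.frame(metric = ms$metric, point = fmt(ms$point),
                     lower = fmt(ms$lower), upper = fmt(ms$upper))
  } else if (inherits(ms, "metric_set")) {
    df <- data.frame(metric = names(ms), point = fmt(as.numeric(ms)),
                     lower = "", upper = "")
  } else {
    stop_validation("write_metrics() expects a metric_set or metric_ci_set")
  }
  utils::write.table(df, con, sep = ",", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' @rdname write_metrics
#' @return `read_metrics()`: a data.frame with columns `metric`, `point`,
#'   `lower`, `upper`, with any recorded run settings in attributes.
#' @export
read_metrics <- function(path) {
  if (!file.exists(path)) stop_io(sprintf("file not found: '%s'", path))
  lines <- readLines(path, encoding = "UTF-8")
  hdr <- grep("^#", lines, value = TRUE)
  df <- utils::read.csv(text = lines[!grepl("^#", lines)],
                        stringsAsFactors = FALSE)
  for (col in c("point", "lower", "upper")) {
    df[[col]] <- suppressWarnings(as.numeric(df[[col]]))
  }
  meta <- list()
  for (h in hdr) {
    kv <- strsplit(sub("^#\\s*", "", h), "=", fixed = TRUE)[[1L]]
    if (length(kv) == 2L) meta[[kv[1L]]] <- kv[2L]
  }
  if (!is.null(meta$level)) attr(df, "level") <- as.numeric(meta$level)
  if (!is.null(meta$replicates)) attr(df, "replicates") <- as.integer(meta$replicates)
  if (!is.null(meta$seed)) attr(df, "seed") <- as.integer(meta$seed)
  if (!is.null(meta$scheme)) attr(df, "scheme") <- meta$scheme
  df
}

#' Write community / individuals / estimate tables
#'
#' Inverse operations of the readers; values are written at full double
#' precision so `read(write(x))` reproduces `x`.
#'
#' @param x the object to write.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_community <- function(x, path) {
  stopifnot(inherits(x, "community_matrix"))
  df <- data.frame(taxon = taxa(x), stringsAsFactors = FALSE)
  for (j in seq_len(n_axes(x))) df[[axis_names(x)[j]]] <- sprintf("%.17g", x$values[, j])
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_community
#' @export
write_individuals <- function(x, path) {
  stopifnot(inherits(x, "individual_observations"))
  df <- data.frame(taxon = x$taxon, stringsAsFactors = FALSE)
  for (j in seq_len(ncol(x$values))) df[[colnames(x$values)[j]]] <- sprintf("%.17g", x$values[, j])
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_community
#' @export
write_estimates <- function(x, path) {
  stopifnot(inherits(x, "estimate_table"))
  df <- data.frame(taxon = x$table$taxon, axis = x$table$axis,
                   mean = sprintf("%.17g", x$table$mean),
                   sd = sprintf("%.17g", x$table$sd))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read the JSON sidecar configuration
#'
#' Axis bounds and run settings live in a small JSON file, not in the data
#' CSVs. Recognized keys: `axes` (array of objects with `name` and optional
#' `unit`, `lower`, `upper`), `ci_level`, `replicates`, `seed`.
#'
#' @param path path to the JSON config.
#' @return a list with elements `axes` (an [axis_descriptor()] table or
#'   `NULL`), `ci_level`, `replicates`, `seed` (each `NULL` when absent).
#' @export
read_axes_config <- function(path) {
  if (!file.exists(path)) stop_io(sprintf("config not found: '%s'", path))
  cfg <- tryCatch(jsonlite::fromJSON(path, simplifyDataFrame = TRUE),
                  error = function(e) stop_parse(sprintf(
                    "cannot parse config '%s': %s", path, conditionMessage(e))))
  axes <- NULL
  if (!is.null(cfg$axes)) {
    ax <- as.data.frame(cfg$axes, stringsAsFactors = FALSE)
    if (is.null(ax$name)) stop_validation("config axes entries need a 'name'")
    unit <- if (is.null(ax$unit)) "" else ifelse(is.na(ax$unit), "", ax$unit)
    lower <- if (is.null(ax$lower)) -Inf else ifelse(is.na(ax$lower), -Inf, ax$lower)
    upper <- if (is.null(ax$upper)) Inf else ifelse(is.na(ax$upper), Inf, ax$upper)
    axes <- axis_descriptor(ax$name, unit = unit, lower = lower, upper = upper)
  }
  list(axes = axes,
       ci_level = if (is.null(cfg$ci_level)) NULL else as.numeric(cfg$ci_level),
       replicates = if (is.null(cfg$replicates)) NULL else as.integer(cfg$replicates),
       seed = if (is.null(cfg$seed)) NULL else as.integer(cfg$seed))
}
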