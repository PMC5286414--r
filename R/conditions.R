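# Classed conditions used throughout the package. Every error inherits from
# "nichehull_error" so callers can catch package errors wholesale, plus a
# specific class for programmatic handling.

nh_stop <- function(class, msg, ...) {
  stop(errorCondition(msg, ..., class = c(class, "nichehull_error", "error")))
}

stop_duplicate_taxon <- function(msg, ...) nh_stop("nichehull_duplicate_taxon_error", msg, ...)
stop_parse <- function(msg, ...) nh_stop("nichehull_parse_error", msg, ...)
stop_missing_value <- function(msg, ...) nh_stop("nichehull_missing_value_error", msg, ...)
stop_empty_taxon <- function(msg, ...) nh_stop("nichehull_empty_taxon_error", msg, ...)
stop_dimension <- function(msg, ...) nh_stop("nichehull_dimension_error", msg, ...)
stop_axis_not_found <- function(msg, ...) nh_stop("nichehull_axis_not_found_error", msg, ...)
stop_insufficient_taxa <- function(msg, ...) nh_stop("nichehull_insufficient_taxa_error", msg, ...)
stop_degenerate_geometry <- function(msg, ...) nh_stop("nichehull_degenerate_geometry_error", msg, ...)
stop_validation <- function(msg, ...) nh_stop("nichehull_validation_error", msg, ...)
stop_undefined_ci <- function(msg, ...) nh_stop("nichehull_undefined_ci_error", msg, ...)
stop_io <- function(msg, ...) nh_stop("nichehull_io_error", msg, ...)

nh_warn <- function(msg, class = "nichehull_warning") {
  warning(warningCondition(msg, class = c(class, "nichehull_warning")))
}
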