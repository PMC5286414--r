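# Derived-axis calculators for compound-specific amino-acid isotope data:
# trophic position from the glutamic-acid / phenylalanine d15N offset,
# mean-normalization of per-amino-acid d13C profiles, the delta-notation
# conversion, and assembly of a derived-axis community matrix (e.g. TP plus
# diet fractions) ready for the dispersion metrics.

#' Trophic-position equation parameters
#'
#' The enrichment constants of the amino-acid trophic position equation:
#' `beta`, the Glu-Phe d15N offset in primary producers (default 3.4 permil),
#' and `tdf`, the trophic discrimination factor per trophic step (default
#' 7.6 permil). The defaults are the conventional literature values; both are
#' parameters, not constants, because published estimates vary by system.
#'
#' @param beta producer-level Glu-Phe offset, permil.
#' @param tdf trophic discrimination factor, permil (non-zero).
#' @return a list of class `trophic_params`.
#' @export
trophic_params <- function(beta = 3.4, tdf = 7.6) {
  if (!(is.numeric(tdf) && length(tdf) == 1L && is.finite(tdf) && tdf != 0)) {
    stop_validation("tdf must be a single non-zero number")
  }
  if (!(is.numeric(beta) && length(beta) == 1L && is.finite(beta))) {
    stop_validation("beta must be a single finite number")
  }
  structure(list(beta = beta, tdf = tdf), class = "trophic_params")
}

#' Trophic position from amino-acid d15N
#'
#' `TP = ((d15N_Glu - d15N_Phe) - beta) / tdf + 1`: the trophic position of a
#' consumer estimated from the d15N offset between a trophic amino acid
#' (Glutamic Acid, which enriches with each trophic transfer) and a source
#' amino acid (Phenylalanine, which barely fractionates). A consumer whose
#' offset equals `beta` sits at TP = 1 (a primary producer).
#'
#' @param glu_n15 d15N of Glutamic Acid, permil (vectorized).
#' @param phe_n15 d15N of Phenylalanine, permil (vectorized).
#' @param params a [trophic_params()].
#' @return trophic position estimate(s).
#' @export
#' @examples
#' trophic_position(13.4, 10.0)  # offset exactly beta -> TP 1
#' trophic_position(21.0, 10.0)  # one trophic step up -> TP 2
trophic_position <- function(glu_n15, phe_n15, params = trophic_params()) {
  if (!inherits(params, "trophic_params")) params <- do.call(trophic_params, params)
  if (anyNA(glu_n15) || anyNA(phe_n15) ||
      any(!is.finite(glu_n15)) || any(!is.finite(phe_n15))) {
    stop_validation("glu_n15 and phe_n15 must be finite")
  }
  ((glu_n15 - phe_n15) - params$beta) / params$tdf + 1
}

#' Mean-normalize an amino-acid carbon profile
#'
#' Centers each present d13C value on the mean of the present values
#' (`d13C_AA - mean d13C_AA`), removing sample-level (e.g. growth-medium)
#' offsets so that profiles are comparable across sources. Absent amino acids
#' (`NA`, e.g. Tyrosine below detection) are left out of the mean and stay
#' absent. The normalized profile sums to zero; the operation is idempotent.
#'
#' @param profile named numeric vector of per-amino-acid d13C values, permil;
#'   `NA` marks an absent amino acid.
#' @return the centered profile (same names, `NA`s preserved).
#' @export
normalize_aa_carbon <- function(profile) {
  if (!is.numeric(profile)) stop_validation("profile must be numeric")
  present <- which(!is.na(profile))
  if (length(present) < 2L) {
    stop_validation("at least 2 amino acids must be present to normalize")
  }
  profile[present] <- profile[present] - mean(profile[present])
  profile
}

#' Delta notation
#'
#' `deltaX = (R_sample / R_standard - 1) * 1000`: the per-mil deviation of a
#' sample's heavy:light isotope ratio from the standard ratio.
#'
#' @param r_sample,r_standard isotope ratios, both strictly positive
#'   (vectorized).
#' @return delta value(s) in permil.
#' @export
#' @examples
#' delta_value(1.1, 1.0)  # 100 permil
delta_value <- function(r_sample, r_standard) {
  if (any(!is.finite(r_sample)) || any(!is.finite(r_standard)) ||
      any(r_sample <= 0) || any(r_standard <= 0)) {
    stop_validation("isotope ratios must be finite and strictly positive")
  }
  (r_sample / r_standard - 1) * 1000
}

#' Pivot a long amino-acid table to wide per-taxon columns
#'
#' Converts the long dialect `taxon,amino_acid,element,delta[,sd]` into a
#' wide data.frame with one column per `<amino_acid>_d<element>` (e.g.
#' `Glutamic Acid` x `15N` becomes `Glutamic.Acid_d15N`), suitable for
#' [build_derived_community()].
#'
#' @param df data.frame with columns `taxon`, `amino_acid`, `element`,
#'   `delta` (element coded `13C` or `15N`).
#' @return wide data.frame, first column `taxon`.
#' @export
aa_long_to_wide <- function(df) {
  need <- c("taxon", "amino_acid", "element", "delta")
  if (!all(need %in% names(df))) {
    stop_parse(sprintf("long amino-acid table needs columns %s",
                       paste(need, collapse = ", ")))
  }
  col <- paste0(make.names(df$amino_acid), "_d", df$element)
  tx <- unique(df$taxon)
  cols <- unique(col)
  wide <- matrix(NA_real_, length(tx), length(cols),
                 dimnames = list(tx, cols))
  wide[cbind(match(df$taxon, tx), match(col, cols))] <- as.numeric(df$delta)
  out <- data.frame(taxon = tx, stringsAsFactors = FALSE)
  for (cc in cols) out[[cc]] <- wide[, cc]
  out
}

unit_default_bounds <- function(unit) {
  switch(unit,
         fraction = c(0, 1),
         percent = c(0, 100),
         c(-Inf, Inf))
}

#' Assemble a community matrix of derived axes
#'
#' Builds the niche space actually analyzed from raw per-taxon columns:
#' trophic position computed from Glu/Phe d15N columns, and pass-through
#' axes such as mixing-model diet fractions. Diet-fraction axes receive their
#' mathematically admissible bounds automatically (`unit = "fraction"` gives
#' \[0, 1\], `unit = "percent"` gives \[0, 100\]); those bounds drive
#' truncation in [parametric_resample()].
#'
#' @param raw data.frame with a `taxon` column plus the raw per-taxon
#'   columns (wide; see [aa_long_to_wide()]).
#' @param axes_spec list of axis definitions. Each is a list with `name` and
#'   `type`:
#'   * `type = "trophic_position"`: optional `glu` / `phe` (raw column names,
#'     defaults `"Glutamic.Acid_d15N"` / `"Phenylalanine_d15N"`), `beta`,
#'     `tdf`.
#'   * `type = "passthrough"`: optional `source` (raw column name, default
#'     the axis name), `unit`, `bounds` (length-2 numeric).
#' @return a [community_matrix()] over the derived axes.
#' @export
build_derived_community <- function(raw, axes_spec) {
  if (!is.data.frame(raw) || !("taxon" %in% names(raw))) {
    stop_validation("'raw' must be a data.frame with a 'taxon' column")
  }
  if (!length(axes_spec)) stop_validation("at least one derived axis is required")
  S <- nrow(raw)
  vals <- matrix(NA_real_, S, length(axes_spec))
  names_ <- character(length(axes_spec))
  units <- character(length(axes_spec))
  lower <- upper <- numeric(length(axes_spec))
  grab <- function(colname, axis) {
    if (!(colname %in% names(raw))) {
      stop_validation(sprintf(
        "derived axis '%s' needs raw column '%s', which is absent", axis, colname))
    }
    as.numeric(raw[[colname]])
  }
  for (i in seq_along(axes_spec)) {
    ax <- axes_spec[[i]]
    if (is.null(ax$name) || is.null(ax$type)) {
      stop_validation("every derived-axis definition needs 'name' and 'type'")
    }
    names_[i] <- ax$name
    if (ax$type == "trophic_position") {
      glu_col <- if (is.null(ax$glu)) "Glutamic.Acid_d15N" else ax$glu
      phe_col <- if (is.null(ax$phe)) "Phenylalanine_d15N" else ax$phe
      pars <- trophic_params(beta = if (is.null(ax$beta)) 3.4 else ax$beta,
                             tdf = if (is.null(ax$tdf)) 7.6 else ax$tdf)
      vals[, i] <- trophic_position(grab(glu_col, ax$name),
                                    grab(phe_col, ax$name), pars)
      units[i] <- "TP"
      lower[i] <- -Inf; upper[i] <- Inf
    } else if (ax$type == "passthrough") {
      src <- if (is.null(ax$source)) ax$name else ax$source
      vals[, i] <- grab(src, ax$name)
      units[i] <- if (is.null(ax$unit)) "" else ax$unit
      b <- if (is.null(ax$bounds)) unit_default_bounds(units[i]) else as.numeric(ax$bounds)
      lower[i] <- b[1L]; upper[i] <- b[2L]
    } else {
      stop_validation(sprintf("unknown derived-axis type '%s'", ax$type))
    }
  }
  community_matrix(vals, taxa = as.character(raw$taxon),
                   axes = axis_descriptor(names_, unit = units,
                                          lower = lower, upper = upper))
}
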