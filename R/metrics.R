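# The generalized Layman dispersion metrics in n dimensions. All distances
# are Euclidean on the raw axis scales; axes are deliberately NOT
# standardized by default (permil, trophic-position units and diet percent
# coexist in one space), an explicit z-score flag is the only preprocessing.

#' Euclidean distance between two niche coordinates
#'
#' @param a,b numeric vectors of equal length n.
#' @return the Euclidean distance, a non-negative number.
#' @export
#' @examples
#' euclidean_distance(c(0, 0), c(3, 4))  # 5
euclidean_distance <- function(a, b) {
  if (length(a) != length(b)) {
    stop_dimension(sprintf("vectors differ in length (%d vs %d)",
                           length(a), length(b)))
  }
  sqrt(sum((as.numeric(a) - as.numeric(b))^2))
}

#' Per-axis range
#'
#' Total distance between the farthest-separated taxa along one axis:
#' maximum minus minimum of that column.
#'
#' @param cm a [community_matrix()].
#' @param axis axis name.
#' @return the range, a non-negative number.
#' @export
axis_range <- function(cm, axis) {
  stopifnot(inherits(cm, "community_matrix"))
  j <- match(axis, axis_names(cm))
  if (is.na(j)) {
    stop_axis_not_found(sprintf("no axis named '%s' (have: %s)", axis,
                                paste(axis_names(cm), collapse = ", ")))
  }
  v <- cm$values[, j]
  max(v) - min(v)
}

#' Community centroid
#'
#' The mean value of each axis over all taxa.
#'
#' @param cm a [community_matrix()].
#' @return numeric vector of length n, named by axis.
#' @export
centroid <- function(cm) {
  stopifnot(inherits(cm, "community_matrix"))
  colMeans(cm$values)
}

#' Mean distance to the centroid (CD)
#'
#' Average Euclidean distance of each taxon to the community centroid; a
#' measure of overall species spread (trophic diversity) in niche space.
#'
#' @param cm a [community_matrix()].
#' @return CD, a non-negative number.
#' @export
mean_distance_to_centroid <- function(cm) {
  stopifnot(inherits(cm, "community_matrix"))
  if (n_taxa(cm) < 2L) {
    nh_warn("CD of a single-taxon community is 0 by convention")
    return(0)
  }
  cd_from_matrix(cm$values)
}

cd_from_matrix <- function(X) {
  dev <- sweep(X, 2L, colMeans(X))
  mean(sqrt(rowSums(dev^2)))
}

#' Nearest neighbor distances
#'
#' For every taxon, the Euclidean distance to its nearest other taxon in
#' n-dimensional niche space (self excluded). Their mean (NND) measures the
#' density of species packing; their standard deviation (SDNND) its evenness.
#'
#' @param cm a [community_matrix()].
#' @return numeric vector of length S, named by taxon.
#' @export
nearest_neighbor_distances <- function(cm) {
  stopifnot(inherits(cm, "community_matrix"))
  if (n_taxa(cm) < 2L) {
    stop_insufficient_taxa("nearest-neighbor distances need at least 2 taxa")
  }
  nnd_from_matrix(cm$values)
}

nnd_from_matrix <- function(X) {
  D <- as.matrix(stats::dist(X))
  diag(D) <- Inf
  stats::setNames(apply(D, 1L, min), rownames(X))
}

#' @rdname nearest_neighbor_distances
#' @return `mean_nnd()`: the mean of the nearest neighbor distances.
#' @export
mean_nnd <- function(cm) mean(nearest_neighbor_distances(cm))

#' @rdname nearest_neighbor_distances
#' @return `sd_nnd()`: their sample standard deviation (divisor S - 1). For
#'   S = 2 the two distances are equal by symmetry and SDNND is 0.
#' @export
sd_nnd <- function(cm) stats::sd(nearest_neighbor_distances(cm))

# Fast path shared with the resamplers: metrics of a plain matrix, optionally
# a subset. CHV is NA (never an error) when S <= n or the points are
# degenerate; the caller decides how to treat the NA.
metrics_from_matrix <- function(X, axis_names = colnames(X),
                                which = c("ranges", "cd", "nnd", "sdnnd", "chv")) {
  out <- numeric(0)
  if ("ranges" %in% which) {
    rng <- apply(X, 2L, function(v) max(v) - min(v))
    out <- c(out, stats::setNames(rng, paste0("range_", axis_names)))
  }
  if ("cd" %in% which) out <- c(out, cd = cd_from_matrix(X))
  if (any(c("nnd", "sdnnd") %in% which)) {
    nn <- nnd_from_matrix(X)
    if ("nnd" %in% which) out <- c(out, nnd = mean(nn))
    if ("sdnnd" %in% which) out <- c(out, sdnnd = stats::sd(nn))
  }
  if ("chv" %in% which) {
    chv <- if (nrow(X) <= ncol(X) || affine_rank(X) < ncol(X)) NA_real_
           else hull_volume_points(X)
    out <- c(out, chv = chv)
  }
  out
}

#' Compute the full generalized Layman metric set
#'
#' One call for all dispersion metrics of a community: the range of every
#' axis, CD (mean distance to centroid), NND (mean nearest neighbor
#' distance), SDNND (its standard deviation) and CHV (convex hull
#' area/volume). CHV is reported as `NA` with a warning — not an error — when
#' the community has too few taxa (S <= n) or its points do not span all n
#' dimensions, so the other metrics still flow.
#'
#' @param cm a [community_matrix()].
#' @param standardize z-score each axis (divide the centered column by its
#'   sample SD) before computing metrics. Off by default: raw scales are the
#'   contract, mixed units and all.
#' @return a [metric_set()].
#' @export
#' @examples
#' cm <- community_matrix(rbind(a = c(0, 0), b = c(1, 0), c = c(0, 1)))
#' compute_all_metrics(cm)
compute_all_metrics <- function(cm, standardize = FALSE) {
  stopifnot(inherits(cm, "community_matrix"))
  S <- n_taxa(cm); n <- n_axes(cm)
  if (S < 2L) stop_insufficient_taxa("metrics need at least 2 taxa")
  X <- cm$values
  if (isTRUE(standardize)) {
    sds <- apply(X, 2L, stats::sd)
    if (any(sds == 0)) {
      stop_degenerate_geometry("cannot standardize an axis with zero variance")
    }
    X <- scale(X, center = TRUE, scale = sds)
    dimnames(X) <- dimnames(cm$values)
  }
  vals <- metrics_from_matrix(X, axis_names(cm))
  if (is.na(vals[["chv"]])) {
    if (S <= n) {
      nh_warn(sprintf(
        "CHV undefined: S = %d taxa do not exceed n = %d axes; reporting NA", S, n))
    } else {
      nh_warn("CHV undefined: taxon points are degenerate (span < n dimensions); reporting NA")
    }
  }
  metric_set(vals, dimension = n, taxon_count = S)
}
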