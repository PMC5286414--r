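# n-dimensional convex hull volume by supporting-hyperplane facet
# enumeration. For every subset of d points we fit the hyperplane through
# them (null space of the centered subset via QR); the subset lies on a hull
# facet iff all remaining points fall on one side. Facets are deduplicated by
# their vertex set (so co-hyperplanar vertices are handled exactly once), the
# facet's (d-1)-measure is computed recursively in an orthonormal in-plane
# coordinate frame, and the volume is assembled as a fan of pyramids over the
# centroid: V = sum_f vol_{d-1}(f) * h_f / d. Exact for the point counts the
# metrics are used at (S up to ~10^2); complexity C(S, n) * S.

# Affine rank of a point set, relative tolerance on singular values.
affine_rank <- function(X, rel_tol = 1e-10) {
  Xc <- sweep(X, 2L, colMeans(X))
  sv <- svd(Xc, nu = 0L, nv = 0L)$d
  if (!length(sv) || max(sv) == 0) return(0L)
  sum(sv > rel_tol * max(sv))
}

hull_volume_points <- function(X, tol = 1e-9) {
  d <- ncol(X)
  if (d == 1L) return(max(X[, 1L]) - min(X[, 1L]))
  m <- nrow(X)
  ctr <- colMeans(X)
  scl <- max(1, max(abs(sweep(X, 2L, ctr))))
  tolb <- tol * scl
  combs <- utils::combn(m, d)
  seen <- new.env(hash = TRUE, parent = emptyenv())
  vol <- 0
  for (ci in seq_len(ncol(combs))) {
    idx <- combs[, ci]
    P <- X[idx, , drop = FALSE]
    A <- P[-1L, , drop = FALSE] - matrix(P[1L, ], d - 1L, d, byrow = TRUE)
    qa <- qr(t(A))
    if (qa$rank < d - 1L) next          # affinely dependent subset
    Q <- qr.Q(qa, complete = TRUE)
    nrm <- Q[, d]
    off <- sum(nrm * P[1L, ])
    s <- drop(X %*% nrm) - off
    if (all(s <= tolb)) {
      # interior already on the negative side
    } else if (all(s >= -tolb)) {
      nrm <- -nrm; off <- -off; s <- -s
    } else next                          # not a supporting hyperplane
    on_facet <- which(s >= -tolb)
    key <- paste(on_facet, collapse = ",")
    if (!is.null(seen[[key]])) next
    assign(key, TRUE, envir = seen)
    h <- off - sum(nrm * ctr)            # centroid-to-facet distance, > 0
    basis <- Q[, seq_len(d - 1L), drop = FALSE]
    Fp <- X[on_facet, , drop = FALSE]
    Y <- (Fp - matrix(P[1L, ], nrow(Fp), d, byrow = TRUE)) %*% basis
    vol <- vol + hull_volume_points(Y, tol) * h / d
  }
  vol
}

#' Convex hull volume of a community
#'
#' The Lebesgue measure of the convex hull of the S taxon points in
#' n-dimensional niche space: a length for n = 1 (max minus min), the usual
#' convex hull area for n = 2, a volume for n = 3, and the n-dimensional
#' hypervolume beyond. Measures the total amount of niche space occupied by
#' the community.
#'
#' Requires strictly more taxa than axes (S > n) and points that genuinely
#' span all n dimensions. When called directly, violating either requirement
#' is an error; [compute_all_metrics()] instead reports CHV as `NA` with a
#' warning so the remaining metrics still flow.
#'
#' @param cm a [community_matrix()] (or a plain numeric matrix of points).
#' @return the hull volume, a non-negative number.
#' @export
#' @examples
#' tri <- community_matrix(rbind(a = c(0, 0), b = c(1, 0), c = c(0, 1)))
#' convex_hull_volume(tri)  # right-triangle area, 0.5
convex_hull_volume <- function(cm) {
  X <- if (inherits(cm, "community_matrix")) cm$values else as.matrix(cm)
  S <- nrow(X); n <- ncol(X)
  if (S <= n) {
    stop_insufficient_taxa(sprintf(
      "convex hull volume needs more taxa than axes (S > n); got S = %d, n = %d",
      S, n))
  }
  if (n == 1L) return(max(X[, 1L]) - min(X[, 1L]))
  if (affine_rank(X) < n) {
    stop_degenerate_geometry(sprintf(
      "taxon points span fewer than n = %d dimensions; hull volume is degenerate", n))
  }
  hull_volume_points(X)
}
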