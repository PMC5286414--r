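# Independent oracles, deliberately naive: O(S^2) loops for the distance
# metrics, the shoelace formula on grDevices::chull() for 2-D areas, and a
# cross-product facet enumeration + rejection sampling for 3-D volumes. None
# of them share code with the package's computation paths.

oracle_dist <- function(a, b) sqrt(sum((a - b)^2))

oracle_cd <- function(X) {
  ctr <- numeric(ncol(X))
  for (j in seq_len(ncol(X))) ctr[j] <- sum(X[, j]) / nrow(X)
  total <- 0
  for (i in seq_len(nrow(X))) total <- total + oracle_dist(X[i, ], ctr)
  total / nrow(X)
}

oracle_nnd_values <- function(X) {
  S <- nrow(X)
  out <- numeric(S)
  for (i in seq_len(S)) {
    best <- Inf
    for (j in seq_len(S)) {
      if (i == j) next
      d <- oracle_dist(X[i, ], X[j, ])
      if (d < best) best <- d
    }
    out[i] <- best
  }
  out
}

oracle_sd <- function(v) {
  m <- sum(v) / length(v)
  sqrt(sum((v - m)^2) / (length(v) - 1))
}

# 2-D polygon area of the hull, via grDevices::chull + shoelace.
oracle_shoelace_area <- function(X) {
  h <- grDevices::chull(X)
  P <- X[h, , drop = FALSE]
  x <- P[, 1L]; y <- P[, 2L]
  abs(sum(x * c(y[-1L], y[1L]) - c(x[-1L], x[1L]) * y)) / 2
}

# Supporting planes of a 3-D point cloud by brute-force triple enumeration
# with cross products (outward normals).
oracle_planes_3d <- function(X, tol = 1e-9) {
  m <- nrow(X)
  cross3 <- function(u, v) c(u[2L] * v[3L] - u[3L] * v[2L],
                             u[3L] * v[1L] - u[1L] * v[3L],
                             u[1L] * v[2L] - u[2L] * v[1L])
  planes <- NULL
  for (i in 1:(m - 2L)) for (j in (i + 1L):(m - 1L)) for (k in (j + 1L):m) {
    nrm <- cross3(X[j, ] - X[i, ], X[k, ] - X[i, ])
    len <- sqrt(sum(nrm^2))
    if (len < 1e-12) next
    nrm <- nrm / len
    s <- drop(X %*% nrm) - sum(nrm * X[i, ])
    if (all(s <= tol)) {
      planes <- rbind(planes, c(nrm, sum(nrm * X[i, ])))
    } else if (all(s >= -tol)) {
      planes <- rbind(planes, c(-nrm, -sum(nrm * X[i, ])))
    }
  }
  planes
}

# Monte-Carlo rejection-sampling estimate of a 3-D hull volume with its
# standard error.
oracle_mc_volume_3d <- function(X, n_draws = 40000L) {
  planes <- oracle_planes_3d(X)
  lo <- apply(X, 2L, min); hi <- apply(X, 2L, max)
  U <- cbind(stats::runif(n_draws, lo[1L], hi[1L]),
             stats::runif(n_draws, lo[2L], hi[2L]),
             stats::runif(n_draws, lo[3L], hi[3L]))
  side <- U %*% t(planes[, 1:3, drop = FALSE])
  inside <- rowSums(sweep(side, 2L, planes[, 4L]) <= 1e-9) == nrow(planes)
  p <- mean(inside)
  vbox <- prod(hi - lo)
  list(estimate = p * vbox, se = vbox * sqrt(p * (1 - p) / n_draws))
}

random_community_matrix <- function(S, n, scale = 10) {
  matrix(stats::runif(S * n, -scale, scale), S, n,
         dimnames = list(sprintf("t%02d", seq_len(S)),
                         paste0("ax", seq_len(n))))
}

triangle_cm <- function() {
  community_matrix(rbind(a = c(0, 0), b = c(1, 0), c = c(0, 1)),
                   axes = axis_descriptor(c("x", "y")))
}

random_orthogonal <- function(n) {
  qr.Q(qr(matrix(stats::rnorm(n * n), n, n)))
}
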