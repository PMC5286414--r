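# Synthetic scenario generator. Emulates the conceptual schematics used to
# motivate a third niche axis: paired 2-D / 3-D communities sharing their
# first two axes exactly, with the third axis constructed per archetype, and
# invasion variants where three new taxa join an existing community. These
# are parameterized equivalents of the schematics, not replicas of any
# figure's coordinates; defaults are chosen so each archetype's documented
# qualitative metric signature holds with margin.

SCENARIO_ARCHETYPES <- c(
  "third_axis_narrow", "third_axis_wide", "single_outlier", "all_spread",
  "correlated_axis", "uncorrelated_axis",
  "invasion_vertical", "invasion_horizontal", "invasion_hidden_third_axis",
  "invasion_clustered_third", "invasion_dispersed_third", "invasion_no_change"
)

#' Scenario specification
#'
#' Parameters of one synthetic community scenario. The first two axes mimic a
#' d13C/d15N bi-plot (taxa scattered with a minimum mutual separation); the
#' third axis is an arbitrary additional isotope whose structure depends on
#' the archetype. Invasion archetypes add exactly three new taxa.
#'
#' @param archetype one of `scenario_archetypes()`.
#' @param S number of taxa in the (pre-invasion) community; default 8.
#' @param seed integer seed; scenarios are deterministic given the spec.
#' @param spread_narrow full width of a "narrow" third axis, permil
#'   (default 1).
#' @param spread_wide full width of a "wide" third axis, permil (default 10,
#'   i.e. 10x the narrow width).
#' @param shift displacement used for outliers and invaders along the third
#'   (or invaded) axis, permil (default 8).
#' @return a list of class `scenario_spec`.
#' @export
scenario_spec <- function(archetype, S = 8L, seed = 1L,
                          spread_narrow = 1, spread_wide = 10, shift = 8) {
  if (!(is.character(archetype) && length(archetype) == 1L &&
        archetype %in% SCENARIO_ARCHETYPES)) {
    stop_validation(sprintf("unknown archetype '%s'; valid archetypes: %s",
                            as.character(archetype)[1L],
                            paste(SCENARIO_ARCHETYPES, collapse = ", ")))
  }
  if (!(is.numeric(S) && S >= 4)) stop_validation("S must be >= 4")
  if (any(c(spread_narrow, spread_wide, shift) <= 0)) {
    stop_validation("spread and shift parameters must be positive")
  }
  structure(list(archetype = archetype, S = as.integer(S),
                 seed = as.integer(seed), base_n = 2L,
                 spread_narrow = spread_narrow, spread_wide = spread_wide,
                 shift = shift),
            class = "scenario_spec")
}

#' @rdname scenario_spec
#' @return `scenario_archetypes()`: the valid archetype names.
#' @export
scenario_archetypes <- function() SCENARIO_ARCHETYPES

scenario_axes_2d <- function() axis_descriptor(c("d13C", "d15N"), unit = "permil")
scenario_axes_3d <- function() axis_descriptor(c("d13C", "d15N", "d34S"), unit = "permil")

# Random 2-D base cloud in a 10 x 10 permil window with minimum mutual
# separation 1 permil, so nearest-neighbor structure is non-trivial.
base_cloud_2d <- function(S, min_sep = 1) {
  for (try in 1:1000) {
    x <- stats::runif(S, -30, -20)
    y <- stats::runif(S, 5, 15)
    D <- stats::dist(cbind(x, y))
    if (min(D) >= min_sep) return(cbind(x, y))
  }
  stop_validation("could not place taxa with the requested separation")
}

Z_CENTER <- -20  # third-axis band center, permil

#' Generate a paired 2-D / 3-D synthetic scenario
#'
#' Builds the communities of one archetype. All archetypes share the
#' contract that the 3-D community's first two axes are *identical* to the
#' 2-D community's coordinates, so any metric difference is attributable to
#' the third axis alone. Invasion archetypes additionally return post-
#' invasion communities containing three new taxa (`inv1`-`inv3`).
#'
#' Archetype sketches (third axis `z`, band center -20 permil):
#' * `third_axis_narrow` / `third_axis_wide`: `z` spans a narrow (default 1)
#'   or wide (default 10 permil) band, evenly spaced in the wide case so the
#'   range is expressed with even packing.
#' * `single_outlier`: narrow band, one taxon displaced by `shift`.
#' * `all_spread` / `uncorrelated_axis`: independent uniform draws across the
#'   wide band (uneven packing).
#' * `correlated_axis`: `z` is an affine image of the first axis plus tiny
#'   jitter, so the third axis adds almost no information.
#' * `invasion_*`: pre-invasion community with a narrow `z` band; invaders
#'   displaced along d15N (`vertical`), d13C (`horizontal`), or the third
#'   axis (`hidden`/`clustered`: a tight distant cluster; `dispersed`:
#'   spread at `0.5 / 1 / 1.5 x shift`); `invasion_no_change` uses a filled
#'   lattice whose three interior vacancies are occupied by the invaders, so
#'   every metric is provably near-unchanged.
#'
#' @param spec a [scenario_spec()].
#' @return a list of class `niche_scenario` with elements `archetype`,
#'   `spec`, `community_2d`, `community_3d` (the pre-invasion community for
#'   invasion archetypes) and, for invasion archetypes, `post_2d`, `post_3d`.
#' @export
generate_scenario <- function(spec) {
  stopifnot(inherits(spec, "scenario_spec"))
  with_preserved_rng({
    set.seed(spec$seed)
    switch(spec$archetype,
      invasion_no_change = scenario_no_change(spec),
      invasion_vertical = ,
      invasion_horizontal = ,
      invasion_hidden_third_axis = ,
      invasion_clustered_third = ,
      invasion_dispersed_third = scenario_invasion(spec),
      scenario_third_axis(spec))
  })
}

scenario_result <- function(spec, xy, z, taxa, post_xy = NULL, post_z = NULL,
                            post_taxa = NULL) {
  c2 <- community_matrix(xy, taxa = taxa, axes = scenario_axes_2d())
  c3 <- community_matrix(cbind(xy, z), taxa = taxa, axes = scenario_axes_3d())
  out <- list(archetype = spec$archetype, spec = spec,
              community_2d = c2, community_3d = c3,
              post_2d = NULL, post_3d = NULL)
  if (!is.null(post_xy)) {
    out$post_2d <- community_matrix(post_xy, taxa = post_taxa,
                                    axes = scenario_axes_2d())
    out$post_3d <- community_matrix(cbind(post_xy, post_z), taxa = post_taxa,
                                    axes = scenario_axes_3d())
  }
  structure(out, class = "niche_scenario")
}

scenario_third_axis <- function(spec) {
  S <- spec$S
  xy <- base_cloud_2d(S)
  taxa <- sprintf("sp%02d", seq_len(S))
  narrow <- function() Z_CENTER + stats::runif(S, -spec$spread_narrow / 2,
                                               spec$spread_narrow / 2)
  z <- switch(spec$archetype,
    third_axis_narrow = narrow(),
    third_axis_wide = Z_CENTER + sample(seq(-spec$spread_wide / 2,
                                            spec$spread_wide / 2,
                                            length.out = S)) +
      stats::runif(S, -0.02, 0.02) * spec$spread_wide,
    single_outlier = {
      zz <- narrow()
      zz[sample.int(S, 1L)] <- Z_CENTER + spec$shift
      zz
    },
    all_spread = ,
    uncorrelated_axis = Z_CENTER + stats::runif(S, -spec$spread_wide / 2,
                                                spec$spread_wide / 2),
    correlated_axis = {
      # slope 0.3 bounds the Euclidean inflation of any inter-taxon distance
      # by sqrt(1 + 0.3^2) ~ 1.044, keeping CD/NND/SDNND close to their 2-D
      # values while the hull still gains a dimension
      x1 <- xy[, 1L]
      Z_CENTER + 0.3 * (x1 - mean(x1)) +
        stats::rnorm(S, 0, 0.01 * spec$spread_wide)
    },
    stop_validation(sprintf("unknown archetype '%s'", spec$archetype)))
  scenario_result(spec, xy, z, taxa)
}

scenario_invasion <- function(spec) {
  S <- spec$S
  xy <- base_cloud_2d(S)
  taxa <- sprintf("sp%02d", seq_len(S))
  z <- Z_CENTER + stats::runif(S, -spec$spread_narrow / 2, spec$spread_narrow / 2)
  inner <- function(v) {  # points well inside the occupied 2-D cloud
    lo <- stats::quantile(v, 0.25); hi <- stats::quantile(v, 0.75)
    stats::runif(3L, lo, hi)
  }
  shift <- spec$shift
  inv_xy <- NULL; inv_z <- NULL
  if (spec$archetype == "invasion_vertical") {
    inv_xy <- cbind(inner(xy[, 1L]),
                    max(xy[, 2L]) + shift + c(0, 1, 2))
    inv_z <- Z_CENTER + stats::runif(3L, -spec$spread_narrow / 2,
                                     spec$spread_narrow / 2)
  } else if (spec$archetype == "invasion_horizontal") {
    inv_xy <- cbind(max(xy[, 1L]) + shift + c(0, 1, 2),
                    inner(xy[, 2L]))
    inv_z <- Z_CENTER + stats::runif(3L, -spec$spread_narrow / 2,
                                     spec$spread_narrow / 2)
  } else if (spec$archetype == "invasion_hidden_third_axis") {
    inv_xy <- cbind(inner(xy[, 1L]), inner(xy[, 2L]))
    inv_z <- Z_CENTER + shift + stats::runif(3L, -0.5, 0.5)
  } else if (spec$archetype == "invasion_clustered_third") {
    cx <- stats::runif(1L, stats::quantile(xy[, 1L], 0.35),
                       stats::quantile(xy[, 1L], 0.65))
    cy <- stats::runif(1L, stats::quantile(xy[, 2L], 0.35),
                       stats::quantile(xy[, 2L], 0.65))
    inv_xy <- cbind(cx + stats::runif(3L, -0.2, 0.2),
                    cy + stats::runif(3L, -0.2, 0.2))
    inv_z <- Z_CENTER + shift + stats::runif(3L, -0.15, 0.15)
  } else if (spec$archetype == "invasion_dispersed_third") {
    # mutual third-axis gaps of one full shift put the invaders well above
    # any pre-invasion nearest-neighbor distance, so NND and SDNND rise
    inv_xy <- cbind(inner(xy[, 1L]), inner(xy[, 2L]))
    inv_z <- Z_CENTER + shift * c(0.5, 1.5, 2.5)
  }
  post_xy <- rbind(xy, inv_xy)
  post_z <- c(z, inv_z)
  post_taxa <- c(taxa, sprintf("inv%d", 1:3))
  scenario_result(spec, xy, z, taxa, post_xy, post_z, post_taxa)
}

# Filled-lattice construction for the no-change invasion: a 4 x 4 grid
# (spacing 2 permil) with three vacancies — two at hull-interior nodes (so
# the hull is untouched) and one at a mid-radius edge node (so the centroid
# radius balance is kept); invaders occupy exactly those vacancies. The
# third axis follows a deterministic checkerboard pattern (amplitude 0.4
# permil) so every node's nearest neighbor is an adjacent grid node at the
# identical distance sqrt(2^2 + 0.4^2), before and after invasion. Ranges,
# IR, NND and SDNND are then invariant, and CD/CHV move by < 7%. S and the
# spread parameters are fixed by the construction (S_pre = 13, S_post = 16).
scenario_no_change <- function(spec) {
  idx <- expand.grid(i = 0:3, j = 0:3)
  gx <- -30 + 2 * idx$i
  gy <- 6 + 2 * idx$j
  gz <- Z_CENTER + 0.4 * ((idx$i + idx$j) %% 2)
  holes <- which((idx$i == 1 & idx$j == 1) | (idx$i == 2 & idx$j == 2) |
                 (idx$i == 3 & idx$j == 1))
  keep <- setdiff(seq_len(nrow(idx)), holes)
  taxa <- sprintf("sp%02d", seq_along(keep))
  post_taxa <- c(taxa, sprintf("inv%d", 1:3))
  xy <- cbind(gx[keep], gy[keep])
  z <- gz[keep]
  post_xy <- rbind(xy, cbind(gx[holes], gy[holes]))
  post_z <- c(z, gz[holes])
  scenario_result(spec, xy, z, taxa, post_xy, post_z, post_taxa)
}

#' @export
print.niche_scenario <- function(x, ...) {
  cat(sprintf("<niche_scenario> archetype '%s', S = %d, seed = %d%s\n",
              x$archetype, n_taxa(x$community_2d), x$spec$seed,
              if (!is.null(x$post_2d))
                sprintf(" (+%d invaders post)", n_taxa(x$post_2d) -
                          n_taxa(x$community_2d)) else ""))
  invisible(x)
}

#' Simulate individual-level observations around taxon means
#'
#' Draws `k` individuals per taxon and axis from `normal(taxon mean, sd)`,
#' emulating replicate captures; the per-taxon means of the output converge
#' to the community matrix as `k` grows. Draws use per-taxon substreams of
#' `seed`, so adding a taxon does not perturb the others.
#'
#' @param cm a [community_matrix()] of true taxon means.
#' @param k individuals per taxon (>= 1).
#' @param sd within-taxon standard deviation (shared across axes; >= 0).
#' @param seed integer seed.
#' @return an [individual_observations()] object with `k` rows per taxon.
#' @export
generate_individuals <- function(cm, k, sd = 0.1, seed = 1L) {
  stopifnot(inherits(cm, "community_matrix"))
  if (!(is.numeric(k) && k >= 1)) stop_validation("k must be >= 1")
  if (sd < 0) stop_validation("sd must be >= 0")
  k <- as.integer(k)
  S <- n_taxa(cm); n <- n_axes(cm)
  vals <- matrix(NA_real_, S * k, n)
  labels <- rep(taxa(cm), each = k)
  with_preserved_rng({
    for (ti in seq_len(S)) {
      set.seed(taxon_seed(seed, taxa(cm)[ti]))
      rows <- (ti - 1L) * k + seq_len(k)
      for (j in seq_len(n)) {
        vals[rows, j] <- cm$values[ti, j] + stats::rnorm(k, 0, sd)
      }
    }
  })
  colnames(vals) <- axis_names(cm)
  if (k == 1L) {
    return(suppressWarnings(individual_observations(labels, vals, axes = cm$axes)))
  }
  individual_observations(labels, vals, axes = cm$axes)
}

#' Build an estimate table around taxon means
#'
#' Pairs the community's taxon means with per-axis standard deviations (and
#' the axis bounds already declared on the community), yielding the
#' mixing-model-shaped input of [parametric_resample()].
#'
#' @param cm a [community_matrix()].
#' @param sd_map per-axis SDs: a single number, or a vector named by axis.
#' @return an [estimate_table()].
#' @export
generate_estimate_table <- function(cm, sd_map) {
  stopifnot(inherits(cm, "community_matrix"))
  ax <- axis_names(cm)
  if (length(sd_map) == 1L && is.null(names(sd_map))) {
    sds <- stats::setNames(rep(as.numeric(sd_map), length(ax)), ax)
  } else {
    if (!all(ax %in% names(sd_map))) {
      stop_validation("sd_map must name every axis")
    }
    sds <- as.numeric(sd_map[ax]); names(sds) <- ax
  }
  if (any(sds < 0)) stop_validation("sd_map entries must be >= 0")
  grid <- expand.grid(taxon = taxa(cm), axis = ax, stringsAsFactors = FALSE)
  estimate_table(grid$taxon, grid$axis,
                 mean = cm$values[cbind(match(grid$taxon, taxa(cm)),
                                        match(grid$axis, ax))],
                 sd = sds[grid$axis], axes = cm$axes)
}
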