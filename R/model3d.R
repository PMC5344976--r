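#' Configuration for restraint-based 3D modelling
#'
#' Defaults follow the established restraint-based modelling of bacterial
#' Hi-C maps: a genomic occupancy scale of 0.0201 nm/bp (100.5 nm particle
#' radius at 10 kb bins), a 250 nm proximal distance for non-interacting
#' particles, and z-score cutoffs of -0.6 (lower) and -0.2 (upper); 5,000
#' models are sampled and the 1,000 lowest-penalty models kept.
#'
#' @param scale nm per bp (default 0.0201).
#' @param maxdist Proximal distance for non-interacting particles, nm
#'   (default 250).
#' @param lower_cutoff,upper_cutoff z-score cutoffs (lower < upper; defaults
#'   -0.6 and -0.2).
#' @param n_models Models sampled (default 5000).
#' @param n_keep Lowest-penalty models kept (default 1000).
#' @param t0 Initial annealing temperature (energy units; default 1e4).
#' @param cooling Geometric cooling factor per temperature step (default 0.85).
#' @param n_temps Number of temperature steps (default 40).
#' @param sweeps_per_temp Metropolis sweeps per temperature (default 5).
#' @param move_sigma Initial single-particle Gaussian move, nm (default 100).
#' @param quench_sweeps Zero-temperature polishing sweeps (default 150).
#' @param force_constant Harmonic force constant for all restraint kinds
#'   (default 1, consistent units).
#' @param seed Master RNG seed; per-model substreams are derived from it.
#' @return A `modeling_config` list.
#' @export
modeling_config <- function(scale = 0.0201, maxdist = 250,
                            lower_cutoff = -0.6, upper_cutoff = -0.2,
                            n_models = 5000L, n_keep = 1000L,
                            t0 = 1e4, cooling = 0.85, n_temps = 40L,
                            sweeps_per_temp = 5L, move_sigma = 100,
                            quench_sweeps = 150L, force_constant = 1,
                            seed = 1L) {
  stopifnot_scalar(scale, "scale", positive = TRUE)
  stopifnot_scalar(maxdist, "maxdist", positive = TRUE)
  if (lower_cutoff >= upper_cutoff) stop("lower_cutoff must be < upper_cutoff", call. = FALSE)
  if (n_keep > n_models) stop("n_keep must be <= n_models", call. = FALSE)
  structure(list(scale = scale, maxdist = maxdist, lower_cutoff = lower_cutoff,
                 upper_cutoff = upper_cutoff, n_models = as.integer(n_models),
                 n_keep = as.integer(n_keep), t0 = t0, cooling = cooling,
                 n_temps = as.integer(n_temps), sweeps_per_temp = as.integer(sweeps_per_temp),
                 move_sigma = move_sigma, quench_sweeps = as.integer(quench_sweeps),
                 force_constant = force_constant, seed = as.integer(seed)),
            class = "modeling_config")
}

#' Particle radius from bin size and occupancy scale
#'
#' A bin of `bin_size` bp occupies `bin_size * scale` nm of chromatin fibre,
#' modelled as a sphere of half that diameter: `radius = bin_size * scale / 2`.
#'
#' @param bin_size Bin size, bp.
#' @param scale nm per bp.
#' @return Radius in nm (10 kb at 0.0201 nm/bp gives 100.5 nm).
#' @export
particle_radius <- function(bin_size, scale = 0.0201) {
  stopifnot_scalar(bin_size, "bin_size", positive = TRUE)
  stopifnot_scalar(scale, "scale", positive = TRUE)
  bin_size * scale / 2
}

#' Translate contact frequencies into spatial restraints
#'
#' Normalized frequencies are z-scored on log10 of the positive entries.
#' Consecutive particles (circularly) always receive a harmonic restraint at
#' the sum of their radii. Non-consecutive pairs with z-score above the
#' upper cutoff receive a harmonic attraction whose equilibrium distance
#' interpolates linearly in z between `maxdist` (at the upper cutoff) and
#' the sum of radii (at the maximum z-score); pairs below the lower cutoff
#' (including zero-contact pairs) receive a one-sided lower-bound restraint
#' at `maxdist`; pairs between the cutoffs are unrestrained.
#'
#' @param matrix Normalized `contact_matrix`.
#' @param config A `modeling_config`.
#' @return A `restraint_set`: tibble with columns `i`, `j`, `kind`
#'   (`adjacent`, `attract`, `repel_lower_bound`), `dist` (nm), `k`;
#'   particle radii in attribute `radii`.
#' @export
build_restraints <- function(matrix, config = modeling_config()) {
  n <- n_bins(matrix)
  m <- matrix$values
  if (all(m == 0)) stop("all-zero matrix: no signal to model", call. = FALSE)
  radius <- particle_radius(matrix$bin_size, config$scale)
  radii <- rep(radius, n)

  pos <- m[upper.tri(m)]
  pos <- pos[pos > 0]
  lv <- log10(pos)
  z <- matrix(NA_real_, n, n)
  ut <- upper.tri(m)
  z[ut] <- ifelse(m[ut] > 0, (log10(pmax(m[ut], .Machine$double.xmin)) - mean(lv)) / stats::sd(lv), -Inf)
  zmax <- max(z[ut][is.finite(z[ut])])

  adj_i <- seq_len(n)
  adj_j <- c(seq_len(n - 1) + 1L, 1L)
  adjacent <- tibble::tibble(i = pmin(adj_i, adj_j), j = pmax(adj_i, adj_j),
                             kind = "adjacent", dist = 2 * radius, k = config$force_constant)
  adjacent <- dplyr::distinct(adjacent, .data$i, .data$j, .keep_all = TRUE)

  idx <- which(ut, arr.ind = TRUE)
  is_adj <- circular_distance(idx[, 1], idx[, 2], n) == 1
  usable <- !(idx[, 1] %in% matrix$blacklist) & !(idx[, 2] %in% matrix$blacklist)
  zz <- z[ut]
  attract_sel <- !is_adj & usable & zz > config$upper_cutoff
  span <- max(zmax - config$upper_cutoff, .Machine$double.eps)
  frac <- pmin((zz[attract_sel] - config$upper_cutoff) / span, 1)
  attract <- tibble::tibble(i = idx[attract_sel, 1], j = idx[attract_sel, 2],
                            kind = "attract",
                            dist = config$maxdist + frac * (2 * radius - config$maxdist),
                            k = config$force_constant)
  repel_sel <- !is_adj & usable & zz < config$lower_cutoff
  repel <- tibble::tibble(i = idx[repel_sel, 1], j = idx[repel_sel, 2],
                          kind = "repel_lower_bound", dist = config$maxdist,
                          k = config$force_constant)
  out <- dplyr::bind_rows(adjacent, attract, repel)
  structure(out, radii = radii, n_particles = n, class = c("restraint_set", class(out)))
}

#' Sample a 3D model ensemble by Monte Carlo simulated annealing
#'
#' Each model starts from random particle positions and is relaxed by
#' single-particle Gaussian Metropolis moves under a geometric cooling
#' schedule, followed by a zero-temperature quench. The objective is the sum
#' of harmonic penalties: `k (d - d0)^2` for adjacent/attract restraints and
#' `k (d0 - d)^2` when `d < d0` for lower-bound restraints. Deterministic
#' given the config seed (per-model substreams are derived from it).
#'
#' @param restraints A `restraint_set`.
#' @param config A `modeling_config`.
#' @return A `model_ensemble`: list with `coords` (list of n x 3 matrices,
#'   nm), `penalty`, `initial_penalty`, `cluster` (NULL until clustered).
#' @export
optimize_ensemble <- function(restraints, config = modeling_config()) {
  n <- attr(restraints, "n_particles")
  radii <- attr(restraints, "radii")
  kind_code <- ifelse(restraints$kind == "repel_lower_bound", 1L, 0L)
  init_radius <- n * 2 * mean(radii) / (2 * pi)
  res <- .anneal_ensemble(n, as.integer(restraints$i) - 1L, as.integer(restraints$j) - 1L,
                          kind_code, restraints$dist, restraints$k,
                          config$n_models, config$t0, config$cooling, config$n_temps,
                          config$sweeps_per_temp, config$move_sigma, config$quench_sweeps,
                          init_radius, config$seed)
  coords <- lapply(seq_len(config$n_models), function(m) {
    x <- matrix(res$coords[(3 * n * (m - 1) + 1):(3 * n * m)], ncol = 3, byrow = TRUE)
    colnames(x) <- c("x", "y", "z")
    x
  })
  structure(list(coords = coords, penalty = res$penalty,
                 initial_penalty = res$initial_penalty, radii = radii,
                 cluster = NULL, centroids = NULL),
            class = "model_ensemble")
}

#' Build a model ensemble from explicit coordinate sets
#'
#' @param coords List of n x 3 coordinate matrices (nm).
#' @param penalty Optional per-model objective values (default 0).
#' @return A `model_ensemble`.
#' @export
model_ensemble <- function(coords, penalty = rep(0, length(coords))) {
  if (!length(coords)) stop("empty ensemble", call. = FALSE)
  structure(list(coords = coords, penalty = penalty, initial_penalty = penalty,
                 radii = NULL, cluster = NULL, centroids = NULL),
            class = "model_ensemble")
}

#' @export
print.model_ensemble <- function(x, ...) {
  cat(sprintf("<model_ensemble> %d models x %d particles; penalty median %.4g\n",
              length(x$coords), nrow(x$coords[[1]]), stats::median(x$penalty)))
  if (!is.null(x$cluster)) cat(sprintf("  clusters: %s\n",
    paste(table(x$cluster), collapse = "/")))
  invisible(x)
}

#' Keep the lowest-penalty models
#'
#' Selection is exact: the `n_keep` models with least objective penalty,
#' ties broken by model index. Idempotent.
#'
#' @param ensemble A `model_ensemble`.
#' @param n_keep Number of models to keep.
#' @return A `model_ensemble` of the kept models, ordered by penalty.
#' @export
select_models <- function(ensemble, n_keep) {
  n <- length(ensemble$coords)
  if (n_keep > n) stop("n_keep exceeds ensemble size", call. = FALSE)
  ord <- order(ensemble$penalty, seq_len(n))[seq_len(n_keep)]
  structure(list(coords = ensemble$coords[ord], penalty = ensemble$penalty[ord],
                 initial_penalty = ensemble$initial_penalty[ord],
                 radii = ensemble$radii, cluster = NULL, centroids = NULL),
            class = "model_ensemble")
}

ensemble_coords_flat <- function(ensemble) {
  unlist(lapply(ensemble$coords, function(x) as.vector(t(x))), use.names = FALSE)
}

#' Cluster models by structural similarity
#'
#' Pairwise dissimilarity is the coordinate RMSD after optimal rigid
#' superposition; reflections are disallowed by default, so mirror-image
#' conformations land in separate clusters (set `allow_reflection = TRUE`
#' to merge them). Average-linkage hierarchical clustering is cut either at
#' a requested number of clusters `k` or, by default, at the largest
#' relative gap in the merge heights, provided that gap exceeds `gap_ratio`;
#' ensembles without a pronounced gap (including near-identical ones) form
#' a single cluster. Each cluster's centroid is the member model with the
#' smallest mean dissimilarity to the other members.
#'
#' @param ensemble A `model_ensemble` with >= 2 models.
#' @param k Optional fixed number of clusters.
#' @param allow_reflection Merge mirror images (default `FALSE`).
#' @param linkage `stats::hclust` method (default `"average"`).
#' @param gap_ratio Minimum ratio between consecutive merge heights for a
#'   split to be accepted (default 2).
#' @return The ensemble with `cluster` labels and `centroids` (model index
#'   per cluster) filled in; the RMSD matrix is attached as attribute `rmsd`.
#' @export
cluster_models <- function(ensemble, k = NULL, allow_reflection = FALSE,
                           linkage = "average", gap_ratio = 2) {
  n <- length(ensemble$coords)
  if (n < 2) stop("need at least 2 models to cluster", call. = FALSE)
  np <- nrow(ensemble$coords[[1]])
  D <- .pairwise_rmsd(ensemble_coords_flat(ensemble), np, n, allow_reflection)
  scale_ref <- stats::median(vapply(ensemble$coords, function(x) {
    sqrt(mean(scale(x, scale = FALSE)^2) * 3)
  }, 1))
  hc <- stats::hclust(stats::as.dist(D), method = linkage)
  if (max(D) < 1e-6 * max(scale_ref, 1)) {
    labels <- rep(1L, n)
  } else if (is.null(k)) {
    h <- pmax(hc$height, 0)
    floor_h <- 1e-9 * max(h)
    ratios <- (h[-1] + floor_h) / (pmax(h[-length(h)], 0) + floor_h)
    best <- which.max(ratios)
    labels <- if (length(h) >= 2 && ratios[best] >= gap_ratio) {
      stats::cutree(hc, k = n - best)
    } else {
      rep(1L, n)
    }
  } else {
    labels <- stats::cutree(hc, k = k)
  }
  centroids <- vapply(sort(unique(labels)), function(cl) {
    members <- which(labels == cl)
    if (length(members) == 1) return(members)
    # lowest mean dissimilarity to the other members
    members[which.min(rowMeans(D[members, members, drop = FALSE]))]
  }, 1L)
  ensemble$cluster <- labels
  ensemble$centroids <- centroids
  attr(ensemble, "rmsd") <- D
  ensemble
}

model_distance_matrices <- function(ensemble) {
  lapply(ensemble$coords, function(x) as.matrix(stats::dist(x)))
}

#' Median inter-particle distance matrix of an ensemble
#'
#' @param ensemble A `model_ensemble`.
#' @return Symmetric matrix of per-pair median distances (nm).
#' @export
ensemble_median_distances <- function(ensemble) {
  dm <- model_distance_matrices(ensemble)
  apply(simplify2array(dm), c(1, 2), stats::median)
}

#' Chromosome geometry of each model
#'
#' Per model: `length` is the largest pairwise particle distance, `width`
#' twice the radius of gyration, and `volume` that of the prolate ellipsoid
#' with the length as major axis and the width as minor-axis diameter,
#' `(4/3) * pi * (length/2) * (width/2)^2`, reported in cubic micrometres.
#' Medians are taken per quantity across models (so the median volume need
#' not equal the ellipsoid volume of the median length and width).
#'
#' @param ensemble A `model_ensemble`.
#' @return Tibble with one row per model (`model`, `length_nm`, `width_nm`,
#'   `volume_um3`); medians in attribute `medians`.
#' @export
ensemble_geometry <- function(ensemble) {
  if (nrow(ensemble$coords[[1]]) < 2) stop("need at least 2 particles", call. = FALSE)
  rows <- purrr::map_dfr(seq_along(ensemble$coords), function(m) {
    x <- ensemble$coords[[m]]
    len <- max(stats::dist(x))
    rg <- sqrt(sum(scale(x, scale = FALSE)^2) / nrow(x))
    wid <- 2 * rg
    vol <- (4 / 3) * pi * (len / 2) * (wid / 2)^2 / 1e9
    tibble::tibble(model = m, length_nm = len, width_nm = wid, volume_um3 = vol)
  })
  attr(rows, "medians") <- c(length_nm = stats::median(rows$length_nm),
                             width_nm = stats::median(rows$width_nm),
                             volume_um3 = stats::median(rows$volume_um3))
  rows
}

#' Contact map implied by a model ensemble
#'
#' `M(i, j)` is the fraction of models in which particles i and j lie closer
#' than `contact_cutoff`. If a reference matrix is supplied, the Pearson
#' correlation over its non-blacklisted off-diagonal pairs is attached;
#' since restraints are derived from log-frequencies, the reference enters
#' the correlation on the log10 scale (positive cells) by default.
#'
#' @param ensemble A `model_ensemble`.
#' @param contact_cutoff Contact distance in nm.
#' @param reference Optional input `contact_matrix` to correlate against.
#' @param log_reference Correlate against `log10` of the positive reference
#'   entries (default `TRUE`); `FALSE` uses the raw values of all entries.
#' @return A normalized-state `contact_matrix` of contact fractions, with
#'   attribute `correlation` when a reference is given.
#' @export
model_contact_map <- function(ensemble, contact_cutoff, reference = NULL,
                              log_reference = TRUE) {
  stopifnot_scalar(contact_cutoff, "contact_cutoff", positive = TRUE)
  dm <- model_distance_matrices(ensemble)
  frac <- Reduce(`+`, lapply(dm, function(d) (d < contact_cutoff) * 1)) / length(dm)
  diag(frac) <- 1
  out <- contact_matrix(frac, if (is.null(reference)) 1 else reference$bin_size,
                        if (is.null(reference)) integer() else reference$blacklist,
                        state = "normalized")
  if (!is.null(reference)) {
    keep <- usable_bins(out)
    ut <- upper.tri(frac)
    sel <- ut & outer(seq_len(nrow(frac)) %in% keep, seq_len(nrow(frac)) %in% keep, `&`)
    if (log_reference) sel <- sel & reference$values > 0
    a <- frac[sel]
    b <- if (log_reference) log10(reference$values[sel]) else reference$values[sel]
    if (stats::sd(a) == 0 || stats::sd(b) == 0) {
      stop("correlation undefined: degenerate contact map", call. = FALSE)
    }
    attr(out, "correlation") <- stats::cor(a, b)
  }
  out
}

#' Pairwise locus distances across an ensemble
#'
#' @param ensemble A `model_ensemble`.
#' @param loci Named or unnamed vector of 1-based particle indices.
#' @return Tibble with one row per locus pair: `locus_a`, `locus_b`,
#'   `median_nm`, `mean_nm`, `sd_nm`.
#' @export
locus_distances <- function(ensemble, loci) {
  np <- nrow(ensemble$coords[[1]])
  if (any(loci < 1 | loci > np)) stop("locus index out of range", call. = FALSE)
  if (is.null(names(loci))) names(loci) <- paste0("locus", loci)
  pairs <- utils::combn(seq_along(loci), 2)
  purrr::map_dfr(seq_len(ncol(pairs)), function(p) {
    a <- pairs[1, p]; b <- pairs[2, p]
    d <- vapply(ensemble$coords, function(x) {
      sqrt(sum((x[loci[a], ] - x[loci[b], ])^2))
    }, 1)
    tibble::tibble(locus_a = names(loci)[a], locus_b = names(loci)[b],
                   median_nm = stats::median(d), mean_nm = mean(d), sd_nm = stats::sd(d))
  })
}

#' Distance of each bin to the structure's centre of mass
#'
#' @param ensemble A `model_ensemble`.
#' @return Tibble with `bin`, `median_nm`, `mean_nm`, `sd_nm` across models.
#' @export
center_of_mass_profile <- function(ensemble) {
  per_model <- vapply(ensemble$coords, function(x) {
    c <- colMeans(x)
    sqrt(rowSums(sweep(x, 2, c)^2))
  }, numeric(nrow(ensemble$coords[[1]])))
  per_model <- matrix(per_model, nrow = nrow(ensemble$coords[[1]]))
  tibble::tibble(bin = seq_len(nrow(per_model)),
                 median_nm = apply(per_model, 1, stats::median),
                 mean_nm = rowMeans(per_model),
                 sd_nm = apply(per_model, 1, stats::sd))
}
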