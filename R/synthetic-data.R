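#' Generate a synthetic circular-genome annotation
#'
#' Emulates the gene organisation of a genome-reduced bacterium: a circular
#' genome densely tiled by genes arranged in strand runs (so convergent and
#' divergent junctions arise at run boundaries), a smooth per-bin GC track
#' around a configurable mean, and a per-bin restriction-site count track.
#'
#' @param genome_length Genome length in bp (>= 10 x `bin_size`).
#' @param n_genes Number of genes to tile (>= 2).
#' @param bin_size Track bin width in bp.
#' @param seed RNG seed; output is deterministic given the seed.
#' @param gc_mean Mean GC fraction of the track (default 0.40, AT-rich).
#' @param site_rate Restriction sites per bp (default 1/450, a frequent
#'   4-cutter).
#' @param mean_run Mean number of consecutive same-strand genes (default 3).
#' @return A `genome_annotation` list with `genome_length`, `circular`,
#'   `bin_size`, `n_bins`, `genes` (tibble: start, end, strand; 0-based
#'   half-open bp), `gc_track` and `site_track`.
#' @export
generate_genome_annotation <- function(genome_length, n_genes, bin_size, seed = 1L,
                                       gc_mean = 0.40, site_rate = 1 / 450,
                                       mean_run = 3) {
  stopifnot_scalar(genome_length, "genome_length", positive = TRUE)
  stopifnot_scalar(bin_size, "bin_size", positive = TRUE)
  if (genome_length < 3 * bin_size) stop("genome_length must span at least 3 bins", call. = FALSE)
  if (n_genes < 2) stop("need at least 2 genes", call. = FALSE)
  n_bins <- as.integer(ceiling(genome_length / bin_size))
  with_seed(seed, {
    # gene boundaries: jittered even spacing, small intergenic gaps
    breaks <- sort(round(seq(0, genome_length, length.out = n_genes + 1) +
                           c(0, stats::runif(n_genes - 1, -0.2, 0.2) * genome_length / n_genes, 0)))
    breaks[1] <- 0; breaks[n_genes + 1] <- genome_length
    gap <- pmin(floor(diff(breaks) * 0.1), 200)
    start <- breaks[-(n_genes + 1)]
    end <- breaks[-1] - gap
    end <- pmax(end, start + 1)
    # strand runs of geometric length -> convergent/divergent junctions
    strand <- character(n_genes)
    s <- sample(c("+", "-"), 1)
    i <- 1L
    while (i <= n_genes) {
      run <- 1L + stats::rgeom(1, 1 / mean_run)
      strand[i:min(n_genes, i + run - 1L)] <- s
      i <- i + run
      s <- if (s == "+") "-" else "+"
    }
    genes <- tibble::tibble(start = start, end = end, strand = strand)
    gc <- gc_mean + as.numeric(stats::filter(stats::rnorm(n_bins, 0, 0.04),
                                             rep(1 / 3, 3), circular = TRUE))
    gc <- pmin(pmax(gc, 0), 1)
    bin_len <- rep(bin_size, n_bins)
    bin_len[n_bins] <- genome_length - (n_bins - 1) * bin_size
    sites <- stats::rpois(n_bins, site_rate * bin_len)
    structure(
      list(genome_length = genome_length, circular = TRUE, bin_size = bin_size,
           n_bins = n_bins, genes = genes, gc_track = gc, site_track = sites),
      class = "genome_annotation"
    )
  })
}

#' @export
print.genome_annotation <- function(x, ...) {
  cat(sprintf("<genome_annotation> %d bp circular, %d genes, %d bins x %d bp\n",
              as.integer(x$genome_length), nrow(x$genes), x$n_bins, as.integer(x$bin_size)))
  invisible(x)
}

#' Generate a ground-truth 3D chromosome structure
#'
#' Builds a closed circular particle chain laid on an elongated ellipse so
#' that the first particle and the diametrically opposite particle (index
#' `1 + n/2`) sit at the two poles and are the most mutually distant pair,
#' mimicking an Ori/midpoint polar arrangement. Consecutive particles are
#' spaced by the sum of their radii (equal radii: `2 * particle_radius`).
#'
#' @param n_particles Number of particles (>= 4).
#' @param particle_radius Particle radius in nm.
#' @param seed RNG seed (used for the small out-of-plane wobble).
#' @param axis_ratio Ellipse major/minor axis ratio (default 2).
#' @param wobble Out-of-plane wobble amplitude as a fraction of the radius
#'   (default 0.05; keeps the pole geometry intact).
#' @return `n_particles x 3` matrix of coordinates in nm.
#' @export
generate_true_structure <- function(n_particles, particle_radius, seed = 1L,
                                    axis_ratio = 2, wobble = 0.05) {
  if (n_particles < 4) stop("need at least 4 particles", call. = FALSE)
  stopifnot_scalar(particle_radius, "particle_radius", positive = TRUE)
  spacing <- 2 * particle_radius
  # dense ellipse, equal arc-length placement, then scale mean chord to spacing
  theta <- seq(0, 2 * pi, length.out = 20000L + 1L)[-1L]
  b <- 1; a <- axis_ratio
  xs <- a * cos(theta); ys <- b * sin(theta)
  seg <- sqrt(diff(c(xs[length(xs)], xs))^2 + diff(c(ys[length(ys)], ys))^2)
  arc <- cumsum(seg) - seg[1]
  targets <- seq(0, arc[length(arc)], length.out = n_particles + 1L)[seq_len(n_particles)]
  idx <- findInterval(targets, arc)
  pts <- cbind(xs[pmax(idx, 1)], ys[pmax(idx, 1)])
  chord <- sqrt(rowSums((pts - pts[c(2:n_particles, 1), ])^2))
  pts <- pts * spacing / mean(chord)
  z <- with_seed(seed, {
    phase <- stats::runif(1, 0, 2 * pi)
    wobble * particle_radius * sin(3 * seq(0, 2 * pi, length.out = n_particles + 1L)[seq_len(n_particles)] + phase)
  })
  coords <- cbind(pts, z)
  colnames(coords) <- c("x", "y", "z")
  coords
}

#' Planted ground truth for the synthetic generator
#'
#' Bundles the parameters that define a synthetic dataset: the planted
#' domain borders (1-based start bins of each domain; bin 1 is implicitly a
#' border on the circular genome), the optional true 3D structure, the
#' power-law decay exponent `b < 0`, the within-domain contact boost, the
#' secondary (anti-)diagonal enhancement and the seed.
#'
#' @param true_borders Strictly increasing integer bin indices (> 1).
#' @param decay_exponent Power-law slope `b` (must be negative).
#' @param domain_boost Multiplicative within-domain intensity (>= 1).
#' @param epsilon Secondary-diagonal enhancement (default 0.3).
#' @param true_structure Optional particle coordinate matrix (nm).
#' @param boost_domains Optional domain indices receiving the boost
#'   (default: all domains).
#' @param noise_seed Seed associated with the truth.
#' @return A `planted_truth` list.
#' @export
planted_truth <- function(true_borders = integer(), decay_exponent = -1,
                          domain_boost = 1, epsilon = 0.3,
                          true_structure = NULL, boost_domains = NULL,
                          noise_seed = 1L) {
  true_borders <- as.integer(true_borders)
  if (length(true_borders) && (is.unsorted(true_borders, strictly = TRUE) || any(true_borders < 2))) {
    stop("`true_borders` must be strictly increasing bin indices > 1", call. = FALSE)
  }
  if (decay_exponent >= 0) stop("`decay_exponent` must be negative", call. = FALSE)
  if (domain_boost < 1) stop("`domain_boost` must be >= 1", call. = FALSE)
  structure(list(true_borders = true_borders, decay_exponent = decay_exponent,
                 domain_boost = domain_boost, epsilon = epsilon,
                 true_structure = true_structure,
                 boost_domains = boost_domains, noise_seed = noise_seed),
            class = "planted_truth")
}

# Domain id (1-based) of each bin given domain start borders (bin 1 implicit).
bin_domains <- function(n_bins, borders) {
  findInterval(seq_len(n_bins), sort(unique(c(1L, borders))))
}

# Expected counts for the planted model.
planted_expectation <- function(truth, n_bins, mean_depth) {
  d <- circular_distance_matrix(n_bins)
  mu <- mean_depth * ifelse(d == 0, 1, d^truth$decay_exponent)
  dom <- bin_domains(n_bins, truth$true_borders)
  same <- outer(dom, dom, `==`)
  if (!is.null(truth$boost_domains)) {
    boosted <- dom %in% truth$boost_domains
    same <- same & outer(boosted, boosted, `&`)
  }
  mu <- mu * ifelse(same, truth$domain_boost, 1)
  if (truth$epsilon != 0) {
    i0 <- seq_len(n_bins) - 1L
    anti <- outer(i0, i0, function(a, b) (a + b) %% n_bins == 0)
    mu <- mu * (1 + truth$epsilon * anti)
  }
  mu
}

#' Simulate a Poisson contact map with planted domains
#'
#' Expected counts for bins i, j at circular distance d are
#' `mean_depth * d^b`, multiplied by `domain_boost` when both bins lie in
#' the same planted domain and by `(1 + epsilon)` on the secondary diagonal
#' (`(i + j) mod n == 0`, 0-based), mirroring the wrap-around arm-to-arm
#' contacts of a circular chromosome. Counts are Poisson-sampled and exactly
#' symmetric; self-contacts are drawn with mean `mean_depth` and flagged.
#'
#' @param truth A `planted_truth`.
#' @param n_bins Number of bins (>= 8).
#' @param mean_depth Expected counts per bin pair at unit distance.
#' @param seed RNG seed.
#' @return A raw `contact_matrix` (attribute `self_contacts = TRUE`).
#' @export
simulate_contact_map <- function(truth, n_bins, mean_depth, seed = truth$noise_seed) {
  if (n_bins < 8) stop("need at least 8 bins", call. = FALSE)
  stopifnot_scalar(mean_depth, "mean_depth", positive = TRUE)
  if (length(truth$true_borders) && max(truth$true_borders) > n_bins) {
    stop("planted borders exceed the bin count", call. = FALSE)
  }
  mu <- planted_expectation(truth, n_bins, mean_depth)
  m <- with_seed(seed, {
    x <- matrix(0, n_bins, n_bins)
    ut <- upper.tri(x, diag = TRUE)
    x[ut] <- stats::rpois(sum(ut), mu[ut])
    x[lower.tri(x)] <- t(x)[lower.tri(x)]
    x
  })
  out <- contact_matrix(m, bin_size = 1, state = "raw")
  attr(out, "self_contacts") <- TRUE
  out
}

#' Simulate a contact map from a known 3D structure
#'
#' Expected counts between particles i and j decay as a power of their
#' spatial distance, `mean_depth * (d_ij / d_min)^exponent` with `d_min` the
#' smallest inter-particle distance, and are Poisson-sampled. Used for
#' structure-recovery experiments where the generating geometry is known.
#'
#' @param coords Particle coordinate matrix (nm).
#' @param mean_depth Expected counts for the closest particle pair.
#' @param exponent Spatial-distance decay exponent (default -2).
#' @param seed RNG seed.
#' @return A raw `contact_matrix`.
#' @export
simulate_map_from_structure <- function(coords, mean_depth, exponent = -2, seed = 1L) {
  if (exponent >= 0) stop("`exponent` must be negative", call. = FALSE)
  d <- as.matrix(stats::dist(coords))
  dmin <- min(d[d > 0])
  mu <- mean_depth * (d / dmin)^exponent
  diag(mu) <- 0
  n <- nrow(d)
  m <- with_seed(seed, {
    x <- matrix(0, n, n)
    ut <- upper.tri(x)
    x[ut] <- stats::rpois(sum(ut), mu[ut])
    x[lower.tri(x)] <- t(x)[lower.tri(x)]
    x
  })
  contact_matrix(m, bin_size = 1, state = "raw")
}

#' Simulate replicate contact libraries
#'
#' Independent Poisson draws from the same planted expectation, with
#' per-replicate sequencing-depth scaling drawn log-normally around 1.
#'
#' @param truth A `planted_truth`.
#' @param n_bins Number of bins.
#' @param mean_depth Base expected counts per bin pair at unit distance.
#' @param n_replicates Number of replicates (>= 1).
#' @param depth_variation Log-scale s.d. of the per-replicate depth factor.
#' @param seed RNG seed.
#' @return List of raw `contact_matrix` objects.
#' @export
simulate_replicates <- function(truth, n_bins, mean_depth, n_replicates,
                                depth_variation = 0.1, seed = 1L) {
  if (n_replicates < 1) stop("need at least 1 replicate", call. = FALSE)
  depths <- with_seed(seed, mean_depth * exp(stats::rnorm(n_replicates, 0, depth_variation)))
  lapply(seq_len(n_replicates), function(r) {
    simulate_contact_map(truth, n_bins, depths[r], seed = seed * 1000L + r)
  })
}

#' Simulate an expression matrix with within-domain co-variation
#'
#' Genes assigned (by midpoint bin) to the same planted domain share a
#' per-condition latent factor with loading `sqrt(rho_within)`, giving
#' pairwise correlation ~ `rho_within` within domains and ~ 0 across
#' domains. Each condition is measured in `n_replicates` samples (default
#' 2, emulating paired RNA-seq samples per condition); the latent factor is
#' shared within a condition while measurement noise is per sample.
#'
#' @param annotation A `genome_annotation`.
#' @param borders Planted domain borders (1-based start bins).
#' @param n_conditions Number of conditions.
#' @param rho_within Target within-domain pairwise correlation in `[0, 1)`.
#' @param seed RNG seed.
#' @param n_replicates Samples per condition (default 2).
#' @return Numeric genes x samples matrix with gene midpoints (bp) in
#'   attribute `midpoint` and condition ids in attribute `condition`.
#' @export
simulate_expression <- function(annotation, borders, n_conditions, rho_within,
                                seed = 1L, n_replicates = 2L) {
  if (rho_within < 0 || rho_within >= 1) stop("`rho_within` must be in [0, 1)", call. = FALSE)
  genes <- annotation$genes
  mid <- (genes$start + genes$end) / 2
  gene_bin <- pmin(floor(mid / annotation$bin_size) + 1L, annotation$n_bins)
  dom <- bin_domains(annotation$n_bins, borders)[gene_bin]
  n_genes <- nrow(genes)
  n_dom <- max(dom)
  n_samples <- n_conditions * n_replicates
  expr <- with_seed(seed, {
    f <- matrix(stats::rnorm(n_dom * n_conditions), n_dom, n_conditions)
    f_samp <- f[, rep(seq_len(n_conditions), each = n_replicates), drop = FALSE]
    noise <- matrix(stats::rnorm(n_genes * n_samples), n_genes, n_samples)
    base <- stats::rnorm(n_genes, 8, 1)
    sqrt(rho_within) * f_samp[dom, , drop = FALSE] +
      sqrt(1 - rho_within) * noise + base
  })
  rownames(expr) <- sprintf("g%04d", seq_len(n_genes))
  colnames(expr) <- sprintf("c%03d_r%d", rep(seq_len(n_conditions), each = n_replicates),
                            rep(seq_len(n_replicates), n_conditions))
  attr(expr, "midpoint") <- mid
  attr(expr, "condition") <- rep(seq_len(n_conditions), each = n_replicates)
  expr
}
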