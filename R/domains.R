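#' Segmentation configuration for CID detection
#'
#' @param bin_size Bin size in bp (default 3000, the resolution at which
#'   local chromatin structure is analysed).
#' @param min_domain Minimum domain size in bins (default 3, i.e. 9 kb,
#'   admitting the smallest domains seen under relaxed supercoiling).
#' @param bic_multiplier Scale of the BIC penalty per domain (default 1);
#'   larger values yield fewer borders.
#' @param band Only cells within this circular bin distance of the diagonal
#'   enter the likelihood (default 20), since the informative Hi-C signal
#'   lies near the diagonal.
#' @param n_confidence_levels Penalty levels used for border confidence
#'   (fixed at 10).
#' @param decay_fit `"beyond_band"` (default) fits the power-law decay on
#'   distances larger than the band, where no domain structure lives, and
#'   extrapolates inwards, so the within-domain enrichment is not absorbed
#'   into the expectation; `"all"` fits on every distance.
#' @return A `segmentation_config` list.
#' @export
segmentation_config <- function(bin_size = 3000, min_domain = 3L,
                                bic_multiplier = 1, band = 20L,
                                n_confidence_levels = 10L,
                                decay_fit = c("beyond_band", "all")) {
  if (min_domain < 2) stop("min_domain must be >= 2", call. = FALSE)
  stopifnot_scalar(bic_multiplier, "bic_multiplier", positive = TRUE)
  structure(list(bin_size = bin_size, min_domain = as.integer(min_domain),
                 bic_multiplier = bic_multiplier, band = as.integer(band),
                 n_confidence_levels = as.integer(n_confidence_levels),
                 decay_fit = match.arg(decay_fit)),
            class = "segmentation_config")
}

#' Fit the power-law distance decay of contact counts
#'
#' Mean counts per circular genomic distance are fit as `A * d^b` by
#' least squares on the log-log scale (distances with positive means only).
#' The raw per-distance means are also returned; they define the expected
#' counts used for domain densities.
#'
#' @param matrix A `contact_matrix`.
#' @param max_distance Largest circular distance to use (default `n/2`).
#' @param min_fit_distance Smallest distance entering the power-law fit
#'   (default 1); the per-distance means are always reported from distance 1.
#'   Fitting only distances beyond the expected domain size and
#'   extrapolating inwards keeps within-domain enrichment out of the fit.
#' @return List with `A`, `b` and `means` (tibble: distance, mean, n_pairs).
#' @export
fit_distance_decay <- function(matrix, max_distance = NULL, min_fit_distance = 1L) {
  n <- n_bins(matrix)
  keep <- usable_bins(matrix)
  d <- circular_distance_matrix(n)
  dmax <- if (is.null(max_distance)) floor(n / 2) else min(max_distance, floor(n / 2))
  sel <- outer(seq_len(n) %in% keep, seq_len(n) %in% keep, `&`) & upper.tri(d)
  dv <- d[sel]; mv <- matrix$values[sel]
  means <- tibble::tibble(distance = seq_len(dmax)) |>
    dplyr::mutate(mean = vapply(.data$distance, function(k) mean(mv[dv == k]), 1),
                  n_pairs = vapply(.data$distance, function(k) sum(dv == k), 1))
  pos <- means[is.finite(means$mean) & means$mean > 0 &
                 means$distance >= min_fit_distance, ]
  if (nrow(pos) < 3) stop("fewer than 3 distances with positive mean counts", call. = FALSE)
  if (stats::sd(pos$mean) == 0) {
    A <- pos$mean[1]; b <- 0
  } else {
    fit <- stats::lm(log(mean) ~ log(distance), data = pos)
    A <- exp(stats::coef(fit)[[1]]); b <- stats::coef(fit)[[2]]
  }
  list(A = A, b = b, means = means)
}

# Cumulative sums per near-diagonal: counts and expectations for all
# non-wrapping cells (i, i+d), d = 1..band, with blacklisted cells zeroed.
segment_cumsums <- function(values, expected, blacklist, band) {
  n <- nrow(values)
  band <- min(band, n - 1L)
  usable <- !(seq_len(n) %in% blacklist)
  lapply(seq_len(band), function(d) {
    i <- seq_len(n - d)
    w <- usable[i] & usable[i + d]
    x <- values[cbind(i, i + d)] * w
    e <- expected[cbind(i, i + d)] * w
    list(cx = c(0, cumsum(x)), ce = c(0, cumsum(e)), d = d)
  })
}

# Sum of counts/expectations of within-segment cells for segment [a, b]
# (1-based inclusive bins), vectorized over `a`.
segment_sums <- function(cums, a, b) {
  S <- numeric(length(a)); E <- numeric(length(a))
  for (cs in cums) {
    d <- cs$d
    ok <- (b - a) >= d
    if (!any(ok)) next
    hi <- b - d
    S[ok] <- S[ok] + (cs$cx[hi[ok] + 1L] - cs$cx[a[ok]])
    E[ok] <- E[ok] + (cs$ce[hi[ok] + 1L] - cs$ce[a[ok]])
  }
  list(S = S, E = E)
}

# Poisson gain of giving segment [a, b] its own intensity multiplier
# lambda = S/E over the background expectation (lambda = 1 elsewhere):
# S log(lambda) - (lambda - 1) E, with the S = 0 limit handled.
segment_gain <- function(S, E) {
  g <- numeric(length(S))
  pos <- E > 0
  lam <- ifelse(pos, S / pmax(E, .Machine$double.xmin), 1)
  nz <- pos & S > 0
  g[nz] <- S[nz] * log(lam[nz]) - (lam[nz] - 1) * E[nz]
  z <- pos & S == 0
  g[z] <- E[z]
  g
}

# Dynamic-programming optimal segmentation for one penalty value.
# Returns 1-based domain start bins (first is 1).
segment_dp <- function(cums, n, min_domain, penalty) {
  best <- c(0, rep(-Inf, n))  # best[j+1]: optimum for prefix of j bins
  back <- integer(n + 1L)
  for (j in seq_len(n)) {
    if (j < min_domain) next
    a <- seq_len(j - min_domain + 1L)           # segment starts (1-based)
    ss <- segment_sums(cums, a, rep(j, length(a)))
    cand <- best[a] + segment_gain(ss$S, ss$E) - penalty
    ok <- is.finite(cand)
    if (!any(ok)) next
    w <- which.max(ifelse(ok, cand, -Inf))
    best[j + 1L] <- cand[w]
    back[j + 1L] <- w
  }
  if (!is.finite(best[n + 1L])) stop("no feasible segmentation (matrix too small?)", call. = FALSE)
  starts <- integer(0)
  j <- n
  while (j > 0) {
    s <- back[j + 1L]
    starts <- c(s, starts)
    j <- s - 1L
  }
  starts
}

#' Detect chromosome interaction domains (CIDs)
#'
#' Change-point segmentation of a binned contact map. The matrix is first
#' balanced with a single ICE iteration; counts within a band of the
#' diagonal are modelled as Poisson with expectation `lambda_k * A * d^b`,
#' where `A * d^b` is the global power-law distance decay and `lambda_k` a
#' per-domain intensity multiplier (cells crossing a border keep
#' `lambda = 1`). The optimal set of borders maximizes the penalized
#' likelihood, with a BIC penalty `bic_multiplier * log(n_cells)` per
#' domain, via dynamic programming; the origin bin is treated as a border
#' (coordinates start at Ori on the circular genome). Each border's
#' confidence score in 1-10 is the number of penalty levels (10
#' geometrically spaced multipliers from the configured value up to 10x) at
#' which it persists in the optimal segmentation.
#'
#' @param matrix A raw (or filtered) `contact_matrix` at the configured
#'   resolution.
#' @param config A `segmentation_config`.
#' @return A `domain_segmentation`: list with `borders` (1-based domain
#'   start bins, first = 1), `confidence` (1-10 per border), `domains`
#'   tibble (`domain`, `start`, `end`, `size`, `density`), `n_bins`,
#'   `bin_size`, `blacklist`.
#' @export
detect_cids <- function(matrix, config = segmentation_config(bin_size = matrix$bin_size)) {
  n <- n_bins(matrix)
  if (n < 2 * config$min_domain) stop("matrix smaller than two minimum domains", call. = FALSE)
  norm <- ice_single_iteration(matrix)
  min_fit <- if (config$decay_fit == "beyond_band" &&
                 floor(n / 2) - config$band >= 3) config$band + 1L else 1L
  decay <- fit_distance_decay(norm, min_fit_distance = min_fit)
  d <- circular_distance_matrix(n)
  expected <- decay$A * ifelse(d == 0, 1, d^decay$b)
  cums <- segment_cumsums(norm$values, expected, norm$blacklist, config$band)
  usable <- !(seq_len(n) %in% norm$blacklist)
  n_cells <- sum(vapply(seq_len(min(config$band, n - 1L)), function(dd) {
    sum(usable[seq_len(n - dd)] & usable[seq_len(n - dd) + dd])
  }, 1))
  n_cells <- max(n_cells, 2)

  levels <- config$bic_multiplier * 10^(seq(0, 1, length.out = config$n_confidence_levels))
  seg_at <- lapply(levels, function(mult) {
    segment_dp(cums, n, config$min_domain, mult * log(n_cells))
  })
  borders <- seg_at[[1]]
  confidence <- vapply(borders, function(b) {
    sum(vapply(seg_at, function(s) b %in% s, TRUE))
  }, 1L)
  confidence <- pmin(pmax(confidence, 1L), config$n_confidence_levels)

  seg <- new_domain_segmentation(borders, confidence, n, config$bin_size, matrix$blacklist)
  seg$domains$density <- cid_density(norm, seg)$density
  seg
}

new_domain_segmentation <- function(borders, confidence, n_bins, bin_size,
                                    blacklist = integer()) {
  borders <- as.integer(borders)
  if (borders[1] != 1L || is.unsorted(borders, strictly = TRUE) || max(borders) > n_bins) {
    stop("invalid border set", call. = FALSE)
  }
  ends <- c(borders[-1] - 1L, n_bins)
  domains <- tibble::tibble(domain = seq_along(borders), start = borders, end = ends,
                            size = ends - borders + 1L, density = NA_real_)
  structure(list(borders = borders, confidence = as.integer(confidence),
                 domains = domains, n_bins = as.integer(n_bins),
                 bin_size = bin_size, blacklist = blacklist),
            class = "domain_segmentation")
}

#' Construct a domain segmentation from border positions
#'
#' @param borders 1-based domain start bins; bin 1 is added if absent.
#' @param n_bins Total bin count.
#' @param bin_size Bin size in bp.
#' @param confidence Optional per-border confidence (default 10).
#' @return A `domain_segmentation`.
#' @export
domain_segmentation <- function(borders, n_bins, bin_size = 3000, confidence = NULL) {
  borders <- sort(unique(as.integer(c(1L, borders))))
  if (is.null(confidence)) confidence <- rep(10L, length(borders))
  new_domain_segmentation(borders, confidence, n_bins, bin_size)
}

#' @export
print.domain_segmentation <- function(x, ...) {
  cat(sprintf("<domain_segmentation> %d domains over %d bins x %d bp; median size %.0f bins\n",
              nrow(x$domains), x$n_bins, as.integer(x$bin_size), stats::median(x$domains$size)))
  invisible(x)
}

#' Relative interaction density of each domain
#'
#' `density_k = sum of within-domain counts / sum of expected counts`, the
#' expectation being the genome-wide per-distance average, so a whole-genome
#' domain has density exactly 1 and a uniformly doubled block has density 2.
#'
#' @param matrix A `contact_matrix` sharing the segmentation's binning.
#' @param segmentation A `domain_segmentation`.
#' @return Tibble `domain`, `density`.
#' @export
cid_density <- function(matrix, segmentation) {
  n <- n_bins(matrix)
  if (n != segmentation$n_bins) stop("matrix and segmentation binning differ", call. = FALSE)
  d <- circular_distance_matrix(n)
  means <- numeric(max(d))
  for (k in seq_len(max(d))) means[k] <- mean(matrix$values[d == k])
  expected <- matrix(0, n, n)
  pos <- d > 0
  expected[pos] <- means[d[pos]]
  dens <- vapply(seq_len(nrow(segmentation$domains)), function(k) {
    bins <- segmentation$domains$start[k]:segmentation$domains$end[k]
    if (length(bins) < 2) stop("empty or single-bin domain", call. = FALSE)
    sub <- matrix$values[bins, bins]
    esub <- expected[bins, bins]
    ut <- upper.tri(sub)
    sum(sub[ut]) / sum(esub[ut])
  }, 1)
  tibble::tibble(domain = segmentation$domains$domain, density = dens)
}

match_circular <- function(b, targets, tolerance, n) {
  any(circular_distance(b, targets, n) <= tolerance)
}

#' Align domain borders across replicate segmentations
#'
#' Borders from different segmentations are grouped when within `tolerance`
#' bins of each other (circularly). The conservation score is the fraction
#' of borders matched in at least half of the segmentations; since a border
#' always matches its own segmentation, at least one other segmentation
#' must also match (so two unrelated segmentations score near the random
#' overlap rate rather than 1).
#'
#' @param segmentations List of >= 2 `domain_segmentation`s on one binning.
#' @param tolerance Matching tolerance in bins (default 1).
#' @return List with `table` (tibble: segmentation, border, n_matched,
#'   conserved) and `score`.
#' @export
align_borders <- function(segmentations, tolerance = 1L) {
  if (length(segmentations) < 2) stop("need at least 2 segmentations", call. = FALSE)
  n <- segmentations[[1]]$n_bins
  if (!all(vapply(segmentations, function(s) s$n_bins, 1L) == n)) {
    stop("segmentations have mixed binning", call. = FALSE)
  }
  k <- length(segmentations)
  tab <- purrr::map_dfr(seq_len(k), function(s) {
    purrr::map_dfr(segmentations[[s]]$borders, function(b) {
      nm <- sum(vapply(seq_len(k), function(o) {
        match_circular(b, segmentations[[o]]$borders, tolerance, n)
      }, TRUE))
      tibble::tibble(segmentation = s, border = b, n_matched = nm,
                     conserved = nm >= max(2, ceiling(k / 2)))
    })
  })
  list(table = tab, score = mean(tab$conserved))
}

#' Permutation test of border conservation across replicates
#'
#' The null keeps the number of borders per segmentation but places them at
#' random bins; the empirical p-value is the fraction of null conservation
#' scores at least as large as the observed one.
#'
#' @inheritParams align_borders
#' @param n_random Number of randomizations (>= 1).
#' @param seed RNG seed.
#' @return A `permutation_result` (see [permutation_feature_test()]).
#' @export
border_alignment_null_test <- function(segmentations, tolerance = 1L,
                                       n_random = 1000L, seed = 1L) {
  if (n_random < 1) stop("n_random must be >= 1", call. = FALSE)
  n <- segmentations[[1]]$n_bins
  bs <- segmentations[[1]]$bin_size
  observed <- align_borders(segmentations, tolerance)$score
  counts <- vapply(segmentations, function(s) length(s$borders), 1L)
  null_values <- with_seed(seed, {
    vapply(seq_len(n_random), function(r) {
      rand <- lapply(counts, function(m) {
        domain_segmentation(sample(2:n, m - 1L), n, bs)
      })
      align_borders(rand, tolerance)$score
    }, 1)
  })
  new_permutation_result(observed, null_values, side = "ge", seed = seed)
}

#' Compare two segmentations
#'
#' A domain is conserved when both of its borders (start and circularly
#' following start) match a border of the other segmentation within
#' `tolerance` bins.
#'
#' @param a,b `domain_segmentation`s on the same binning.
#' @param tolerance Matching tolerance in bins (default 1).
#' @return List with `n_conserved` (domains of `a` conserved in `b`) and a
#'   `summary` tibble (per segmentation: n_domains, median_size_bins,
#'   median_confidence).
#' @export
compare_segmentations <- function(a, b, tolerance = 1L) {
  if (a$n_bins != b$n_bins) stop("segmentations have mixed binning", call. = FALSE)
  n <- a$n_bins
  next_border <- function(s, k) {
    if (k < length(s$borders)) s$borders[k + 1L] else 1L  # circular wrap
  }
  conserved <- vapply(seq_along(a$borders), function(k) {
    match_circular(a$borders[k], b$borders, tolerance, n) &&
      match_circular(next_border(a, k), b$borders, tolerance, n)
  }, TRUE)
  summary <- tibble::tibble(
    segmentation = c("a", "b"),
    n_domains = c(nrow(a$domains), nrow(b$domains)),
    median_size_bins = c(stats::median(a$domains$size), stats::median(b$domains$size)),
    median_confidence = c(stats::median(a$confidence), stats::median(b$confidence))
  )
  list(n_conserved = sum(conserved), conserved = conserved, summary = summary)
}
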