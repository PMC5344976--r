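new_permutation_result <- function(observed, null_values, side, seed,
                                   warning_note = NULL) {
  p <- if (side == "ge") mean(null_values >= observed) else mean(null_values <= observed)
  structure(list(observed = observed, null_values = null_values, p_value = p,
                 side = side, n_permutations = length(null_values), seed = seed,
                 note = warning_note),
            class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf("<permutation_result> observed %.4g, p = %.4g (%s, %d permutations)\n",
              x$observed, x$p_value, x$side, x$n_permutations))
  invisible(x)
}

#' Border bin pairs of a segmentation
#'
#' Each domain border is defined by two bins: the last bin of the preceding
#' domain and the first bin of the following domain. On a circular genome
#' the origin border pairs the final bin with bin 1, so a segmentation with
#' `k` domains yields `k` borders and `2k` border bins.
#'
#' @param segmentation A `domain_segmentation`.
#' @return Tibble with `border`, `bin_before`, `bin_after`.
#' @export
border_bins <- function(segmentation) {
  n <- segmentation$n_bins
  starts <- segmentation$borders
  before <- ifelse(starts == 1L, n, starts - 1L)
  tibble::tibble(border = seq_along(starts), bin_before = as.integer(before),
                 bin_after = as.integer(starts))
}

#' Permutation test of a genomic feature at domain borders
#'
#' The observed statistic is the mean (or sum) of the track over the border
#' bins. Each permutation applies one uniform-random circular rotation to
#' the whole border set jointly, which conserves the number of domains and
#' every domain size exactly, and recomputes the statistic. The empirical
#' p-value is the fraction of null values at least as extreme as the
#' observed one on the requested side (no +1 correction by default).
#'
#' @param track Numeric per-bin feature track (length = number of bins).
#' @param segmentation A `domain_segmentation`.
#' @param n_perm Number of permutations (>= 100).
#' @param side `"ge"` for enrichment, `"le"` for depletion.
#' @param stat `"mean"` (default) or `"sum"` over border bins.
#' @param plus_one Use the (k+1)/(N+1) estimator (default `FALSE`).
#' @param exhaustive Enumerate all `n_bins` circular offsets instead of
#'   sampling (`n_perm` is then ignored).
#' @param seed RNG seed.
#' @return A `permutation_result`.
#' @export
permutation_feature_test <- function(track, segmentation, n_perm = 1000L,
                                     side = c("ge", "le"), stat = c("mean", "sum"),
                                     plus_one = FALSE, exhaustive = FALSE, seed = 1L) {
  side <- match.arg(side)
  stat <- match.arg(stat)
  n <- segmentation$n_bins
  if (length(track) != n) stop("track length must equal the bin count", call. = FALSE)
  if (!exhaustive && n_perm < 100) stop("need at least 100 permutations", call. = FALSE)
  f <- if (stat == "mean") mean else sum
  bb <- border_bins(segmentation)
  bins <- c(bb$bin_before, bb$bin_after)
  observed <- f(track[bins])
  null_values <- with_seed(seed, {
    offsets <- if (exhaustive) 0:(n - 1L) else sample.int(n, n_perm, replace = TRUE) - 1L
    vapply(offsets, function(off) f(track[(bins - 1L + off) %% n + 1L]), 1)
  })
  note <- NULL
  if (stats::sd(track) == 0) {
    note <- "constant track: every rotation reproduces the observed value"
    warning(note, call. = FALSE)
  }
  res <- new_permutation_result(observed, null_values, side, seed, note)
  if (plus_one) {
    k <- if (side == "ge") sum(null_values >= observed) else sum(null_values <= observed)
    res$p_value <- (k + 1) / (length(null_values) + 1)
  }
  res
}

#' Convergent and divergent gene-junction tracks
#'
#' Walks adjacent gene pairs in genomic order and classifies each junction:
#' convergent when the upstream gene is on `+` and the downstream on `-`
#' (transcription pointing together), divergent for `-` then `+`, and
#' co-directional otherwise. The bin containing the junction midpoint is
#' marked; overlapping genes are assigned the overlap midpoint.
#'
#' @param annotation A `genome_annotation` with >= 2 genes.
#' @param circular Include the wrap-around junction between the last and
#'   first gene (default: the annotation's circularity flag).
#' @return Tibble with per-bin `bin`, `convergent`, `divergent` counts.
#' @export
convergent_divergent_track <- function(annotation, circular = annotation$circular) {
  genes <- annotation$genes[order(annotation$genes$start), ]
  if (nrow(genes) < 2) stop("need at least 2 genes", call. = FALSE)
  n_genes <- nrow(genes)
  n_bins <- annotation$n_bins
  idx2 <- if (circular) c(seq_len(n_genes)[-1], 1L) else seq_len(n_genes)[-1]
  idx1 <- if (circular) seq_len(n_genes) else seq_len(n_genes - 1L)
  conv <- integer(n_bins); div <- integer(n_bins)
  overlap_note <- FALSE
  for (k in seq_along(idx1)) {
    g1 <- genes[idx1[k], ]; g2 <- genes[idx2[k], ]
    if (idx2[k] == 1L) {  # wrap-around junction
      midpoint <- ((g1$end + (g2$start + annotation$genome_length)) / 2) %% annotation$genome_length
    } else if (g2$start < g1$end) {
      overlap_note <- TRUE
      midpoint <- (max(g1$start, g2$start) + min(g1$end, g2$end)) / 2
    } else {
      midpoint <- (g1$end + g2$start) / 2
    }
    bin <- pmin(floor(midpoint / annotation$bin_size) + 1L, n_bins)
    if (g1$strand == "+" && g2$strand == "-") conv[bin] <- conv[bin] + 1L
    else if (g1$strand == "-" && g2$strand == "+") div[bin] <- div[bin] + 1L
  }
  if (overlap_note) message("overlapping gene pair(s): junction assigned to overlap midpoint")
  tibble::tibble(bin = seq_len(n_bins), convergent = conv, divergent = div)
}

#' Validated per-bin GC track from an annotation
#'
#' @param annotation A `genome_annotation` carrying a `gc_track`.
#' @return Numeric GC-fraction vector (one value per bin).
#' @export
gc_track_from_annotation <- function(annotation) {
  gc <- annotation$gc_track
  if (is.null(gc)) stop("annotation carries no GC track", call. = FALSE)
  if (length(gc) != annotation$n_bins) stop("GC track length mismatch", call. = FALSE)
  if (any(gc < 0 | gc > 1)) stop("GC fractions must lie in [0, 1]", call. = FALSE)
  gc
}
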