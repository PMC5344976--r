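#' Contact matrix container
#'
#' A `contact_matrix` wraps a symmetric, non-negative matrix of binned
#' chromosome contact counts (or balanced scores) on a circular genome,
#' together with the bin size, a blacklist of unusable bins and the
#' processing state (`"raw"`, `"filtered"` or `"normalized"`).
#'
#' Bin indices are 1-based in all R interfaces; the underlying genomic
#' intervals are half-open `[ (k-1)*bin_size, k*bin_size )` with the final
#' partial bin kept, so a 816,394 bp genome at 10 kb yields 82 bins.
#'
#' @param values Symmetric numeric matrix of non-negative values.
#' @param bin_size Bin width in base pairs.
#' @param blacklist Integer vector of 1-based bin indices excluded from
#'   normalization and statistics.
#' @param state Processing state string.
#' @param total_reads Total raw counts behind the matrix (defaults to
#'   `sum(values)` when the matrix is raw).
#' @return An object of class `contact_matrix`.
#' @export
contact_matrix <- function(values, bin_size, blacklist = integer(),
                           state = c("raw", "filtered", "normalized"),
                           total_reads = NULL) {
  state <- match.arg(state)
  values <- as.matrix(values)
  if (nrow(values) != ncol(values)) stop("contact matrix must be square", call. = FALSE)
  if (any(values < 0, na.rm = TRUE)) stop("contact values must be non-negative", call. = FALSE)
  if (max(abs(values - t(values))) > 1e-8 * max(1, max(abs(values)))) {
    stop("contact matrix must be symmetric", call. = FALSE)
  }
  values <- (values + t(values)) / 2  # enforce exact symmetry
  blacklist <- sort(unique(as.integer(blacklist)))
  if (length(blacklist) && (min(blacklist) < 1L || max(blacklist) > nrow(values))) {
    stop("blacklist indices out of range", call. = FALSE)
  }
  if (is.null(total_reads)) total_reads <- sum(values)
  structure(
    list(values = values, bin_size = as.numeric(bin_size), blacklist = blacklist,
         state = state, total_reads = total_reads),
    class = "contact_matrix"
  )
}

#' @export
print.contact_matrix <- function(x, ...) {
  cat(sprintf("<contact_matrix> %d bins x %d bp (%s), %d blacklisted, total %.4g\n",
              n_bins(x), x$bin_size, x$state, length(x$blacklist), sum(x$values)))
  invisible(x)
}

#' Number of bins of a contact matrix
#' @param x A `contact_matrix`.
#' @return Integer bin count.
#' @export
n_bins <- function(x) nrow(x$values)

usable_bins <- function(x) setdiff(seq_len(n_bins(x)), x$blacklist)

#' Pool fragment-level contacts into genomic bins
#'
#' Divides a circular genome into fixed-width bins (the last, possibly
#' partial, bin is kept) and pools contact records symmetrically. Total
#' counts are conserved exactly.
#'
#' @param contacts Data frame with columns `pos_i`, `pos_j` (0-based bp in
#'   `[0, genome_length)`) and `count`.
#' @param genome_length Genome length in bp.
#' @param bin_size Bin width in bp.
#' @return A raw `contact_matrix` with `ceiling(genome_length / bin_size)` bins.
#' @export
bin_contacts <- function(contacts, genome_length, bin_size) {
  stopifnot_scalar(genome_length, "genome_length", positive = TRUE)
  stopifnot_scalar(bin_size, "bin_size", positive = TRUE)
  contacts <- tibble::as_tibble(contacts)
  if (!all(c("pos_i", "pos_j", "count") %in% names(contacts))) {
    stop("`contacts` needs columns pos_i, pos_j, count", call. = FALSE)
  }
  bad <- which(contacts$pos_i < 0 | contacts$pos_i >= genome_length |
               contacts$pos_j < 0 | contacts$pos_j >= genome_length)
  if (length(bad)) {
    stop(sprintf("contact record %d has a position outside [0, %d)",
                 bad[1], as.integer(genome_length)), call. = FALSE)
  }
  n <- as.integer(ceiling(genome_length / bin_size))
  bi <- pmin(floor(contacts$pos_i / bin_size) + 1L, n)
  bj <- pmin(floor(contacts$pos_j / bin_size) + 1L, n)
  m <- matrix(0, n, n)
  for (k in seq_along(bi)) {
    i <- bi[k]; j <- bj[k]; cnt <- contacts$count[k]
    if (i == j) m[i, i] <- m[i, i] + cnt
    else { m[i, j] <- m[i, j] + cnt; m[j, i] <- m[j, i] + cnt }
  }
  contact_matrix(m, bin_size, state = "raw")
}

#' Classify read pairs as valid, non-ligation or self-ligation products
#'
#' Standard Hi-C library triage on the restriction-fragment digest: pairs
#' with both ends on the same fragment and outward-facing (or identical)
#' orientation are circularised self-ligation products; pairs on the same or
#' circularly adjacent fragments with inward-facing orientation are
#' non-ligation (dangling/re-ligation) products; everything else is a valid
#' Hi-C product. Only valid pairs should be binned.
#'
#' @param pairs Data frame with columns `fragment_i`, `fragment_j` (1-based
#'   fragment indices) and `strand_i`, `strand_j` (`"+"`/`"-"`).
#' @param n_fragments Number of fragments in the (circular) digest map.
#' @return The input tibble with an added `class` factor column.
#' @export
classify_pairs <- function(pairs, n_fragments) {
  pairs <- tibble::as_tibble(pairs)
  req <- c("fragment_i", "fragment_j", "strand_i", "strand_j")
  if (!all(req %in% names(pairs))) stop("`pairs` needs fragment/strand columns", call. = FALSE)
  if (any(pairs$fragment_i < 1 | pairs$fragment_i > n_fragments |
          pairs$fragment_j < 1 | pairs$fragment_j > n_fragments)) {
    stop("fragment index outside the digest map", call. = FALSE)
  }
  lo <- pmin(pairs$fragment_i, pairs$fragment_j)
  hi <- pmax(pairs$fragment_i, pairs$fragment_j)
  strand_lo <- ifelse(pairs$fragment_i <= pairs$fragment_j, pairs$strand_i, pairs$strand_j)
  strand_hi <- ifelse(pairs$fragment_i <= pairs$fragment_j, pairs$strand_j, pairs$strand_i)
  same <- lo == hi
  adjacent_lin <- (hi - lo) == 1L
  adjacent_wrap <- (hi - lo) == (n_fragments - 1L)
  inward <- strand_lo == "+" & strand_hi == "-"
  # across the origin the genomic order is hi -> lo, so orientations swap
  inward_wrap <- strand_hi == "+" & strand_lo == "-"
  cls <- rep("valid", nrow(pairs))
  cls[((same | adjacent_lin) & inward) | (adjacent_wrap & inward_wrap)] <- "non_ligation"
  cls[same & !inward] <- "self_ligation"
  pairs$class <- factor(cls, levels = c("valid", "non_ligation", "self_ligation"))
  pairs
}

# Threshold above which a control entry "supports" removal of a cell.
control_threshold <- function(control, quantile) {
  n <- n_bins(control)
  d <- circular_distance_matrix(n)
  off <- control$values[d >= 2]
  stats::quantile(off, quantile, names = FALSE)
}

#' Filter artefact contacts using an unfixed control library
#'
#' Among a supplied set of affected bins, cells at circular distance >= 2
#' whose (depth-normalized) control signal exceeds a high quantile of the
#' control's off-diagonal values are zeroed: such contacts are present
#' without cross-linking and are not 3D contacts. The main diagonal and the
#' first off-diagonal are never touched. Entries are never increased.
#'
#' @param matrix,control `contact_matrix` objects with identical shape.
#' @param affected_bins Integer vector of 1-based bins suspected of artefacts.
#' @param quantile Control off-diagonal quantile defining "supported" (default 0.99).
#' @return Filtered `contact_matrix`; the removed cells and the removed cell
#'   fraction are attached as attributes `removed` and `removed_fraction`.
#' @export
filter_with_control <- function(matrix, control, affected_bins, quantile = 0.99) {
  if (n_bins(matrix) != n_bins(control) || matrix$bin_size != control$bin_size) {
    stop("matrix and control must share shape and bin size", call. = FALSE)
  }
  n <- n_bins(matrix)
  affected_bins <- unique(as.integer(affected_bins))
  m <- matrix$values
  removed <- tibble::tibble(bin_i = integer(), bin_j = integer(), value = numeric())
  if (length(affected_bins)) {
    ctrl <- control$values / sum(control$values)
    thr <- control_threshold(contact_matrix(ctrl, control$bin_size), quantile)
    d <- circular_distance_matrix(n)
    cand <- expand.grid(i = affected_bins, j = affected_bins)
    cand <- cand[cand$i < cand$j, , drop = FALSE]
    for (r in seq_len(nrow(cand))) {
      i <- cand$i[r]; j <- cand$j[r]
      if (d[i, j] >= 2 && ctrl[i, j] > thr && m[i, j] > 0) {
        removed <- dplyr::bind_rows(removed,
          tibble::tibble(bin_i = i, bin_j = j, value = m[i, j]))
        m[i, j] <- 0; m[j, i] <- 0
      }
    }
  }
  out <- contact_matrix(m, matrix$bin_size, matrix$blacklist, state = "filtered",
                        total_reads = matrix$total_reads)
  attr(out, "removed") <- removed
  attr(out, "removed_fraction") <- 2 * nrow(removed) / (n * n)
  out
}

#' Iterative correction (ICE) of a contact matrix
#'
#' Balances per-bin visibility by repeating the update
#' `m_ij <- m_ij * total / (rowsum_i * rowsum_j)` on the whole matrix until
#' the maximum relative error of the per-bin totals (over non-blacklisted
#' bins) drops below `tolerance` (default `1e-5`). Bins with zero total are
#' auto-blacklisted with a warning (or raise an error). After convergence the
#' matrix is rescaled so the mean non-blacklisted entry is 1, which leaves
#' the balance untouched and makes magnitudes comparable across libraries.
#'
#' @param matrix A `contact_matrix`.
#' @param tolerance Relative-error convergence threshold.
#' @param max_iter Iteration cap; non-convergence warns with the residual.
#' @param on_zero_bin `"blacklist"` (default) or `"error"`.
#' @param rescale Rescale converged entries to mean 1 (default `TRUE`).
#' @return Normalized `contact_matrix` (state `"normalized"`), with the
#'   number of iterations in attribute `iterations`.
#' @export
ice_normalize <- function(matrix, tolerance = 1e-5, max_iter = 2000L,
                          on_zero_bin = c("blacklist", "error"), rescale = TRUE) {
  on_zero_bin <- match.arg(on_zero_bin)
  blacklist <- matrix$blacklist
  m <- matrix$values
  keep <- setdiff(seq_len(nrow(m)), blacklist)
  zero <- keep[rowSums(m[keep, keep, drop = FALSE]) == 0]
  if (length(zero)) {
    if (on_zero_bin == "error") stop("bin(s) with zero total: ", paste(zero, collapse = ", "), call. = FALSE)
    warning("auto-blacklisting zero-total bin(s): ", paste(zero, collapse = ", "), call. = FALSE)
    blacklist <- sort(union(blacklist, zero))
    keep <- setdiff(seq_len(nrow(m)), blacklist)
  }
  if (length(keep) < 2) stop("need at least 2 non-blacklisted bins with positive totals", call. = FALSE)
  w <- m[keep, keep, drop = FALSE]
  iter <- 0L
  repeat {
    rs <- rowSums(w)
    rel <- max(abs(rs - mean(rs)) / mean(rs))
    if (rel < tolerance || iter >= max_iter) break
    total <- sum(w)
    w <- w * total / outer(rs, rs)
    iter <- iter + 1L
  }
  if (rel >= tolerance) {
    warning(sprintf("ICE did not converge in %d iterations (residual %.3g)", max_iter, rel),
            call. = FALSE)
  }
  if (rescale) w <- w / mean(w)
  out <- matrix$values * 0
  out[keep, keep] <- w
  res <- contact_matrix(out, matrix$bin_size, blacklist, state = "normalized",
                        total_reads = matrix$total_reads)
  attr(res, "iterations") <- iter
  attr(res, "residual") <- rel
  res
}

# One cycle of the ICE update (used by domain detection, which normalizes
# with a single iteration only).
ice_single_iteration <- function(matrix) {
  suppressWarnings(ice_normalize(matrix, tolerance = 0, max_iter = 1L, rescale = FALSE))
}

#' Depth-normalized sum of replicate contact matrices
#'
#' Each replicate is divided by its own total counts before summation, so
#' deep and shallow libraries contribute equally.
#'
#' @param matrices List of `contact_matrix` objects of identical shape.
#' @return A `contact_matrix` of summed depth-normalized values.
#' @export
sum_replicates <- function(matrices) {
  if (!length(matrices)) stop("empty replicate list", call. = FALSE)
  n <- n_bins(matrices[[1]])
  if (!all(vapply(matrices, n_bins, 1L) == n)) stop("replicates differ in shape", call. = FALSE)
  vals <- Reduce(`+`, lapply(matrices, function(m) m$values / sum(m$values)))
  blk <- sort(unique(unlist(lapply(matrices, function(m) m$blacklist))))
  contact_matrix(vals, matrices[[1]]$bin_size, blk, state = matrices[[1]]$state,
                 total_reads = sum(vapply(matrices, function(m) m$total_reads, 1)))
}

#' Row-by-row Pearson correlation between two contact matrices
#'
#' Both matrices are unrolled row by row into vectors (bins blacklisted in
#' either matrix are dropped pairwise) and a single Pearson coefficient is
#' returned. Used to assess replicate reproducibility.
#'
#' @param a,b `contact_matrix` objects of identical shape.
#' @return Pearson correlation coefficient in `[-1, 1]`.
#' @export
replicate_correlation <- function(a, b) {
  if (n_bins(a) != n_bins(b)) stop("matrices differ in shape", call. = FALSE)
  drop <- union(a$blacklist, b$blacklist)
  keep <- setdiff(seq_len(n_bins(a)), drop)
  va <- as.vector(t(a$values[keep, keep, drop = FALSE]))
  vb <- as.vector(t(b$values[keep, keep, drop = FALSE]))
  if (stats::sd(va) == 0 || stats::sd(vb) == 0) {
    stop("correlation undefined: zero variance", call. = FALSE)
  }
  stats::cor(va, vb)
}

#' Matrix modelling potential (MMP) score
#'
#' A 0-1 index of how suitable a balanced contact matrix is for accurate 3D
#' model reconstruction. It combines (i) matrix size, (ii) the contribution
#' of eigenvectors whose eigenvalues exceed those of randomized (entry-
#' shuffled) matrices, and (iii) the skewness and kurtosis of the z-scores of
#' the log-transformed non-zero entries. The components are combined by a
#' configurable linear map squashed to (0, 1); shuffling preserves the entry
#' distribution and the size, so paired structured-vs-shuffled comparisons
#' isolate the eigenvector structure.
#'
#' @param matrix A normalized `contact_matrix` with at least 8 bins.
#' @param n_randomizations Number of shuffled matrices for the eigenvalue
#'   null (default 20).
#' @param seed RNG seed for the shuffles.
#' @param weights Named numeric vector of combination coefficients
#'   (`intercept`, `size`, `eigen`, `skewness`, `kurtosis`).
#' @return A one-row tibble (`mmp_report`) with the score and components.
#' @export
mmp_score <- function(matrix, n_randomizations = 20L, seed = 1L,
                      weights = c(intercept = 0, size = 1, eigen = 4,
                                  skewness = -0.5, kurtosis = -0.25)) {
  n <- n_bins(matrix)
  if (n < 8) stop("matrix too small for MMP scoring (< 8 bins)", call. = FALSE)
  keep <- usable_bins(matrix)
  m <- matrix$values[keep, keep, drop = FALSE]
  nz <- m[upper.tri(m)][m[upper.tri(m)] > 0]
  z <- (log10(nz) - mean(log10(nz))) / stats::sd(log10(nz))
  skw <- moment_skewness(z)
  krt <- moment_kurtosis(z)
  size_term <- 1 - exp(-nrow(m) / 100)

  ev_obs <- sort(abs(eigen(m, symmetric = TRUE, only.values = TRUE)$values), decreasing = TRUE)
  null_ev <- with_seed(seed, {
    vapply(seq_len(n_randomizations), function(k) {
      s <- m
      ut <- upper.tri(s)
      s[ut] <- sample(s[ut])
      s[lower.tri(s)] <- t(s)[lower.tri(s)]
      sort(abs(eigen(s, symmetric = TRUE, only.values = TRUE)$values), decreasing = TRUE)
    }, numeric(nrow(m)))
  })
  thr <- apply(null_ev, 1, stats::quantile, 0.95)
  sig <- ev_obs > thr
  eigen_term <- sum(ev_obs[sig]^2) / sum(ev_obs^2)

  lin <- weights[["intercept"]] + weights[["size"]] * size_term +
    weights[["eigen"]] * eigen_term + weights[["skewness"]] * abs(skw) +
    weights[["kurtosis"]] * abs(krt)
  score <- stats::plogis(lin)
  out <- tibble::tibble(
    mmp_score = score, size_term = size_term, eigenvector_term = eigen_term,
    skewness_term = skw, kurtosis_term = krt, n_significant_eigenvectors = sum(sig),
    predicted_accuracy = 0.9 * score  # heuristic correlation-scale mapping
  )
  class(out) <- c("mmp_report", class(out))
  out
}
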