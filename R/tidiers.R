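#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a contact matrix into a triplet tibble
#'
#' @param x A `contact_matrix`.
#' @param keep_zeros Include zero cells (default `FALSE`).
#' @param ... Unused.
#' @return Tibble with `bin_i`, `bin_j` (upper triangle incl. diagonal),
#'   `value` and circular `distance`.
#' @method tidy contact_matrix
#' @export
tidy.contact_matrix <- function(x, keep_zeros = FALSE, ...) {
  m <- x$values
  sel <- upper.tri(m, diag = TRUE)
  if (!keep_zeros) sel <- sel & m != 0
  idx <- which(sel, arr.ind = TRUE)
  tibble::tibble(bin_i = idx[, 1], bin_j = idx[, 2], value = m[idx],
                 distance = circular_distance(idx[, 1], idx[, 2], n_bins(x)))
}

#' @rdname tidy.contact_matrix
#' @method glance contact_matrix
#' @export
glance.contact_matrix <- function(x, ...) {
  tibble::tibble(n_bins = n_bins(x), bin_size = x$bin_size, state = x$state,
                 n_blacklisted = length(x$blacklist), total = sum(x$values),
                 total_reads = x$total_reads)
}

#' Tidy a domain segmentation
#'
#' @param x A `domain_segmentation`.
#' @param ... Unused.
#' @return The domain tibble with bp coordinates and border confidence.
#' @method tidy domain_segmentation
#' @export
tidy.domain_segmentation <- function(x, ...) {
  dplyr::mutate(x$domains,
                start_bp = (.data$start - 1L) * x$bin_size,
                end_bp = .data$end * x$bin_size,
                confidence = x$confidence)
}

#' @rdname tidy.domain_segmentation
#' @method glance domain_segmentation
#' @export
glance.domain_segmentation <- function(x, ...) {
  tibble::tibble(n_domains = nrow(x$domains),
                 median_size_bins = stats::median(x$domains$size),
                 median_size_bp = stats::median(x$domains$size) * x$bin_size,
                 median_confidence = stats::median(x$confidence),
                 median_density = stats::median(x$domains$density))
}

#' Tidy a model ensemble into long coordinates
#'
#' @param x A `model_ensemble`.
#' @param ... Unused.
#' @return Tibble `model`, `particle`, `x`, `y`, `z` (nm).
#' @method tidy model_ensemble
#' @export
tidy.model_ensemble <- function(x, ...) {
  purrr::map_dfr(seq_along(x$coords), function(m) {
    xm <- x$coords[[m]]
    tibble::tibble(model = m, particle = seq_len(nrow(xm)),
                   x = xm[, 1], y = xm[, 2], z = xm[, 3])
  })
}

#' @rdname tidy.model_ensemble
#' @method glance model_ensemble
#' @export
glance.model_ensemble <- function(x, ...) {
  g <- ensemble_geometry(x)
  med <- attr(g, "medians")
  tibble::tibble(n_models = length(x$coords), n_particles = nrow(x$coords[[1]]),
                 median_penalty = stats::median(x$penalty),
                 n_clusters = if (is.null(x$cluster)) NA_integer_ else length(unique(x$cluster)),
                 median_length_nm = med[["length_nm"]],
                 median_width_nm = med[["width_nm"]],
                 median_volume_um3 = med[["volume_um3"]])
}

#' Tidy a permutation result
#'
#' @param x A `permutation_result`.
#' @param ... Unused.
#' @return Tibble of the null values.
#' @method tidy permutation_result
#' @export
tidy.permutation_result <- function(x, ...) {
  tibble::tibble(permutation = seq_along(x$null_values), value = x$null_values)
}

#' @rdname tidy.permutation_result
#' @method glance permutation_result
#' @export
glance.permutation_result <- function(x, ...) {
  tibble::tibble(observed = x$observed, p_value = x$p_value, side = x$side,
                 n_permutations = x$n_permutations,
                 null_mean = mean(x$null_values), null_sd = stats::sd(x$null_values))
}

#' Tidy a co-expression matrix into gene pairs
#'
#' @param x A `coexpression_matrix`.
#' @param ... Unused.
#' @return Tibble `gene_a`, `gene_b`, `value` (upper triangle).
#' @method tidy coexpression_matrix
#' @export
tidy.coexpression_matrix <- function(x, ...) {
  idx <- which(upper.tri(x$values), arr.ind = TRUE)
  tibble::tibble(gene_a = x$genes[idx[, 1]], gene_b = x$genes[idx[, 2]],
                 value = x$values[idx])
}

#' @rdname tidy.coexpression_matrix
#' @method glance coexpression_matrix
#' @export
glance.coexpression_matrix <- function(x, ...) {
  ut <- x$values[upper.tri(x$values)]
  tibble::tibble(n_genes = nrow(x$values), method = x$method,
                 mean_abs = mean(abs(ut)), median = stats::median(ut))
}
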