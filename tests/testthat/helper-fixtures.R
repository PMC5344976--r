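# Shared fixture builders; everything is generated in code.

toy_truth <- function(borders = c(11L, 21L), boost = 3, ...) {
  planted_truth(borders, decay_exponent = -1, domain_boost = boost, ...)
}

# a minimal annotation object without the generator (for junction tests)
manual_annotation <- function(genes, genome_length = 60000, bin_size = 3000,
                              circular = TRUE) {
  n_bins <- as.integer(ceiling(genome_length / bin_size))
  structure(list(genome_length = genome_length, circular = circular,
                 bin_size = bin_size, n_bins = n_bins,
                 genes = tibble::tibble(start = genes$start, end = genes$end,
                                        strand = genes$strand),
                 gc_track = rep(0.4, n_bins), site_track = rep(5L, n_bins)),
            class = "genome_annotation")
}

# independent slow oracle for the tendency statistic
tendency_oracle <- function(g, h) {
  m <- length(g)
  conc <- 0L; disc <- 0L
  for (s in 1:(m - 1)) for (t in (s + 1):m) {
    p <- (g[s] - g[t]) * (h[s] - h[t])
    if (p > 0) conc <- conc + 1L else if (p < 0) disc <- disc + 1L
  }
  (conc - disc) / (m * (m - 1) / 2)
}

# independent brute-force iteration of the printed ICE update
ice_oracle <- function(m, tolerance = 1e-5, max_iter = 5000) {
  repeat {
    rs <- rowSums(m)
    if (max(abs(rs - mean(rs)) / mean(rs)) < tolerance || max_iter <= 0) break
    m <- m * sum(m) / outer(rs, rs)
    max_iter <- max_iter - 1
  }
  m
}

random_symmetric_counts <- function(n, seed, lambda = 20) {
  set.seed(seed)
  x <- matrix(0, n, n)
  ut <- upper.tri(x, diag = TRUE)
  x[ut] <- rpois(sum(ut), lambda) + 1
  x[lower.tri(x)] <- t(x)[lower.tri(x)]
  x
}
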