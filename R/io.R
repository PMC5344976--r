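# Plain-text readers/writers for the pipeline's standard formats.

#' Write and read contact matrices as TSV
#'
#' Dense format: a square tab-separated numeric matrix, no headers.
#' Triplet format: three columns `bin_i`, `bin_j`, `value` (upper triangle
#' plus diagonal, 1-based).
#'
#' @param matrix A `contact_matrix`.
#' @param path Output file.
#' @return `write_*` return `path` invisibly; `read_*` return a
#'   `contact_matrix`.
#' @name matrix_io
NULL

#' @rdname matrix_io
#' @export
write_dense_matrix <- function(matrix, path) {
  utils::write.table(matrix$values, path, sep = "\t", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' @rdname matrix_io
#' @param bin_size,state,blacklist Metadata for the reconstructed object.
#' @export
read_dense_matrix <- function(path, bin_size, state = "raw", blacklist = integer()) {
  m <- as.matrix(utils::read.table(path, sep = "\t", header = FALSE))
  dimnames(m) <- NULL
  contact_matrix(m, bin_size, blacklist, state = state)
}

#' @rdname matrix_io
#' @export
write_triplet_matrix <- function(matrix, path) {
  m <- matrix$values
  sel <- which(upper.tri(m, diag = TRUE) & m != 0, arr.ind = TRUE)
  df <- data.frame(bin_i = sel[, 1], bin_j = sel[, 2], value = m[sel])
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname matrix_io
#' @param n_bins Number of bins of the reconstructed matrix.
#' @export
read_triplet_matrix <- function(path, n_bins, bin_size, state = "raw",
                                blacklist = integer()) {
  df <- utils::read.table(path, sep = "\t", header = TRUE)
  m <- matrix(0, n_bins, n_bins)
  m[cbind(df$bin_i, df$bin_j)] <- df$value
  m[cbind(df$bin_j, df$bin_i)] <- df$value
  contact_matrix(m, bin_size, blacklist, state = state)
}

#' Write a segmentation as BED
#'
#' One record per domain, 0-based half-open bp coordinates; the score column
#' is 100 x the smaller confidence of the domain's two borders.
#'
#' @param segmentation A `domain_segmentation`.
#' @param path Output file.
#' @param chrom Chromosome name (default `"chr"`).
#' @return `path`, invisibly.
#' @export
write_segmentation_bed <- function(segmentation, path, chrom = "chr") {
  d <- segmentation$domains
  conf <- segmentation$confidence
  conf_next <- c(conf[-1], conf[1])
  df <- data.frame(
    chrom = chrom,
    start = (d$start - 1L) * segmentation$bin_size,
    end = d$end * segmentation$bin_size,
    name = sprintf("CID%d", d$domain),
    score = 100L * pmin(conf, conf_next)
  )
  utils::write.table(df, path, sep = "\t", row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Write a per-bin track as BEDGRAPH
#'
#' @param track Numeric per-bin values.
#' @param bin_size Bin width in bp.
#' @param path Output file.
#' @param chrom Chromosome name.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(track, bin_size, path, chrom = "chr") {
  df <- data.frame(chrom = chrom, start = (seq_along(track) - 1L) * bin_size,
                   end = seq_along(track) * bin_size, value = track)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Read a BEDGRAPH track into a per-bin vector
#'
#' @param path BEDGRAPH file (0-based half-open, constant bin width).
#' @return Numeric vector of per-bin values.
#' @export
read_bedgraph <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE)
  df[[4]][order(df[[2]])]
}

#' Write a model ensemble in XYZ format
#'
#' One file per model would be wasteful for big ensembles; the manifest
#' format used here stacks records `model particle genomic_start x y z`
#' (coordinates in nm, genomic start in bp).
#'
#' @param ensemble A `model_ensemble`.
#' @param path Output file.
#' @param bin_size Bin size in bp for the genomic-start column.
#' @return `path`, invisibly.
#' @export
write_models_xyz <- function(ensemble, path, bin_size = 10000) {
  rows <- purrr::map_dfr(seq_along(ensemble$coords), function(m) {
    x <- ensemble$coords[[m]]
    data.frame(model = m, particle = seq_len(nrow(x)),
               genomic_start = (seq_len(nrow(x)) - 1L) * bin_size,
               x = x[, 1], y = x[, 2], z = x[, 3])
  })
  utils::write.table(rows, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write/read an expression matrix as TSV
#'
#' Genes x samples with gene ids in the first column; the gene midpoint
#' coordinates (bp), when present, travel in a `.coords.tsv` sidecar.
#'
#' @param expr Genes x samples matrix (optionally with attribute `midpoint`).
#' @param path Output file.
#' @return `path` / the matrix.
#' @export
write_expression_tsv <- function(expr, path) {
  df <- data.frame(gene = rownames(expr), expr, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  mid <- attr(expr, "midpoint")
  if (!is.null(mid)) {
    utils::write.table(data.frame(gene = rownames(expr), midpoint = mid),
                       paste0(path, ".coords.tsv"), sep = "\t",
                       row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' @rdname write_expression_tsv
#' @export
read_expression_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  sidecar <- paste0(path, ".coords.tsv")
  if (file.exists(sidecar)) {
    co <- utils::read.table(sidecar, sep = "\t", header = TRUE)
    attr(m, "midpoint") <- co$midpoint[match(rownames(m), co$gene)]
  }
  m
}
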