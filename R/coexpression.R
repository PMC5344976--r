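new_coexpression_matrix <- function(values, method, midpoints = NULL) {
  structure(list(values = values, method = method, midpoints = midpoints,
                 genes = rownames(values)),
            class = "coexpression_matrix")
}

#' @export
print.coexpression_matrix <- function(x, ...) {
  cat(sprintf("<coexpression_matrix> %d genes (%s)\n", nrow(x$values), x$method))
  invisible(x)
}

collapse_expr <- function(expr, conditions) {
  if (is.null(conditions)) conditions <- attr(expr, "condition")
  if (is.null(conditions)) stop("no condition labels to collapse over", call. = FALSE)
  out <- vapply(split(seq_len(ncol(expr)), conditions),
                function(cols) rowMeans(expr[, cols, drop = FALSE]),
                numeric(nrow(expr)))
  attr(out, "midpoint") <- attr(expr, "midpoint")
  out
}

#' Co-expression tendency matrix
#'
#' For each gene pair, counts the sample pairs in which the two genes change
#' in the same direction (concordant) versus opposite directions
#' (discordant) and returns `(concordant - discordant) / total sample
#' pairs`, a concordance statistic in `[-1, 1]` that highlights basal
#' co-regulation irrespective of large expression shifts. Ties count to
#' neither side but remain in the denominator. Runs over the sample columns
#' as given; set `collapse_replicates = TRUE` to average replicate samples
#' per condition first.
#'
#' @param expr Genes x samples numeric matrix (>= 2 genes, >= 2 samples);
#'   gene midpoints (bp) may be attached as attribute `midpoint`.
#' @param collapse_replicates Average replicates per condition first.
#' @param conditions Condition labels per column (defaults to the matrix's
#'   `condition` attribute) when collapsing.
#' @return A `coexpression_matrix` (method `"tendency"`).
#' @export
coexpression_tendency <- function(expr, collapse_replicates = FALSE, conditions = NULL) {
  if (nrow(expr) < 2 || ncol(expr) < 2) stop("need >= 2 genes and >= 2 samples", call. = FALSE)
  mid <- attr(expr, "midpoint")
  if (collapse_replicates) expr <- collapse_expr(expr, conditions)
  flat <- apply(expr, 1, stats::sd) == 0
  if (any(flat)) message(sum(flat), " constant gene(s): tendency 0 against all genes")
  v <- .tendency_matrix(unname(as.matrix(expr)))
  dimnames(v) <- list(rownames(expr), rownames(expr))
  new_coexpression_matrix(v, "tendency", mid)
}

#' Pearson co-expression matrix
#'
#' @inheritParams coexpression_tendency
#' @return A `coexpression_matrix` (method `"pearson"`); zero-variance genes
#'   get 0 against all others with a note.
#' @export
pearson_coexpression <- function(expr, collapse_replicates = FALSE, conditions = NULL) {
  if (nrow(expr) < 2 || ncol(expr) < 2) stop("need >= 2 genes and >= 2 samples", call. = FALSE)
  mid <- attr(expr, "midpoint")
  if (collapse_replicates) expr <- collapse_expr(expr, conditions)
  flat <- apply(expr, 1, stats::sd) == 0
  if (any(flat)) message(sum(flat), " zero-variance gene(s): correlation set to 0")
  v <- suppressWarnings(stats::cor(t(expr)))
  v[!is.finite(v)] <- 0
  diag(v) <- 1
  new_coexpression_matrix(v, "pearson", mid)
}

# Domain id per gene from its midpoint bin.
gene_domains <- function(coexpr, segmentation) {
  if (is.null(coexpr$midpoints)) stop("co-expression matrix lacks gene midpoints", call. = FALSE)
  gene_bin <- pmin(floor(coexpr$midpoints / segmentation$bin_size) + 1L, segmentation$n_bins)
  list(bin = gene_bin,
       domain = findInterval(gene_bin, segmentation$borders))
}

#' Within- versus between-domain co-expression
#'
#' Splits all gene pairs into within-domain (both genes in the same domain
#' by midpoint bin) and between-domain pairs, compares the absolute
#' co-expression of the two sets (Mann-Whitney rank-sum and Welch t-test),
#' and reports the per-domain mean absolute within- and between-domain
#' co-expression.
#'
#' @param coexpr A `coexpression_matrix` with gene midpoints.
#' @param segmentation A `domain_segmentation`.
#' @return List with `global` (one-row tibble: mean_within, mean_between,
#'   p_wilcox, p_ttest, n_within, n_between) and `per_domain` (tibble;
#'   domains with < 2 genes are dropped with a note).
#' @export
within_between_domains <- function(coexpr, segmentation) {
  gd <- gene_domains(coexpr, segmentation)
  v <- coexpr$values
  ng <- nrow(v)
  pair <- which(upper.tri(v), arr.ind = TRUE)
  same <- gd$domain[pair[, 1]] == gd$domain[pair[, 2]]
  av <- abs(v[upper.tri(v)])
  w <- av[same]; b <- av[!same]
  if (!length(w) || !length(b)) stop("need both within- and between-domain pairs", call. = FALSE)
  global <- tibble::tibble(
    mean_within = mean(w), mean_between = mean(b),
    p_wilcox = stats::wilcox.test(w, b, alternative = "greater")$p.value,
    p_ttest = stats::t.test(w, b, alternative = "greater")$p.value,
    n_within = length(w), n_between = length(b)
  )
  doms <- sort(unique(gd$domain))
  per_domain <- purrr::map_dfr(doms, function(k) {
    in_k <- gd$domain == k
    if (sum(in_k) < 2) return(NULL)
    wk <- same & in_k[pair[, 1]]  # both genes in k
    bk <- !same & (in_k[pair[, 1]] | in_k[pair[, 2]])
    tibble::tibble(domain = k, n_genes = sum(in_k),
                   mean_within = mean(av[wk]),
                   mean_between = if (any(bk)) mean(av[bk]) else NA_real_,
                   higher_within = mean(av[wk]) > mean(av[bk]))
  })
  dropped <- sum(vapply(doms, function(k) sum(gd$domain == k) < 2, TRUE))
  if (dropped) message(dropped, " domain(s) with < 2 genes excluded from the per-domain table")
  list(global = global, per_domain = per_domain)
}

#' Permutation test for low co-expression at domain borders
#'
#' The observed statistic is the mean co-expression of gene pairs facing
#' each other across a border, i.e. pairs with one gene in the last bin of
#' the preceding domain and one in the first bin of the following domain
#' (`pairs = "spanning"`, the default); `pairs = "all"` instead averages
#' over all pairs of genes located in any border bin. The null is
#' built by jointly rotating all borders by a random circular offset, which
#' conserves the number and sizes of domains; the empirical p-value is
#' lower-tailed (fraction of null values less than or equal to the observed).
#'
#' @param coexpr A `coexpression_matrix` with gene midpoints.
#' @param segmentation A `domain_segmentation`.
#' @param n_perm Number of permutations.
#' @param pairs Pair definition at borders (see above).
#' @param seed RNG seed.
#' @return A `permutation_result` (side `"le"`).
#' @export
border_low_coexpression_test <- function(coexpr, segmentation, n_perm = 1000L,
                                         pairs = c("spanning", "all"), seed = 1L) {
  pairs <- match.arg(pairs)
  gd <- gene_domains(coexpr, segmentation)
  n <- segmentation$n_bins
  v <- coexpr$values
  bb <- border_bins(segmentation)
  border_stat <- function(offset) {
    before <- (bb$bin_before - 1L + offset) %% n + 1L
    after <- (bb$bin_after - 1L + offset) %% n + 1L
    if (pairs == "all") {
      genes <- which(gd$bin %in% c(before, after))
      if (length(genes) < 2) return(NA_real_)
      sub <- v[genes, genes]
      mean(sub[upper.tri(sub)])
    } else {
      vals <- unlist(lapply(seq_len(nrow(bb)), function(k) {
        g1 <- which(gd$bin == before[k]); g2 <- which(gd$bin == after[k])
        if (!length(g1) || !length(g2)) return(NULL)
        as.vector(v[g1, g2, drop = FALSE])
      }))
      if (!length(vals)) return(NA_real_)
      mean(vals)
    }
  }
  observed <- border_stat(0L)
  if (is.na(observed)) stop("no genes at any border bin", call. = FALSE)
  null_values <- with_seed(seed, {
    offs <- sample.int(n, n_perm, replace = TRUE) - 1L
    vapply(offs, border_stat, 1)
  })
  null_values <- null_values[!is.na(null_values)]
  new_permutation_result(observed, null_values, side = "le", seed = seed)
}

#' Co-expression versus genomic distance, stratified by domain membership
#'
#' Gene pairs are bucketed by circular genomic distance (midpoint to
#' midpoint) up to `max_distance` and the mean absolute co-expression is
#' traced for same-domain pairs, cross-domain pairs and all pairs. A
#' same-versus-cross contrast (Welch t-test) is reported for proximal pairs
#' below `split_distance`.
#'
#' @param coexpr A `coexpression_matrix` with gene midpoints.
#' @param segmentation A `domain_segmentation`.
#' @param max_distance Largest pair distance considered, bp (default 30 kb).
#' @param split_distance Proximal-pair threshold, bp (default 12 kb).
#' @param bucket_width Distance bucket width, bp (default one bin).
#' @return List with `curves` (tibble: bucket midpoint distance, stratum,
#'   mean_abs_coexpression, n_pairs; empty strata are absent) and
#'   `proximal_contrast` (one-row tibble with means and t-test p).
#' @export
distance_stratified_coexpression <- function(coexpr, segmentation,
                                             max_distance = 30000,
                                             split_distance = 12000,
                                             bucket_width = NULL) {
  gd <- gene_domains(coexpr, segmentation)
  if (is.null(bucket_width)) bucket_width <- segmentation$bin_size
  glen <- segmentation$n_bins * segmentation$bin_size
  mids <- coexpr$midpoints
  v <- coexpr$values
  pair <- which(upper.tri(v), arr.ind = TRUE)
  dd <- abs(mids[pair[, 1]] - mids[pair[, 2]])
  dd <- pmin(dd, glen - dd)
  keep <- dd <= max_distance
  pair <- pair[keep, , drop = FALSE]; dd <- dd[keep]
  same <- gd$domain[pair[, 1]] == gd$domain[pair[, 2]]
  av <- abs(v[pair])
  bucket <- (floor(dd / bucket_width) + 0.5) * bucket_width
  strata <- list(same_domain = same, cross_domain = !same, all_pairs = rep(TRUE, length(av)))
  curves <- purrr::map_dfr(names(strata), function(s) {
    sel <- strata[[s]]
    if (!any(sel)) return(NULL)
    tibble::tibble(distance = sort(unique(bucket[sel])), stratum = s) |>
      dplyr::mutate(
        mean_abs_coexpression = vapply(.data$distance, function(d) mean(av[sel & bucket == d]), 1),
        n_pairs = vapply(.data$distance, function(d) sum(sel & bucket == d), 1))
  })
  prox <- dd < split_distance
  contrast <- if (any(prox & same) && any(prox & !same) &&
                  sum(prox & same) > 1 && sum(prox & !same) > 1) {
    tibble::tibble(mean_same = mean(av[prox & same]),
                   mean_cross = mean(av[prox & !same]),
                   p_ttest = stats::t.test(av[prox & same], av[prox & !same],
                                           alternative = "greater")$p.value,
                   n_same = sum(prox & same), n_cross = sum(prox & !same))
  } else {
    tibble::tibble(mean_same = NA_real_, mean_cross = NA_real_, p_ttest = NA_real_,
                   n_same = sum(prox & same), n_cross = sum(prox & !same))
  }
  list(curves = curves, proximal_contrast = contrast)
}
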