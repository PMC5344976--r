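#' Full domain-analysis reproduction driver
#'
#' Runs the complete CID workflow on externally supplied dense contact
#' matrices (e.g. deposited 3 kb raw HpaII matrices for a stationary-phase
#' and a gyrase-inhibited culture): segmentation of each condition,
#' densities, the condition comparison and, when replicate matrices are
#' given, the border-alignment permutation test. Everything is computed at
#' call time; nothing is read besides the supplied files.
#'
#' @param stationary_path Dense TSV matrix of the reference condition.
#' @param treated_path Optional dense TSV matrix of the treated condition.
#' @param replicate_paths Optional character vector of replicate matrices.
#' @param bin_size Bin size in bp (default 3000).
#' @param bic_multiplier Segmentation penalty scale (default 1; exposed
#'   because the exact penalty constant of the original segmentation tool
#'   is not published).
#' @param tolerance Border-matching tolerance in bins (default 1).
#' @param n_random Randomizations for the alignment test (default 1000).
#' @param seed RNG seed.
#' @return List with `stationary` / `treated` (each: segmentation + glance),
#'   `comparison` (when treated given) and `alignment_test` (when
#'   replicates given).
#' @export
reproduce_cid_analysis <- function(stationary_path, treated_path = NULL,
                                   replicate_paths = NULL, bin_size = 3000,
                                   bic_multiplier = 1, tolerance = 1L,
                                   n_random = 1000L, seed = 1L) {
  cfg <- segmentation_config(bin_size = bin_size, bic_multiplier = bic_multiplier)
  run_one <- function(path) {
    m <- read_dense_matrix(path, bin_size)
    seg <- detect_cids(m, cfg)
    list(segmentation = seg, summary = glance(seg))
  }
  out <- list(stationary = run_one(stationary_path))
  if (!is.null(treated_path)) {
    out$treated <- run_one(treated_path)
    out$comparison <- compare_segmentations(out$stationary$segmentation,
                                            out$treated$segmentation, tolerance)
  }
  if (!is.null(replicate_paths)) {
    segs <- lapply(replicate_paths, function(p) run_one(p)$segmentation)
    out$alignment_test <- border_alignment_null_test(segs, tolerance, n_random, seed)
  }
  out
}

#' Full 3D-modelling reproduction driver
#'
#' Models a supplied 10 kb filtered/normalized matrix: restraints, annealed
#' ensemble, selection, mirror clustering, geometry medians and the
#' model-versus-input contact-map correlation.
#'
#' @param matrix_path Dense TSV matrix.
#' @param bin_size Bin size in bp (default 10000).
#' @param config A `modeling_config`.
#' @param contact_cutoff Contact distance for the model map (nm; default
#'   `maxdist`).
#' @return List with `ensemble` (kept, clustered), `geometry` medians,
#'   `map_correlation` and `cluster_sizes`.
#' @export
reproduce_model_analysis <- function(matrix_path, bin_size = 10000,
                                     config = modeling_config(),
                                     contact_cutoff = NULL) {
  m <- read_dense_matrix(matrix_path, bin_size, state = "raw")
  norm <- ice_normalize(m)
  restraints <- build_restraints(norm, config)
  kept <- optimize_ensemble(restraints, config) |>
    select_models(config$n_keep) |>
    cluster_models()
  if (is.null(contact_cutoff)) contact_cutoff <- config$maxdist
  map <- model_contact_map(kept, contact_cutoff, reference = norm)
  geom <- ensemble_geometry(kept)
  list(ensemble = kept, geometry = attr(geom, "medians"),
       map_correlation = attr(map, "correlation"),
       cluster_sizes = as.integer(table(kept$cluster)))
}
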