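#' Configuration for the paired-omics simulator
#'
#' Defines the ground-truth structure of a simulated paired dataset: K cell
#' types with planted marker features per modality, a rare population, and
#' optional additive batch effects (applied separately, see
#' [add_batch_effect()]).
#'
#' Defaults describe the benchmark conditions used throughout the package:
#' 1000 cells, five types of which one is rare (1% abundance), 2000 genes +
#' 2000 peaks, 20 markers per type with a fourfold expression change.
#'
#' @param n_cells number of cells.
#' @param n_types number of cell types K.
#' @param type_proportions simplex vector of length K (must sum to 1). The
#'   default gives `n_types - 1` equally abundant types plus one rare type at
#'   1% abundance.
#' @param n_rna,n_atac,n_adt feature counts; modality 2 is ATAC when
#'   `n_atac > 0`, otherwise ADT (`n_adt` features).
#' @param n_markers_per_type planted marker features per type (per modality).
#' @param marker_fold_change multiplier (> 1) applied to marker-gene means in
#'   their own type; also scales ADT marker means.
#' @param rna_dispersion negative-binomial size (inverse dispersion) for RNA.
#' @param atac_open_prob_base,atac_open_prob_marker Bernoulli accessibility
#'   probabilities for background and in-type marker peaks.
#' @param batch_shift_sd default shift scale forwarded to [add_batch_effect()].
#' @param seed integer; all randomness in [generate_paired_dataset()] flows
#'   from it.
#' @return list of class `simulation_config`.
#' @export
simulation_config <- function(n_cells = 1000, n_types = 5,
                              type_proportions = NULL,
                              n_rna = 2000, n_atac = 2000, n_adt = 0,
                              n_markers_per_type = 20,
                              marker_fold_change = 4,
                              rna_dispersion = 2,
                              atac_open_prob_base = 0.05,
                              atac_open_prob_marker = 0.4,
                              batch_shift_sd = 0.5,
                              seed = 1) {
  if (is.null(type_proportions))
    type_proportions <- c(rep((1 - 0.01) / (n_types - 1), n_types - 1), 0.01)
  if (length(type_proportions) != n_types)
    stop("type_proportions must have length n_types")
  if (abs(sum(type_proportions) - 1) > 1e-9)
    stop("type_proportions must sum to 1")
  if (any(type_proportions <= 0)) stop("type_proportions must be positive")
  if (n_cells < 2 * n_types) stop("n_cells too small for n_types")
  if (n_atac > 0 && n_adt > 0)
    stop("modality 2 is either ATAC or ADT; set n_atac or n_adt to 0")
  if (n_atac == 0 && n_adt == 0) stop("one of n_atac/n_adt must be positive")
  probs <- c(atac_open_prob_base, atac_open_prob_marker)
  if (any(probs < 0 | probs > 1)) stop("accessibility probabilities in [0,1]")
  if (marker_fold_change <= 0) stop("marker_fold_change must be positive")
  n_m2 <- if (n_atac > 0) n_atac else n_adt
  if (n_markers_per_type * n_types > min(n_rna, n_m2))
    stop("n_markers_per_type x n_types exceeds the feature count")
  structure(list(n_cells = n_cells, n_types = n_types,
                 type_proportions = type_proportions,
                 n_rna = n_rna, n_atac = n_atac, n_adt = n_adt,
                 n_markers_per_type = n_markers_per_type,
                 marker_fold_change = marker_fold_change,
                 rna_dispersion = rna_dispersion,
                 atac_open_prob_base = atac_open_prob_base,
                 atac_open_prob_marker = atac_open_prob_marker,
                 batch_shift_sd = batch_shift_sd, seed = seed),
            class = "simulation_config")
}

# Synthetic gene/peak geometry: gene g occupies chr1:[g*1e4, g*1e4 + 2e3)
# (0-based half-open, alternating strand); the marker peak paired with gene g
# sits inside the gene body, so peak-to-gene mapping has recoverable truth.
synthetic_gene_annotation <- function(n_genes) {
  start <- (seq_len(n_genes)) * 10000L
  data.frame(gene_id = paste0("gene_", seq_len(n_genes)),
             chrom = "chr1", start = start, end = start + 2000L,
             strand = rep(c("+", "-"), length.out = n_genes),
             stringsAsFactors = FALSE)
}

#' Generate a paired multi-omics dataset with known ground truth
#'
#' RNA counts are negative binomial around per-type mean profiles in which
#' each type's marker genes are elevated by `marker_fold_change`; ATAC counts
#' are Bernoulli accessibility with elevated open probability at marker peaks
#' geometrically paired with the marker genes (same index, overlapping
#' coordinates); ADT counts (when configured) are negative binomial over all
#' proteins with type-specific elevated markers. Cell types are drawn i.i.d.
#' from `type_proportions`, re-drawn (deterministically, from the same seeded
#' stream) until every declared type has at least 2 cells so stratified
#' cross-validation is definable. Fully reproducible from `cfg$seed`.
#'
#' @param cfg a [simulation_config()].
#' @return `list(dataset = paired_dataset, ground_truth = list(...))`; the
#'   ground truth records each cell's type, the planted marker feature IDs per
#'   type and modality, and the synthetic gene annotation used for peak
#'   coordinates.
#' @export
generate_paired_dataset <- function(cfg) {
  stopifnot(inherits(cfg, "simulation_config"))
  set.seed(cfg$seed)
  n <- cfg$n_cells
  K <- cfg$n_types
  types <- paste0("type_", seq_len(K))

  repeat {
    type_of <- sample.int(K, n, replace = TRUE, prob = cfg$type_proportions)
    if (min(tabulate(type_of, K)) >= 2) break
  }

  # disjoint marker blocks: type k owns features ((k-1)*m+1) .. k*m
  m <- cfg$n_markers_per_type
  marker_idx <- lapply(seq_len(K), function(k) ((k - 1) * m + 1):(k * m))

  # RNA: lognormal baseline gene means, per-cell lognormal size factors
  base_mu <- stats::rlnorm(cfg$n_rna, meanlog = 0, sdlog = 0.5)
  size_factor <- exp(stats::rnorm(n, 0, 0.2))
  fold <- matrix(1, n, cfg$n_rna)
  for (k in seq_len(K))
    fold[type_of == k, marker_idx[[k]]] <- cfg$marker_fold_change
  mu <- (size_factor %o% base_mu) * fold
  rna <- matrix(stats::rnbinom(n * cfg$n_rna, size = cfg$rna_dispersion,
                               mu = mu), n, cfg$n_rna)
  gene_ids <- paste0("gene_", seq_len(cfg$n_rna))

  if (cfg$n_atac > 0) {
    p <- matrix(cfg$atac_open_prob_base, n, cfg$n_atac)
    for (k in seq_len(K))
      p[type_of == k, marker_idx[[k]]] <- cfg$atac_open_prob_marker
    m2 <- matrix(stats::rbinom(n * cfg$n_atac, 1, p), n, cfg$n_atac)
    ann <- synthetic_gene_annotation(cfg$n_atac)
    m2_ids <- sprintf("chr1:%d-%d", ann$start + 500L, ann$start + 1500L)
    m2_tag <- "ATAC"
  } else {
    adt_mu <- stats::rlnorm(cfg$n_adt, meanlog = 3, sdlog = 0.4)
    fold2 <- matrix(1, n, cfg$n_adt)
    for (k in seq_len(K))
      fold2[type_of == k, marker_idx[[k]]] <- cfg$marker_fold_change
    m2 <- matrix(stats::rnbinom(n * cfg$n_adt, size = 4,
                                mu = (size_factor %o% adt_mu) * fold2),
                 n, cfg$n_adt)
    ann <- synthetic_gene_annotation(cfg$n_rna)
    m2_ids <- paste0("protein_", seq_len(cfg$n_adt))
    m2_tag <- "ADT"
  }

  cell_ids <- sprintf("cell_%05d", seq_len(n))
  labels <- types[type_of]
  ds <- paired_dataset(
    omics_matrix(rna, gene_ids, "RNA", check_counts = TRUE),
    omics_matrix(m2, m2_ids, m2_tag, check_counts = TRUE),
    cell_ids, cell_labels = labels)

  gt <- list(
    cell_type_of_cell = stats::setNames(labels, cell_ids),
    marker_features_of_type = lapply(stats::setNames(seq_len(K), types),
      function(k) list(RNA = gene_ids[marker_idx[[k]]],
                       m2 = m2_ids[marker_idx[[k]]])),
    batch_of_cell = NULL,
    gene_annotation = if (cfg$n_atac > 0) ann else NULL)
  names(gt$marker_features_of_type) <- types
  for (k in seq_len(K))
    names(gt$marker_features_of_type[[k]])[2] <- m2_tag
  list(dataset = ds, ground_truth = gt)
}

#' Add an additive batch effect
#'
#' Assigns cells uniformly at random to `n_batches` batches and adds one
#' per-(batch, feature) shift drawn from `N(0, shift_sd)` to every modality.
#' Intended for normalized (log-scale) data, emulating technical variation
#' that makes cells cluster by batch rather than by type.
#'
#' @param ds a [paired_dataset()] (normalized scale recommended).
#' @param gt ground-truth list from [generate_paired_dataset()] (batch
#'   assignment is recorded into it).
#' @param n_batches number of batches (>= 2).
#' @param shift_sd nonnegative scale of the per-(batch, feature) shifts.
#' @param seed integer seed.
#' @return `list(dataset, ground_truth)` with `batch_labels` populated.
#' @export
add_batch_effect <- function(ds, gt, n_batches = 2, shift_sd = 0.5, seed = 1) {
  stopifnot(inherits(ds, "paired_dataset"))
  if (n_batches < 2) stop("n_batches must be >= 2")
  if (shift_sd < 0) stop("shift_sd must be nonnegative")
  set.seed(seed)
  batch_of <- sample.int(n_batches, ds$n_cells, replace = TRUE)
  out <- ds
  for (slot in c("modality_1", "modality_2")) {
    om <- ds[[slot]]
    shift <- matrix(stats::rnorm(n_batches * ncol(om$values), 0, shift_sd),
                    n_batches)
    out[[slot]] <- omics_matrix(om$values + shift[batch_of, , drop = FALSE],
                                om$feature_ids, om$modality)
  }
  out$batch_labels <- paste0("batch_", batch_of)
  gt$batch_of_cell <- stats::setNames(out$batch_labels, ds$cell_ids)
  list(dataset = out, ground_truth = gt)
}

#' Write simulator ground truth to disk
#'
#' Cell assignments go to `ground_truth.csv` (`cell_id, cell_type[, batch]`);
#' the marker manifest goes to `markers.json`.
#'
#' @param gt ground-truth list from [generate_paired_dataset()].
#' @param dir output directory.
#' @return invisibly, the paths written.
#' @export
write_ground_truth <- function(gt, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  df <- data.table::data.table(cell_id = names(gt$cell_type_of_cell),
                               cell_type = unname(gt$cell_type_of_cell))
  if (!is.null(gt$batch_of_cell)) df$batch <- unname(gt$batch_of_cell)
  p1 <- file.path(dir, "ground_truth.csv")
  data.table::fwrite(df, p1)
  p2 <- file.path(dir, "markers.json")
  jsonlite::write_json(gt$marker_features_of_type, p2, auto_unbox = FALSE,
                       pretty = TRUE)
  invisible(c(p1, p2))
}
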