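#' Construct a single-modality cell-by-feature matrix
#'
#' Thin validated container around a dense numeric matrix of cells (rows) by
#' features (columns), tagged with its modality. ATAC peak identifiers are
#' expected as `"chrom:start-end"` with 0-based half-open coordinates.
#'
#' @param values numeric matrix, cells x features.
#' @param feature_ids character vector of unique feature identifiers (genes,
#'   peaks, or proteins), one per column.
#' @param modality one of `"RNA"`, `"ATAC"`, `"ADT"`.
#' @param check_counts if `TRUE`, reject negative values (raw counts).
#' @return an object of class `omics_matrix`.
#' @export
omics_matrix <- function(values, feature_ids = colnames(values),
                         modality = c("RNA", "ATAC", "ADT"),
                         check_counts = FALSE) {
  modality <- match.arg(modality)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(feature_ids)) stop("feature_ids are required")
  feature_ids <- as.character(feature_ids)
  if (length(feature_ids) != ncol(values))
    stop("feature_ids length does not match the number of columns")
  if (anyDuplicated(feature_ids))
    stop("duplicate feature identifiers in ", modality, " modality")
  if (check_counts && any(values < 0))
    stop("negative values are not valid raw counts")
  colnames(values) <- feature_ids
  structure(list(values = values, feature_ids = feature_ids,
                 modality = modality),
            class = "omics_matrix")
}

#' @export
print.omics_matrix <- function(x, ...) {
  cat(sprintf("<omics_matrix> %s: %d cells x %d features\n",
              x$modality, nrow(x$values), length(x$feature_ids)))
  invisible(x)
}

#' Construct a paired two-modality dataset
#'
#' Bundles two row-aligned [omics_matrix()] objects measured in the same cells
#' with optional cell-type and batch labels. Exactly two modalities are
#' supported (RNA plus ATAC or ADT).
#'
#' @param modality_1,modality_2 [omics_matrix()] objects with identical row
#'   counts and row order (cells).
#' @param cell_ids character vector of unique cell barcodes.
#' @param cell_labels optional character vector of cell-type names per cell.
#' @param batch_labels optional character vector of batch names per cell.
#' @param normalized logical; set by [normalize_counts()].
#' @return an object of class `paired_dataset`.
#' @export
paired_dataset <- function(modality_1, modality_2, cell_ids,
                           cell_labels = NULL, batch_labels = NULL,
                           normalized = FALSE) {
  stopifnot(inherits(modality_1, "omics_matrix"),
            inherits(modality_2, "omics_matrix"))
  n <- nrow(modality_1$values)
  if (nrow(modality_2$values) != n)
    stop("modalities have different cell counts")
  cell_ids <- as.character(cell_ids)
  if (length(cell_ids) != n) stop("cell_ids length != number of cells")
  if (anyDuplicated(cell_ids)) stop("duplicate cell identifiers")
  if (!is.null(cell_labels) && length(cell_labels) != n)
    stop("cell_labels must have one entry per cell")
  if (!is.null(batch_labels) && length(batch_labels) != n)
    stop("batch_labels must have one entry per cell")
  rownames(modality_1$values) <- cell_ids
  rownames(modality_2$values) <- cell_ids
  structure(list(modality_1 = modality_1, modality_2 = modality_2,
                 cell_ids = cell_ids,
                 cell_labels = if (!is.null(cell_labels)) as.character(cell_labels),
                 batch_labels = if (!is.null(batch_labels)) as.character(batch_labels),
                 n_cells = n, normalized = normalized),
            class = "paired_dataset")
}

#' @export
print.paired_dataset <- function(x, ...) {
  cat(sprintf("<paired_dataset> %d cells; %s (%d features) + %s (%d features)%s%s\n",
              x$n_cells,
              x$modality_1$modality, length(x$modality_1$feature_ids),
              x$modality_2$modality, length(x$modality_2$feature_ids),
              if (!is.null(x$cell_labels))
                sprintf("; %d cell types", length(unique(x$cell_labels))) else "",
              if (x$normalized) "; normalized" else ""))
  invisible(x)
}

#' Subset a paired dataset by cell index
#'
#' @param ds a [paired_dataset()].
#' @param idx integer or logical index over cells.
#' @return the subset [paired_dataset()] (labels/batches carried along).
#' @export
subset_cells <- function(ds, idx) {
  paired_dataset(
    omics_matrix(ds$modality_1$values[idx, , drop = FALSE],
                 ds$modality_1$feature_ids, ds$modality_1$modality),
    omics_matrix(ds$modality_2$values[idx, , drop = FALSE],
                 ds$modality_2$feature_ids, ds$modality_2$modality),
    ds$cell_ids[idx],
    cell_labels = if (!is.null(ds$cell_labels)) ds$cell_labels[idx],
    batch_labels = if (!is.null(ds$batch_labels)) ds$batch_labels[idx],
    normalized = ds$normalized)
}

#' Cell-type label codec
#'
#' Bijective mapping between cell-type names and integer codes `1..C`
#' (class order is sorted and fixed at construction).
#'
#' @param labels character vector of cell-type names.
#' @return list with `classes` (ordered names) and `n_classes`.
#' @export
label_codec <- function(labels) {
  classes <- sort(unique(as.character(labels)))
  if (length(classes) < 2) stop("at least 2 cell types are required")
  list(classes = classes, n_classes = length(classes))
}

encode_labels <- function(codec, labels) {
  code <- match(as.character(labels), codec$classes)
  if (anyNA(code)) stop("unknown cell type(s): ",
                        paste(setdiff(labels, codec$classes), collapse = ", "))
  code
}

one_hot <- function(code, n_classes) {
  y <- matrix(0, length(code), n_classes)
  y[cbind(seq_along(code), code)] <- 1
  y
}

# ---- readers ---------------------------------------------------------------

read_matrix_any <- function(path, fmt) {
  if (fmt == "auto") {
    fmt <- if (dir.exists(path) || grepl("\\.mtx$", path)) "mtx"
           else if (grepl("\\.(h5|h5ad|hdf5)$", path)) "h5ad"
           else "delim"
  }
  if (fmt == "h5ad")
    stop("HDF5/.h5ad input is not supported by this build; ",
         "export to MatrixMarket or delimited text: ", path)
  if (fmt == "mtx") {
    dir <- if (dir.exists(path)) path else dirname(path)
    mtx <- if (dir.exists(path)) file.path(path, "matrix.mtx") else path
    for (f in c(mtx, file.path(dir, "features.tsv"), file.path(dir, "barcodes.tsv")))
      if (!file.exists(f)) stop("cannot read file: ", f)
    m <- as.matrix(Matrix::readMM(mtx))
    features <- data.table::fread(file.path(dir, "features.tsv"),
                                  header = FALSE, sep = "\t")[[1]]
    barcodes <- data.table::fread(file.path(dir, "barcodes.tsv"),
                                  header = FALSE, sep = "\t")[[1]]
    # 10x convention stores features x cells; transpose to cells x features.
    if (nrow(m) != length(features) || ncol(m) != length(barcodes))
      stop("matrix dimensions do not match features/barcodes sidecars: ", mtx)
    m <- t(m)
    dimnames(m) <- list(barcodes, features)
    m
  } else {
    if (!file.exists(path)) stop("cannot read file: ", path)
    dt <- data.table::fread(path, header = TRUE)
    ids <- as.character(dt[[1]])
    m <- as.matrix(dt[, -1, drop = FALSE])
    storage.mode(m) <- "double"
    rownames(m) <- ids
    m
  }
}

#' Read a paired two-modality dataset from disk
#'
#' Supported formats: MatrixMarket (`matrix.mtx` plus `features.tsv` /
#' `barcodes.tsv` sidecars, features x cells as written by 10x tooling) and
#' delimited text (cells x features, header row of feature IDs, first column
#' of cell IDs). Cells are aligned across modalities by barcode intersection,
#' preserving modality-1 order; cells present in only one modality are dropped
#' with a warning.
#'
#' @param path_m1,path_m2 paths (file or MatrixMarket directory) per modality.
#' @param labels_path optional CSV with columns `cell_id, cell_type[, batch]`;
#'   must cover every aligned cell.
#' @param fmt `"auto"`, `"mtx"` or `"delim"` (applies to both modalities).
#' @param modality_1,modality_2 modality tags for the two inputs.
#' @return a [paired_dataset()].
#' @export
read_paired_dataset <- function(path_m1, path_m2, labels_path = NULL,
                                fmt = "auto",
                                modality_1 = "RNA", modality_2 = "ATAC") {
  m1 <- read_matrix_any(path_m1, fmt)
  m2 <- read_matrix_any(path_m2, fmt)
  if (anyDuplicated(rownames(m1)) || anyDuplicated(rownames(m2)))
    stop("duplicate cell identifiers within a modality")
  shared <- intersect(rownames(m1), rownames(m2))
  if (length(shared) == 0) stop("no overlapping cells between modalities")
  shared <- rownames(m1)[rownames(m1) %in% shared]  # preserve modality-1 order
  dropped <- (nrow(m1) - length(shared)) + (nrow(m2) - length(shared))
  if (dropped > 0)
    warning(sprintf("dropped %d cell(s) present in only one modality", dropped))
  m1 <- m1[shared, , drop = FALSE]
  m2 <- m2[shared, , drop = FALSE]
  labels <- batches <- NULL
  if (!is.null(labels_path)) {
    lab <- data.table::fread(labels_path, header = TRUE)
    miss <- setdiff(shared, as.character(lab[[1]]))
    if (length(miss) > 0)
      stop("labels file is missing ", length(miss), " cell(s), e.g. ", miss[1])
    ord <- match(shared, as.character(lab[[1]]))
    labels <- as.character(lab[[2]])[ord]
    if (ncol(lab) >= 3) batches <- as.character(lab[[3]])[ord]
  }
  paired_dataset(omics_matrix(m1, modality = modality_1, check_counts = FALSE),
                 omics_matrix(m2, modality = modality_2, check_counts = FALSE),
                 cell_ids = shared, cell_labels = labels,
                 batch_labels = batches)
}

#' Write a paired dataset to disk
#'
#' Inverse of [read_paired_dataset()]: writes both modalities (and labels when
#' present) in a format the reader accepts.
#'
#' @param ds a [paired_dataset()].
#' @param dir output directory (created if absent).
#' @param fmt `"csv"` or `"mtx"`.
#' @return invisibly, the paths written.
#' @export
write_paired_dataset <- function(ds, dir, fmt = c("csv", "mtx")) {
  fmt <- match.arg(fmt)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (slot in c("modality_1", "modality_2")) {
    om <- ds[[slot]]
    if (fmt == "csv") {
      p <- file.path(dir, paste0(slot, ".csv"))
      dt <- data.table::data.table(cell_id = ds$cell_ids)
      dt <- cbind(dt, data.table::as.data.table(om$values))
      data.table::fwrite(dt, p)
    } else {
      p <- file.path(dir, slot)
      dir.create(p, showWarnings = FALSE)
      Matrix::writeMM(Matrix::Matrix(t(om$values), sparse = TRUE),
                      file.path(p, "matrix.mtx"))
      writeLines(om$feature_ids, file.path(p, "features.tsv"))
      writeLines(ds$cell_ids, file.path(p, "barcodes.tsv"))
    }
    paths <- c(paths, p)
  }
  if (!is.null(ds$cell_labels)) {
    p <- file.path(dir, "labels.csv")
    lab <- data.table::data.table(cell_id = ds$cell_ids,
                                  cell_type = ds$cell_labels)
    if (!is.null(ds$batch_labels)) lab$batch <- ds$batch_labels
    data.table::fwrite(lab, p)
    paths <- c(paths, p)
  }
  invisible(paths)
}

# ---- normalization ---------------------------------------------------------

depth_log_normalize <- function(m, target) {
  totals <- rowSums(m)
  log1p(m * (target / totals))
}

clr_normalize <- function(m) {
  lg <- log1p(m)
  lg - rowMeans(lg)
}

#' Normalize raw counts per modality
#'
#' RNA and ATAC are depth-normalized to the median per-cell total and
#' log1p-transformed; ADT is centered-log-ratio transformed per cell
#' (`log1p(x) - mean(log1p(x))`). Cells with zero total counts in either
#' depth-normalized modality cannot be normalized and are removed with a
#' warning. Calling on an already-normalized dataset returns it unchanged.
#'
#' @param ds a raw-count [paired_dataset()].
#' @return a normalized [paired_dataset()] (flagged `normalized = TRUE`).
#' @export
normalize_counts <- function(ds) {
  stopifnot(inherits(ds, "paired_dataset"))
  if (isTRUE(ds$normalized)) return(ds)
  needs_depth <- function(om) om$modality %in% c("RNA", "ATAC")
  zero <- rep(FALSE, ds$n_cells)
  for (slot in c("modality_1", "modality_2"))
    if (needs_depth(ds[[slot]]))
      zero <- zero | rowSums(ds[[slot]]$values) == 0
  if (any(zero)) {
    warning(sprintf("removed %d all-zero cell(s) that cannot be depth-normalized",
                    sum(zero)))
    ds <- subset_cells(ds, which(!zero))
  }
  out <- ds
  for (slot in c("modality_1", "modality_2")) {
    om <- ds[[slot]]
    vals <- if (needs_depth(om)) {
      depth_log_normalize(om$values, stats::median(rowSums(om$values)))
    } else {
      clr_normalize(om$values)
    }
    out[[slot]] <- omics_matrix(vals, om$feature_ids, om$modality)
  }
  out$normalized <- TRUE
  out
}

# Seurat-style normalized dispersion on log data: mean and dispersion
# (var/mean) computed on the expm1 scale, dispersion z-scored within 20
# equal-width mean bins. Returns a ranking score per feature (higher = more
# variable); ties resolve by column order.
hvg_score <- function(values, n_bins = 20) {
  y <- expm1(values)
  mu <- colMeans(y)
  v <- colMeans(y * y) - mu^2
  v <- v * nrow(y) / max(1, nrow(y) - 1)
  disp <- ifelse(mu > 0, v / mu, 0)
  bins <- cut(mu, breaks = n_bins, include.lowest = TRUE)
  g_mean <- mean(disp)
  g_sd <- stats::sd(disp)
  z <- disp
  for (b in levels(bins)) {
    i <- which(bins == b)
    if (length(i) == 0) next
    s <- stats::sd(disp[i])
    z[i] <- if (length(i) > 1 && isTRUE(s > 0)) {
      (disp[i] - mean(disp[i])) / s
    } else if (isTRUE(g_sd > 0)) {
      # degenerate bin (single feature or zero spread): rank against the
      # global dispersion distribution instead of discarding the feature
      (disp[i] - g_mean) / g_sd
    } else 0
  }
  z
}

select_hvg_idx <- function(values, n_keep) {
  score <- hvg_score(values)
  ord <- order(score, decreasing = TRUE)
  sort(ord[seq_len(n_keep)])  # keep original column order
}

#' Select highly variable features per modality
#'
#' Reduces RNA to the top `n_rna` and ATAC to the top `n_atac` features by
#' normalized dispersion (mean-binned, seurat-style); ADT modalities are kept
#' in full. Selection is deterministic for identical input.
#'
#' @param ds a normalized [paired_dataset()].
#' @param n_rna,n_atac number of features to keep per modality (defaults 4000).
#' @return the reduced [paired_dataset()]; selected feature IDs are also
#'   recorded in the `hvg` element.
#' @export
select_highly_variable <- function(ds, n_rna = 4000, n_atac = 4000) {
  stopifnot(inherits(ds, "paired_dataset"))
  out <- ds
  kept <- list()
  for (slot in c("modality_1", "modality_2")) {
    om <- ds[[slot]]
    n_keep <- switch(om$modality, RNA = n_rna, ATAC = n_atac, ADT = NA)
    if (is.na(n_keep)) { kept[[om$modality]] <- om$feature_ids; next }
    if (n_keep > length(om$feature_ids)) {
      warning(sprintf("requested %d features but %s has only %d; keeping all",
                      n_keep, om$modality, length(om$feature_ids)))
      n_keep <- length(om$feature_ids)
    }
    idx <- select_hvg_idx(om$values, n_keep)
    out[[slot]] <- omics_matrix(om$values[, idx, drop = FALSE],
                                om$feature_ids[idx], om$modality)
    kept[[om$modality]] <- om$feature_ids[idx]
  }
  out$hvg <- kept
  out
}

#' Stratified k-fold split of cells
#'
#' Partitions cell indices into `k` folds stratified by cell type: per-class
#' counts differ by at most one cell across folds. Classes with fewer than `k`
#' cells are placed entirely in every training fold (with a warning) and never
#' appear in a test fold.
#'
#' @param ds a labeled [paired_dataset()].
#' @param k number of folds (default 5).
#' @param seed integer seed controlling the shuffle.
#' @return list of `k` elements, each `list(train = idx, test = idx)`.
#' @export
split_folds <- function(ds, k = 5, seed = 1) {
  stopifnot(inherits(ds, "paired_dataset"))
  if (is.null(ds$cell_labels)) stop("split_folds requires cell labels")
  if (k < 2) stop("k must be >= 2")
  set.seed(seed)
  n <- ds$n_cells
  fold_of <- integer(n)        # 0 = never in a test fold
  small <- character(0)
  offset <- 0L
  for (cl in sort(unique(ds$cell_labels))) {
    idx <- which(ds$cell_labels == cl)
    if (length(idx) < k) { small <- c(small, cl); next }
    idx <- idx[sample.int(length(idx))]
    f <- ((seq_along(idx) - 1L + offset) %% k) + 1L
    fold_of[idx] <- f
    offset <- (offset + length(idx)) %% k
  }
  if (length(small) > 0)
    warning("class(es) with fewer than k cells kept in training only: ",
            paste(small, collapse = ", "))
  lapply(seq_len(k), function(f)
    list(train = which(fold_of != f), test = which(fold_of == f)))
}
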