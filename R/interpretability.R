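# Shapley-value feature attribution by permutation sampling, and ATAC
# peak-to-gene mapping through promoter-window overlap.

#' Sampling estimator of Shapley values
#'
#' Unbiased permutation-sampling estimate of each input feature's Shapley
#' value for a (possibly vector-valued) model `f`. For every sampled
#' permutation a background row is drawn and features are switched from the
#' background value to the explained value one at a time; the marginal change
#' in `f` at each switch is that feature's contribution for the permutation.
#' By telescoping, the per-permutation contributions sum exactly to
#' `f(x) - f(b)`, so the estimate satisfies local accuracy with respect to
#' the averaged background draw.
#'
#' @param f function taking a matrix (rows = inputs) and returning a numeric
#'   vector (one value per row) or matrix (one row per input).
#' @param x numeric vector: the input to explain.
#' @param background numeric matrix of background rows (the "absent feature"
#'   reference distribution).
#' @param n_perm number of sampled permutations (default 8).
#' @param seed integer seed.
#' @param chunk_rows maximum rows per model evaluation call.
#' @return list with `phi` (features x outputs matrix of Shapley estimates),
#'   `f_x` (model at `x`) and `f_b` (mean model value over the sampled
#'   backgrounds); `colSums(phi) == f_x - f_b` up to floating point.
#' @export
sampling_shapley <- function(f, x, background, n_perm = 8, seed = 1,
                             chunk_rows = 4096) {
  x <- as.numeric(x)
  background <- as.matrix(background)
  d <- length(x)
  if (ncol(background) != d) stop("background width does not match x")
  set.seed(seed)
  eval_f <- function(m) {
    outs <- vector("list", ceiling(nrow(m) / chunk_rows))
    for (ci in seq_along(outs)) {
      rows <- ((ci - 1) * chunk_rows + 1):min(ci * chunk_rows, nrow(m))
      o <- f(m[rows, , drop = FALSE])
      outs[[ci]] <- if (is.matrix(o)) o else matrix(o, ncol = 1)
    }
    do.call(rbind, outs)
  }
  phi <- NULL
  f_x_acc <- f_b_acc <- NULL
  for (p in seq_len(n_perm)) {
    b <- background[sample.int(nrow(background), 1), ]
    perm <- sample.int(d)
    # rows 1..d+1: background, then cumulative replacement along perm
    grid <- matrix(rep(b, d + 1), nrow = d + 1, byrow = TRUE)
    for (j in seq_len(d)) grid[(j + 1):(d + 1), perm[j]] <- x[perm[j]]
    vals <- eval_f(grid)
    contrib <- vals[-1, , drop = FALSE] - vals[-(d + 1), , drop = FALSE]
    if (is.null(phi)) {
      phi <- matrix(0, d, ncol(vals))
      f_x_acc <- f_b_acc <- numeric(ncol(vals))
    }
    phi[perm, ] <- phi[perm, , drop = FALSE] + contrib
    f_x_acc <- f_x_acc + vals[d + 1, ]
    f_b_acc <- f_b_acc + vals[1, ]
  }
  list(phi = phi / n_perm, f_x = f_x_acc / n_perm, f_b = f_b_acc / n_perm)
}

#' Shapley feature attribution for the classification or embedding head
#'
#' Estimates per-feature Shapley values over both modalities jointly (the
#' model input is the concatenated feature vector) and aggregates them per
#' cell type as the mean absolute value over explained cells of that type.
#' For `task = "classification"` the explained output is the predicted
#' probability of the cell's own type; for `task = "dimension_reduction"` it
#' is the cell embedding, with absolute contributions summed across the
#' embedding coordinates.
#'
#' @param state a trained `scmomtf_model`.
#' @param ds a normalized, labeled [paired_dataset()] on the training feature
#'   space.
#' @param task `"classification"` or `"dimension_reduction"`.
#' @param background_size background cells sampled from `ds` (default 100).
#' @param n_samples total model-evaluation budget per cell; translated into
#'   sampled permutations of the concatenated feature vector (default
#'   `2 * d + 2048`). Values below `d + 2` are increased with a warning.
#' @param n_cells_per_type explained cells sampled per type (default 20).
#' @param seed integer seed.
#' @return named list with one `attribution_table` per modality
#'   (`modality_1`, `modality_2`), each holding `scores` and min-max
#'   `normalized_scores` (features x cell types).
#' @export
attribute_features <- function(state, ds,
                               task = c("classification", "dimension_reduction"),
                               background_size = 100, n_samples = NULL,
                               n_cells_per_type = 20, seed = 1) {
  task <- match.arg(task)
  stopifnot(inherits(state, "scmomtf_model"), inherits(ds, "paired_dataset"))
  if (is.null(ds$cell_labels)) stop("attribution requires cell labels")
  check_features(state, ds)
  v1 <- state$config$v1
  d <- v1 + state$config$v2
  if (is.null(n_samples)) n_samples <- 2 * d + 2048
  if (n_samples < d + 2) {
    warning("n_samples below the minimum of features + 2; increasing")
    n_samples <- d + 2
  }
  n_perm <- max(2L, as.integer(ceiling(n_samples / (d + 1))))

  set.seed(seed)
  xall <- cbind(ds$modality_1$values, ds$modality_2$values)
  bg_idx <- sample.int(ds$n_cells, min(background_size, ds$n_cells))
  background <- xall[bg_idx, , drop = FALSE]
  classes <- sort(unique(ds$cell_labels))
  explain_idx <- unlist(lapply(classes, function(cl) {
    i <- which(ds$cell_labels == cl)
    i[sample.int(length(i), min(n_cells_per_type, length(i)))]
  }))
  cell_seeds <- sample.int(.Machine$integer.max, length(explain_idx))

  model_fun <- function(target_class) {
    force(target_class)
    function(m) {
      x1 <- m[, seq_len(v1), drop = FALSE]
      x2 <- m[, (v1 + 1):d, drop = FALSE]
      emb <- encode(state, x1, x2)
      if (task == "classification") {
        classify(state, emb$z)[, target_class]
      } else {
        emb$z
      }
    }
  }

  acc <- matrix(0, d, length(classes), dimnames = list(NULL, classes))
  cnt <- stats::setNames(numeric(length(classes)), classes)
  for (ii in seq_along(explain_idx)) {
    i <- explain_idx[ii]
    cl <- ds$cell_labels[i]
    res <- sampling_shapley(model_fun(cl), xall[i, ], background,
                            n_perm = n_perm, seed = cell_seeds[ii])
    contrib <- if (task == "classification") abs(res$phi[, 1])
               else rowSums(abs(res$phi))
    acc[, cl] <- acc[, cl] + contrib
    cnt[cl] <- cnt[cl] + 1
  }
  scores <- sweep(acc, 2, pmax(cnt, 1), `/`)

  make_table <- function(rows, slot) {
    s <- scores[rows, , drop = FALSE]
    rng <- range(s)
    norm <- if (diff(rng) > 0) (s - rng[1]) / diff(rng) else s * 0
    structure(list(scores = s, normalized_scores = norm,
                   feature_ids = ds[[slot]]$feature_ids,
                   modality = ds[[slot]]$modality, task = task,
                   classes = classes),
              class = "attribution_table")
  }
  list(modality_1 = make_table(seq_len(v1), "modality_1"),
       modality_2 = make_table((v1 + 1):d, "modality_2"))
}

#' @export
print.attribution_table <- function(x, ...) {
  cat(sprintf("<attribution_table> %s / %s: %d features x %d cell types\n",
              x$modality, x$task, length(x$feature_ids), length(x$classes)))
  invisible(x)
}

#' Rank candidate marker features for a cell type
#'
#' @param table an `attribution_table` from [attribute_features()].
#' @param cell_type a cell type present in the table.
#' @param top_k number of features to return (truncated to the table size).
#' @return data.frame (feature, score, normalized_score) in descending score
#'   order; ties break lexicographically by feature ID.
#' @export
rank_markers <- function(table, cell_type, top_k = 10) {
  stopifnot(inherits(table, "attribution_table"))
  if (!cell_type %in% table$classes)
    stop("unknown cell type '", cell_type, "'; known: ",
         paste(table$classes, collapse = ", "))
  s <- table$normalized_scores[, cell_type]
  ord <- order(-s, table$feature_ids)
  ord <- ord[seq_len(min(top_k, length(ord)))]
  data.frame(feature = table$feature_ids[ord],
             score = table$scores[ord, cell_type],
             normalized_score = s[ord], row.names = NULL)
}

parse_peaks <- function(peaks) {
  m <- regmatches(peaks, regexec("^([^:]+):([0-9]+)-([0-9]+)$", peaks))
  bad <- vapply(m, length, 0L) != 4
  if (any(bad))
    stop("malformed peak ID(s): ", paste(peaks[bad], collapse = ", "))
  data.frame(peak = peaks,
             chrom = vapply(m, `[`, "", 2),
             start = as.integer(vapply(m, `[`, "", 3)),
             end = as.integer(vapply(m, `[`, "", 4)),
             stringsAsFactors = FALSE)
}

#' Read a gene annotation (BED6 or GTF)
#'
#' BED6 intervals are 0-based half-open; GTF records of type `gene` are
#' converted to the same convention. Returns the data.frame layout consumed
#' by [map_peaks_to_genes()].
#'
#' @param path annotation file (`.bed`, `.gtf` or `.gff`).
#' @return data.frame with gene_id, chrom, start, end, strand.
#' @export
read_gene_annotation <- function(path) {
  if (!file.exists(path)) stop("cannot read file: ", path)
  if (grepl("\\.bed$", path, ignore.case = TRUE)) {
    bed <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE)
    if (ncol(bed) < 6) stop("BED6 requires 6 columns: ", path)
    data.frame(gene_id = bed[[4]], chrom = bed[[1]], start = bed[[2]],
               end = bed[[3]], strand = bed[[6]], stringsAsFactors = FALSE)
  } else if (grepl("\\.(gtf|gff3?)$", path, ignore.case = TRUE)) {
    gr <- rtracklayer::import(path)
    if ("type" %in% names(S4Vectors::mcols(gr)))
      gr <- gr[S4Vectors::mcols(gr)$type == "gene"]
    ids <- S4Vectors::mcols(gr)$gene_id
    if (is.null(ids)) ids <- S4Vectors::mcols(gr)$ID
    data.frame(gene_id = as.character(ids),
               chrom = as.character(GenomicRanges::seqnames(gr)),
               start = GenomicRanges::start(gr) - 1L,  # to 0-based half-open
               end = GenomicRanges::end(gr),
               strand = as.character(GenomicRanges::strand(gr)),
               stringsAsFactors = FALSE)
  } else stop("unsupported annotation format: ", path)
}

#' Map ATAC peaks to genes via promoter-window overlap
#'
#' A peak maps to every gene whose interval, extended `window` basepairs
#' upstream of the transcription start site (strand-aware), overlaps the
#' peak. Peak IDs use 0-based half-open `"chrom:start-end"` coordinates.
#'
#' @param peaks character vector of peak IDs.
#' @param genes gene annotation: a data.frame (gene_id, chrom, start, end,
#'   strand; 0-based half-open) or a path accepted by
#'   [read_gene_annotation()].
#' @param window upstream extension in basepairs (default 2000).
#' @return named list mapping each peak ID to a character vector of gene IDs
#'   (empty for unmapped peaks).
#' @export
map_peaks_to_genes <- function(peaks, genes, window = 2000) {
  if (is.character(genes) && length(genes) == 1 && file.exists(genes))
    genes <- read_gene_annotation(genes)
  stopifnot(is.data.frame(genes))
  if (any(genes$start >= genes$end)) stop("gene intervals must have start < end")
  pk <- parse_peaks(peaks)
  ext_start <- ifelse(genes$strand == "-", genes$start, genes$start - window)
  ext_end <- ifelse(genes$strand == "-", genes$end + window, genes$end)
  # convert 0-based half-open to 1-based closed for IRanges
  gr_genes <- GenomicRanges::GRanges(
    genes$chrom, IRanges::IRanges(pmax(ext_start, 0) + 1L, ext_end))
  gr_peaks <- GenomicRanges::GRanges(
    pk$chrom, IRanges::IRanges(pk$start + 1L, pk$end))
  hits <- suppressWarnings(GenomicRanges::findOverlaps(gr_peaks, gr_genes))
  qh <- S4Vectors::queryHits(hits)
  sh <- S4Vectors::subjectHits(hits)
  out <- split(genes$gene_id[sh], factor(qh, levels = seq_along(peaks)))
  stats::setNames(lapply(out, function(g) sort(as.character(g))), peaks)
}
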