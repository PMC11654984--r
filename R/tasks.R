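# User-facing tasks built on a trained model: dimension reduction, cell-type
# prediction, data simulation, and reference-batch batch correction.

check_features <- function(state, ds) {
  if (is.null(state$feature_ids)) return(invisible(TRUE))
  for (slot in c("modality_1", "modality_2")) {
    want <- state$feature_ids[[slot]]
    have <- ds[[slot]]$feature_ids
    if (!identical(want, have)) {
      missing <- setdiff(want, have)
      extra <- setdiff(have, want)
      stop(sprintf(
        "%s feature space does not match training (%d missing, e.g. %s; %d extra%s)",
        slot, length(missing),
        if (length(missing)) missing[1] else "-",
        length(extra),
        if (length(extra)) paste0(", e.g. ", extra[1]) else ""))
    }
  }
  invisible(TRUE)
}

#' Embed cells with a trained model (dimension reduction)
#'
#' @param state a trained `scmomtf_model`.
#' @param ds a [paired_dataset()] on the training feature space.
#' @return a `cell_embedding` (`z`: n x cell_embed_dim; `h1`, `h2`).
#' @export
embed_cells <- function(state, ds) {
  stopifnot(inherits(state, "scmomtf_model"), inherits(ds, "paired_dataset"))
  check_features(state, ds)
  emb <- encode(state, ds$modality_1$values, ds$modality_2$values)
  rownames(emb$z) <- ds$cell_ids
  emb
}

#' Predict cell types with a trained model
#'
#' @param state a trained `scmomtf_model`.
#' @param ds a [paired_dataset()] on the training feature space.
#' @return list with `labels` (character, argmax class per cell) and
#'   `probabilities` (n x C matrix, rows sum to 1).
#' @export
predict_cell_types <- function(state, ds) {
  emb <- embed_cells(state, ds)
  probs <- classify(state, emb$z)
  labels <- state$classes[max.col(probs, ties.method = "first")]
  rownames(probs) <- ds$cell_ids
  list(labels = stats::setNames(labels, ds$cell_ids), probabilities = probs)
}

#' Request for model-based data simulation
#'
#' @param target_cell_type a cell-type name known to the model, or `"ALL"` to
#'   draw proportionally from every type.
#' @param n_cells number of cells to simulate (>= 1).
#' @param noise_scale nonnegative latent perturbation scale, expressed as a
#'   multiple of the per-dimension latent standard deviation of the target
#'   type's embeddings (default 0.1).
#' @param seed integer seed.
#' @return list of class `simulation_request`.
#' @export
simulation_request <- function(target_cell_type = "ALL", n_cells = 200,
                               noise_scale = 0.1, seed = 1) {
  if (n_cells < 1) stop("n_cells must be >= 1")
  if (noise_scale < 0) stop("noise_scale must be nonnegative")
  structure(list(target_cell_type = target_cell_type, n_cells = n_cells,
                 noise_scale = noise_scale, seed = seed),
            class = "simulation_request")
}

#' Simulate cells of a given type with the trained generator
#'
#' Source cells of the target type are resampled (with replacement), encoded,
#' perturbed in latent space with seeded Gaussian noise of scale
#' `noise_scale` x the per-dimension latent standard deviation of that type,
#' and decoded through both modality decoders. Output is on the normalized
#' scale; `inverse_transform = TRUE` maps depth-normalized modalities back to
#' count-like values (`expm1`, clamped at zero, rounded).
#'
#' @param state a trained `scmomtf_model`.
#' @param ds the (normalized) [paired_dataset()] providing source cells.
#' @param req a [simulation_request()].
#' @param inverse_transform return count-like values instead of the
#'   normalized scale (default FALSE).
#' @return a [paired_dataset()] of simulated cells carrying the requested
#'   labels.
#' @export
simulate_cells <- function(state, ds, req = simulation_request(),
                           inverse_transform = FALSE) {
  stopifnot(inherits(state, "scmomtf_model"), inherits(req, "simulation_request"))
  if (is.null(ds$cell_labels)) stop("source dataset must carry cell labels")
  check_features(state, ds)
  set.seed(req$seed)
  if (identical(req$target_cell_type, "ALL")) {
    pool <- seq_len(ds$n_cells)
  } else {
    if (!req$target_cell_type %in% ds$cell_labels)
      stop("unknown target cell type '", req$target_cell_type,
           "'; known types: ", paste(sort(unique(ds$cell_labels)), collapse = ", "))
    pool <- which(ds$cell_labels == req$target_cell_type)
  }
  take <- pool[sample.int(length(pool), req$n_cells, replace = TRUE)]
  emb <- encode(state, ds$modality_1$values[take, , drop = FALSE],
                ds$modality_2$values[take, , drop = FALSE])
  z <- emb$z
  if (req$noise_scale > 0) {
    ref <- encode(state, ds$modality_1$values[pool, , drop = FALSE],
                  ds$modality_2$values[pool, , drop = FALSE])$z
    sd_dim <- apply(ref, 2, stats::sd)
    sd_dim[!is.finite(sd_dim)] <- 0
    z <- z + matrix(stats::rnorm(length(z)), nrow(z)) *
      rep(req$noise_scale * sd_dim, each = nrow(z))
  }
  rec <- decode(state, z)
  to_om <- function(vals, slot) {
    om <- ds[[slot]]
    if (inverse_transform && om$modality %in% c("RNA", "ATAC"))
      vals <- round(pmax(expm1(vals), 0))
    omics_matrix(vals, om$feature_ids, om$modality)
  }
  paired_dataset(to_om(rec$x1_hat, "modality_1"),
                 to_om(rec$x2_hat, "modality_2"),
                 cell_ids = sprintf("sim_%05d", seq_len(req$n_cells)),
                 cell_labels = ds$cell_labels[take],
                 normalized = !inverse_transform)
}

#' Batch correction by reference-batch training
#'
#' Trains the model on a labeled reference batch only, then embeds and
#' classifies every query batch with the frozen model, projecting all batches
#' into the reference embedding space.
#'
#' @param reference a normalized, labeled [paired_dataset()] (the reference
#'   batch).
#' @param queries list of [paired_dataset()] objects sharing the reference
#'   feature space.
#' @param mcfg optional [model_config()].
#' @param tcfg a [train_config()].
#' @return list with `state`, `log`, and `queries`: per query a list with
#'   `embedding` and `labels` (+ `probabilities`).
#' @export
correct_batches <- function(reference, queries, mcfg = NULL,
                            tcfg = train_config()) {
  if (inherits(queries, "paired_dataset")) queries <- list(queries)
  fit <- train_scmomtf(reference, mcfg, tcfg)
  out <- lapply(queries, function(q) {
    pred <- predict_cell_types(fit$state, q)
    list(embedding = embed_cells(fit$state, q),
         labels = pred$labels, probabilities = pred$probabilities)
  })
  list(state = fit$state, log = fit$log, queries = out)
}

#' Two-dimensional embedding scatter (thin plotting hook)
#'
#' Projects the cell embedding onto its first two principal components and
#' draws a base-graphics scatter colored by label.
#'
#' @param z embedding matrix or `cell_embedding`.
#' @param labels optional labels used for coloring.
#' @param ... passed to [graphics::plot()].
#' @export
plot_embedding <- function(z, labels = NULL, ...) {
  if (inherits(z, "cell_embedding")) z <- z$z
  pc <- stats::prcomp(z, rank. = 2)$x
  col <- if (is.null(labels)) 1 else as.integer(factor(labels))
  graphics::plot(pc, col = col, pch = 16, cex = 0.6,
                 xlab = "PC1", ylab = "PC2", ...)
  if (!is.null(labels))
    graphics::legend("topright", legend = levels(factor(labels)),
                     col = seq_along(levels(factor(labels))), pch = 16,
                     cex = 0.7, bty = "n")
  invisible(pc)
}
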