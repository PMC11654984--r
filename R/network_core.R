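#' Model configuration
#'
#' Architecture hyperparameters of the multitask network. The two quantities
#' fixed by the method are the per-modality embedding width (150) and the cell
#' embedding width (64); layer counts and hidden widths are implementation
#' choices, kept shallow deliberately so that feature attribution remains
#' tractable and interpretable.
#'
#' @param v1,v2 input feature counts of the two modalities.
#' @param n_classes number of cell types C (>= 2).
#' @param modality_embed_dim width of each modality embedding h (default 150).
#' @param cell_embed_dim width of the cell embedding z (default 64).
#' @param enc_hidden hidden width of each modality encoder (default 256).
#' @param cell_hidden hidden width of the cell encoder (default 128).
#' @param dec_hidden hidden width of each decoder (default 128).
#' @param dis_hidden two hidden widths of each discriminator.
#' @param label_smoothing_alpha label-smoothing alpha in [0, 1).
#' @param classification_weight gamma >= 0 weighting the classification loss
#'   in the total objective (default 8). The reconstruction term sums squared
#'   error over thousands of features while the cross entropy is order one,
#'   so gamma well above 1 is needed before the classification task shapes
#'   the shared embedding.
#' @param seed integer seed for parameter initialization.
#' @return list of class `model_config`.
#' @export
model_config <- function(v1, v2, n_classes,
                         modality_embed_dim = 150, cell_embed_dim = 64,
                         enc_hidden = 256, cell_hidden = 128, dec_hidden = 128,
                         dis_hidden = c(64, 64),
                         label_smoothing_alpha = 0.1,
                         classification_weight = 8,
                         seed = 0) {
  dims <- c(v1, v2, n_classes, modality_embed_dim, cell_embed_dim,
            enc_hidden, cell_hidden, dec_hidden, dis_hidden)
  if (any(dims <= 0) || any(dims != round(dims)))
    stop("all dimensions must be positive integers")
  if (n_classes < 2) stop("n_classes must be >= 2")
  if (label_smoothing_alpha < 0 || label_smoothing_alpha >= 1)
    stop("label_smoothing_alpha must be in [0, 1)")
  if (classification_weight < 0)
    stop("classification_weight must be nonnegative")
  structure(list(v1 = v1, v2 = v2, n_classes = n_classes,
                 modality_embed_dim = modality_embed_dim,
                 cell_embed_dim = cell_embed_dim,
                 enc_hidden = enc_hidden, cell_hidden = cell_hidden,
                 dec_hidden = dec_hidden, dis_hidden = dis_hidden,
                 label_smoothing_alpha = label_smoothing_alpha,
                 classification_weight = classification_weight,
                 seed = seed),
            class = "model_config")
}

#' Initialize the multitask model
#'
#' Builds the two modality encoders, the cell encoder, two decoders, two
#' discriminators and the classifier head with seeded Glorot-normal weights.
#' Two calls with the same config produce parameter-wise identical states.
#'
#' @param cfg a [model_config()].
#' @return list of class `scmomtf_model` holding all sub-networks, the config
#'   and a training step counter.
#' @export
init_model <- function(cfg) {
  stopifnot(inherits(cfg, "model_config"))
  set.seed(cfg$seed)
  enc <- function(v) nn_net(nn_dense(v, cfg$enc_hidden),
                            nn_layernorm(cfg$enc_hidden), nn_act("elu"),
                            nn_dense(cfg$enc_hidden, cfg$modality_embed_dim))
  dec <- function(v) nn_net(nn_dense(cfg$cell_embed_dim, cfg$dec_hidden),
                            nn_layernorm(cfg$dec_hidden), nn_act("elu"),
                            nn_dense(cfg$dec_hidden, v))
  dis <- function(v) nn_net(nn_dense(v, cfg$dis_hidden[1]), nn_act("elu"),
                            nn_dense(cfg$dis_hidden[1], cfg$dis_hidden[2]),
                            nn_act("elu"),
                            nn_dense(cfg$dis_hidden[2], 1), nn_act("sigmoid"))
  state <- list(
    enc1 = enc(cfg$v1), enc2 = enc(cfg$v2),
    enc_cell = nn_net(nn_dense(2 * cfg$modality_embed_dim, cfg$cell_hidden),
                      nn_layernorm(cfg$cell_hidden), nn_act("elu"),
                      nn_dense(cfg$cell_hidden, cfg$cell_embed_dim)),
    dec1 = dec(cfg$v1), dec2 = dec(cfg$v2),
    dis1 = dis(cfg$v1), dis2 = dis(cfg$v2),
    clf = nn_net(nn_dense(cfg$cell_embed_dim, cfg$n_classes)),
    config = cfg, step = 0L,
    feature_ids = NULL, classes = NULL)
  class(state) <- "scmomtf_model"
  state
}

#' @export
print.scmomtf_model <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(paste0("<scmomtf_model> %d + %d features -> %d-dim embedding, ",
                     "%d classes; %d training steps\n"),
              cfg$v1, cfg$v2, cfg$cell_embed_dim, cfg$n_classes, x$step))
  invisible(x)
}

as_batch <- function(x, v, what) {
  x <- as.matrix(x)
  if (ncol(x) != v)
    stop(sprintf("%s has %d columns, expected %d", what, ncol(x), v))
  storage.mode(x) <- "double"
  x
}

#' Encode a batch of cells into modality and cell embeddings
#'
#' Each modality is mapped through its own encoder to a modality embedding
#' h(m); the concatenation of the two is mapped by the cell encoder to the
#' final cell embedding z. Deterministic (inference mode): no dropout, and
#' normalization is per cell.
#'
#' @param state a [init_model()] state.
#' @param x1,x2 row-aligned batch matrices with `v1` / `v2` columns.
#' @return list of class `cell_embedding` with `z`, `h1`, `h2`.
#' @export
encode <- function(state, x1, x2) {
  cfg <- state$config
  x1 <- as_batch(x1, cfg$v1, "modality 1 batch")
  x2 <- as_batch(x2, cfg$v2, "modality 2 batch")
  if (nrow(x1) != nrow(x2)) stop("modality batches are not row-aligned")
  h1 <- nn_forward(state$enc1, x1)
  h2 <- nn_forward(state$enc2, x2)
  z <- nn_forward(state$enc_cell, cbind(h1, h2))
  structure(list(z = z, h1 = h1, h2 = h2), class = "cell_embedding")
}

#' Decode cell embeddings back to both feature spaces
#'
#' @param state a [init_model()] state.
#' @param z matrix with `cell_embed_dim` columns (or a `cell_embedding`).
#' @return list `(x1_hat, x2_hat)` of reconstructions with `v1` / `v2` columns.
#' @export
decode <- function(state, z) {
  if (inherits(z, "cell_embedding")) z <- z$z
  z <- as_batch(z, state$config$cell_embed_dim, "cell embedding")
  list(x1_hat = nn_forward(state$dec1, z),
       x2_hat = nn_forward(state$dec2, z))
}

#' Discriminator probability that a batch is real
#'
#' @param state a [init_model()] state.
#' @param x batch matrix in the feature space of `modality`.
#' @param modality 1 or 2.
#' @return numeric vector in [0, 1], one entry per row of `x`.
#' @export
discriminate <- function(state, x, modality) {
  if (!modality %in% c(1, 2)) stop("modality must be 1 or 2")
  v <- if (modality == 1) state$config$v1 else state$config$v2
  x <- as_batch(x, v, sprintf("modality %d batch", modality))
  net <- if (modality == 1) state$dis1 else state$dis2
  as.vector(nn_forward(net, x))
}

#' Class probabilities from cell embeddings
#'
#' A single affine layer followed by softmax: each row is a probability
#' distribution over the C cell types.
#'
#' @param state a [init_model()] state.
#' @param z matrix with `cell_embed_dim` columns (or a `cell_embedding`).
#' @return n x C matrix of class probabilities (rows sum to 1).
#' @export
classify <- function(state, z) {
  if (inherits(z, "cell_embedding")) z <- z$z
  z <- as_batch(z, state$config$cell_embed_dim, "cell embedding")
  p <- row_softmax(nn_forward(state$clf, z))
  colnames(p) <- state$classes
  p
}

#' Save / load a trained model
#'
#' Checkpoints are single-file serialized R objects holding every parameter
#' tensor, the config, and the training-time feature vocabulary.
#'
#' @param state a `scmomtf_model`.
#' @param path file path.
#' @return `load_model` returns the restored model.
#' @export
save_model <- function(state, path) {
  stopifnot(inherits(state, "scmomtf_model"))
  saveRDS(state, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  state <- readRDS(path)
  if (!inherits(state, "scmomtf_model")) stop("not a scmomtf checkpoint: ", path)
  state
}
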