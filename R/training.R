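#' Training configuration
#'
#' Optimization settings for the joint adversarial multitask loop. The
#' method itself fixes none of these; defaults are chosen so
#' that desk-scale datasets train in seconds to a few minutes on one CPU.
#'
#' @param epochs number of passes over the data (default 100).
#' @param batch_size minibatch size (default 64).
#' @param lr_generator Adam learning rate for encoders, decoders and the
#'   classifier head (default 1e-3).
#' @param lr_discriminator Adam learning rate for the discriminators
#'   (default 1e-4).
#' @param gamma,alpha optional overrides of the model config's
#'   classification weight / label smoothing (NULL = inherit).
#' @param input_dropout fraction of input features zeroed (with inverted
#'   scaling) in each training minibatch, per cell (default 0.2). The
#'   reconstruction target stays the clean input, making the autoencoder
#'   denoising; this is what forces the encoder to rely on redundant
#'   biological signal (marker programs) rather than memorizing individual
#'   cells, and it is essential for generalization on rare populations.
#'   Inference never applies dropout.
#' @param class_balance tempering exponent in [0, 1] for class-balanced
#'   minibatch sampling (default 1). Each epoch draws cells with replacement
#'   with probability proportional to `(1 / class frequency)^class_balance`,
#'   so rare cell types are revisited (under fresh dropout corruption) often
#'   enough for their marker program to be learned rather than memorized; 0
#'   restores plain epoch shuffling.
#' @param within_class_mix probability in [0, 1] that a sampled training cell
#'   is replaced by a convex combination of itself and another cell of the
#'   same type (mixing weight uniform; default 0.5). Interpolation averages
#'   out cell-specific noise while preserving the type's shared expression
#'   program, which keeps small populations from being memorized cell by
#'   cell; 0 disables it.
#' @param input_noise scale of additive Gaussian noise applied to training
#'   inputs, as a multiple of each feature's standard deviation across the
#'   training data (default 1). Fresh noise per presentation makes
#'   cell-specific noise directions useless as classification shortcuts, so
#'   the network must key on the stable type programs; essential for
#'   generalizing types represented by a handful of cells. 0 disables it.
#'   Reconstruction targets and the discriminators' real branch always see
#'   clean data (denoising setup).
#' @param seed integer seed for shuffling (model init is seeded separately by
#'   [model_config()]).
#' @param device only `"cpu"` is supported.
#' @param verbose print the loss bundle every `log_every` epochs.
#' @param log_every epoch interval for verbose output.
#' @return list of class `train_config`.
#' @export
train_config <- function(epochs = 100, batch_size = 64,
                         lr_generator = 1e-3, lr_discriminator = 1e-4,
                         gamma = NULL, alpha = NULL, input_dropout = 0.2,
                         class_balance = 1, within_class_mix = 0.5,
                         input_noise = 1, seed = 0, device = "cpu",
                         verbose = FALSE, log_every = 10) {
  if (epochs < 1 || batch_size < 1) stop("epochs and batch_size must be positive")
  if (lr_generator <= 0 || lr_discriminator <= 0) stop("learning rates must be positive")
  if (input_dropout < 0 || input_dropout >= 1) stop("input_dropout must be in [0, 1)")
  if (class_balance < 0 || class_balance > 1) stop("class_balance must be in [0, 1]")
  if (within_class_mix < 0 || within_class_mix > 1)
    stop("within_class_mix must be in [0, 1]")
  if (input_noise < 0) stop("input_noise must be nonnegative")
  if (device != "cpu") stop("only device = 'cpu' is supported")
  structure(list(epochs = epochs, batch_size = batch_size,
                 lr_generator = lr_generator,
                 lr_discriminator = lr_discriminator,
                 gamma = gamma, alpha = alpha, input_dropout = input_dropout,
                 class_balance = class_balance,
                 within_class_mix = within_class_mix,
                 input_noise = input_noise, seed = seed,
                 device = device,
                 verbose = verbose, log_every = log_every),
            class = "train_config")
}

#' Train the multitask model
#'
#' Joint adversarial training on a preprocessed (normalized, feature-selected)
#' labeled dataset. Each minibatch takes two alternating steps: (A) the two
#' discriminators minimize the least-squares discriminator loss with the
#' generator frozen; (B) encoders, decoders and classifier minimize
#' `L_res + gamma * L_cls + L_gen` with the discriminators frozen. The epoch
#' log records every loss component. Fully deterministic for fixed seeds on
#' CPU.
#'
#' @param ds a normalized, labeled [paired_dataset()].
#' @param mcfg a [model_config()] (or NULL to build one from `ds` defaults).
#' @param tcfg a [train_config()].
#' @return list with `state` (trained `scmomtf_model`) and `log`
#'   (data.frame: epoch, l_res, l_cls, l_gen, l_dis, l_total).
#' @export
train_scmomtf <- function(ds, mcfg = NULL, tcfg = train_config()) {
  stopifnot(inherits(ds, "paired_dataset"), inherits(tcfg, "train_config"))
  if (is.null(ds$cell_labels))
    stop("training requires cell labels; unsupervised operation is not supported")
  if (!isTRUE(ds$normalized))
    warning("dataset is not flagged as normalized; training on raw counts is not recommended")
  codec <- label_codec(ds$cell_labels)
  if (is.null(mcfg))
    mcfg <- model_config(v1 = length(ds$modality_1$feature_ids),
                         v2 = length(ds$modality_2$feature_ids),
                         n_classes = codec$n_classes)
  stopifnot(inherits(mcfg, "model_config"))
  if (mcfg$n_classes != codec$n_classes)
    stop("model config declares ", mcfg$n_classes, " classes but data has ",
         codec$n_classes)
  gamma <- if (!is.null(tcfg$gamma)) tcfg$gamma else mcfg$classification_weight
  alpha <- if (!is.null(tcfg$alpha)) tcfg$alpha else mcfg$label_smoothing_alpha
  if (gamma < 0) stop("gamma must be nonnegative")

  state <- init_model(mcfg)
  state$feature_ids <- list(modality_1 = ds$modality_1$feature_ids,
                            modality_2 = ds$modality_2$feature_ids)
  state$classes <- codec$classes

  x1 <- ds$modality_1$values
  x2 <- ds$modality_2$values
  y_code <- encode_labels(codec, ds$cell_labels)
  n <- ds$n_cells
  C <- codec$n_classes

  opt <- list(
    enc1 = adam_init(state$enc1, tcfg$lr_generator),
    enc2 = adam_init(state$enc2, tcfg$lr_generator),
    enc_cell = adam_init(state$enc_cell, tcfg$lr_generator),
    dec1 = adam_init(state$dec1, tcfg$lr_generator),
    dec2 = adam_init(state$dec2, tcfg$lr_generator),
    clf = adam_init(state$clf, tcfg$lr_generator),
    dis1 = adam_init(state$dis1, tcfg$lr_discriminator),
    dis2 = adam_init(state$dis2, tcfg$lr_discriminator))
  upd <- function(name, grads) {
    res <- adam_step(state[[name]], grads, opt[[name]])
    state[[name]] <<- res$net
    opt[[name]] <<- res$opt
  }

  same_class_idx <- split(seq_len(n), y_code)
  noise_sc <- if (is.null(tcfg$input_noise)) 0 else tcfg$input_noise
  if (noise_sc > 0) {
    sd1 <- noise_sc * apply(x1, 2, stats::sd)
    sd2 <- noise_sc * apply(x2, 2, stats::sd)
  }
  cb <- if (is.null(tcfg$class_balance)) 0 else tcfg$class_balance
  cell_w <- if (cb > 0) {
    freq <- table(y_code)[as.character(y_code)] / n
    as.vector((1 / freq)^cb)
  }

  set.seed(tcfg$seed)
  log <- vector("list", tcfg$epochs)
  for (epoch in seq_len(tcfg$epochs)) {
    ord <- if (cb > 0) sample.int(n, n, replace = TRUE, prob = cell_w)
           else sample.int(n)
    starts <- seq(1, n, by = tcfg$batch_size)
    acc <- c(l_res = 0, l_cls = 0, l_gen = 0, l_dis = 0)
    for (s in starts) {
      idx <- ord[s:min(s + tcfg$batch_size - 1, n)]
      nb <- length(idx)
      b1 <- x1[idx, , drop = FALSE]
      b2 <- x2[idx, , drop = FALSE]
      y_ls <- smooth_labels(one_hot(y_code[idx], C), alpha, C)

      # within-class interpolation (labels unchanged: partners share the type)
      wcm <- if (is.null(tcfg$within_class_mix)) 0 else tcfg$within_class_mix
      if (wcm > 0) {
        mixed <- which(stats::runif(nb) < wcm)
        if (length(mixed) > 0) {
          partner <- vapply(idx[mixed], function(i) {
            pool <- same_class_idx[[y_code[i]]]
            pool[sample.int(length(pool), 1)]
          }, 0L)
          lam <- stats::runif(length(mixed))
          b1[mixed, ] <- lam * b1[mixed, , drop = FALSE] +
            (1 - lam) * x1[partner, , drop = FALSE]
          b2[mixed, ] <- lam * b2[mixed, , drop = FALSE] +
            (1 - lam) * x2[partner, , drop = FALSE]
        }
      }

      # denoising corruption (additive feature noise, then dropout): encoders
      # see corrupted inputs, the reconstruction target and the
      # discriminators' real branch stay clean
      in1 <- b1; in2 <- b2
      if (noise_sc > 0) {
        in1 <- in1 + matrix(stats::rnorm(nb * ncol(b1)), nb) *
          rep(sd1, each = nb)
        in2 <- in2 + matrix(stats::rnorm(nb * ncol(b2)), nb) *
          rep(sd2, each = nb)
      }
      if (tcfg$input_dropout > 0) {
        keep <- 1 - tcfg$input_dropout
        in1 <- in1 * (matrix(stats::runif(nb * ncol(b1)), nb) < keep) / keep
        in2 <- in2 * (matrix(stats::runif(nb * ncol(b2)), nb) < keep) / keep
      }

      # ---- forward through the generator (cached for step B) ----
      f_e1 <- nn_forward(state$enc1, in1, keep_cache = TRUE)
      f_e2 <- nn_forward(state$enc2, in2, keep_cache = TRUE)
      h <- cbind(f_e1$out, f_e2$out)
      f_ec <- nn_forward(state$enc_cell, h, keep_cache = TRUE)
      z <- f_ec$out
      f_d1 <- nn_forward(state$dec1, z, keep_cache = TRUE)
      f_d2 <- nn_forward(state$dec2, z, keep_cache = TRUE)
      xh1 <- f_d1$out
      xh2 <- f_d2$out

      # ---- step A: discriminators (generator frozen) ----
      for (m in 1:2) {
        dnm <- paste0("dis", m)
        fake <- if (m == 1) xh1 else xh2
        real <- if (m == 1) b1 else b2
        ff <- nn_forward(state[[dnm]], fake, keep_cache = TRUE)
        fr <- nn_forward(state[[dnm]], real, keep_cache = TRUE)
        # d/dD of (1/(nM)) [sum D(fake)^2 + sum (D(real)-1)^2]
        gf <- nn_backward(state[[dnm]], ff$caches, 2 * ff$out / (nb * 2))
        gr <- nn_backward(state[[dnm]], fr$caches, 2 * (fr$out - 1) / (nb * 2))
        g <- mapply(function(a, b) {
          if (is.null(a)) return(NULL)
          mapply(`+`, a, b, SIMPLIFY = FALSE)
        }, gf$grads, gr$grads, SIMPLIFY = FALSE)
        upd(dnm, g)
      }

      # ---- step B: generator + classifier (discriminators frozen) ----
      # reconstruction term
      d_xh1 <- 2 * (xh1 - b1) / (nb * 2)
      d_xh2 <- 2 * (xh2 - b2) / (nb * 2)
      # generator (LSGAN) term through the frozen discriminators
      fd1 <- nn_forward(state$dis1, xh1, keep_cache = TRUE)
      fd2 <- nn_forward(state$dis2, xh2, keep_cache = TRUE)
      d_xh1 <- d_xh1 + nn_backward(state$dis1, fd1$caches,
                                   2 * (fd1$out - 1) / (nb * 2))$dx
      d_xh2 <- d_xh2 + nn_backward(state$dis2, fd2$caches,
                                   2 * (fd2$out - 1) / (nb * 2))$dx
      back_d1 <- nn_backward(state$dec1, f_d1$caches, d_xh1)
      back_d2 <- nn_backward(state$dec2, f_d2$caches, d_xh2)
      dz <- back_d1$dx + back_d2$dx
      # classification term: softmax cross-entropy gradient at the logits
      f_clf <- nn_forward(state$clf, z, keep_cache = TRUE)
      probs <- row_softmax(f_clf$out)
      l_cls <- classification_loss(y_ls, probs)
      if (gamma > 0) {
        back_clf <- nn_backward(state$clf, f_clf$caches,
                                gamma * (probs - y_ls) / nb)
        dz <- dz + back_clf$dx
        upd("clf", back_clf$grads)
      }
      back_ec <- nn_backward(state$enc_cell, f_ec$caches, dz)
      k <- ncol(f_e1$out)
      back_e1 <- nn_backward(state$enc1, f_e1$caches,
                             back_ec$dx[, seq_len(k), drop = FALSE])
      back_e2 <- nn_backward(state$enc2, f_e2$caches,
                             back_ec$dx[, k + seq_len(k), drop = FALSE])
      upd("dec1", back_d1$grads); upd("dec2", back_d2$grads)
      upd("enc_cell", back_ec$grads)
      upd("enc1", back_e1$grads); upd("enc2", back_e2$grads)

      # ---- bookkeeping (losses at the pre-update parameters) ----
      l_res <- reconstruction_loss(list(b1, b2), list(xh1, xh2))
      l_gen <- generator_loss(list(as.vector(fd1$out), as.vector(fd2$out)))
      l_dis <- discriminator_loss(
        list(as.vector(fd1$out), as.vector(fd2$out)),
        list(discriminate(state, b1, 1), discriminate(state, b2, 2)))
      if (!all(is.finite(c(l_res, l_cls, l_gen, l_dis))))
        stop(sprintf("non-finite loss at epoch %d (L_res=%g, L_cls=%g, L_gen=%g, L_dis=%g); try a lower learning rate",
                     epoch, l_res, l_cls, l_gen, l_dis))
      acc <- acc + c(l_res, l_cls, l_gen, l_dis) * nb
      state$step <- state$step + 1L
    }
    acc <- acc / n
    bundle <- total_loss(acc[["l_res"]], acc[["l_cls"]], acc[["l_gen"]],
                         acc[["l_dis"]], gamma)
    log[[epoch]] <- data.frame(epoch = epoch, l_res = bundle$l_res,
                               l_cls = bundle$l_cls, l_gen = bundle$l_gen,
                               l_dis = bundle$l_dis, l_total = bundle$l_total)
    if (tcfg$verbose && (epoch %% tcfg$log_every == 0 || epoch == 1)) {
      cat(sprintf("epoch %3d  ", epoch)); print(bundle)
    }
  }
  list(state = state, log = do.call(rbind, log))
}

#' Write a training log to CSV
#'
#' @param log data.frame returned by [train_scmomtf()].
#' @param path output CSV path.
#' @export
write_training_log <- function(log, path) {
  data.table::fwrite(data.table::as.data.table(log), path)
  invisible(path)
}
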