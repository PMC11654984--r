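# Training objectives. All losses are minibatch means: sums over cells and
# modalities are divided by n*M (n = cells in the batch, M = 2 modalities),
# the standard stochastic estimator of the full-data objective.

.prob_eps <- 1e-8

#' Reconstruction loss
#'
#' Mean over cells and modalities of the squared Euclidean distance between
#' the original and reconstructed feature vectors:
#' `(1/(nM)) * sum_i sum_m ||xhat_i^(m) - x_i^(m)||^2`.
#'
#' @param x list of original batch matrices, one per modality.
#' @param x_hat list of matched reconstructions.
#' @return nonnegative scalar.
#' @export
reconstruction_loss <- function(x, x_hat) {
  if (!is.list(x)) x <- list(x)
  if (!is.list(x_hat)) x_hat <- list(x_hat)
  if (length(x) != length(x_hat)) stop("modality count mismatch")
  n <- nrow(as.matrix(x[[1]]))
  M <- length(x)
  total <- 0
  for (m in seq_len(M)) {
    a <- as.matrix(x[[m]]); b <- as.matrix(x_hat[[m]])
    if (!all(dim(a) == dim(b))) stop("shape mismatch in modality ", m)
    total <- total + sum((b - a)^2)
  }
  total / (n * M)
}

#' Label smoothing
#'
#' Replaces one-hot targets with `(1 - alpha) * y + alpha / C`; every row
#' still sums to exactly 1.
#'
#' @param y_real one-hot matrix (n x C).
#' @param alpha smoothing parameter in [0, 1).
#' @param C number of classes (defaults to `ncol(y_real)`).
#' @return smoothed label matrix.
#' @export
smooth_labels <- function(y_real, alpha, C = ncol(y_real)) {
  if (alpha < 0 || alpha >= 1) stop("alpha must be in [0, 1)")
  y_real <- as.matrix(y_real)
  (1 - alpha) * y_real + alpha / C
}

#' Classification loss (cross entropy with smoothed labels)
#'
#' Mean over cells of `-sum_c y_ls^(c) * log y_pred^(c)`; predictions are
#' clamped at 1e-8 inside the log.
#'
#' @param y_ls smoothed label matrix (rows sum to 1).
#' @param y_pred class-probability matrix (rows sum to 1).
#' @return scalar (zero only for exact one-hot agreement at alpha = 0).
#' @export
classification_loss <- function(y_ls, y_pred) {
  y_ls <- as.matrix(y_ls); y_pred <- as.matrix(y_pred)
  if (!all(dim(y_ls) == dim(y_pred))) stop("shape mismatch")
  if (any(y_pred < 0)) stop("negative predicted probabilities")
  mean(-rowSums(y_ls * log(pmax(y_pred, .prob_eps))))
}

#' Generator loss (least squares)
#'
#' `(1/(nM)) * sum ||Dis^(m)(xhat_i^(m)) - 1||^2`: the generator is rewarded
#' when the discriminators score its reconstructions as real.
#'
#' @param dis_on_fake list (per modality) of discriminator outputs on
#'   reconstructions, each a vector in [0, 1].
#' @return nonnegative scalar.
#' @export
generator_loss <- function(dis_on_fake) {
  if (!is.list(dis_on_fake)) dis_on_fake <- list(dis_on_fake)
  n <- length(dis_on_fake[[1]])
  M <- length(dis_on_fake)
  sum(vapply(dis_on_fake, function(d) sum((d - 1)^2), 0)) / (n * M)
}

#' Discriminator loss (least squares)
#'
#' `(1/(nM)) * sum ||Dis(xhat)||^2 + (1/(nM)) * sum ||Dis(x) - 1||^2`: the
#' discriminators are rewarded for scoring reconstructions as fake and real
#' data as real.
#'
#' @param dis_on_fake,dis_on_real lists (per modality) of discriminator
#'   outputs on reconstructions / real data.
#' @return nonnegative scalar.
#' @export
discriminator_loss <- function(dis_on_fake, dis_on_real) {
  if (!is.list(dis_on_fake)) dis_on_fake <- list(dis_on_fake)
  if (!is.list(dis_on_real)) dis_on_real <- list(dis_on_real)
  if (length(dis_on_fake) != length(dis_on_real))
    stop("modality count mismatch")
  n <- length(dis_on_fake[[1]])
  M <- length(dis_on_fake)
  fake <- sum(vapply(dis_on_fake, function(d) sum(d^2), 0))
  real <- sum(vapply(dis_on_real, function(d) sum((d - 1)^2), 0))
  (fake + real) / (n * M)
}

#' Combine loss components into the total objective
#'
#' `L_total = L_res + gamma * L_cls + L_gen + L_dis`. The raw (unweighted)
#' classification loss is kept alongside so logs show both.
#'
#' @param l_res,l_cls,l_gen,l_dis component values.
#' @param gamma nonnegative classification weight.
#' @return list of class `loss_bundle`.
#' @export
total_loss <- function(l_res, l_cls, l_gen, l_dis, gamma = 1) {
  if (gamma < 0) stop("gamma must be nonnegative")
  structure(list(l_res = l_res, l_cls = l_cls, l_gen = l_gen, l_dis = l_dis,
                 gamma = gamma,
                 l_total = l_res + gamma * l_cls + l_gen + l_dis),
            class = "loss_bundle")
}

#' @export
print.loss_bundle <- function(x, ...) {
  cat(sprintf("L_res=%.4g  L_cls=%.4g  L_gen=%.4g  L_dis=%.4g  L_total=%.4g\n",
              x$l_res, x$l_cls, x$l_gen, x$l_dis, x$l_total))
  invisible(x)
}
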