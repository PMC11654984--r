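# Dense feed-forward building blocks with explicit reverse-mode gradients.
# Parameters are plain numeric matrices/vectors inside lists, so model states
# serialize with saveRDS() and CPU runs are bit-reproducible under set.seed().

nn_dense <- function(n_in, n_out) {
  # Glorot-style normal init; biases start at zero.
  sd <- sqrt(2 / (n_in + n_out))
  list(type = "dense",
       W = matrix(stats::rnorm(n_in * n_out, 0, sd), n_in, n_out),
       b = numeric(n_out))
}

nn_layernorm <- function(width) {
  list(type = "layernorm", gamma = rep(1, width), beta = numeric(width))
}

nn_act <- function(kind) {
  stopifnot(kind %in% c("elu", "sigmoid"))
  list(type = kind)
}

nn_net <- function(...) list(layers = list(...))

add_row_vec <- function(m, v) m + rep(v, each = nrow(m))

.ln_eps <- 1e-5

layer_forward <- function(layer, x) {
  switch(layer$type,
    dense = {
      y <- x %*% layer$W
      add_bias_inplace(y, layer$b)  # y is a fresh matmul result
      list(y = y, cache = list(x = x))
    },
    layernorm = {
      mu <- rowMeans(x)
      xc <- x - mu
      v <- rowMeans(xc * xc)
      inv <- 1 / sqrt(v + .ln_eps)
      xhat <- xc * inv
      y <- add_row_vec(sweep(xhat, 2, layer$gamma, `*`), layer$beta)
      list(y = y, cache = list(xhat = xhat, inv = inv))
    },
    elu = {
      y <- elu_forward(x)
      list(y = y, cache = list(y = y))
    },
    sigmoid = {
      y <- stats::plogis(x)
      list(y = y, cache = list(y = y))
    })
}

layer_backward <- function(layer, cache, dy) {
  switch(layer$type,
    dense = {
      list(dx = dy %*% t(layer$W),
           grads = list(W = crossprod(cache$x, dy), b = colSums(dy)))
    },
    layernorm = {
      xhat <- cache$xhat
      dxhat <- sweep(dy, 2, layer$gamma, `*`)
      dx <- cache$inv * (dxhat - rowMeans(dxhat) - xhat * rowMeans(dxhat * xhat))
      list(dx = dx,
           grads = list(gamma = colSums(dy * xhat), beta = colSums(dy)))
    },
    elu = {
      list(dx = elu_backward(dy, cache$y), grads = NULL)
    },
    sigmoid = {
      list(dx = dy * cache$y * (1 - cache$y), grads = NULL)
    })
}

#' @noRd
nn_forward <- function(net, x, keep_cache = FALSE) {
  caches <- if (keep_cache) vector("list", length(net$layers))
  for (i in seq_along(net$layers)) {
    out <- layer_forward(net$layers[[i]], x)
    x <- out$y
    if (keep_cache) caches[[i]] <- out$cache
  }
  if (keep_cache) list(out = x, caches = caches) else x
}

# Returns gradient wrt the network input plus per-layer parameter gradients.
nn_backward <- function(net, caches, dy) {
  grads <- vector("list", length(net$layers))
  for (i in rev(seq_along(net$layers))) {
    back <- layer_backward(net$layers[[i]], caches[[i]], dy)
    dy <- back$dx
    grads[i] <- list(back$grads)  # [[<-]] with NULL would drop the slot
  }
  list(dx = dy, grads = grads)
}

# ---- Adam ------------------------------------------------------------------

adam_init <- function(net, lr, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  zeros_like <- function(p) lapply(p, function(v) v * 0)
  state <- lapply(net$layers, function(l) {
    p <- l[setdiff(names(l), "type")]
    if (length(p) == 0) NULL else list(m = zeros_like(p), v = zeros_like(p))
  })
  list(state = state, lr = lr, beta1 = beta1, beta2 = beta2, eps = eps, t = 0)
}

adam_step <- function(net, grads, opt) {
  # Parameters and moment estimates are updated in place by the compiled
  # kernel; net/opt own their tensors (allocated fresh at training start), so
  # no external object can alias them.
  opt$t <- opt$t + 1
  corr1 <- 1 - opt$beta1^opt$t
  corr2 <- 1 - opt$beta2^opt$t
  for (i in seq_along(net$layers)) {
    g <- grads[[i]]
    if (is.null(g)) next
    st <- opt$state[[i]]
    for (nm in names(g)) {
      adam_update_inplace(net$layers[[i]][[nm]], st$m[[nm]], st$v[[nm]],
                          g[[nm]], opt$lr, opt$beta1, opt$beta2, opt$eps,
                          corr1, corr2)
    }
  }
  list(net = net, opt = opt)
}

row_softmax <- function(logits) {
  z <- logits - apply(logits, 1, max)
  e <- exp(z)
  e / rowSums(e)
}
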