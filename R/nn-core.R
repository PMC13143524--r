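# Minimal neural-network engine: layers as mutable environments with
# explicit forward / backward passes, driven by BLAS matrix products.
#
# Conventions
#   dense tensors:  N x D matrices (rows = samples)
#   conv tensors:   C x H x W x N arrays, channel-first (see nn-conv.R)
# Each layer caches what its backward pass needs during forward; backward
# accumulates parameter gradients into the layer's param environments and
# returns the gradient w.r.t. its input. All randomness (init, dropout)
# draws from R's global RNG so a single seed fixes the whole run.

new_param <- function(value, name = "") {
  p <- new.env(parent = emptyenv())
  p$value <- value
  p$grad <- value * 0
  p$name <- name
  class(p) <- "nn_param"
  p
}

n_values <- function(p) length(p$value)

new_layer <- function(type, fields = list()) {
  e <- new.env(parent = emptyenv())
  for (n in names(fields)) assign(n, fields[[n]], envir = e)
  class(e) <- c(paste0("nn_", type), "nn_layer")
  e
}

nn_forward <- function(layer, x, training = FALSE) UseMethod("nn_forward")
nn_backward <- function(layer, dout) UseMethod("nn_backward")
nn_params <- function(layer) UseMethod("nn_params")
#' @export
nn_params.default <- function(layer) list()

# He-normal init (fan_in) for ReLU-family layers
init_he <- function(fan_in, n) stats::rnorm(n, 0, sqrt(2 / fan_in))
# Glorot-uniform init for linear projections
init_glorot <- function(fan_in, fan_out, n) {
  lim <- sqrt(6 / (fan_in + fan_out))
  stats::runif(n, -lim, lim)
}

## ---- linear ----------------------------------------------------------------

nn_linear <- function(in_dim, out_dim, bias = TRUE, init = c("he", "glorot")) {
  init <- match.arg(init)
  w <- if (init == "he") init_he(in_dim, in_dim * out_dim)
       else init_glorot(in_dim, out_dim, in_dim * out_dim)
  new_layer("linear", list(
    W = new_param(matrix(w, in_dim, out_dim), "W"),
    b = if (bias) new_param(numeric(out_dim), "b") else NULL,
    in_dim = in_dim, out_dim = out_dim
  ))
}
#' @export
nn_forward.nn_linear <- function(layer, x, training = FALSE) {
  layer$x <- x
  y <- x %*% layer$W$value
  if (!is.null(layer$b)) y <- sweep(y, 2, layer$b$value, "+")
  y
}
#' @export
nn_backward.nn_linear <- function(layer, dout) {
  layer$W$grad <- layer$W$grad + crossprod(layer$x, dout)
  if (!is.null(layer$b)) layer$b$grad <- layer$b$grad + colSums(dout)
  dout %*% t(layer$W$value)
}
#' @export
nn_params.nn_linear <- function(layer) {
  if (is.null(layer$b)) list(layer$W) else list(layer$W, layer$b)
}

## ---- elementwise activations ----------------------------------------------

nn_relu <- function() new_layer("relu")
#' @export
nn_forward.nn_relu <- function(layer, x, training = FALSE) {
  layer$mask <- x > 0
  x * layer$mask
}
#' @export
nn_backward.nn_relu <- function(layer, dout) dout * layer$mask

nn_hardswish <- function() new_layer("hardswish")
#' @export
nn_forward.nn_hardswish <- function(layer, x, training = FALSE) {
  layer$x <- x
  x * pmin(pmax(x + 3, 0), 6) / 6
}
#' @export
nn_backward.nn_hardswish <- function(layer, dout) {
  x <- layer$x
  d <- ifelse(x <= -3, 0, ifelse(x >= 3, 1, (2 * x + 3) / 6))
  dout * d
}

nn_hardsigmoid <- function() new_layer("hardsigmoid")
#' @export
nn_forward.nn_hardsigmoid <- function(layer, x, training = FALSE) {
  layer$x <- x
  pmin(pmax(x + 3, 0), 6) / 6
}
#' @export
nn_backward.nn_hardsigmoid <- function(layer, dout) {
  dout * ifelse(layer$x > -3 & layer$x < 3, 1 / 6, 0)
}

nn_sigmoid <- function() new_layer("sigmoid")
#' @export
nn_forward.nn_sigmoid <- function(layer, x, training = FALSE) {
  layer$y <- 1 / (1 + exp(-x))
  layer$y
}
#' @export
nn_backward.nn_sigmoid <- function(layer, dout) dout * layer$y * (1 - layer$y)

## ---- dropout ---------------------------------------------------------------

nn_dropout <- function(p = 0.3) new_layer("dropout", list(p = p))
#' @export
nn_forward.nn_dropout <- function(layer, x, training = FALSE) {
  if (!training || layer$p <= 0) {
    layer$mask <- NULL
    return(x)
  }
  m <- array(stats::runif(length(x)) >= layer$p, dim(as.array(x))) / (1 - layer$p)
  layer$mask <- m
  x * m
}
#' @export
nn_backward.nn_dropout <- function(layer, dout) {
  if (is.null(layer$mask)) dout else dout * layer$mask
}

## ---- 1-d batch normalization (N x D) --------------------------------------

nn_bn1d <- function(dim, eps = 1e-5, momentum = 0.1) {
  new_layer("bn1d", list(
    gamma = new_param(rep(1, dim), "gamma"),
    beta = new_param(numeric(dim), "beta"),
    running_mean = numeric(dim), running_var = rep(1, dim),
    eps = eps, momentum = momentum, dim = dim
  ))
}
#' @export
nn_forward.nn_bn1d <- function(layer, x, training = FALSE) {
  if (training) {
    mu <- colMeans(x)
    v <- colMeans(x^2) - mu^2
    v <- pmax(v, 0)
    layer$running_mean <- (1 - layer$momentum) * layer$running_mean +
      layer$momentum * mu
    nb <- nrow(x)
    vu <- if (nb > 1) v * nb / (nb - 1) else v
    layer$running_var <- (1 - layer$momentum) * layer$running_var +
      layer$momentum * vu
    layer$sigma <- sqrt(v + layer$eps)
    layer$xhat <- sweep(sweep(x, 2, mu), 2, layer$sigma, "/")
    layer$train_mode <- TRUE
  } else {
    layer$sigma <- sqrt(layer$running_var + layer$eps)
    layer$xhat <- sweep(sweep(x, 2, layer$running_mean), 2, layer$sigma, "/")
    layer$train_mode <- FALSE
  }
  sweep(sweep(layer$xhat, 2, layer$gamma$value, "*"), 2, layer$beta$value, "+")
}
#' @export
nn_backward.nn_bn1d <- function(layer, dout) {
  layer$gamma$grad <- layer$gamma$grad + colSums(dout * layer$xhat)
  layer$beta$grad <- layer$beta$grad + colSums(dout)
  dxhat <- sweep(dout, 2, layer$gamma$value, "*")
  if (!isTRUE(layer$train_mode)) {
    return(sweep(dxhat, 2, layer$sigma, "/"))
  }
  m <- nrow(dout)
  t1 <- sweep(dxhat, 2, colMeans(dxhat))
  t2 <- sweep(layer$xhat, 2, colMeans(dxhat * layer$xhat), "*")
  sweep(t1 - t2, 2, layer$sigma, "/")
}
#' @export
nn_params.nn_bn1d <- function(layer) list(layer$gamma, layer$beta)

## ---- sequential container --------------------------------------------------

nn_seq <- function(...) new_layer("seq", list(layers = list(...)))
#' @export
nn_forward.nn_seq <- function(layer, x, training = FALSE) {
  for (l in layer$layers) x <- nn_forward(l, x, training)
  x
}
#' @export
nn_backward.nn_seq <- function(layer, dout) {
  for (l in rev(layer$layers)) dout <- nn_backward(l, dout)
  dout
}
#' @export
nn_params.nn_seq <- function(layer) {
  do.call(c, lapply(layer$layers, nn_params))
}

# residual add around an inner layer (used by inverted-residual blocks)
nn_residual <- function(inner) new_layer("residual", list(inner = inner))
#' @export
nn_forward.nn_residual <- function(layer, x, training = FALSE) {
  x + nn_forward(layer$inner, x, training)
}
#' @export
nn_backward.nn_residual <- function(layer, dout) {
  dout + nn_backward(layer$inner, dout)
}
#' @export
nn_params.nn_residual <- function(layer) nn_params(layer$inner)

# identity tap: records its forward activation and backward gradient
# (used to expose the last convolutional maps to Grad-CAM)
nn_tap <- function() new_layer("tap")
#' @export
nn_forward.nn_tap <- function(layer, x, training = FALSE) {
  layer$act <- x
  x
}
#' @export
nn_backward.nn_tap <- function(layer, dout) {
  layer$grad <- dout
  dout
}

## ---- optimizer -------------------------------------------------------------

# Adam with the conventional defaults; params is a list of nn_param envs.
opt_adam <- function(params, lr = 1e-4, beta1 = 0.9, beta2 = 0.999,
                     eps = 1e-8) {
  o <- new.env(parent = emptyenv())
  o$params <- params
  o$lr <- lr; o$beta1 <- beta1; o$beta2 <- beta2; o$eps <- eps
  o$t <- 0
  o$m <- lapply(params, function(p) p$value * 0)
  o$v <- lapply(params, function(p) p$value * 0)
  class(o) <- "nn_optimizer"
  o
}

opt_step <- function(opt) {
  opt$t <- opt$t + 1
  bc1 <- 1 - opt$beta1^opt$t
  bc2 <- 1 - opt$beta2^opt$t
  for (i in seq_along(opt$params)) {
    p <- opt$params[[i]]
    g <- p$grad
    opt$m[[i]] <- opt$beta1 * opt$m[[i]] + (1 - opt$beta1) * g
    opt$v[[i]] <- opt$beta2 * opt$v[[i]] + (1 - opt$beta2) * g^2
    mhat <- opt$m[[i]] / bc1
    vhat <- opt$v[[i]] / bc2
    p$value <- p$value - opt$lr * mhat / (sqrt(vhat) + opt$eps)
  }
  invisible(opt)
}

zero_grads <- function(params) {
  for (p in params) p$grad <- p$value * 0
  invisible(params)
}
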