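# Convolutional layers for channel-first C x H x W x N tensors, via im2col
# gathers and a single GEMM per layer. With channels first, per-channel
# batch-norm and pooling reduce to row-recycled matrix operations and conv
# outputs reshape into place without transposition. Patch-index tables are
# cached per input geometry.

# im2col index table: rows ordered (kh fastest, then kw, then channel) so a
# depthwise layer sees k^2 contiguous rows per channel; columns ordered
# (output row fastest, then output column). Index 0 marks a zero-padding
# cell; gathers use a prepended zero row (index + 1).
conv_index <- function(H, W, C, kh, kw, stride, pad) {
  H_out <- (H + 2 * pad - kh) %/% stride + 1
  W_out <- (W + 2 * pad - kw) %/% stride + 1
  oh <- rep(seq_len(H_out), times = W_out)
  ow <- rep(seq_len(W_out), each = H_out)
  ih0 <- (oh - 1) * stride - pad      # 0-based top-left
  iw0 <- (ow - 1) * stride - pad
  ncols <- H_out * W_out
  R <- C * kh * kw
  idx <- matrix(0L, R, ncols)
  r <- 0L
  for (c in seq_len(C)) {
    for (dw in seq_len(kw)) {
      iw <- iw0 + dw            # 1-based column
      for (dh in seq_len(kh)) {
        r <- r + 1L
        ih <- ih0 + dh
        ok <- ih >= 1 & ih <= H & iw >= 1 & iw <= W
        row <- integer(ncols)
        row[ok] <- c + (ih[ok] - 1L) * C + (iw[ok] - 1L) * C * H
        idx[r, ] <- row
      }
    }
  }
  iv <- as.vector(idx)
  keys <- sort(unique(iv))
  list(idx = iv, scatter_group = iv, keys = keys, has_pad = keys[1] == 0L,
       R = R, H_out = H_out, W_out = W_out, chw = as.integer(C * H * W),
       batch_cache = new.env(parent = emptyenv()))
}

# per-batch-size expansion of the gather index (pad cells clamped to 1 and
# zeroed after the gather); cached inside the ci environment
batch_index <- function(ci, N) {
  key <- as.character(N)
  bc <- ci$batch_cache
  if (is.null(bc[[key]])) {
    len <- length(ci$idx)
    idx_all <- rep.int(ci$idx, N) +
      rep(0:(N - 1) * ci$chw, each = len)
    pad <- which(rep.int(ci$idx == 0L, N))
    idx_all[pad] <- 1L
    bc[[key]] <- list(idx = idx_all, pad = pad)
  }
  bc[[key]]
}

# gather patches for a batch: x is C x H x W x N -> (R, H_out*W_out*N)
gather_patches <- function(x, ci) {
  N <- dim(x)[4]
  bi <- batch_index(ci, N)
  P <- x[bi$idx]
  if (length(bi$pad)) P[bi$pad] <- 0
  dim(P) <- c(ci$R, ci$H_out * ci$W_out * N)
  P
}

# scatter-add patch gradients back to input shape
scatter_patches <- function(dP, ci, in_dim) {
  dim(dP) <- c(ci$R * ci$H_out * ci$W_out, in_dim[4])
  s <- rowsum(dP, group = ci$scatter_group, reorder = TRUE)
  dXf <- matrix(0, in_dim[1] * in_dim[2] * in_dim[3], in_dim[4])
  keep <- if (ci$has_pad) -1L else seq_along(ci$keys)
  dXf[ci$keys[keep], ] <- s[keep, , drop = FALSE]
  dim(dXf) <- in_dim
  dXf
}

## ---- standard convolution --------------------------------------------------

nn_conv2d <- function(in_ch, out_ch, kernel, stride = 1,
                      pad = (kernel - 1) %/% 2, bias = FALSE) {
  fan_in <- in_ch * kernel * kernel
  new_layer("conv2d", list(
    W = new_param(matrix(init_he(fan_in, fan_in * out_ch), out_ch, fan_in), "W"),
    b = if (bias) new_param(numeric(out_ch), "b") else NULL,
    in_ch = in_ch, out_ch = out_ch, kernel = kernel,
    stride = stride, pad = pad, ci = NULL, ci_key = ""
  ))
}

conv_ci <- function(layer, d, C) {
  key <- paste(d[2], d[3], C, sep = "x")
  if (!identical(layer$ci_key, key)) {
    layer$ci <- conv_index(d[2], d[3], C, layer$kernel, layer$kernel,
                           layer$stride, layer$pad)
    layer$ci_key <- key
  }
  layer$ci
}

#' @export
nn_forward.nn_conv2d <- function(layer, x, training = FALSE) {
  d <- dim(x)
  stopifnot(d[1] == layer$in_ch)
  ci <- conv_ci(layer, d, layer$in_ch)
  P <- gather_patches(x, ci)
  layer$P <- P
  layer$in_dim <- d
  out <- layer$W$value %*% P
  if (!is.null(layer$b)) out <- out + layer$b$value
  dim(out) <- c(layer$out_ch, ci$H_out, ci$W_out, d[4])
  out
}
#' @export
nn_backward.nn_conv2d <- function(layer, dout) {
  D <- matrix(dout, layer$out_ch)
  layer$W$grad <- layer$W$grad + tcrossprod(D, layer$P)
  if (!is.null(layer$b)) layer$b$grad <- layer$b$grad + rowSums(D)
  dP <- crossprod(layer$W$value, D)
  scatter_patches(dP, layer$ci, layer$in_dim)
}
#' @export
nn_params.nn_conv2d <- function(layer) {
  if (is.null(layer$b)) list(layer$W) else list(layer$W, layer$b)
}

## ---- depthwise convolution -------------------------------------------------

nn_dwconv2d <- function(channels, kernel, stride = 1,
                        pad = (kernel - 1) %/% 2) {
  k2 <- kernel * kernel
  new_layer("dwconv2d", list(
    W = new_param(matrix(init_he(k2, k2 * channels), k2, channels), "W"),
    channels = channels, kernel = kernel, stride = stride, pad = pad,
    ci = NULL, ci_key = "", grp = NULL
  ))
}
#' @export
nn_forward.nn_dwconv2d <- function(layer, x, training = FALSE) {
  d <- dim(x)
  stopifnot(d[1] == layer$channels)
  ci <- conv_ci(layer, d, layer$channels)
  P <- gather_patches(x, ci)           # k2 contiguous rows per channel
  layer$P <- P
  layer$in_dim <- d
  if (is.null(layer$grp))
    layer$grp <- rep(seq_len(layer$channels), each = layer$kernel^2)
  out <- rowsum(P * as.vector(layer$W$value), group = layer$grp,
                reorder = TRUE)
  dim(out) <- c(layer$channels, ci$H_out, ci$W_out, d[4])
  out
}
#' @export
nn_backward.nn_dwconv2d <- function(layer, dout) {
  k2 <- layer$kernel^2
  D <- matrix(dout, layer$channels)
  Dexp <- D[rep(seq_len(layer$channels), each = k2), , drop = FALSE]
  layer$W$grad <- layer$W$grad +
    matrix(rowSums(layer$P * Dexp), k2, layer$channels)
  dP <- Dexp * as.vector(layer$W$value)
  scatter_patches(dP, layer$ci, layer$in_dim)
}
#' @export
nn_params.nn_dwconv2d <- function(layer) list(layer$W)

## ---- 2-d batch normalization ----------------------------------------------

nn_bn2d <- function(channels, eps = 1e-5, momentum = 0.1) {
  new_layer("bn2d", list(
    gamma = new_param(rep(1, channels), "gamma"),
    beta = new_param(numeric(channels), "beta"),
    running_mean = numeric(channels), running_var = rep(1, channels),
    eps = eps, momentum = momentum, channels = channels
  ))
}
#' @export
nn_forward.nn_bn2d <- function(layer, x, training = FALSE) {
  d <- dim(x)
  C <- layer$channels
  M <- matrix(x, C)                    # C x (H*W*N), channel rows
  if (training) {
    mu <- rowMeans(M)
    varc <- pmax(rowMeans(M^2) - mu^2, 0)
    m_count <- ncol(M)
    layer$running_mean <- (1 - layer$momentum) * layer$running_mean +
      layer$momentum * mu
    vu <- if (m_count > 1) varc * m_count / (m_count - 1) else varc
    layer$running_var <- (1 - layer$momentum) * layer$running_var +
      layer$momentum * vu
    layer$train_mode <- TRUE
  } else {
    mu <- layer$running_mean
    varc <- layer$running_var
    layer$train_mode <- FALSE
  }
  sg <- sqrt(varc + layer$eps)
  xhat <- (M - mu) / sg                # row recycling over channels
  layer$xhat <- xhat
  layer$sigma <- sg
  layer$d <- d
  y <- xhat * layer$gamma$value + layer$beta$value
  dim(y) <- d
  y
}
#' @export
nn_backward.nn_bn2d <- function(layer, dout) {
  dm <- matrix(dout, layer$channels)
  layer$gamma$grad <- layer$gamma$grad + rowSums(dm * layer$xhat)
  layer$beta$grad <- layer$beta$grad + rowSums(dm)
  dxhat <- dm * layer$gamma$value
  if (!isTRUE(layer$train_mode)) {
    dx <- dxhat / layer$sigma
    dim(dx) <- layer$d
    return(dx)
  }
  dx <- (dxhat - rowMeans(dxhat) -
           layer$xhat * rowMeans(dxhat * layer$xhat)) / layer$sigma
  dim(dx) <- layer$d
  dx
}
#' @export
nn_params.nn_bn2d <- function(layer) list(layer$gamma, layer$beta)

## ---- global average pooling ------------------------------------------------

nn_gap <- function() new_layer("gap")
#' @export
nn_forward.nn_gap <- function(layer, x, training = FALSE) {
  d <- dim(x)
  layer$in_dim <- d
  hw <- d[2] * d[3]
  M <- matrix(x, d[1] * hw, d[4])
  t(rowsum(M, group = rep_len(seq_len(d[1]), d[1] * hw),
           reorder = TRUE)) / hw       # N x C
}
#' @export
nn_backward.nn_gap <- function(layer, dout) {
  d <- layer$in_dim
  hw <- d[2] * d[3]
  g <- t(dout) / hw                    # C x N
  array(apply(g, 2, rep, times = hw), d)
}

## ---- squeeze-and-excitation (2-d) ------------------------------------------

nn_se2d <- function(channels, squeeze) {
  new_layer("se2d", list(
    gap = nn_gap(),
    fc1 = nn_linear(channels, squeeze, bias = TRUE),
    relu = nn_relu(),
    fc2 = nn_linear(squeeze, channels, bias = TRUE),
    gate_act = nn_hardsigmoid(),
    channels = channels
  ))
}

# expand an N x C per-channel gate to the (C*HW, N) row layout
se_expand <- function(g, C, hw) {
  t(g)[rep_len(seq_len(C), C * hw), , drop = FALSE]
}
#' @export
nn_forward.nn_se2d <- function(layer, x, training = FALSE) {
  s <- nn_forward(layer$gap, x, training)
  z <- nn_forward(layer$relu, nn_forward(layer$fc1, s, training), training)
  g <- nn_forward(layer$gate_act, nn_forward(layer$fc2, z, training), training)
  d <- dim(x)
  hw <- d[2] * d[3]
  layer$x <- x
  layer$g <- g
  E <- se_expand(g, d[1], hw)
  array(matrix(x, d[1] * hw, d[4]) * E, d)
}
#' @export
nn_backward.nn_se2d <- function(layer, dout) {
  d <- dim(layer$x)
  hw <- d[2] * d[3]
  dm <- matrix(dout, d[1] * hw, d[4])
  xm <- matrix(layer$x, d[1] * hw, d[4])
  E <- se_expand(layer$g, d[1], hw)
  dx_direct <- array(dm * E, d)
  dg <- t(rowsum(dm * xm, group = rep_len(seq_len(d[1]), d[1] * hw),
                 reorder = TRUE))      # N x C
  dz <- nn_backward(layer$fc2, nn_backward(layer$gate_act, dg))
  ds <- nn_backward(layer$fc1, nn_backward(layer$relu, dz))
  dx_direct + nn_backward(layer$gap, ds)
}
#' @export
nn_params.nn_se2d <- function(layer) {
  c(nn_params(layer$fc1), nn_params(layer$fc2))
}
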