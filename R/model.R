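# CSF-Net model assembly: branch encoders, attention fusion, classification
# head, ablation variants, parameter accounting and checkpoints.

softmax_rows <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

## ---- single-head scaled dot-product attention fusion -----------------------

# Q/K/V linear projections over the fused feature vector (with bias, the
# standard linear-layer convention the published parameter total implies).
# In the default single-token mode the softmax over one token is degenerate
# (weight 1), so the output equals the value projection of the input
# exactly and the query/key projections receive no gradient; this is an
# analytic property of the architecture as described, not an implementation
# shortcut. A three-token mode (one token per color space, d x d
# projections) is provided as a configuration alternative.
nn_attention <- function(dim, tokens = 1L) {
  stopifnot(dim %% tokens == 0)
  dt <- dim %/% tokens
  new_layer("attention", list(
    Wq = new_param(matrix(init_glorot(dt, dt, dt * dt), dt, dt), "Wq"),
    Wk = new_param(matrix(init_glorot(dt, dt, dt * dt), dt, dt), "Wk"),
    Wv = new_param(matrix(init_glorot(dt, dt, dt * dt), dt, dt), "Wv"),
    bq = new_param(numeric(dt), "bq"),
    bk = new_param(numeric(dt), "bk"),
    bv = new_param(numeric(dt), "bv"),
    dim = as.integer(dim), tokens = as.integer(tokens), dt = as.integer(dt)
  ))
}
#' @export
nn_forward.nn_attention <- function(layer, x, training = FALSE) {
  T <- layer$tokens; dt <- layer$dt
  Xs <- lapply(seq_len(T), function(t) x[, ((t - 1) * dt + 1):(t * dt),
                                         drop = FALSE])
  Q <- lapply(Xs, function(m) sweep(m %*% layer$Wq$value, 2, layer$bq$value, "+"))
  K <- lapply(Xs, function(m) sweep(m %*% layer$Wk$value, 2, layer$bk$value, "+"))
  V <- lapply(Xs, function(m) sweep(m %*% layer$Wv$value, 2, layer$bv$value, "+"))
  N <- nrow(x)
  S <- array(0, c(N, T, T))
  for (i in seq_len(T)) for (j in seq_len(T))
    S[, i, j] <- rowSums(Q[[i]] * K[[j]]) / sqrt(dt)
  A <- array(0, c(N, T, T))
  for (i in seq_len(T)) {
    sm <- S[, i, , drop = FALSE]
    dim(sm) <- c(N, T)
    A[, i, ] <- softmax_rows(sm)
  }
  out <- lapply(seq_len(T), function(i) {
    o <- matrix(0, N, dt)
    for (j in seq_len(T)) o <- o + A[, i, j] * V[[j]]
    o
  })
  layer$Xs <- Xs; layer$Q <- Q; layer$K <- K; layer$V <- V; layer$A <- A
  do.call(cbind, out)
}
#' @export
nn_backward.nn_attention <- function(layer, dout) {
  T <- layer$tokens; dt <- layer$dt
  N <- nrow(dout)
  dOut <- lapply(seq_len(T), function(i) dout[, ((i - 1) * dt + 1):(i * dt),
                                              drop = FALSE])
  A <- layer$A
  dV <- lapply(seq_len(T), function(j) {
    g <- matrix(0, N, dt)
    for (i in seq_len(T)) g <- g + A[, i, j] * dOut[[i]]
    g
  })
  dA <- array(0, c(N, T, T))
  for (i in seq_len(T)) for (j in seq_len(T))
    dA[, i, j] <- rowSums(dOut[[i]] * layer$V[[j]])
  dS <- array(0, c(N, T, T))
  for (i in seq_len(T)) {
    dot <- rowSums(matrix(A[, i, ] * dA[, i, ], N, T))
    dS[, i, ] <- A[, i, ] * (matrix(dA[, i, ], N, T) - dot)
  }
  dQ <- lapply(seq_len(T), function(i) {
    g <- matrix(0, N, dt)
    for (j in seq_len(T)) g <- g + dS[, i, j] * layer$K[[j]]
    g / sqrt(dt)
  })
  dK <- lapply(seq_len(T), function(j) {
    g <- matrix(0, N, dt)
    for (i in seq_len(T)) g <- g + dS[, i, j] * layer$Q[[i]]
    g / sqrt(dt)
  })
  dXs <- vector("list", T)
  for (t in seq_len(T)) {
    layer$Wq$grad <- layer$Wq$grad + crossprod(layer$Xs[[t]], dQ[[t]])
    layer$Wk$grad <- layer$Wk$grad + crossprod(layer$Xs[[t]], dK[[t]])
    layer$Wv$grad <- layer$Wv$grad + crossprod(layer$Xs[[t]], dV[[t]])
    layer$bq$grad <- layer$bq$grad + colSums(dQ[[t]])
    layer$bk$grad <- layer$bk$grad + colSums(dK[[t]])
    layer$bv$grad <- layer$bv$grad + colSums(dV[[t]])
    dXs[[t]] <- dQ[[t]] %*% t(layer$Wq$value) +
      dK[[t]] %*% t(layer$Wk$value) + dV[[t]] %*% t(layer$Wv$value)
  }
  do.call(cbind, dXs)
}
#' @export
nn_params.nn_attention <- function(layer) {
  list(layer$Wq, layer$Wk, layer$Wv, layer$bq, layer$bk, layer$bv)
}

## ---- channel-recalibration fusion gates (ablation variants) ----------------

# squeeze-excitation gate on a feature vector: x * sigmoid(W2 relu(W1 x))
nn_se1d <- function(dim, reduction = 16) {
  new_layer("se1d", list(
    fc1 = nn_linear(dim, max(1L, dim %/% reduction), bias = TRUE),
    relu = nn_relu(),
    fc2 = nn_linear(max(1L, dim %/% reduction), dim, bias = TRUE),
    sig = nn_sigmoid(), dim = dim
  ))
}
#' @export
nn_forward.nn_se1d <- function(layer, x, training = FALSE) {
  z <- nn_forward(layer$relu, nn_forward(layer$fc1, x, training), training)
  g <- nn_forward(layer$sig, nn_forward(layer$fc2, z, training), training)
  layer$x <- x; layer$g <- g
  x * g
}
#' @export
nn_backward.nn_se1d <- function(layer, dout) {
  dg <- dout * layer$x
  dz <- nn_backward(layer$fc2, nn_backward(layer$sig, dg))
  dx_gate <- nn_backward(layer$fc1, nn_backward(layer$relu, dz))
  dout * layer$g + dx_gate
}
#' @export
nn_params.nn_se1d <- function(layer) c(nn_params(layer$fc1), nn_params(layer$fc2))

# CBAM channel gate on a feature vector: with no spatial extent the average
# and max pooled descriptors coincide with x, so the gate degenerates to
# sigmoid(2 * MLP(x)) with the shared bias-free MLP.
nn_cbam_channel1d <- function(dim, reduction = 16) {
  new_layer("cbam1d", list(
    fc1 = nn_linear(dim, max(1L, dim %/% reduction), bias = FALSE),
    relu = nn_relu(),
    fc2 = nn_linear(max(1L, dim %/% reduction), dim, bias = FALSE),
    sig = nn_sigmoid(), dim = dim
  ))
}
#' @export
nn_forward.nn_cbam1d <- function(layer, x, training = FALSE) {
  z <- nn_forward(layer$relu, nn_forward(layer$fc1, x, training), training)
  g <- nn_forward(layer$sig, 2 * nn_forward(layer$fc2, z, training), training)
  layer$x <- x; layer$g <- g
  x * g
}
#' @export
nn_backward.nn_cbam1d <- function(layer, dout) {
  dg <- dout * layer$x
  dz <- nn_backward(layer$fc2, 2 * nn_backward(layer$sig, dg))
  dx_gate <- nn_backward(layer$fc1, nn_backward(layer$relu, dz))
  dout * layer$g + dx_gate
}
#' @export
nn_params.nn_cbam1d <- function(layer) c(nn_params(layer$fc1), nn_params(layer$fc2))

# ECA gate: 1-d convolution of width k across the channel axis, sigmoid
nn_eca1d <- function(dim, k = 5L) {
  new_layer("eca1d", list(
    w = new_param(init_he(k, k), "w"), k = as.integer(k), dim = dim,
    sig = nn_sigmoid()
  ))
}
eca_conv <- function(x, w, k) {
  D <- ncol(x); half <- (k - 1L) %/% 2L
  z <- matrix(0, nrow(x), D)
  for (j in seq_len(k)) {
    off <- j - 1L - half
    src <- seq_len(D) + off
    ok <- src >= 1 & src <= D
    z[, which(ok)] <- z[, which(ok)] + w[j] * x[, src[ok], drop = FALSE]
  }
  z
}
#' @export
nn_forward.nn_eca1d <- function(layer, x, training = FALSE) {
  z <- eca_conv(x, layer$w$value, layer$k)
  g <- nn_forward(layer$sig, z, training)
  layer$x <- x; layer$g <- g
  x * g
}
#' @export
nn_backward.nn_eca1d <- function(layer, dout) {
  dg <- dout * layer$x
  dz <- nn_backward(layer$sig, dg)
  D <- ncol(dout); half <- (layer$k - 1L) %/% 2L
  for (j in seq_len(layer$k)) {
    off <- j - 1L - half
    src <- seq_len(D) + off
    ok <- src >= 1 & src <= D
    layer$w$grad[j] <- layer$w$grad[j] +
      sum(dz[, which(ok), drop = FALSE] * layer$x[, src[ok], drop = FALSE])
  }
  # transpose convolution for dx, then add the direct gate path
  dx <- eca_conv(dz, rev(layer$w$value), layer$k)
  dout * layer$g + dx
}
#' @export
nn_params.nn_eca1d <- function(layer) list(layer$w)

# NAM channel gate: batch-normalize, weight each channel by its normalized
# batch-norm scale |gamma_c| / sum|gamma|, sigmoid, multiply. The gradient
# of the normalization weights w.r.t. gamma is not propagated (gamma still
# learns through the batch-norm path); a documented simplification.
nn_nam1d <- function(dim) {
  new_layer("nam1d", list(bn = nn_bn1d(dim), sig = nn_sigmoid(), dim = dim))
}
#' @export
nn_forward.nn_nam1d <- function(layer, x, training = FALSE) {
  u <- nn_forward(layer$bn, x, training)
  gam <- abs(layer$bn$gamma$value)
  wts <- gam / max(sum(gam), 1e-12)
  g <- nn_forward(layer$sig, sweep(u, 2, wts, "*"), training)
  layer$x <- x; layer$g <- g; layer$wts <- wts
  x * g
}
#' @export
nn_backward.nn_nam1d <- function(layer, dout) {
  dg <- dout * layer$x
  du <- sweep(nn_backward(layer$sig, dg), 2, layer$wts, "*")
  dx_gate <- nn_backward(layer$bn, du)
  dout * layer$g + dx_gate
}
#' @export
nn_params.nn_nam1d <- function(layer) nn_params(layer$bn)

## ---- classification head ---------------------------------------------------

# in -> hidden1 -> hidden2 -> C, batch norm + ReLU + dropout on both hidden
# layers; the final linear emits raw logits.
build_head <- function(in_dim, hidden = c(1024L, 512L), n_classes = 6L,
                       dropout = 0.3) {
  layers <- list()
  prev <- in_dim
  for (h in hidden) {
    layers <- c(layers, list(nn_linear(prev, h, bias = TRUE), nn_bn1d(h),
                             nn_relu(), nn_dropout(dropout)))
    prev <- h
  }
  layers <- c(layers, list(nn_linear(prev, n_classes, bias = TRUE)))
  do.call(nn_seq, layers)
}

## ---- model configuration and assembly --------------------------------------

#' Model configuration
#'
#' @param backbone Backbone id (`"mobilenetv3-small"` or `"tinycnn"`).
#' @param feature_dim Per-branch feature dimension d. Defaults to the
#'   backbone's native width (1024 for the canonical small backbone, 256
#'   for `"tinycnn"`).
#' @param attention_tokens 1 (default: global single-token attention over
#'   the fused 3d vector, bias-free 3d x 3d projections) or 3 (one token
#'   per color space, d x d projections).
#' @param head_hidden Hidden widths of the classification head.
#' @param dropout Head dropout rate.
#' @param n_classes Number of classes (6).
#' @param image_size Input resolution the model is intended for (the
#'   convolutional trunk accepts any size >= 32).
#' @param pretrained Use pretrained weights for the RGB branch. Requires
#'   `pretrained_weights` (a checkpoint path); there is no download.
#' @param pretrained_weights Optional path to RGB-branch weights.
#' @param class_names Class labels, canonical order.
#' @return A `csf_model_config` list.
#' @export
model_config <- function(backbone = "mobilenetv3-small", feature_dim = NULL,
                         attention_tokens = 1L, head_hidden = c(1024L, 512L),
                         dropout = 0.3, n_classes = 6L, image_size = 224L,
                         pretrained = FALSE, pretrained_weights = NULL,
                         class_names = CSF_CLASSES) {
  if (is.null(feature_dim))
    feature_dim <- if (backbone == "mobilenetv3-small") 1024L else 256L
  stopifnot(attention_tokens %in% c(1L, 3L))
  structure(list(backbone = backbone, feature_dim = as.integer(feature_dim),
                 attention_tokens = as.integer(attention_tokens),
                 head_hidden = as.integer(head_hidden), dropout = dropout,
                 n_classes = as.integer(n_classes),
                 image_size = as.integer(image_size),
                 pretrained = pretrained,
                 pretrained_weights = pretrained_weights,
                 class_names = class_names),
            class = "csf_model_config")
}

CSF_VARIANTS <- c("csfnet", "rgb-only", "fusion-no-attention", "fusion-se",
                  "fusion-cbam-channel", "fusion-eca", "fusion-nam",
                  "baseline-resnet50", "baseline-efficientnet", "baseline-vit")

make_branch <- function(config) {
  bb <- build_backbone(config$backbone, out_dim = config$feature_dim)
  if (bb$out_dim != config$feature_dim)
    stop("backbone '", config$backbone, "' has feature dimension ",
         bb$out_dim, ", not ", config$feature_dim)
  bb
}

#' Build a CSF-Net model or an ablation / baseline variant
#'
#' Tags: `csfnet` (three branches + single-head self-attention + MLP head),
#' `rgb-only` (one branch + head), `fusion-no-attention` (concatenation fed
#' directly to the head), `fusion-se` / `fusion-cbam-channel` / `fusion-eca`
#' / `fusion-nam` (channel-recalibration gates replacing self-attention),
#' and `baseline-*` (single-backbone RGB classifiers behind the common
#' encoder contract).
#'
#' @param tag Variant tag (see above).
#' @param config A [model_config()].
#' @return A `csfnet_model` object.
#' @export
build_variant <- function(tag = "csfnet", config = model_config()) {
  if (!tag %in% CSF_VARIANTS)
    stop("unknown variant tag: '", tag, "' (known: ",
         paste(CSF_VARIANTS, collapse = ", "), ")")
  d <- config$feature_dim
  fused <- 3L * d
  single <- tag %in% c("rgb-only", "baseline-resnet50",
                       "baseline-efficientnet", "baseline-vit")
  branches <- if (single) list(rgb = make_branch(config))
              else list(rgb = make_branch(config), hsv = make_branch(config),
                        ycbcr = make_branch(config))
  if (isTRUE(config$pretrained)) {
    if (is.null(config$pretrained_weights))
      stop("pretrained = TRUE requires 'pretrained_weights' (a weights ",
           "file for the RGB branch); no weights are bundled")
    rgb_state <- readRDS(config$pretrained_weights)
    layer_load_state(branches$rgb$net, rgb_state)
  }
  fusion <- switch(tag,
    "csfnet" = nn_attention(fused, tokens = config$attention_tokens),
    "fusion-no-attention" = NULL,
    "fusion-se" = nn_se1d(fused, reduction = 16),
    "fusion-cbam-channel" = nn_cbam_channel1d(fused, reduction = 16),
    "fusion-eca" = nn_eca1d(fused, k = 5L),
    "fusion-nam" = nn_nam1d(fused),
    NULL
  )
  head_in <- if (single) d else fused
  head <- if (grepl("^baseline-", tag)) {
    nn_seq(nn_linear(head_in, config$n_classes, bias = TRUE))
  } else {
    build_head(head_in, config$head_hidden, config$n_classes, config$dropout)
  }
  structure(list(branches = branches, fusion = fusion, head = head,
                 config = config, variant = tag,
                 class_names = config$class_names),
            class = "csfnet_model")
}

#' @export
print.csfnet_model <- function(x, ...) {
  cat("CSF-Net model, variant '", x$variant, "'\n", sep = "")
  cat("  backbone: ", x$config$backbone, " (d = ", x$config$feature_dim,
      "), branches: ", length(x$branches), "\n", sep = "")
  if (!is.null(x$fusion))
    cat("  fusion: ", class(x$fusion)[1],
        if (inherits(x$fusion, "nn_attention"))
          paste0(" (tokens = ", x$fusion$tokens, ", d_k = ", x$fusion$dt, ")"),
        "\n", sep = "")
  cat("  trainable parameters: ", format(count_parameters(x), big.mark = ","),
      "\n", sep = "")
  invisible(x)
}

## ---- forward / backward ----------------------------------------------------

# batch input: a list with channel-first 3 x H x W x N arrays named
# rgb / hsv / ycbcr (see mci_batch(); single-branch variants use only $rgb,
# where a bare array is accepted)
as_branch_input <- function(model, batch) {
  if (is.list(batch)) return(batch)
  if (length(model$branches) == 1L) return(list(rgb = batch))
  stop("multi-branch models need a list with rgb, hsv and ycbcr planes")
}

#' Encode the color-space planes of a batch through the branch backbones
#'
#' @param model A `csfnet_model`.
#' @param batch List of channel-first 3 x H x W x N arrays (`rgb`, `hsv`,
#'   `ycbcr`), as produced by the data pipeline.
#' @param training Training mode (batch-norm batch statistics, dropout).
#' @return List of N x d feature matrices, one per branch.
#' @export
encode_branches <- function(model, batch, training = FALSE) {
  batch <- as_branch_input(model, batch)
  feats <- list()
  for (nm in names(model$branches)) {
    x <- batch[[nm]]
    if (is.null(x)) stop("batch is missing the '", nm, "' plane")
    feats[[nm]] <- nn_forward(model$branches[[nm]]$net, x, training)
  }
  feats
}

#' Concatenate branch features and apply the fusion stage
#'
#' Order RGB; HSV; YCbCr. For the default model this is single-token scaled
#' dot-product attention; ablation variants substitute a channel gate or
#' plain concatenation.
#'
#' @param model A `csfnet_model`.
#' @param features List of N x d matrices from [encode_branches()].
#' @param training Training mode flag.
#' @return N x (3d) refined feature matrix (N x d for single-branch tags).
#' @export
fuse_and_attend <- function(model, features, training = FALSE) {
  f <- do.call(cbind, features)
  if (is.null(model$fusion)) f else nn_forward(model$fusion, f, training)
}

#' Classification head: logits in training, probabilities at inference
#'
#' @param model A `csfnet_model`.
#' @param refined N x D refined feature matrix.
#' @param training If TRUE return raw logits (the loss applies softmax
#'   internally); if FALSE return softmax probabilities.
#' @return N x C matrix.
#' @export
classify <- function(model, refined, training = FALSE) {
  z <- nn_forward(model$head, refined, training)
  if (training) z else softmax_rows(z)
}

# full forward returning logits (training or eval mode)
model_forward <- function(model, batch, training = FALSE) {
  feats <- encode_branches(model, batch, training)
  refined <- fuse_and_attend(model, feats, training)
  nn_forward(model$head, refined, training)
}

# full backward from dlogits; relies on caches from the last forward
model_backward <- function(model, dlogits) {
  dref <- nn_backward(model$head, dlogits)
  dfused <- if (is.null(model$fusion)) dref else nn_backward(model$fusion, dref)
  d <- model$config$feature_dim
  i <- 0
  for (nm in names(model$branches)) {
    dfeat <- dfused[, (i * d + 1):((i + 1) * d), drop = FALSE]
    nn_backward(model$branches[[nm]]$net, dfeat)
    i <- i + 1
  }
  invisible(NULL)
}

#' Predict class probabilities for a batch
#' @inheritParams encode_branches
#' @return N x C probability matrix (columns named by class).
#' @export
predict_proba <- function(model, batch) {
  p <- softmax_rows(model_forward(model, batch, training = FALSE))
  colnames(p) <- model$class_names
  p
}

model_params <- function(model) {
  p <- do.call(c, lapply(model$branches, function(b) nn_params(b$net)))
  if (!is.null(model$fusion)) p <- c(p, nn_params(model$fusion))
  c(p, nn_params(model$head))
}

#' Count trainable parameters
#' @param model A `csfnet_model` (or any `nn_layer`).
#' @return Integer number of trainable scalars.
#' @export
count_parameters <- function(model) {
  params <- if (inherits(model, "csfnet_model")) model_params(model)
            else nn_params(model)
  sum(vapply(params, n_values, numeric(1)))
}

## ---- checkpoints -----------------------------------------------------------

# state of a layer tree: parameter values plus batch-norm running buffers,
# in deterministic traversal order
nn_children <- function(layer) UseMethod("nn_children")
#' @export
nn_children.default <- function(layer) list()
#' @export
nn_children.nn_seq <- function(layer) layer$layers
#' @export
nn_children.nn_residual <- function(layer) list(layer$inner)
#' @export
nn_children.nn_se2d <- function(layer) list(layer$fc1, layer$fc2)
#' @export
nn_children.nn_se1d <- function(layer) list(layer$fc1, layer$fc2)
#' @export
nn_children.nn_cbam1d <- function(layer) list(layer$fc1, layer$fc2)
#' @export
nn_children.nn_nam1d <- function(layer) list(layer$bn)

walk_layers <- function(layer) {
  out <- list(layer)
  for (ch in nn_children(layer)) out <- c(out, walk_layers(ch))
  out
}

layer_state <- function(root) {
  ls <- walk_layers(root)
  list(
    params = lapply(ls, function(l) lapply(nn_params(l), function(p) p$value)),
    buffers = lapply(ls, function(l) {
      if (inherits(l, c("nn_bn1d", "nn_bn2d")))
        list(running_mean = l$running_mean, running_var = l$running_var)
      else NULL
    })
  )
}

layer_load_state <- function(root, state) {
  ls <- walk_layers(root)
  stopifnot(length(ls) == length(state$params))
  for (i in seq_along(ls)) {
    ps <- nn_params(ls[[i]])
    vs <- state$params[[i]]
    stopifnot(length(ps) == length(vs))
    for (j in seq_along(ps)) {
      stopifnot(length(ps[[j]]$value) == length(vs[[j]]))
      ps[[j]]$value <- vs[[j]]
    }
    if (!is.null(state$buffers[[i]])) {
      ls[[i]]$running_mean <- state$buffers[[i]]$running_mean
      ls[[i]]$running_var <- state$buffers[[i]]$running_var
    }
  }
  invisible(root)
}

model_state <- function(model) {
  s <- list(branches = lapply(model$branches, function(b) layer_state(b$net)),
            head = layer_state(model$head))
  if (!is.null(model$fusion)) s$fusion <- layer_state(model$fusion)
  s
}

model_load_state <- function(model, state) {
  for (nm in names(model$branches))
    layer_load_state(model$branches[[nm]]$net, state$branches[[nm]])
  layer_load_state(model$head, state$head)
  if (!is.null(model$fusion)) layer_load_state(model$fusion, state$fusion)
  invisible(model)
}

#' Save / load a model checkpoint
#'
#' The checkpoint stores a manifest header (variant, config, class order,
#' optional normalization-statistics reference) plus all weights and
#' batch-norm buffers.
#'
#' @param model A `csfnet_model`.
#' @param path Checkpoint file path.
#' @param norm_stats Optional `csf_norm_stats` stored alongside the weights.
#' @param extra Optional named list of run metadata.
#' @return `path` (save) / the restored model with attributes
#'   `norm_stats` and `extra` (load).
#' @export
save_checkpoint <- function(model, path, norm_stats = NULL, extra = NULL) {
  saveRDS(list(format = "csfnet-checkpoint-1", variant = model$variant,
               config = model$config, class_names = model$class_names,
               state = model_state(model), norm_stats = norm_stats,
               extra = extra),
          path, compress = FALSE)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  ck <- readRDS(path)
  stopifnot(identical(ck$format, "csfnet-checkpoint-1"))
  model <- build_variant(ck$variant, ck$config)
  model_load_state(model, ck$state)
  attr(model, "norm_stats") <- ck$norm_stats
  attr(model, "extra") <- ck$extra
  model
}
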