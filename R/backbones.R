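# Branch-encoder backbones.
#
# "mobilenetv3-small" reproduces the canonical small backbone layer by
# layer (inverted residual blocks with squeeze-excitation and hard-swish),
# with the final 1000-way classification linear removed and the 1024-unit
# penultimate linear retained, so one branch holds exactly 1,517,856
# trainable parameters (1.52 M). "tinycnn" is a small 4-conv encoder used
# for desk-scale experiments behind the same contract.
#
# A backbone is a list: `net` (an nn_seq mapping H x W x 3 x N to N x d),
# `tap` (identity layer over the last convolutional maps, for Grad-CAM),
# `out_dim`, and `id`.

# channel rounding rule used by the canonical architecture
make_divisible <- function(v, divisor = 8) {
  new_v <- max(divisor, (as.integer(v + divisor / 2) %/% divisor) * divisor)
  if (new_v < 0.9 * v) new_v <- new_v + divisor
  as.integer(new_v)
}

mbv3_act <- function(kind) if (kind == "RE") nn_relu() else nn_hardswish()

# one inverted-residual block: expand (1x1) -> depthwise -> [SE] -> project
mbv3_block <- function(in_ch, kernel, exp_ch, out_ch, se, act, stride) {
  layers <- list()
  if (exp_ch != in_ch) {
    layers <- c(layers, list(nn_conv2d(in_ch, exp_ch, 1), nn_bn2d(exp_ch),
                             mbv3_act(act)))
  }
  layers <- c(layers, list(nn_dwconv2d(exp_ch, kernel, stride),
                           nn_bn2d(exp_ch), mbv3_act(act)))
  if (se) {
    layers <- c(layers, list(nn_se2d(exp_ch, make_divisible(exp_ch %/% 4))))
  }
  layers <- c(layers, list(nn_conv2d(exp_ch, out_ch, 1), nn_bn2d(out_ch)))
  inner <- do.call(nn_seq, layers)
  if (stride == 1 && in_ch == out_ch) nn_residual(inner) else inner
}

# (in, kernel, expanded, out, SE, activation, stride)
MBV3_SMALL_CFG <- list(
  list(16, 3, 16, 16, TRUE, "RE", 2),
  list(16, 3, 72, 24, FALSE, "RE", 2),
  list(24, 3, 88, 24, FALSE, "RE", 1),
  list(24, 5, 96, 40, TRUE, "HS", 2),
  list(40, 5, 240, 40, TRUE, "HS", 1),
  list(40, 5, 240, 40, TRUE, "HS", 1),
  list(40, 5, 120, 48, TRUE, "HS", 1),
  list(48, 5, 144, 48, TRUE, "HS", 1),
  list(48, 5, 288, 96, TRUE, "HS", 2),
  list(96, 5, 576, 96, TRUE, "HS", 1),
  list(96, 5, 576, 96, TRUE, "HS", 1)
)

backbone_mobilenetv3_small <- function() {
  blocks <- lapply(MBV3_SMALL_CFG, function(cf) {
    mbv3_block(cf[[1]], cf[[2]], cf[[3]], cf[[4]], cf[[5]], cf[[6]], cf[[7]])
  })
  tap <- nn_tap()
  net <- do.call(nn_seq, c(
    list(nn_conv2d(3, 16, 3, stride = 2), nn_bn2d(16), nn_hardswish()),
    blocks,
    list(nn_conv2d(96, 576, 1), nn_bn2d(576), nn_hardswish(), tap,
         nn_gap(), nn_linear(576, 1024, bias = TRUE), nn_hardswish())
  ))
  list(net = net, tap = tap, out_dim = 1024L, id = "mobilenetv3-small")
}

backbone_tinycnn <- function(out_dim = 256L) {
  tap <- nn_tap()
  net <- nn_seq(
    nn_conv2d(3, 16, 3, stride = 2), nn_bn2d(16), nn_relu(),
    nn_conv2d(16, 32, 3, stride = 2), nn_bn2d(32), nn_relu(),
    nn_conv2d(32, 64, 3, stride = 2), nn_bn2d(64), nn_relu(), tap,
    nn_gap(), nn_linear(64, out_dim, bias = TRUE), nn_relu()
  )
  list(net = net, tap = tap, out_dim = as.integer(out_dim), id = "tinycnn")
}

#' Build a branch-encoder backbone
#'
#' @param id Backbone identifier: `"mobilenetv3-small"` (default, feature
#'   dimension 1024) or `"tinycnn"` (small encoder for desk-scale runs).
#' @param out_dim Feature dimension for `"tinycnn"` (default 256; the
#'   canonical small backbone is fixed at 1024).
#' @return Backbone list with fields `net`, `tap`, `out_dim`, `id`.
#' @export
build_backbone <- function(id = "mobilenetv3-small", out_dim = NULL) {
  switch(id,
    "mobilenetv3-small" = backbone_mobilenetv3_small(),
    "tinycnn" = backbone_tinycnn(if (is.null(out_dim)) 256L else out_dim),
    stop("unknown backbone id: ", id)
  )
}
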