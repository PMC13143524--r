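# Grad-CAM saliency for the multi-branch model.
#
# Each branch backbone exposes its last convolutional feature maps through
# an identity tap. The class-score gradient is propagated back from the
# target logit; channel weights are the spatial means of the gradient, the
# map is the rectified weighted channel sum, max-normalized to [0, 1]
# (all-zero maps stay zero and are flagged degenerate) and bilinearly
# upsampled to the input size. The combined map is the unweighted mean of
# the branch maps.

#' Grad-CAM saliency maps for one sample
#'
#' @param model A `csfnet_model` (evaluation mode is used).
#' @param mci A `multi_color_image` (normalized sample, see
#'   [decompose_and_normalize()]).
#' @param target_class Class id in 1..C, or NULL for the predicted class.
#' @return A `saliency_result`: per-branch maps, `combined` map (input-size
#'   matrices in \[0, 1\]), `target_class`, `probs`, `degenerate` flags.
#' @export
gradcam <- function(model, mci, target_class = NULL) {
  S <- dim(mci$rgb)[1]
  batch <- mci_batch(list(mci))
  logits <- model_forward(model, batch, training = FALSE)
  probs <- softmax_rows(logits)
  C <- ncol(logits)
  if (is.null(target_class)) target_class <- which.max(probs[1, ])
  if (target_class < 1 || target_class > C)
    stop("target_class must lie in 1..", C)
  dlogits <- matrix(0, 1, C)
  dlogits[1, target_class] <- 1
  model_backward(model, dlogits)

  maps <- list()
  degenerate <- logical(0)
  for (nm in names(model$branches)) {
    tap <- model$branches[[nm]]$tap
    act <- tap$act; grad <- tap$grad
    if (is.null(act) || length(dim(act)) != 4L)
      stop("branch '", nm, "' exposes no convolutional feature maps")
    ch <- dim(act)[1]; h <- dim(act)[2]; w <- dim(act)[3]
    wts <- rowMeans(matrix(grad[, , , 1], ch))
    m <- matrix(colSums(matrix(act[, , , 1], ch) * wts), h, w)
    m <- pmax(m, 0)
    degenerate[nm] <- max(m) <= 0
    # upsample first, then max-normalize, so the full-resolution map peaks
    # at exactly 1 (bilinear interpolation would otherwise shave the peak)
    m <- resize_bilinear(m, S, S)
    mx <- max(m)
    if (mx > 0) m <- m / mx
    maps[[nm]] <- m
  }
  combined <- Reduce(`+`, maps) / length(maps)
  structure(list(branch_maps = maps, combined = combined,
                 target_class = target_class, probs = probs[1, ],
                 degenerate = degenerate),
            class = "saliency_result")
}

# simple blue -> cyan -> green -> yellow -> red colormap on [0, 1]
jet_colormap <- function(v) {
  r <- clip01(1.5 - abs(4 * v - 3))
  g <- clip01(1.5 - abs(4 * v - 2))
  b <- clip01(1.5 - abs(4 * v - 1))
  list(r = r, g = g, b = b)
}

#' Overlay a saliency map on the original RGB image
#'
#' Blends a color-mapped heat map over the image at fixed alpha 0.4.
#'
#' @param rgb H x W x 3 array in \[0, 255\] (the original image).
#' @param saliency A `saliency_result` or an H x W map matrix in \[0, 1\].
#' @param alpha Blend weight of the heat map (default 0.4).
#' @param path Optional output PNG path.
#' @return H x W x 3 annotated image array in \[0, 255\].
#' @export
overlay <- function(rgb, saliency, alpha = 0.4, path = NULL) {
  m <- if (inherits(saliency, "saliency_result")) saliency$combined
       else saliency
  if (!all(dim(m) == dim(rgb)[1:2]))
    stop("saliency map size does not match the image")
  cm <- jet_colormap(m)
  out <- rgb
  out[, , 1] <- (1 - alpha) * rgb[, , 1] + alpha * 255 * cm$r
  out[, , 2] <- (1 - alpha) * rgb[, , 2] + alpha * 255 * cm$g
  out[, , 3] <- (1 - alpha) * rgb[, , 3] + alpha * 255 * cm$b
  if (!is.null(path)) write_image(out, path)
  out
}

#' Export a saliency map as a grayscale PNG plus a numeric grid
#'
#' @param saliency A `saliency_result`.
#' @param prefix Output path prefix; writes `<prefix>_<branch>.png`,
#'   `<prefix>_combined.png` and `<prefix>_combined.csv`.
#' @return Character vector of written paths.
#' @export
export_saliency <- function(saliency, prefix) {
  paths <- c()
  for (nm in names(saliency$branch_maps)) {
    p <- paste0(prefix, "_", nm, ".png")
    png::writePNG(clip01(saliency$branch_maps[[nm]]), p)
    paths <- c(paths, p)
  }
  p <- paste0(prefix, "_combined.png")
  png::writePNG(clip01(saliency$combined), p)
  pc <- paste0(prefix, "_combined.csv")
  utils::write.table(saliency$combined, pc, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  c(paths, p, pc)
}
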