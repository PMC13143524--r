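# Color-space decomposition, augmentation and normalization.
#
# All conversions take and return 8-bit-scale arrays (values in [0, 255],
# stored as doubles, not rounded). The HSV encoding is full-range: hue in
# degrees is mapped linearly from [0, 360) onto [0, 255]; saturation and
# value onto [0, 255]. YCbCr uses the ITU-R BT.601 full-range matrix with
# achromatic pixels at Cb = Cr = 128 (no studio swing).

#' Convert an RGB plane to full-range HSV
#'
#' Standard hexcone conversion. Hue (0–360 degrees) is encoded linearly into
#' \[0, 255\]; achromatic pixels get H = 0 and S = 0.
#'
#' @param rgb H x W x 3 array with values in \[0, 255\].
#' @return H x W x 3 array (H, S, V), each channel in \[0, 255\].
#' @export
rgb_to_hsv8 <- function(rgb) {
  check_rgb_range(rgb)
  r <- matrix(rgb[, , 1], dim(rgb)[1]); g <- matrix(rgb[, , 2], dim(rgb)[1])
  b <- matrix(rgb[, , 3], dim(rgb)[1])
  mx <- pmax(r, g, b); mn <- pmin(r, g, b)
  d <- mx - mn
  h <- matrix(0, nrow(r), ncol(r))
  nz <- d > 0
  ir <- nz & mx == r
  ig <- nz & mx == g & !ir
  ib <- nz & !ir & !ig
  h[ir] <- ((g[ir] - b[ir]) / d[ir]) %% 6
  h[ig] <- (b[ig] - r[ig]) / d[ig] + 2
  h[ib] <- (r[ib] - g[ib]) / d[ib] + 4
  h <- h * 60                      # degrees in [0, 360)
  s <- ifelse(mx > 0, d / mx, 0)
  out <- array(0, dim(rgb))
  out[, , 1] <- h * 255 / 360
  out[, , 2] <- s * 255
  out[, , 3] <- mx
  out
}

#' Convert an RGB plane to full-range BT.601 YCbCr
#'
#' Y = 0.299 R + 0.587 G + 0.114 B; Cb = 128 - 0.168736 R - 0.331264 G +
#' 0.5 B; Cr = 128 + 0.5 R - 0.418688 G - 0.081312 B; clipped to \[0, 255\].
#'
#' @inheritParams rgb_to_hsv8
#' @return H x W x 3 array (Y, Cb, Cr), each channel in \[0, 255\].
#' @export
rgb_to_ycbcr <- function(rgb) {
  check_rgb_range(rgb)
  r <- rgb[, , 1]; g <- rgb[, , 2]; b <- rgb[, , 3]
  out <- array(0, dim(rgb))
  out[, , 1] <- 0.299 * r + 0.587 * g + 0.114 * b
  out[, , 2] <- 128 - 0.168736 * r - 0.331264 * g + 0.5 * b
  out[, , 3] <- 128 + 0.5 * r - 0.418688 * g - 0.081312 * b
  clip255(out)
}

check_rgb_range <- function(rgb) {
  if (length(dim(rgb)) != 3L || dim(rgb)[3] != 3L)
    stop("expected an H x W x 3 array")
  if (anyNA(rgb) || min(rgb) < 0 || max(rgb) > 255)
    stop("RGB values must lie in [0, 255]")
  invisible(TRUE)
}

#' Training-time augmentation of an RGB image
#'
#' Horizontal flip with probability 0.5, rotation uniform in ±15 degrees
#' (bilinear, zero fill), then brightness / contrast / saturation jitter
#' with factors uniform in \[0.8, 1.2\]. Applied to the RGB image before
#' color-space decomposition so the three planes stay geometrically aligned.
#'
#' Draws come from R's global RNG; pass `draws` to fix them explicitly
#' (fields `flip` in \[0,1\], `angle` degrees, `brightness`, `contrast`,
#' `saturation` factors).
#'
#' @param rgb H x W x 3 array in \[0, 255\].
#' @param p_flip Flip probability (default 0.5).
#' @param max_rotate Max absolute rotation in degrees (default 15).
#' @param jitter Half-width of the jitter factor range (default 0.2).
#' @param draws Optional list overriding the random draws.
#' @return Augmented H x W x 3 array in \[0, 255\].
#' @export
augment_rgb <- function(rgb, p_flip = 0.5, max_rotate = 15, jitter = 0.2,
                        draws = NULL) {
  if (is.null(draws)) {
    draws <- list(
      flip = stats::runif(1),
      angle = stats::runif(1, -max_rotate, max_rotate),
      brightness = stats::runif(1, 1 - jitter, 1 + jitter),
      contrast = stats::runif(1, 1 - jitter, 1 + jitter),
      saturation = stats::runif(1, 1 - jitter, 1 + jitter)
    )
  }
  x <- rgb
  if (dim(x)[1] > 1L || dim(x)[2] > 1L) {
    if (draws$flip < p_flip) x <- x[, rev(seq_len(dim(x)[2])), , drop = FALSE]
    x <- rotate_image(x, draws$angle)
  }
  # brightness: scale; contrast: blend with mean luma; saturation: blend
  # with per-pixel luma (the common imaging-library definitions)
  x <- x * draws$brightness
  luma <- 0.299 * x[, , 1] + 0.587 * x[, , 2] + 0.114 * x[, , 3]
  x <- draws$contrast * x + (1 - draws$contrast) * mean(luma)
  for (c in 1:3) x[, , c] <- draws$saturation * x[, , c] +
    (1 - draws$saturation) * luma
  clip255(x)
}

decompose_rgb <- function(rgb) {
  list(rgb = rgb, hsv = rgb_to_hsv8(rgb), ycbcr = rgb_to_ycbcr(rgb))
}

#' Compute per-channel normalization statistics from training images
#'
#' Accumulates the pixel-wise mean and standard deviation of every channel
#' of every color space (9 channel pairs) over a set of images, after
#' resizing to the working resolution and converting to HSV / YCbCr.
#' Statistics must be computed from the training split only; the fold id and
#' split tag are recorded on the result for audit.
#'
#' @param filepaths Character vector of image paths (training split).
#' @param image_size Working resolution (square, pixels).
#' @param fold,split Provenance tags stored with the statistics.
#' @return A `csf_norm_stats` object: per color space, `$mean` and `$sd`
#'   length-3 vectors in 0–255 units.
#' @export
compute_norm_stats <- function(filepaths, image_size = 64,
                               fold = NA_integer_, split = "train") {
  if (length(filepaths) == 0L) stop("cannot compute statistics from an empty subset")
  imgs <- lapply(filepaths, function(f)
    resize_bilinear(read_image(f), image_size, image_size))
  stats_from_images(imgs, image_size, fold = fold, split = split)
}

# statistics from already-loaded, already-resized RGB arrays
stats_from_images <- function(imgs, image_size, fold = NA_integer_,
                              split = "train") {
  if (length(imgs) == 0L) stop("cannot compute statistics from an empty subset")
  spaces <- c("rgb", "hsv", "ycbcr")
  s1 <- s2 <- sapply(spaces, function(s) numeric(3), simplify = FALSE)
  npix <- 0
  for (img in imgs) {
    planes <- decompose_rgb(img)
    npix <- npix + image_size * image_size
    for (s in spaces) {
      v <- planes[[s]]
      s1[[s]] <- s1[[s]] + apply(v, 3, sum)
      s2[[s]] <- s2[[s]] + apply(v, 3, function(ch) sum(ch^2))
    }
  }
  stats <- sapply(spaces, function(s) {
    m <- s1[[s]] / npix
    # population variance over all pooled pixels
    v <- pmax(s2[[s]] / npix - m^2, 0)
    list(mean = m, sd = sqrt(v))
  }, simplify = FALSE)
  for (s in spaces) {
    if (any(stats[[s]]$sd <= 1e-12))
      stop("degenerate (zero-variance) channel in color space '", s,
           "'; cannot normalize")
  }
  structure(list(spaces = stats, image_size = image_size,
                 fold = fold, split = split, n_images = length(imgs)),
            class = "csf_norm_stats")
}

#' @export
print.csf_norm_stats <- function(x, ...) {
  cat("Normalization statistics (", x$n_images, " images, fold ",
      x$fold, ", ", x$split, " split)\n", sep = "")
  for (s in names(x$spaces)) {
    cat(sprintf("  %-6s mean: %s  sd: %s\n", s,
                paste(sprintf("%7.2f", x$spaces[[s]]$mean), collapse = " "),
                paste(sprintf("%7.2f", x$spaces[[s]]$sd), collapse = " ")))
  }
  invisible(x)
}

#' Save / load normalization statistics as a JSON sidecar
#' @param stats A `csf_norm_stats` object.
#' @param path JSON file path.
#' @return `path` (write) or the restored object (read).
#' @export
save_norm_stats <- function(stats, path) {
  jsonlite::write_json(list(
    spaces = lapply(stats$spaces, function(s) list(mean = s$mean, sd = s$sd)),
    image_size = stats$image_size, fold = stats$fold, split = stats$split,
    n_images = stats$n_images
  ), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_norm_stats
#' @export
load_norm_stats <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(
    spaces = lapply(j$spaces, function(s) list(mean = as.numeric(s$mean),
                                               sd = as.numeric(s$sd))),
    image_size = j$image_size, fold = j$fold, split = j$split,
    n_images = j$n_images
  ), class = "csf_norm_stats")
}

#' Decompose an RGB image and normalize every channel
#'
#' Resizes to the working resolution (bilinear), converts to HSV and YCbCr,
#' and standardizes each channel as (x - mean) / sd using training-split
#' statistics. Validation preprocessing is exactly this (no stochastic op).
#'
#' @param rgb H x W x 3 array in \[0, 255\].
#' @param stats A `csf_norm_stats` object.
#' @param label Optional class id carried along.
#' @return A `multi_color_image`: list with normalized `rgb`, `hsv`,
#'   `ycbcr` planes (all `image_size` square) and `label`.
#' @export
decompose_and_normalize <- function(rgb, stats, label = NULL) {
  stopifnot(inherits(stats, "csf_norm_stats"))
  img <- resize_bilinear(rgb, stats$image_size, stats$image_size)
  planes <- decompose_rgb(img)
  out <- list()
  for (s in names(planes)) {
    st <- stats$spaces[[s]]
    if (is.null(st)) stop("missing statistics for color space '", s, "'")
    v <- planes[[s]]
    for (c in 1:3) v[, , c] <- (v[, , c] - st$mean[c]) / st$sd[c]
    out[[s]] <- v
  }
  out$label <- label
  class(out) <- "multi_color_image"
  out
}
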