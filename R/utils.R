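#' @keywords internal
"_PACKAGE"

# Derive a 31-bit sub-seed from a base seed and integer keys. Used to give
# every synthetic image (and every fold / repeat) its own reproducible
# pseudo-random stream, independent of generation order.
derive_seed <- function(seed, ...) {
  keys <- c(seed, ...)
  h <- 0
  for (k in keys) h <- (h * 1000003 + (as.numeric(k) %% 2147483647)) %% 2147483647
  as.integer(h)
}

clip01 <- function(x) pmin(pmax(x, 0), 1)
clip255 <- function(x) pmin(pmax(x, 0), 255)

#' Read an 8-bit color image
#'
#' Loads a PNG or JPEG file and returns an H x W x 3 numeric array with
#' values in \[0, 255\]. Grayscale images are replicated across channels;
#' alpha channels are dropped.
#'
#' @param path File path to a PNG image.
#' @return Numeric array of dimension H x W x 3 in \[0, 255\].
#' @export
read_image <- function(path) {
  if (!file.exists(path)) stop("image file not found: ", path)
  a <- tryCatch(png::readPNG(path), error = function(e) {
    stop("cannot read image file '", path, "': ", conditionMessage(e))
  })
  if (length(dim(a)) == 2L) a <- array(rep(a, 3L), c(dim(a), 3L))
  if (dim(a)[3] > 3L) a <- a[, , 1:3, drop = FALSE]
  if (dim(a)[3] == 1L) a <- array(rep(a, 3L), c(dim(a)[1:2], 3L))
  a * 255
}

#' Write an 8-bit color image
#'
#' Values are clipped to \[0, 255\] and rounded, so repeated writes of the
#' same array are byte-identical.
#'
#' @param img H x W x 3 numeric array in \[0, 255\] (or H x W matrix).
#' @param path Output PNG path.
#' @return `path`, invisibly.
#' @export
write_image <- function(img, path) {
  png::writePNG(round(clip255(img)) / 255, path)
  invisible(path)
}

# Bilinear sampling of plane (H x W matrix) at fractional coordinates.
# Coordinates outside the plane read as `fill`.
bilinear_sample <- function(plane, ys, xs, fill = 0) {
  H <- nrow(plane); W <- ncol(plane)
  y0 <- floor(ys); x0 <- floor(xs)
  fy <- ys - y0; fx <- xs - x0
  gv <- function(yy, xx) {
    ok <- yy >= 1 & yy <= H & xx >= 1 & xx <= W
    v <- rep(fill, length(yy))
    if (any(ok)) v[ok] <- plane[cbind(yy[ok], xx[ok])]
    v
  }
  v00 <- gv(y0, x0); v01 <- gv(y0, x0 + 1)
  v10 <- gv(y0 + 1, x0); v11 <- gv(y0 + 1, x0 + 1)
  (1 - fy) * ((1 - fx) * v00 + fx * v01) + fy * ((1 - fx) * v10 + fx * v11)
}

#' Bilinear image resize
#'
#' @param img H x W x C array or H x W matrix.
#' @param out_h,out_w Output height and width in pixels.
#' @return Resized array/matrix.
#' @export
resize_bilinear <- function(img, out_h, out_w) {
  ismat <- is.matrix(img)
  if (ismat) img <- array(img, c(dim(img), 1L))
  H <- dim(img)[1]; W <- dim(img)[2]; C <- dim(img)[3]
  if (H == out_h && W == out_w) {
    return(if (ismat) img[, , 1] else img)
  }
  # align-corners = FALSE convention (pixel centers at i - 0.5)
  ys <- ((seq_len(out_h) - 0.5) * H / out_h) + 0.5
  xs <- ((seq_len(out_w) - 0.5) * W / out_w) + 0.5
  ys <- pmin(pmax(ys, 1), H); xs <- pmin(pmax(xs, 1), W)
  yy <- rep(ys, times = out_w); xx <- rep(xs, each = out_h)
  out <- array(0, c(out_h, out_w, C))
  for (c in seq_len(C))
    out[, , c] <- bilinear_sample(matrix(img[, , c], H, W), yy, xx)
  if (ismat) out[, , 1] else out
}

# Rotate about the image center by `angle` degrees, bilinear, zero fill.
# All channels share one set of sampling weights.
rotate_image <- function(img, angle) {
  if (angle == 0) return(img)
  H <- dim(img)[1]; W <- dim(img)[2]; C <- dim(img)[3]
  th <- angle * pi / 180
  cy <- (H + 1) / 2; cx <- (W + 1) / 2
  gy <- rep(seq_len(H), times = W) - cy
  gx <- rep(seq_len(W), each = H) - cx
  # inverse rotation: sample source at R(-th) * (x, y)
  sy <- cy + (sin(-th) * gx + cos(-th) * gy)
  sx <- cx + (cos(-th) * gx - sin(-th) * gy)
  y0 <- floor(sy); x0 <- floor(sx)
  fy <- sy - y0; fx <- sx - x0
  # clamp neighbours into range; out-of-range samples get weight 0
  ok <- function(yy, xx) (yy >= 1 & yy <= H & xx >= 1 & xx <= W)
  cl <- function(v, hi) pmin(pmax(v, 1), hi)
  n00 <- cl(y0, H) + (cl(x0, W) - 1) * H
  n01 <- cl(y0, H) + (cl(x0 + 1, W) - 1) * H
  n10 <- cl(y0 + 1, H) + (cl(x0, W) - 1) * H
  n11 <- cl(y0 + 1, H) + (cl(x0 + 1, W) - 1) * H
  w00 <- (1 - fy) * (1 - fx) * ok(y0, x0)
  w01 <- (1 - fy) * fx * ok(y0, x0 + 1)
  w10 <- fy * (1 - fx) * ok(y0 + 1, x0)
  w11 <- fy * fx * ok(y0 + 1, x0 + 1)
  out <- array(0, dim(img))
  for (c in seq_len(C)) {
    p <- matrix(img[, , c], H, W)
    out[, , c] <- p[n00] * w00 + p[n01] * w01 + p[n10] * w10 + p[n11] * w11
  }
  out
}

# Format "mean ± sd" to four decimals (cross-fold table convention).
fmt_mean_sd <- function(m, s) sprintf("%.4f ± %.4f", m, s)
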