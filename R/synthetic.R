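# Synthetic eye-image generator.
#
# Produces reproducible labelled eye-like images whose class signal is
# deliberately split across color spaces: chromatic perturbations (redness
# of conjunctivitis / blepharitis) live mostly in hue, luminance
# perturbations (dark sequestrum plaque, bright ulcer blob, keratitis haze)
# mostly in value / luma. Nuisance illumination variation (brightness /
# contrast jitter, glare) is applied to every class so that the nuisance is
# not itself a label signal. Each image has its own RNG stream keyed by
# (seed, class, index), so subsetting and generation order are irrelevant.

#' Canonical class order
#'
#' The six classes in the fixed order used for labels, class weights and
#' confusion matrices: Blepharitis, Regular (healthy), Conjunctivitis,
#' Corneal Sequestrum, Corneal Ulcer, Non-Ulcerative Keratitis.
#' @export
CSF_CLASSES <- c("Blepharitis", "Regular", "Conjunctivitis",
                 "Corneal Sequestrum", "Corneal Ulcer",
                 "Non-Ulcerative Keratitis")

# classes whose perturbation is spatially localized (have a lesion mask)
CSF_LOCALIZED <- c("Blepharitis", "Conjunctivitis", "Corneal Sequestrum",
                   "Corneal Ulcer")

class_slug <- function(label) gsub("[^a-z0-9]+", "_", tolower(label))

#' Specification of a synthetic eye-image dataset
#'
#' @param n_per_class Images per class (with `class_imbalance`, the total
#'   `6 * n_per_class` is redistributed by the given proportions).
#' @param image_size Square image size in pixels (default 64).
#' @param seed Integer seed; identical specs produce byte-identical files.
#' @param nuisance_strength Illumination-nuisance magnitude in \[0, 1\].
#' @param class_imbalance Optional length-6 proportions summing to 1.
#' @param class_names The six class labels (fixed canonical order).
#' @return A `synthetic_spec` object.
#' @export
synthetic_spec <- function(n_per_class, image_size = 64, seed = 1,
                           nuisance_strength = 0, class_imbalance = NULL,
                           class_names = CSF_CLASSES) {
  if (n_per_class < 1) stop("n_per_class must be >= 1")
  if (length(class_names) != 6L) stop("exactly 6 class names are required")
  if (nuisance_strength < 0 || nuisance_strength > 1)
    stop("nuisance_strength must lie in [0, 1]")
  if (!is.null(class_imbalance)) {
    if (length(class_imbalance) != 6L)
      stop("class_imbalance must have 6 proportions")
    if (abs(sum(class_imbalance) - 1) > 1e-6)
      stop("class_imbalance proportions must sum to 1 (within 1e-6)")
  }
  structure(list(n_per_class = n_per_class, image_size = image_size,
                 seed = seed, nuisance_strength = nuisance_strength,
                 class_imbalance = class_imbalance,
                 class_names = class_names),
            class = "synthetic_spec")
}

# Per-class image counts: equal by default, else largest-remainder rounding
# of the requested proportions so the counts sum exactly to the total.
spec_class_counts <- function(spec) {
  if (is.null(spec$class_imbalance)) return(rep(spec$n_per_class, 6L))
  total <- spec$n_per_class * 6L
  raw <- spec$class_imbalance * total
  counts <- floor(raw)
  rem <- total - sum(counts)
  if (rem > 0) {
    order_frac <- order(raw - counts, decreasing = TRUE)
    counts[order_frac[seq_len(rem)]] <- counts[order_frac[seq_len(rem)]] + 1
  }
  as.integer(counts)
}

# disc / annulus helpers on a pixel grid
grid_dist <- function(S, cy, cx) {
  gy <- rep(seq_len(S), times = S); gx <- rep(seq_len(S), each = S)
  matrix(sqrt((gy - cy)^2 + (gx - cx)^2), S, S)
}

soft_disc <- function(S, cy, cx, r, soft = 1.5) {
  clip01((r - grid_dist(S, cy, cx)) / soft + 0.5)
}

# Render one eye image (+ lesion mask) for a given class using the stream
# keyed by (seed, class index, image index). Returns list(img, mask).
render_eye <- function(spec, class_idx, index) {
  S <- spec$image_size
  label <- spec$class_names[class_idx]
  set.seed(derive_seed(spec$seed, class_idx * 1009L, index))

  cy <- S / 2 + stats::runif(1, -0.02, 0.02) * S
  cx <- S / 2 + stats::runif(1, -0.02, 0.02) * S
  r_iris <- S * stats::runif(1, 0.40, 0.45)
  r_pupil <- S * stats::runif(1, 0.14, 0.18)

  sclera <- c(225, 218, 205) + stats::rnorm(3, 0, 1.5)
  iris <- c(150, 170, 110) + stats::rnorm(3, 0, 6)
  pupil <- c(25, 22, 20) + stats::rnorm(3, 0, 2)

  d <- grid_dist(S, cy, cx)
  w_iris <- soft_disc(S, cy, cx, r_iris)
  w_pupil <- soft_disc(S, cy, cx, r_pupil)

  img <- array(0, c(S, S, 3))
  # radial iris texture
  tex <- 1 + 0.08 * sin(d / S * 40 + stats::runif(1, 0, 2 * pi))
  for (c in 1:3) {
    base <- sclera[c] * (1 - w_iris) + iris[c] * tex * w_iris
    img[, , c] <- base * (1 - w_pupil) + pupil[c] * w_pupil
  }
  img <- img + array(stats::rnorm(S * S * 3, 0, 2.5), c(S, S, 3))

  mask <- matrix(FALSE, S, S)
  if (label == "Conjunctivitis") {
    # peripheral hue shift toward red on the sclera annulus
    # hue shifts toward red but stays clearly on the G > B side of the
    # red/magenta wrap-around so the mean annulus hue is a stable statistic
    w <- clip01((d - r_iris) / 1.5)
    img[, , 1] <- img[, , 1] + w * 25
    img[, , 2] <- img[, , 2] - w * 48
    img[, , 3] <- img[, , 3] - w * 62
    mask <- d > r_iris
  } else if (label == "Blepharitis") {
    # red, textured rim at the image border
    bw <- max(2L, round(0.09 * S))
    rim <- matrix(FALSE, S, S)
    rim[c(seq_len(bw), S - seq_len(bw) + 1L), ] <- TRUE
    rim[, c(seq_len(bw), S - seq_len(bw) + 1L)] <- TRUE
    tex_r <- matrix(stats::rnorm(S * S, 0, 12), S, S)
    img[, , 1][rim] <- img[, , 1][rim] + 45 + tex_r[rim]
    img[, , 2][rim] <- img[, , 2][rim] - 50 + 0.5 * tex_r[rim]
    img[, , 3][rim] <- img[, , 3][rim] - 40
    mask <- rim
  } else if (label == "Corneal Sequestrum") {
    # dark low-luminance plaque over the iris, jittered position
    pr <- S * stats::runif(1, 0.09, 0.13)
    ang <- stats::runif(1, 0, 2 * pi)
    rad <- stats::runif(1, 0, 0.45) * r_iris
    pcy <- cy + rad * sin(ang); pcx <- cx + rad * cos(ang)
    wp <- soft_disc(S, pcy, pcx, pr)
    plaque <- c(32, 22, 16)
    for (c in 1:3) img[, , c] <- img[, , c] * (1 - 0.9 * wp) +
      plaque[c] * 0.9 * wp
    mask <- wp > 0.5
  } else if (label == "Corneal Ulcer") {
    # bright irregular blob with local contrast loss
    pr <- S * stats::runif(1, 0.10, 0.14)
    ang <- stats::runif(1, 0, 2 * pi)
    rad <- stats::runif(1, 0, 0.4) * r_iris
    pcy <- cy + rad * sin(ang); pcx <- cx + rad * cos(ang)
    dd <- grid_dist(S, pcy, pcx)
    theta <- atan2(rep(seq_len(S), times = S) - pcy,
                   rep(seq_len(S), each = S) - pcx)
    wob <- matrix(1 + 0.25 * sin(3 * theta + stats::runif(1, 0, 2 * pi)), S, S)
    wu <- clip01((pr * wob - dd) / 1.5 + 0.5)
    local_mean <- mean(img[, , ][wu > 0.5])
    bright <- c(238, 235, 228)
    for (c in 1:3) {
      flat <- 0.55 * img[, , c] + 0.45 * local_mean   # contrast loss
      img[, , c] <- img[, , c] * (1 - wu) + (0.6 * bright[c] + 0.4 * flat) * wu
    }
    mask <- wu > 0.5
  } else if (label == "Non-Ulcerative Keratitis") {
    # global haze: luminance contrast reduced, chroma largely preserved
    h <- 0.32 + stats::runif(1, -0.04, 0.04)
    img <- (1 - h) * img + h * 200
  }

  # nuisance illumination, applied to every class
  nu <- spec$nuisance_strength
  if (nu > 0) {
    bf <- 1 + stats::runif(1, -0.25, 0.25) * nu
    cf <- 1 + stats::runif(1, -0.25, 0.25) * nu
    img <- img * bf
    img <- cf * img + (1 - cf) * mean(img)
    if (stats::runif(1) < 0.5 * nu) {
      gcy <- stats::runif(1, 0.2, 0.8) * S; gcx <- stats::runif(1, 0.2, 0.8) * S
      gry <- stats::runif(1, 0.05, 0.12) * S; grx <- stats::runif(1, 0.08, 0.18) * S
      gy <- rep(seq_len(S), times = S); gx <- rep(seq_len(S), each = S)
      wg <- clip01(1.2 - matrix(sqrt(((gy - gcy) / gry)^2 +
                                     ((gx - gcx) / grx)^2), S, S))
      a <- 0.7 * nu
      for (c in 1:3) img[, , c] <- img[, , c] * (1 - a * wg) + 255 * a * wg
    }
  }
  list(img = clip255(img), mask = mask)
}

#' Generate a labelled synthetic eye-image dataset
#'
#' Writes one PNG per image, a sidecar lesion mask PNG
#' (`<image_id>.mask.png`) for every image, and a `manifest.csv` with header
#' `filepath,label`. Regeneration under the same spec is byte-identical.
#'
#' @param spec A [synthetic_spec()].
#' @param out_dir Output directory (created if needed).
#' @return The dataset manifest, as returned by [load_manifest()].
#' @export
generate_dataset <- function(spec, out_dir) {
  stopifnot(inherits(spec, "synthetic_spec"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop("cannot create output directory: ", out_dir)
  counts <- spec_class_counts(spec)
  rows <- list()
  for (ci in seq_along(spec$class_names)) {
    label <- spec$class_names[ci]
    slug <- class_slug(label)
    for (i in seq_len(counts[ci])) {
      r <- render_eye(spec, ci, i)
      id <- sprintf("%s_%04d", slug, i)
      fp <- file.path(out_dir, paste0(id, ".png"))
      write_image(r$img, fp)
      png::writePNG(r$mask * 1.0, file.path(out_dir, paste0(id, ".mask.png")))
      rows[[length(rows) + 1L]] <- data.frame(filepath = paste0(id, ".png"),
                                              label = label,
                                              stringsAsFactors = FALSE)
    }
  }
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                   row.names = FALSE, quote = TRUE)
  load_manifest(file.path(out_dir, "manifest.csv"),
                class_names = spec$class_names)
}

#' Ground-truth lesion mask of a generated image
#'
#' Localized perturbation classes (blepharitis rim, conjunctivitis annulus,
#' sequestrum plaque, ulcer blob) have a non-empty planted mask; "Regular"
#' and the global-haze keratitis class return an empty mask.
#'
#' @param out_dir Directory the dataset was generated into.
#' @param image_id Image id (PNG file name without extension).
#' @return Logical H x W matrix.
#' @export
planted_lesion_mask <- function(out_dir, image_id) {
  path <- file.path(out_dir, paste0(image_id, ".mask.png"))
  if (!file.exists(path)) stop("unknown image_id: ", image_id)
  png::readPNG(path) > 0.5
}
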