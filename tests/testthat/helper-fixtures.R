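# Shared fixtures, generated once per test session and cached on disk under
# the session temp directory.

.fixture_env <- new.env(parent = emptyenv())

# clean synthetic dataset (no nuisance), 50 images/class at 64 px: used for
# generator statistics and learnability checks
fixture_clean_dataset <- function() {
  if (is.null(.fixture_env$clean)) {
    dir <- file.path(tempdir(), "csfnet-clean-data")
    spec <- synthetic_spec(n_per_class = 50, image_size = 64, seed = 7,
                           nuisance_strength = 0)
    manifest <- if (dir.exists(dir)) load_manifest(dir)
                else generate_dataset(spec, dir)
    .fixture_env$clean <- list(dir = dir, spec = spec, manifest = manifest)
  }
  .fixture_env$clean
}

# tiny dataset for fast training smoke tests (32 px, 8 images/class)
fixture_tiny_dataset <- function() {
  if (is.null(.fixture_env$tiny)) {
    dir <- file.path(tempdir(), "csfnet-tiny-data")
    spec <- synthetic_spec(n_per_class = 8, image_size = 32, seed = 11,
                           nuisance_strength = 0.25)
    manifest <- if (dir.exists(dir)) load_manifest(dir)
                else generate_dataset(spec, dir)
    .fixture_env$tiny <- list(dir = dir, spec = spec, manifest = manifest)
  }
  .fixture_env$tiny
}

# model / train configuration small enough for test-time training
tiny_model_config <- function(image_size = 32L, d = 32L) {
  model_config(backbone = "tinycnn", feature_dim = d,
               head_hidden = c(32L, 16L), dropout = 0.1,
               image_size = image_size)
}

# random RGB array fixture in [0, 255]
random_rgb <- function(h = 8, w = 8, seed = 1) {
  set.seed(seed)
  array(stats::runif(h * w * 3, 0, 255), c(h, w, 3))
}

# finite-difference gradient check of a layer against its backward pass,
# using a random linear functional of the output
expect_layer_gradient <- function(layer, x, training = TRUE, tol = 1e-6,
                                  eps = 1e-5) {
  set.seed(99)
  y0 <- nn_forward(layer, x, training)
  R <- array(stats::rnorm(length(y0)), dim(as.array(y0)))
  f <- function(xx) sum(nn_forward(layer, xx, training) * R)
  params <- nn_params(layer)
  zero_grads(params)
  nn_forward(layer, x, training)
  dx <- nn_backward(layer, R)
  # input gradient at a sample of positions
  pos <- sample(length(x), min(25, length(x)))
  for (i in pos) {
    xp <- x; xp[i] <- xp[i] + eps
    xm <- x; xm[i] <- xm[i] - eps
    g <- (f(xp) - f(xm)) / (2 * eps)
    expect_lt(abs(dx[i] - g), tol * max(1, abs(g)))
  }
  # parameter gradients at a sample of positions
  for (p in params) {
    pos <- sample(length(p$value), min(10, length(p$value)))
    for (i in pos) {
      v0 <- p$value[i]
      p$value[i] <- v0 + eps; fp <- f(x)
      p$value[i] <- v0 - eps; fm <- f(x)
      p$value[i] <- v0
      g <- (fp - fm) / (2 * eps)
      expect_lt(abs(p$grad[i] - g), tol * max(1, abs(g)))
    }
  }
  invisible(TRUE)
}

# connected-component count of a logical mask (4-connectivity flood fill);
# independent of any package code
n_components <- function(mask) {
  lab <- matrix(0L, nrow(mask), ncol(mask))
  comp <- 0L
  for (start in which(mask)) {
    if (lab[start] != 0L) next
    comp <- comp + 1L
    queue <- start
    lab[start] <- comp
    H <- nrow(mask)
    while (length(queue)) {
      cur <- queue[1]; queue <- queue[-1]
      r <- (cur - 1L) %% H + 1L
      cc <- (cur - 1L) %/% H + 1L
      for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
        rr <- r + d[1]; cc2 <- cc + d[2]
        if (rr >= 1 && rr <= H && cc2 >= 1 && cc2 <= ncol(mask)) {
          pos <- rr + (cc2 - 1L) * H
          if (mask[pos] && lab[pos] == 0L) {
            lab[pos] <- comp
            queue <- c(queue, pos)
          }
        }
      }
    }
  }
  comp
}
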