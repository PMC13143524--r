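# Model assembly: branch encoding, attention fusion, classification head,
# parameter accounting, variants and checkpoints.

test_that("branch encoders emit d-dimensional features independently per branch", {
  set.seed(1)
  cfg <- tiny_model_config()
  model <- build_variant("csfnet", cfg)
  x <- array(rnorm(3 * 32 * 32 * 2), c(3, 32, 32, 2))
  batch <- list(rgb = x, hsv = x + 1, ycbcr = x - 1)
  feats <- encode_branches(model, batch)
  expect_equal(sapply(feats, dim), matrix(c(2, 32), 2, 3,
               dimnames = list(NULL, c("rgb", "hsv", "ycbcr"))),
               ignore_attr = TRUE)
  # perturbing only the HSV plane changes only the HSV features
  batch2 <- batch
  batch2$hsv <- batch2$hsv + rnorm(length(x))
  feats2 <- encode_branches(model, batch2)
  expect_identical(feats$rgb, feats2$rgb)
  expect_identical(feats$ycbcr, feats2$ycbcr)
  expect_false(identical(feats$hsv, feats2$hsv))
})

test_that("zeroing a branch's final linear weights leaves only its bias", {
  set.seed(2)
  cfg <- tiny_model_config()
  model <- build_variant("csfnet", cfg)
  bb <- model$branches$hsv
  lin <- bb$net$layers[[length(bb$net$layers) - 1L]]
  expect_s3_class(lin, "nn_linear")
  lin$W$value[] <- 0
  x1 <- array(rnorm(3 * 32 * 32 * 1), c(3, 32, 32, 1))
  x2 <- array(rnorm(3 * 32 * 32 * 1), c(3, 32, 32, 1))
  f1 <- nn_forward(bb$net, x1)
  f2 <- nn_forward(bb$net, x2)
  expect_equal(f1, f2, tolerance = 1e-12)
  expect_equal(as.numeric(f1), pmax(lin$b$value, 0), tolerance = 1e-12)
})

test_that("single-token attention output equals the value projection exactly", {
  set.seed(3)
  att <- nn_attention(24, tokens = 1L)
  x <- matrix(rnorm(5 * 24), 5, 24)
  out <- nn_forward(att, x)
  vproj <- sweep(x %*% att$Wv$value, 2, att$bv$value, "+")
  expect_identical(out, vproj)
  # with an identity value projection the output equals the input
  att$Wv$value <- diag(24)
  att$bv$value[] <- 0
  expect_equal(nn_forward(att, x), x, tolerance = 1e-15)
})

test_that("in single-token mode gradients reach W_v but not W_q / W_k", {
  set.seed(4)
  att <- nn_attention(16, tokens = 1L)
  x <- matrix(rnorm(3 * 16), 3, 16)
  zero_grads(nn_params(att))
  nn_forward(att, x)
  nn_backward(att, matrix(rnorm(3 * 16), 3, 16))
  expect_gt(max(abs(att$Wv$grad)), 0)
  expect_equal(max(abs(att$Wq$grad)), 0)
  expect_equal(max(abs(att$Wk$grad)), 0)
})

test_that("three-token attention weights match a brute-force softmax oracle", {
  set.seed(5)
  d <- 4L
  att <- nn_attention(3L * d, tokens = 3L)
  x <- matrix(rnorm(2 * 12), 2, 12)
  out <- nn_forward(att, x)
  # brute force per sample: tokens are the three d-wide slices
  for (n in 1:2) {
    toks <- lapply(1:3, function(t) x[n, ((t - 1) * d + 1):(t * d)])
    Q <- lapply(toks, function(v) drop(v %*% att$Wq$value) + att$bq$value)
    K <- lapply(toks, function(v) drop(v %*% att$Wk$value) + att$bk$value)
    V <- lapply(toks, function(v) drop(v %*% att$Wv$value) + att$bv$value)
    for (i in 1:3) {
      s <- sapply(1:3, function(j) sum(Q[[i]] * K[[j]])) / sqrt(d)
      a <- exp(s - max(s)); a <- a / sum(a)
      o_ref <- Reduce(`+`, lapply(1:3, function(j) a[j] * V[[j]]))
      expect_equal(out[n, ((i - 1) * d + 1):(i * d)], o_ref,
                   tolerance = 1e-12)
      expect_equal(att$A[n, i, ], a, tolerance = 1e-12)
    }
  }
})

test_that("classification emits logits in training and normalized probabilities at inference", {
  set.seed(6)
  cfg <- model_config(backbone = "tinycnn", feature_dim = 32L,
                      head_hidden = c(32L, 16L), dropout = 0,
                      image_size = 32L)
  model <- build_variant("csfnet", cfg)
  f <- matrix(rnorm(4 * 96), 4, 96)
  probs <- classify(model, f, training = FALSE)
  expect_equal(rowSums(probs), rep(1, 4), tolerance = 1e-6)
  # with the head's dropout disabled, training-mode logits only differ from
  # inference by batch-norm statistics; compare against eval-mode logits
  logits <- nn_forward(model$head, f, training = FALSE)
  expect_equal(max.col(probs), max.col(logits))
  expect_equal(probs, softmax_rows(logits), tolerance = 1e-12)
  # equal logits give uniform probabilities
  expect_equal(as.numeric(softmax_rows(matrix(3.7, 1, 6))), rep(1 / 6, 6))
  # argmax of softmax equals argmax of logits on random vectors
  z <- matrix(rnorm(1000 * 6), 1000, 6)
  expect_equal(max.col(softmax_rows(z)), max.col(z))
})

test_that("parameter accounting matches the closed-form layer sums", {
  set.seed(7)
  cfg <- model_config()  # canonical backbone, d = 1024
  model <- build_variant("csfnet", cfg)
  # head: (3072*1024 + 1024) + 2*1024 + (1024*512 + 512) + 2*512 + (512*6 + 6)
  expect_equal(count_parameters(model$head), 3677702)
  # attention: 3 * (3072^2 + 3072)
  expect_equal(count_parameters(model$fusion), 3 * (3072^2 + 3072))
  # one branch: canonical small backbone sans 1000-way classifier
  expect_equal(count_parameters(model$branches$rgb$net), 1517856)
  expect_equal(count_parameters(model), 36552038)
})

test_that("variant registry builds consistent architectures", {
  set.seed(8)
  cfg <- tiny_model_config()
  full <- build_variant("csfnet", cfg)
  noatt <- build_variant("fusion-no-attention", cfg)
  d3 <- 3L * cfg$feature_dim
  expect_equal(count_parameters(full) - count_parameters(noatt),
               3 * (d3^2 + d3))
  # rgb-only accepts a bare RGB batch
  rgb_only <- build_variant("rgb-only", cfg)
  x <- array(rnorm(3 * 32 * 32 * 2), c(3, 32, 32, 2))
  p <- predict_proba(rgb_only, x)
  expect_equal(dim(p), c(2L, 6L))
  expect_equal(rowSums(p), rep(1, 2), tolerance = 1e-6)
  # baselines share the single-backbone contract
  base <- build_variant("baseline-resnet50", cfg)
  expect_equal(length(base$branches), 1L)
  expect_equal(dim(predict_proba(base, x)), c(2L, 6L))
  expect_error(build_variant("no-such-variant", cfg), "unknown variant")
  # channel-gate variants preserve dimensions
  for (tag in c("fusion-se", "fusion-cbam-channel", "fusion-eca",
                "fusion-nam")) {
    v <- build_variant(tag, cfg)
    expect_equal(dim(predict_proba(v, list(rgb = x, hsv = x, ycbcr = x))),
                 c(2L, 6L))
  }
})

test_that("the SE fusion gate equals a hand-computed sigmoid gate", {
  set.seed(9)
  se <- nn_se1d(8, reduction = 16)  # squeeze width max(1, 8 %/% 16) = 1
  x <- matrix(rnorm(8), 1, 8)
  out <- nn_forward(se, x)
  z <- pmax(drop(x %*% se$fc1$W$value) + se$fc1$b$value, 0)
  g <- 1 / (1 + exp(-(drop(z %*% se$fc2$W$value) + se$fc2$b$value)))
  expect_equal(as.numeric(out), as.numeric(x) * g, tolerance = 1e-12)
})

test_that("evaluation-mode forward is bitwise repeatable", {
  set.seed(10)
  model <- build_variant("csfnet", tiny_model_config())
  x <- array(rnorm(3 * 32 * 32 * 2), c(3, 32, 32, 2))
  batch <- list(rgb = x, hsv = x, ycbcr = x)
  y1 <- model_forward(model, batch, training = FALSE)
  y2 <- model_forward(model, batch, training = FALSE)
  expect_identical(y1, y2)
})

test_that("checkpoints restore weights, buffers and metadata exactly", {
  set.seed(11)
  model <- build_variant("csfnet", tiny_model_config())
  x <- array(rnorm(3 * 32 * 32 * 2), c(3, 32, 32, 2))
  batch <- list(rgb = x, hsv = x + 0.5, ycbcr = x - 0.5)
  model_forward(model, batch, training = TRUE)  # move BN buffers
  y <- model_forward(model, batch, training = FALSE)
  path <- withr::local_tempfile(fileext = ".rds")
  save_checkpoint(model, path, extra = list(note = "test"))
  set.seed(99)
  restored <- load_checkpoint(path)
  expect_equal(model_forward(restored, batch, training = FALSE), y,
               tolerance = 1e-15)
  expect_equal(attr(restored, "extra")$note, "test")
  expect_equal(restored$variant, "csfnet")
})

test_that("default architecture dimensions follow the printed design", {
  cfg <- model_config()
  expect_equal(cfg$feature_dim, 1024L)
  expect_equal(cfg$head_hidden, c(1024L, 512L))
  set.seed(12)
  att <- nn_attention(3072, tokens = 1L)
  expect_equal(att$dt, 3072L)  # d_k = full fused width in single-token mode
})
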