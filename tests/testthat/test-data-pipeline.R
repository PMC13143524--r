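# Manifest loading, stratified folds and inverse-frequency class weights.

write_manifest_csv <- function(dir, labels, files = NULL) {
  if (is.null(files)) files <- sprintf("img%03d.png", seq_along(labels))
  for (f in files) write_image(array(runif(12, 0, 255), c(2, 2, 3)),
                               file.path(dir, f))
  path <- file.path(dir, "manifest.csv")
  utils::write.csv(data.frame(filepath = files, label = labels), path,
                   row.names = FALSE)
  path
}

test_that("manifest loading maps labels and excludes unmapped records", {
  dir <- withr::local_tempdir()
  path <- write_manifest_csv(dir, CSF_CLASSES)
  m <- load_manifest(path)
  expect_s3_class(m, "csf_manifest")
  expect_equal(nrow(m), 6L)
  expect_equal(unname(attr(m, "counts")), rep(1L, 6))
  expect_equal(m$class_id, 1:6)

  # a record with an unknown label is excluded and logged
  dir2 <- withr::local_tempdir()
  path2 <- write_manifest_csv(dir2, c(CSF_CLASSES, "Glaucoma"))
  m2 <- load_manifest(path2)
  expect_equal(nrow(m2), 6L)
  expect_equal(nrow(attr(m2, "excluded")), 1L)
  expect_equal(attr(m2, "excluded")$label, "Glaucoma")
})

test_that("duplicate filepaths and empty manifests are rejected", {
  dir <- withr::local_tempdir()
  path <- write_manifest_csv(dir, c("Regular", "Regular"),
                             files = c("a.png", "a.png"))
  expect_error(load_manifest(path), "duplicate")
  expect_error(load_manifest(file.path(dir, "missing.csv")), "not exist")
  dir3 <- withr::local_tempdir()
  path3 <- write_manifest_csv(dir3, c("Foo", "Bar"))
  expect_error(load_manifest(path3), "mappable")
})

test_that("directory-per-class layouts are read", {
  dir <- withr::local_tempdir()
  for (lbl in c("Regular", "Blepharitis")) {
    sub <- file.path(dir, lbl)
    dir.create(sub)
    for (i in 1:3) write_image(array(runif(12, 0, 255), c(2, 2, 3)),
                               file.path(sub, paste0(i, ".png")))
  }
  m <- load_manifest(dir)
  expect_equal(nrow(m), 6L)
  expect_equal(sort(unique(m$label)), c("Blepharitis", "Regular"))
})

test_that("stratified folds are exact covers with forced per-class counts", {
  dir <- withr::local_tempdir()
  path <- write_manifest_csv(dir, rep(c("Regular", "Blepharitis"), each = 5))
  m <- load_manifest(path)
  folds <- stratified_kfold(m, k = 5, seed = 3)
  for (f in 1:5) {
    idx <- fold_indices(folds, f)
    expect_equal(sort(c(idx$train, idx$val)), 1:10)
    expect_length(intersect(idx$train, idx$val), 0)
    expect_equal(unname(table(m$label[idx$val])), c(1L, 1L),
                 ignore_attr = TRUE)
  }
  # divisible counts (10, 50, 10, 10, 10, 10) with k = 5
  spec <- synthetic_spec(100 / 6, image_size = 16, seed = 2,
                         class_imbalance = c(.1, .5, .1, .1, .1, .1))
  d2 <- withr::local_tempdir()
  m2 <- generate_dataset(spec, d2)
  folds2 <- stratified_kfold(m2, k = 5, seed = 1)
  for (f in 1:5) {
    idx <- fold_indices(folds2, f)
    cnt <- table(factor(m2$label[idx$val], levels = CSF_CLASSES))
    expect_equal(unname(c(cnt)), c(2, 10, 2, 2, 2, 2))
  }
})

test_that("fold splitting is seed-deterministic with stable per-class counts", {
  fx <- fixture_tiny_dataset()
  f1 <- stratified_kfold(fx$manifest, k = 4, seed = 9)
  f2 <- stratified_kfold(fx$manifest, k = 4, seed = 9)
  f3 <- stratified_kfold(fx$manifest, k = 4, seed = 10)
  expect_identical(f1$assignment, f2$assignment)
  expect_false(identical(f1$assignment, f3$assignment))
  # different seeds still balance classes identically
  for (f in 1:4) {
    c1 <- table(fx$manifest$class_id[fold_indices(f1, f)$val])
    c3 <- table(fx$manifest$class_id[fold_indices(f3, f)$val])
    expect_equal(c1, c3)
  }
  expect_error(stratified_kfold(fx$manifest, k = 10), "at least k")
})

test_that("stratification error is at most one per class per fold", {
  set.seed(21)
  for (rep in 1:20) {
    k <- sample(2:6, 1)
    counts <- sample(k:30, 6, replace = TRUE)
    labels <- rep(CSF_CLASSES, times = counts)
    m <- structure(data.frame(filepath = sprintf("f%04d", seq_along(labels)),
                              label = labels,
                              class_id = match(labels, CSF_CLASSES)),
                   class = c("csf_manifest", "data.frame"),
                   class_names = CSF_CLASSES,
                   counts = stats::setNames(counts, CSF_CLASSES),
                   excluded = data.frame())
    folds <- stratified_kfold(m, k = k, seed = rep)
    expect_equal(sort(unlist(lapply(1:k, function(f)
      fold_indices(folds, f)$val))), seq_along(labels))
    for (f in 1:k) {
      vc <- table(factor(m$label[fold_indices(folds, f)$val],
                         levels = CSF_CLASSES))
      expect_true(all(abs(vc - counts / k) <= 1))
    }
  }
})

test_that("class weights implement normalized inverse frequency", {
  # balanced counts give unit weights
  expect_equal(compute_class_weights(rep(7L, 6)), rep(1, 6))
  expect_equal(compute_class_weights(rep(123L, 4)), rep(1, 4))
  # N = 100, C = 3, counts (10, 30, 60) -> (10/3, 10/9, 5/9)
  expect_equal(compute_class_weights(c(10L, 30L, 60L)),
               c(10 / 3, 10 / 9, 5 / 9), tolerance = 1e-12)
  # weighted-count identity sum(w_c * N_c) = N
  set.seed(5)
  for (i in 1:25) {
    counts <- sample(1:500, sample(2:8, 1), replace = TRUE)
    w <- compute_class_weights(counts)
    expect_equal(sum(w * counts), sum(counts), tolerance = 1e-9)
  }
  expect_error(compute_class_weights(c(3L, 0L)), "at least one")
})

test_that("fold export writes filepath, label and fold columns", {
  fx <- fixture_tiny_dataset()
  folds <- stratified_kfold(fx$manifest, k = 2, seed = 1)
  path <- withr::local_tempfile(fileext = ".csv")
  export_folds(fx$manifest, folds, path)
  df <- utils::read.csv(path)
  expect_equal(names(df), c("filepath", "label", "fold"))
  expect_equal(nrow(df), nrow(fx$manifest))
  expect_true(all(df$fold %in% 1:2))
})
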