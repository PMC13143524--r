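# Dataset manifests, stratified k-fold splits and inverse-frequency class
# weights.

#' Load a labelled image manifest
#'
#' Accepts either a manifest CSV with header `filepath,label`, a directory
#' containing `manifest.csv`, or a directory-per-class layout (one
#' subdirectory per class holding images). Labels are mapped to integer
#' class ids via `class_names` (canonical order: Blepharitis, Regular,
#' Conjunctivitis, Corneal Sequestrum, Corneal Ulcer, Non-Ulcerative
#' Keratitis); records with missing or unmapped labels are excluded and
#' recorded in the `excluded` attribute.
#'
#' @param path Manifest CSV path or dataset directory.
#' @param class_names Label strings defining the class order.
#' @return A `csf_manifest`: data.frame with columns `filepath`, `label`,
#'   `class_id` (1-based), plus attributes `class_names`, `counts`,
#'   `excluded`.
#' @export
load_manifest <- function(path, class_names = CSF_CLASSES) {
  base_dir <- NULL
  if (dir.exists(path)) {
    mf <- file.path(path, "manifest.csv")
    if (file.exists(mf)) {
      df <- utils::read.csv(mf, stringsAsFactors = FALSE)
      base_dir <- path
    } else {
      subdirs <- list.dirs(path, recursive = FALSE)
      if (length(subdirs) == 0L) stop("no readable records under ", path)
      df <- do.call(rbind, lapply(subdirs, function(d) {
        files <- list.files(d, pattern = "\\.(png|jpg|jpeg)$",
                            ignore.case = TRUE, full.names = TRUE)
        files <- files[!grepl("\\.mask\\.png$", files)]
        if (length(files) == 0L) return(NULL)
        data.frame(filepath = files, label = basename(d),
                   stringsAsFactors = FALSE)
      }))
    }
  } else if (file.exists(path)) {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    base_dir <- dirname(path)
  } else {
    stop("manifest path does not exist: ", path)
  }
  if (is.null(df) || nrow(df) == 0L) stop("no readable records under ", path)
  if (!all(c("filepath", "label") %in% names(df)))
    stop("manifest must have columns 'filepath' and 'label'")
  if (!is.null(base_dir)) {
    rel <- !grepl("^(/|[A-Za-z]:)", df$filepath)
    df$filepath[rel] <- file.path(base_dir, df$filepath[rel])
  }
  if (anyDuplicated(df$filepath))
    stop("duplicate filepaths in manifest: ",
         df$filepath[duplicated(df$filepath)][1])
  mapped <- !is.na(df$label) & df$label %in% class_names
  excluded <- df[!mapped, , drop = FALSE]
  df <- df[mapped, , drop = FALSE]
  if (nrow(df) == 0L) stop("no records with mappable labels")
  df$class_id <- match(df$label, class_names)
  rownames(df) <- NULL
  counts <- as.integer(table(factor(df$class_id,
                                    levels = seq_along(class_names))))
  names(counts) <- class_names
  structure(df, class = c("csf_manifest", "data.frame"),
            class_names = class_names, counts = counts, excluded = excluded)
}

#' @export
print.csf_manifest <- function(x, ...) {
  counts <- attr(x, "counts")
  cat("Dataset manifest: ", nrow(x), " images, ", length(counts),
      " classes\n", sep = "")
  for (i in seq_along(counts))
    cat(sprintf("  %-26s %d\n", names(counts)[i], counts[i]))
  nex <- nrow(attr(x, "excluded"))
  if (nex > 0) cat("  (", nex, " records excluded: unmapped labels)\n", sep = "")
  invisible(x)
}

manifest_counts <- function(manifest) attr(manifest, "counts")

#' Stratified k-fold split of a manifest
#'
#' Each class is shuffled under the seed and dealt round-robin to the k
#' folds, so per-class validation counts differ from N_c / k by at most 1,
#' every index appears in exactly one fold's validation set, and each fold's
#' training set is the complement of its validation set.
#'
#' @param manifest A `csf_manifest`.
#' @param k Number of folds (default 5).
#' @param seed Integer seed for the per-class shuffles.
#' @return A `csf_folds` object: `assignment` (validation fold id per row),
#'   `k`, `seed`.
#' @export
stratified_kfold <- function(manifest, k = 5, seed = 1) {
  counts <- manifest_counts(manifest)
  low <- counts[counts > 0 & counts < k]  # absent classes are simply unused
  if (length(low) > 0)
    stop("class '", names(low)[1], "' has ", low[1],
         " samples; need at least k = ", k)
  assignment <- integer(nrow(manifest))
  set.seed(derive_seed(seed, 77L))
  for (ci in sort(unique(manifest$class_id))) {
    idx <- which(manifest$class_id == ci)
    idx <- idx[sample.int(length(idx))]
    assignment[idx] <- rep_len(seq_len(k), length(idx))
  }
  structure(list(assignment = assignment, k = k, seed = seed),
            class = "csf_folds")
}

#' Train / validation indices of one fold
#' @param folds A `csf_folds` object.
#' @param fold Fold id in 1..k.
#' @return List with integer vectors `train` and `val`.
#' @export
fold_indices <- function(folds, fold) {
  stopifnot(fold >= 1, fold <= folds$k)
  list(train = which(folds$assignment != fold),
       val = which(folds$assignment == fold))
}

#' Export fold assignments as a CSV (`filepath,label,fold`)
#' @param manifest A `csf_manifest`.
#' @param folds Matching `csf_folds`.
#' @param path Output CSV path.
#' @export
export_folds <- function(manifest, folds, path) {
  utils::write.csv(data.frame(filepath = manifest$filepath,
                              label = manifest$label,
                              fold = folds$assignment),
                   path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Normalized inverse-frequency class weights
#'
#' w_c = N / (N_c * C): the balanced case gives every class weight 1, and
#' the weighted count identity sum_c w_c N_c = N always holds.
#'
#' @param x A `csf_manifest`, or an integer vector of per-class counts.
#' @return Numeric weight vector (length C).
#' @export
compute_class_weights <- function(x) {
  counts <- if (inherits(x, "csf_manifest")) manifest_counts(x) else x
  if (any(counts <= 0))
    stop("every class must have at least one sample to compute weights")
  N <- sum(counts); C <- length(counts)
  as.numeric(N / (counts * C))
}
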