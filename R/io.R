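# BraTS-layout cohort I/O: <ID>/<ID>_{flair,t1,t1ce,t2,seg}.nii.gz

.modalities <- c("t1", "t1ce", "t2", "flair")

#' Subject record
#'
#' Bundles the file paths of one patient's four co-registered MRI modalities
#' (T1, T1ce, T2, FLAIR) and, optionally, the segmentation mask.
#'
#' @param subject_id Non-empty subject identifier.
#' @param modality_paths Named list/vector with exactly the entries
#'   `t1`, `t1ce`, `t2`, `flair`.
#' @param mask_path Optional path to the segmentation mask.
#' @return An object of class `subject_record`.
#' @export
subject_record <- function(subject_id, modality_paths, mask_path = NULL) {
  if (!is.character(subject_id) || length(subject_id) != 1L ||
      !nzchar(subject_id))
    stop("subject_record: subject_id must be a non-empty string")
  modality_paths <- as.list(modality_paths)
  missing <- setdiff(.modalities, names(modality_paths))
  if (length(missing))
    stop("subject_record: missing modality path(s): ",
         paste(missing, collapse = ", "))
  extra <- setdiff(names(modality_paths), .modalities)
  if (length(extra))
    stop("subject_record: unknown modality name(s): ",
         paste(extra, collapse = ", "))
  structure(list(subject_id = subject_id,
                 modality_paths = modality_paths[.modalities],
                 mask_path = mask_path),
            class = "subject_record")
}

#' Locate a BraTS-layout subject directory
#'
#' Builds a [subject_record()] from the standard layout
#' `<dir>/<id>/<id>_{flair,t1,t1ce,t2,seg}.nii.gz`. The mask entry is included
#' only when the `seg` file exists.
#'
#' @param dir Cohort root directory.
#' @param id Subject identifier (directory name).
#' @return A `subject_record`.
#' @export
brats_subject_record <- function(dir, id) {
  base <- file.path(dir, id, paste0(id, "_"))
  paths <- stats::setNames(paste0(base, .modalities, ".nii.gz"), .modalities)
  seg <- paste0(base, "seg.nii.gz")
  subject_record(id, as.list(paths),
                 mask_path = if (file.exists(seg)) seg else NULL)
}

#' Read one subject's volumes
#'
#' Reads the four modality volumes (and the mask, if recorded) as plain R
#' arrays with the NIfTI affine attached as attribute `"affine"`. Raw mask
#' values are preserved; remapping is a separate, observable step
#' ([remap_labels()]).
#'
#' @param record A [subject_record()].
#' @return A list with `volumes` (named list of 3D arrays, order t1, t1ce,
#'   t2, flair), `mask` (3D integer array or `NULL`) and `subject_id`.
#' @export
read_subject <- function(record) {
  stopifnot(inherits(record, "subject_record"))
  vols <- lapply(.modalities, function(m) {
    path <- record$modality_paths[[m]]
    if (!file.exists(path))
      stop("read_subject: missing file for modality '", m, "': ", path)
    read_nifti_array(path)
  })
  names(vols) <- .modalities
  shapes <- vapply(vols, function(v) paste(dim(v), collapse = "x"), "")
  if (length(unique(shapes)) != 1L)
    stop("read_subject: modality volume shapes differ: ",
         paste(sprintf("%s=%s", names(shapes), shapes), collapse = ", "))
  mask <- NULL
  if (!is.null(record$mask_path)) {
    if (!file.exists(record$mask_path))
      stop("read_subject: missing mask file: ", record$mask_path)
    mask <- read_nifti_array(record$mask_path)
    storage.mode(mask) <- "integer"
    if (!identical(dim(mask), dim(vols[[1L]])))
      stop("read_subject: mask shape differs from modality shape")
  }
  list(subject_id = record$subject_id, volumes = vols, mask = mask)
}

#' @noRd
read_nifti_array <- function(path) {
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  aff <- matrix(as.numeric(RNifti::xform(img)), 4L, 4L)
  attributes(arr) <- list(dim = dim(img))
  attr(arr, "affine") <- aff
  arr
}

#' Write a volume as NIfTI-1
#'
#' @param volume 3D or 4D numeric/integer array.
#' @param path Output path (`.nii` or `.nii.gz`).
#' @param affine Optional 4x4 spatial transform (defaults to the array's
#'   `"affine"` attribute, else identity spacing).
#' @return The path, invisibly.
#' @export
write_nifti <- function(volume, path, affine = NULL) {
  nd <- length(dim(volume))
  if (is.null(dim(volume)) || nd < 3L || nd > 4L)
    stop("write_nifti: volume must be a 3D or 4D array")
  if (is.null(affine)) affine <- attr(volume, "affine")
  attr(volume, "affine") <- NULL
  img <- RNifti::asNifti(volume)
  if (!is.null(affine)) {
    RNifti::sform(img) <- structure(affine, code = 2L)
  }
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  RNifti::writeNifti(img, path,
                     datatype = if (is.integer(volume)) "int16" else "double")
  invisible(path)
}

#' Remap raw BraTS labels
#'
#' BraTS masks use raw labels \{0, 1, 2, 4\}; label 4 (enhancing tumor) is
#' remapped to 3 so classes are contiguous. Idempotent: masks already in
#' \{0, 1, 2, 3\} pass through unchanged.
#'
#' @param mask 3D integer array (or any integer vector/array).
#' @return The mask with every 4 replaced by 3.
#' @export
remap_labels <- function(mask) {
  vals <- unique(as.integer(mask))
  bad <- setdiff(vals, c(0L, 1L, 2L, 3L, 4L))
  if (length(bad))
    stop("remap_labels: unexpected label value(s): ",
         paste(sort(bad), collapse = ", "))
  mask[mask == 4L] <- 3L
  mask
}

#' Deterministic cohort split
#'
#' Shuffles subject ids with a seeded pseudo-random permutation and cuts them
#' into train/validation/test partitions. Sizes follow the floor rule:
#' `n_train = floor(f_train * n)`, `n_val = floor(f_val * n)`, remainder to
#' test — for 1,250 subjects at 70/10/20 this gives (875, 125, 250). With a
#' `strata` grouping the rule is applied within every stratum
#' (class-balanced split).
#'
#' @param subject_ids Character vector of unique subject ids.
#' @param fractions Numeric triple `(f_train, f_val, f_test)`, non-negative,
#'   summing to 1.
#' @param seed Integer seed; identical inputs give identical member lists.
#' @param strata Optional per-subject grouping for a stratified split.
#' @return A list of class `dataset_split` with `train_ids`, `val_ids`,
#'   `test_ids`, `fractions` and `seed`.
#' @examples
#' sp <- make_split(sprintf("S%04d", 1:1250), c(0.7, 0.1, 0.2), seed = 1)
#' lengths(sp[c("train_ids", "val_ids", "test_ids")]) # 875 125 250
#' @export
make_split <- function(subject_ids, fractions = c(0.7, 0.1, 0.2), seed = 42L,
                       strata = NULL) {
  if (anyDuplicated(subject_ids))
    stop("make_split: duplicate subject ids")
  if (length(fractions) != 3L || any(fractions < 0) ||
      abs(sum(fractions) - 1) > 1e-9)
    stop("make_split: fractions must be 3 non-negative values summing to 1")
  if (!is.null(strata) && length(strata) != length(subject_ids))
    stop("make_split: strata must match subject_ids in length")

  split_one <- function(ids, seed) {
    n <- length(ids)
    shuffled <- with_seed(seed, sample(ids, n))
    n_train <- floor(fractions[1L] * n)
    n_val <- floor(fractions[2L] * n)
    list(train = shuffled[seq_len(n_train)],
         val = shuffled[n_train + seq_len(n_val)],
         test = shuffled[setdiff(seq_len(n), seq_len(n_train + n_val))])
  }
  if (is.null(strata)) {
    parts <- split_one(subject_ids, seed)
  } else {
    groups <- split(subject_ids, strata)
    sub <- lapply(seq_along(groups), function(i)
      split_one(groups[[i]], seed + i - 1L))
    parts <- list(train = unlist(lapply(sub, `[[`, "train"), use.names = FALSE),
                  val = unlist(lapply(sub, `[[`, "val"), use.names = FALSE),
                  test = unlist(lapply(sub, `[[`, "test"), use.names = FALSE))
  }
  structure(list(train_ids = parts$train, val_ids = parts$val,
                 test_ids = parts$test,
                 fractions = fractions, seed = as.integer(seed)),
            class = "dataset_split")
}

#' @export
print.dataset_split <- function(x, ...) {
  cat(sprintf("dataset_split: %d train / %d val / %d test (seed %d)\n",
              length(x$train_ids), length(x$val_ids), length(x$test_ids),
              x$seed))
  invisible(x)
}

#' Write / read a split manifest
#'
#' Plain CSV with columns `subject_id` and `partition`.
#'
#' @param split A `dataset_split`.
#' @param path CSV file path.
#' @return `write_manifest` the path; `read_manifest` a `dataset_split`
#'   (fractions recovered from partition sizes).
#' @export
write_manifest <- function(split, path) {
  stopifnot(inherits(split, "dataset_split"))
  df <- data.frame(
    subject_id = c(split$train_ids, split$val_ids, split$test_ids),
    partition = rep(c("train", "val", "test"),
                    c(length(split$train_ids), length(split$val_ids),
                      length(split$test_ids))))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_manifest
#' @param path CSV file path.
#' @export
read_manifest <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("subject_id", "partition") %in% names(df)))
  n <- nrow(df)
  parts <- split(df$subject_id, factor(df$partition,
                                       levels = c("train", "val", "test")))
  structure(list(train_ids = parts$train %||% character(),
                 val_ids = parts$val %||% character(),
                 test_ids = parts$test %||% character(),
                 fractions = if (n) lengths(parts) / n else c(0, 0, 0),
                 seed = NA_integer_),
            class = "dataset_split")
}

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

# Runs expr under a temporary RNG state so library calls never disturb the
# caller's random stream.
#' @noRd
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}
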