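# Hard per-region Dice evaluation over the BraTS regions:
#   ET (enhancing tumor)  = label {3}
#   TC (tumor core)       = labels {1, 3}  (tumor excluding edema)
#   WT (whole tumor)      = labels {1, 2, 3}

#' Region specification
#'
#' Named binary-region definition as a set of (remapped) label values. The
#' three standard regions nest: ET (3) within TC (1, 3) within WT (1, 2, 3).
#'
#' @param name Region name.
#' @param labels Integer label values belonging to the region.
#' @return An object of class `region_spec`.
#' @export
region_spec <- function(name, labels) {
  structure(list(name = name, labels = as.integer(labels)),
            class = "region_spec")
}

#' @rdname region_spec
#' @export
brats_regions <- function() {
  list(ET = region_spec("ET", 3L),
       TC = region_spec("TC", c(1L, 3L)),
       WT = region_spec("WT", c(1L, 2L, 3L)))
}

#' Binary region mask
#'
#' True exactly where the voxel label belongs to the region. Refuses
#' unremapped masks (raw label 4 present).
#'
#' @param mask 3D integer array with remapped labels in \{0, 1, 2, 3\}.
#' @param region A [region_spec()].
#' @return Logical array of the mask's shape.
#' @export
region_mask <- function(mask, region) {
  stopifnot(inherits(region, "region_spec"))
  if (any(mask == 4L))
    stop("region_mask: raw label 4 present; run remap_labels() first")
  array(mask %in% region$labels, dim(mask) %||% length(mask))
}

#' Hard Dice score
#'
#' `2|X intersect Y| / (|X| + |Y|)` between two binary masks. When both masks
#' are empty the score is 1 (nothing to find, nothing found — the BraTS
#' community convention); when exactly one is empty it is 0.
#'
#' @param x,y Binary (logical or 0/1) arrays of identical shape.
#' @return Dice score in `[0, 1]`.
#' @examples
#' hard_dice(c(1, 1, 0, 0), c(0, 1, 1, 0)) # 0.5
#' @export
hard_dice <- function(x, y) {
  if (length(x) != length(y) || !identical(dim(x), dim(y)))
    stop("hard_dice: shape mismatch")
  x <- as.logical(x); y <- as.logical(y)
  nx <- sum(x); ny <- sum(y)
  if (nx + ny == 0L) return(1.0)
  2 * sum(x & y) / (nx + ny)
}

#' Evaluate a cohort of predictions
#'
#' Computes the per-subject, per-region hard Dice between predicted and
#' ground-truth label volumes, plus unweighted cohort means. Deterministic.
#'
#' @param predictions Named list of predicted label arrays (remapped labels).
#' @param ground_truth Named list of ground-truth label arrays; must contain
#'   every prediction's subject.
#' @param regions List of [region_spec()]s (default [brats_regions()]).
#' @return An object of class `dice_report`: a data.frame with one row per
#'   subject and one column per region, plus attribute `"means"`.
#' @export
evaluate_cohort <- function(predictions, ground_truth,
                            regions = brats_regions()) {
  ids <- names(predictions)
  if (is.null(ids) || any(!nzchar(ids)))
    stop("evaluate_cohort: predictions must be a named list")
  missing <- setdiff(ids, names(ground_truth))
  if (length(missing))
    stop("evaluate_cohort: missing ground truth for subject(s): ",
         paste(missing, collapse = ", "))
  rows <- lapply(ids, function(id) {
    p <- predictions[[id]]; g <- ground_truth[[id]]
    vapply(regions, function(r)
      hard_dice(region_mask(p, r), region_mask(g, r)), numeric(1))
  })
  df <- as.data.frame(do.call(rbind, rows))
  names(df) <- names(regions)
  df <- cbind(subject_id = ids, df)
  rownames(df) <- NULL
  attr(df, "means") <- colMeans(df[, names(regions), drop = FALSE])
  class(df) <- c("dice_report", "data.frame")
  df
}

#' @export
print.dice_report <- function(x, ...) {
  cat("Per-region hard Dice (", nrow(x), " subject",
      if (nrow(x) != 1L) "s", ")\n", sep = "")
  print.data.frame(x, row.names = FALSE, digits = 4)
  m <- attr(x, "means")
  cat("cohort means: ",
      paste(sprintf("%s=%.4f", names(m), m), collapse = "  "), "\n", sep = "")
  invisible(x)
}

#' Write a Dice report as CSV
#'
#' One row per subject plus a final `mean` summary row.
#'
#' @param report A `dice_report`.
#' @param path Output CSV path.
#' @return The path, invisibly.
#' @export
write_dice_report <- function(report, path) {
  stopifnot(inherits(report, "dice_report"))
  m <- attr(report, "means")
  out <- rbind(as.data.frame(report),
               data.frame(subject_id = "mean", t(m)))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# Soft (probabilistic) region Dice used for training logs: region probability
# = sum of member-class probability channels, region truth = union mask.
#' @noRd
soft_region_dice <- function(P, G, regions = brats_regions(), eps = 1e-6) {
  vapply(regions, function(r) {
    cols <- r$labels + 1L
    p <- rowSums(P[, cols, drop = FALSE])
    g <- rowSums(G[, cols, drop = FALSE])
    (2 * sum(p * g) + eps) / (sum(p * p) + sum(g * g) + eps)
  }, numeric(1))
}
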