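# Preprocessing: intensity normalization, spatial resampling, modality
# stacking and one-hot encoding. Pipeline order is resize -> normalize so the
# output range is guaranteed regardless of interpolation overshoot.

#' Min-max intensity normalization
#'
#' Rescales a volume to `[0, 1]` via `(X - X_min) / (X_max - X_min)`, computed
#' per volume (per modality, per subject). A constant volume maps to all
#' zeros with a warning rather than dividing by zero.
#'
#' @param vol Numeric array (any shape), finite values.
#' @return A list with `volume` (normalized array) and `params`
#'   (`x_min`, `x_max`, `mode = "minmax"`).
#' @examples
#' minmax_normalize(c(2, 4, 6))$volume # 0 0.5 1
#' @export
minmax_normalize <- function(vol) {
  if (!length(vol)) stop("minmax_normalize: empty volume")
  if (!all(is.finite(vol))) stop("minmax_normalize: non-finite values")
  lo <- min(vol); hi <- max(vol)
  if (hi == lo) {
    warning("minmax_normalize: constant volume, returning all zeros")
    out <- vol * 0
  } else {
    out <- (vol - lo) / (hi - lo)
  }
  list(volume = out, params = list(mode = "minmax", x_min = lo, x_max = hi))
}

#' Z-score intensity normalization
#'
#' Centers and scales a volume to zero mean and unit variance using the
#' population standard deviation. A constant volume maps to all zeros.
#'
#' @param vol Numeric array, finite values.
#' @return A list with `volume` and `params` (`mean`, `sd`, `mode =
#'   "zscore"`).
#' @examples
#' zscore_normalize(c(1, 3))$volume # -1 1
#' @export
zscore_normalize <- function(vol) {
  if (!length(vol)) stop("zscore_normalize: empty volume")
  if (!all(is.finite(vol))) stop("zscore_normalize: non-finite values")
  mu <- mean(vol)
  sd_pop <- sqrt(mean((vol - mu)^2))
  if (sd_pop == 0) {
    out <- vol * 0
  } else {
    out <- (vol - mu) / sd_pop
  }
  list(volume = out, params = list(mode = "zscore", mean = mu, sd = sd_pop))
}

#' @noRd
normalize_volume <- function(vol, mode = c("minmax", "zscore")) {
  mode <- match.arg(mode)
  if (mode == "minmax") minmax_normalize(vol) else zscore_normalize(vol)
}

# Separable 1D linear resampling along one array dimension; output centers
# are aligned with input centers (half-voxel convention), coordinates clamped
# to the volume.
#' @noRd
.axis_coords <- function(src, dst) {
  x <- (seq_len(dst) - 0.5) * (src / dst) + 0.5
  pmin(pmax(x, 1), src)
}

#' Resample a volume to a target shape
#'
#' Intensity volumes are resampled with (separable) trilinear interpolation;
#' label volumes with nearest-neighbour, which guarantees the output value
#' set is a subset of the input's. Resampling to the source shape is the
#' identity.
#'
#' @param vol 3D array.
#' @param target_shape Integer triple of positive output dimensions.
#' @param kind `"intensity"` (trilinear) or `"label"` (nearest).
#' @return The resampled 3D array (integer for labels).
#' @export
resize_volume <- function(vol, target_shape, kind = c("intensity", "label")) {
  kind <- match.arg(kind)
  d <- dim(vol)
  if (is.null(d) || length(d) != 3L)
    stop("resize_volume: input must be a 3D array")
  target_shape <- as.integer(target_shape)
  if (length(target_shape) != 3L || any(target_shape < 1L))
    stop("resize_volume: target_shape must be 3 positive integers")
  if (identical(d, target_shape)) return(vol)
  if (kind == "label") {
    idx <- lapply(1:3, function(a) {
      as.integer(round(.axis_coords(d[a], target_shape[a])))
    })
    out <- vol[idx[[1L]], idx[[2L]], idx[[3L]], drop = FALSE]
    storage.mode(out) <- "integer"
    return(out)
  }
  out <- vol
  for (a in 1:3) {
    cur <- dim(out)
    if (cur[a] == target_shape[a]) next
    x <- .axis_coords(cur[a], target_shape[a])
    lo <- pmin(floor(x), cur[a] - 1L); lo <- pmax(lo, 1L)
    w <- x - lo
    hi <- lo + 1L
    if (a == 1L) {
      out <- out[lo, , , drop = FALSE] * (1 - w) + out[hi, , , drop = FALSE] * w
    } else if (a == 2L) {
      wr <- rep(rep(w, each = cur[1L]), times = cur[3L])
      out <- out[, lo, , drop = FALSE] * (1 - wr) + out[, hi, , drop = FALSE] * wr
    } else {
      wr <- rep(w, each = cur[1L] * cur[2L])
      out <- out[, , lo, drop = FALSE] * (1 - wr) + out[, , hi, drop = FALSE] * wr
    }
  }
  out
}

#' Stack the four modalities into one tensor
#'
#' Channels in the fixed order (t1, t1ce, t2, flair).
#'
#' @param volumes Named list of four 3D arrays with identical shapes, names
#'   `t1`, `t1ce`, `t2`, `flair`.
#' @return A 4D array of shape `(D, H, W, 4)` with attribute
#'   `"channel_order"`.
#' @export
stack_modalities <- function(volumes) {
  missing <- setdiff(.modalities, names(volumes))
  if (length(missing))
    stop("stack_modalities: missing modality: ",
         paste(missing, collapse = ", "))
  volumes <- volumes[.modalities]
  shapes <- lapply(volumes, dim)
  if (any(vapply(shapes, is.null, logical(1))) ||
      !all(vapply(shapes, identical, logical(1), shapes[[1L]])))
    stop("stack_modalities: modality shapes differ")
  d <- shapes[[1L]]
  out <- array(0, c(d, 4L))
  for (i in seq_along(volumes)) out[, , , i] <- volumes[[i]]
  attr(out, "channel_order") <- .modalities
  out
}

#' One-hot encode a label volume
#'
#' Channel `c` is 1 exactly where the mask equals class `c - 1`; per-voxel
#' channel sums are 1. `decode_one_hot` is the inverse (per-voxel argmax).
#'
#' @param mask 3D integer array with values in `0:(n_classes - 1)`.
#' @param n_classes Number of classes (default 4).
#' @return 4D array `(D, H, W, n_classes)` of 0/1.
#' @export
one_hot_encode <- function(mask, n_classes = 4L) {
  vals <- unique(as.integer(mask))
  if (any(vals < 0L | vals >= n_classes))
    stop("one_hot_encode: label values outside [0, ", n_classes - 1L, "]: ",
         paste(sort(setdiff(vals, 0:(n_classes - 1L))), collapse = ", "))
  d <- dim(mask)
  if (is.null(d) || length(d) != 3L)
    stop("one_hot_encode: mask must be a 3D array")
  out <- array(0, c(d, n_classes))
  for (c in seq_len(n_classes)) out[, , , c] <- (mask == (c - 1L)) * 1
  out
}

#' @rdname one_hot_encode
#' @param onehot 4D array `(D, H, W, C)`.
#' @export
decode_one_hot <- function(onehot) {
  d <- dim(onehot)
  if (is.null(d) || length(d) != 4L)
    stop("decode_one_hot: input must be a 4D array")
  m <- matrix(onehot, nrow = prod(d[1:3]), ncol = d[4L])
  array(max.col(m, ties.method = "first") - 1L, d[1:3])
}

#' Preprocess one subject for the network
#'
#' The documented pipeline order: resample every modality to `target_shape`
#' (trilinear), then normalize per modality ([minmax_normalize()] by default
#' or [zscore_normalize()]), then stack in the fixed channel order. The mask,
#' if present, is resampled with nearest-neighbour, remapped
#' ([remap_labels()]) and one-hot encoded.
#'
#' @param subject A list as returned by [read_subject()] (elements `volumes`,
#'   optional `mask`).
#' @param target_shape Spatial shape fed to the network (default 128-cubed).
#' @param normalize `"minmax"` or `"zscore"`.
#' @return A list with `x` (D,H,W,4 tensor), `mask` (remapped label array or
#'   `NULL`) and `y` (one-hot array or `NULL`).
#' @export
preprocess_subject <- function(subject, target_shape = c(128L, 128L, 128L),
                               normalize = c("minmax", "zscore")) {
  normalize <- match.arg(normalize)
  vols <- lapply(subject$volumes, function(v) {
    attr(v, "affine") <- NULL
    v <- resize_volume(v, target_shape, kind = "intensity")
    normalize_volume(v, normalize)$volume
  })
  x <- stack_modalities(vols)
  mask <- NULL; y <- NULL
  if (!is.null(subject$mask)) {
    m <- subject$mask
    attr(m, "affine") <- NULL
    mask <- remap_labels(resize_volume(m, target_shape, kind = "label"))
    y <- one_hot_encode(mask, 4L)
  }
  list(x = x, mask = mask, y = y)
}
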