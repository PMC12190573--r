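# Synthetic BraTS-like phantoms: a brain ellipsoid containing three nested
# tumor ellipsoids — edema shell (label 2), enhancing rim (label 3) and
# necrotic/non-enhancing core (label 1) — with modality-dependent contrast.
# Phantoms trade realism for controllable geometry and exactly known labels.

# Mean intensities per (modality, tissue). Contrast rules: FLAIR is brightest
# in edema, T1ce in the enhancing rim, T2 bright across the whole tumor, T1
# near-uniform across tissues.
.default_intensity_table <- function() {
  m <- rbind(
    #        air brain edema necrotic enhancing
    t1    = c(0,  100,   90,      80,        95),
    t1ce  = c(0,  100,   95,      70,       180),
    t2    = c(0,  100,  160,     170,       150),
    flair = c(0,  100,  200,     120,       130)
  )
  colnames(m) <- c("air", "brain", "edema", "necrotic", "enhancing")
  m
}

#' Phantom generator configuration
#'
#' @param shape Volume shape (default 64-cubed; `c(240, 240, 155)` exercises
#'   the exact BraTS resampling path).
#' @param n_subjects Number of phantoms in a cohort.
#' @param radii Named list of semi-axis ranges, in voxel units relative to
#'   the volume's half-extent: `wt`, `tc`, `et` are `(min, max)` fractions
#'   for the edema, enhancing-rim and necrotic-core ellipsoids. Nesting
#'   `et < tc < wt < brain` is enforced.
#' @param intensity_table Numeric matrix of mean intensities, rows = the four
#'   modalities, columns = `air`, `brain`, `edema`, `necrotic`, `enhancing`.
#' @param noise_sd Gaussian noise standard deviation added per voxel
#'   (intensity units; default 10, i.e. 10–20% of the tissue contrasts).
#' @param seed Base seed; each subject uses an independent stream derived
#'   from `(seed, subject_index)`, so cohorts are order-independent.
#' @return A list of class `phantom_config`.
#' @export
phantom_config <- function(shape = c(64L, 64L, 64L), n_subjects = 1L,
                           radii = list(wt = c(0.30, 0.45),
                                        tc = c(0.16, 0.26),
                                        et = c(0.07, 0.12)),
                           intensity_table = .default_intensity_table(),
                           noise_sd = 10, seed = 42L) {
  if (noise_sd < 0) stop("phantom_config: noise_sd must be >= 0")
  if (!(max(radii$et) < min(radii$tc) && max(radii$tc) < min(radii$wt) &&
        max(radii$wt) < 0.85))
    stop("phantom_config: radii must nest: et < tc < wt < brain")
  if (!setequal(rownames(intensity_table), .modalities))
    stop("phantom_config: intensity_table rows must be the four modalities")
  structure(list(shape = as.integer(shape), n_subjects = as.integer(n_subjects),
                 radii = radii, intensity_table = intensity_table,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "phantom_config")
}

#' @noRd
.ellipsoid_mask <- function(shape, center, semi) {
  d <- (seq_len(shape[1L]) - center[1L]) / semi[1L]
  h <- (seq_len(shape[2L]) - center[2L]) / semi[2L]
  w <- (seq_len(shape[3L]) - center[3L]) / semi[3L]
  outer(outer(d^2, h^2, "+"), w^2, "+") <= 1
}

#' Generate one phantom subject
#'
#' Deterministic given `(cfg$seed, subject_index)`: the same pair always
#' yields bit-identical volumes and mask. Geometry: a centred brain
#' ellipsoid; inside it a randomly placed whole-tumor (edema) ellipsoid
#' containing the enhancing rim which itself wraps the necrotic core. The
#' mask uses remapped labels \{0, 1, 2, 3\} (or raw label 4 for the enhancing
#' rim when `raw_label4 = TRUE`, to exercise the remapping path).
#'
#' @param cfg A [phantom_config()].
#' @param subject_index 1-based subject index.
#' @param raw_label4 Emit raw BraTS label 4 instead of 3.
#' @return A list of class `phantom_subject`: `subject_id`, `volumes` (named
#'   list of four 3D arrays), `mask` (3D integer array), `config`.
#' @export
generate_phantom <- function(cfg, subject_index = 1L, raw_label4 = FALSE) {
  stopifnot(inherits(cfg, "phantom_config"))
  with_seed(.subject_seed(cfg$seed, subject_index), {
    shape <- cfg$shape
    half <- shape / 2
    brain_semi <- half * 0.85
    center <- half + 0.5
    brain <- .ellipsoid_mask(shape, center, brain_semi)

    rr <- function(rng) stats::runif(1L, rng[1L], rng[2L])
    r_wt <- min(shape) * c(rr(cfg$radii$wt), rr(cfg$radii$wt), rr(cfg$radii$wt))
    r_tc <- min(shape) * c(rr(cfg$radii$tc), rr(cfg$radii$tc), rr(cfg$radii$tc))
    r_et <- min(shape) * c(rr(cfg$radii$et), rr(cfg$radii$et), rr(cfg$radii$et))
    # tumor center placed so the whole tumor stays inside the brain
    margin <- (brain_semi - r_wt) * 0.5
    tcenter <- center + stats::runif(3L, -1, 1) * margin

    wt <- .ellipsoid_mask(shape, tcenter, r_wt) & brain
    tc <- .ellipsoid_mask(shape, tcenter, r_tc) & wt
    core <- .ellipsoid_mask(shape, tcenter, r_et) & tc

    mask <- array(0L, shape)
    mask[wt] <- 2L                      # edema shell
    mask[tc] <- if (raw_label4) 4L else 3L  # enhancing rim
    mask[core] <- 1L                    # necrotic / non-enhancing core

    tissue <- array(1L, shape)          # 1 = air
    tissue[brain] <- 2L
    tissue[wt] <- 3L
    tissue[tc] <- 5L
    tissue[core] <- 4L
    volumes <- lapply(.modalities, function(m) {
      mu <- cfg$intensity_table[m, ][tissue]
      v <- array(mu, shape)
      if (cfg$noise_sd > 0)
        v <- v + array(stats::rnorm(prod(shape), sd = cfg$noise_sd), shape)
      v
    })
    names(volumes) <- .modalities
    structure(list(subject_id = sprintf("PHANTOM_%05d", subject_index),
                   volumes = volumes, mask = mask, config = cfg),
              class = "phantom_subject")
  })
}

#' @noRd
.subject_seed <- function(seed, index) {
  (as.numeric(seed) * 7919 + as.numeric(index) * 104729) %% 2147483647
}

#' Generate a BraTS-layout phantom cohort on disk
#'
#' Writes `cfg$n_subjects` subject directories, each with the four modality
#' NIfTI files and the segmentation mask, readable by [read_subject()].
#'
#' @param cfg A [phantom_config()].
#' @param out_dir Output directory (created if needed).
#' @param emit_raw_label4 Write raw label 4 instead of 3 in the masks, to
#'   exercise [remap_labels()] on read-back.
#' @return Character vector of subject ids, invisibly.
#' @export
generate_cohort <- function(cfg, out_dir, emit_raw_label4 = FALSE) {
  stopifnot(inherits(cfg, "phantom_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  ids <- character(cfg$n_subjects)
  for (i in seq_len(cfg$n_subjects)) {
    ph <- generate_phantom(cfg, i, raw_label4 = emit_raw_label4)
    id <- ph$subject_id
    base <- file.path(out_dir, id)
    for (m in .modalities)
      write_nifti(ph$volumes[[m]],
                  file.path(base, paste0(id, "_", m, ".nii.gz")))
    write_nifti(ph$mask, file.path(base, paste0(id, "_seg.nii.gz")))
    ids[i] <- id
  }
  invisible(ids)
}
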