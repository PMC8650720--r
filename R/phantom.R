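#' Parameters for the synthetic QSM phantom generator
#'
#' The phantom emulates the contrast structure that drives SN-conditioned
#' Parkinson's classification: a pair of small, bright, bilateral
#' midbrain-like nuclei embedded in a darker background, with the disease
#' class showing both elevated and more heterogeneous susceptibility inside
#' the nuclei (iron deposition), spatially correlated texture noise, and a
#' sharp intensity rim at the nucleus boundary.
#'
#' Intensities are in QSM-like parts per billion (ppb). Between-subject
#' heterogeneity enters through `hc_sd`/`pd_sd` (standard deviation of the
#' subject-level interior mean), voxel-level texture through `texture_sd`
#' with correlation length `texture_correlation_length`.
#'
#' Each nucleus also gets an adjacent bright distractor structure (red
#' nucleus analogue) whose intensity does not depend on diagnosis: iron-rich
#' neighbors give the SN border its sharp, bright image contrast, so masks
#' that drift off the SN pick up high-intensity voxels — the mechanism that
#' destabilizes intensity features under label perturbation.
#'
#' @param grid_shape Integer length-3, voxels per axis.
#' @param spacing Voxel size in mm.
#' @param n_nuclei Number of nuclei (default 2, bilateral).
#' @param nucleus_radius_range Range (mm) for ellipsoid semi-axes.
#' @param hc_mean,pd_mean Class-conditional interior mean intensity (ppb);
#'   `pd_mean` must exceed `hc_mean`.
#' @param hc_sd,pd_sd Between-subject SD of the interior mean (ppb).
#' @param background_mean,background_sd Background intensity statistics (ppb).
#' @param texture_sd Voxel-level texture noise amplitude inside nuclei (ppb).
#' @param texture_correlation_length Smoothing length of the correlated
#'   noise (mm).
#' @param rim_contrast Extra intensity (ppb) added on the one-voxel interior
#'   shell of each nucleus; sharpens the edge gradient.
#' @param distractor_mean,distractor_sd Intensity statistics (ppb) of the
#'   adjacent bright distractor structures; identical for both classes.
#'   `distractor_mean = 0` disables them.
#' @param distractor_radius_range Range (mm) for distractor semi-axes.
#' @param distractor_offset_mm Center offset (mm) of each distractor from
#'   its nucleus, applied in the medial (x toward midline) and anterior (y)
#'   directions.
#' @param seed Default seed used when none is supplied downstream.
#' @return A `phantom_params` list.
#' @export
phantom_params <- function(grid_shape = c(48, 48, 32),
                           spacing = c(0.86, 0.86, 1.0),
                           n_nuclei = 2,
                           nucleus_radius_range = c(3.0, 4.2),
                           hc_mean = 90, pd_mean = 120,
                           hc_sd = 10, pd_sd = 18,
                           background_mean = 20, background_sd = 10,
                           texture_sd = 8,
                           texture_correlation_length = 2,
                           rim_contrast = 25,
                           distractor_mean = 150, distractor_sd = 10,
                           distractor_radius_range = c(2.0, 3.0),
                           distractor_offset_mm = c(2.5, 5.0),
                           seed = 1) {
  p <- list(grid_shape = as.integer(grid_shape), spacing = as.numeric(spacing),
            n_nuclei = as.integer(n_nuclei),
            nucleus_radius_range = as.numeric(nucleus_radius_range),
            hc_mean = hc_mean, pd_mean = pd_mean, hc_sd = hc_sd, pd_sd = pd_sd,
            background_mean = background_mean, background_sd = background_sd,
            texture_sd = texture_sd,
            texture_correlation_length = texture_correlation_length,
            rim_contrast = rim_contrast,
            distractor_mean = distractor_mean, distractor_sd = distractor_sd,
            distractor_radius_range = as.numeric(distractor_radius_range),
            distractor_offset_mm = as.numeric(distractor_offset_mm),
            seed = as.integer(seed))
  if (p$pd_mean <= p$hc_mean)
    stop("pd_mean must exceed hc_mean (disease class has higher intensity)")
  if (any(c(p$hc_sd, p$pd_sd, p$background_sd, p$texture_sd,
            p$distractor_sd) < 0))
    stop("standard deviations must be >= 0")
  if (any(p$grid_shape < 8)) stop("grid_shape components must be >= 8")
  if (diff(p$nucleus_radius_range) < 0 || p$nucleus_radius_range[1] <= 0)
    stop("nucleus_radius_range must be an increasing positive range")
  class(p) <- "phantom_params"
  p
}

# Sample ellipsoid centers/semi-axes (mm) for one subject; bilateral layout
# around the field-of-view center with mild jitter.
sample_nuclei <- function(params) {
  fov <- params$grid_shape * params$spacing
  mid <- fov / 2
  lateral <- 0.16 * fov[1]
  lapply(seq_len(params$n_nuclei), function(i) {
    side <- if (i %% 2 == 1) -1 else 1
    center <- c(mid[1] + side * (lateral + runif(1, -1, 1)),
                mid[2] + runif(1, -1.5, 1.5),
                mid[3] + runif(1, -1.5, 1.5))
    axes <- runif(3, params$nucleus_radius_range[1],
                  params$nucleus_radius_range[2])
    list(center = center, axes = axes, side = side)
  })
}

# Bright distractor structures (red nucleus analogues) medial-anterior to
# each nucleus; drawn after the nuclei so their RNG stream is appended.
sample_distractors <- function(params, nuclei) {
  if (params$distractor_mean == 0) return(list())
  lapply(nuclei, function(nu) {
    center <- nu$center +
      c(-nu$side * params$distractor_offset_mm[1],
        params$distractor_offset_mm[2], 0) +
      runif(3, -0.8, 0.8)
    axes <- runif(3, params$distractor_radius_range[1],
                  params$distractor_radius_range[2])
    list(center = center, axes = axes)
  })
}

# Exact voxelized support of a set of ellipsoids: voxel is foreground iff its
# center satisfies the ellipsoid inequality (ties count as foreground).
ellipsoid_support <- function(nuclei, grid_shape, spacing) {
  xs <- (seq_len(grid_shape[1]) - 1) * spacing[1]
  ys <- (seq_len(grid_shape[2]) - 1) * spacing[2]
  zs <- (seq_len(grid_shape[3]) - 1) * spacing[3]
  m <- array(FALSE, grid_shape)
  for (nu in nuclei) {
    qx <- ((xs - nu$center[1]) / nu$axes[1])^2
    qy <- ((ys - nu$center[2]) / nu$axes[2])^2
    qz <- ((zs - nu$center[3]) / nu$axes[3])^2
    q <- outer(outer(qx, qy, `+`), qz, `+`)
    m <- m | (q <= 1)
  }
  m
}

# Interior one-voxel shell: foreground voxels with at least one of the six
# face neighbors in the background.
interior_rim <- function(m) {
  d <- dim(m)
  pad <- array(FALSE, d + 2)
  pad[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- m
  nb <- array(TRUE, d)
  shifts <- list(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                 c(0, 0, 1), c(0, 0, -1))
  for (s in shifts) {
    nb <- nb & pad[2:(d[1] + 1) + s[1], 2:(d[2] + 1) + s[2],
                   2:(d[3] + 1) + s[3], drop = FALSE]
  }
  m & !nb
}

#' Generate one synthetic subject (volume plus reference SN mask)
#'
#' Deterministic in `(params, diagnosis, seed)`.
#'
#' @param params A [phantom_params()] object.
#' @param diagnosis `"PD"` or `"HC"`.
#' @param seed Integer seed.
#' @return List with elements `volume` (`volume_grid`) and `mask`
#'   (`binary_mask`).
#' @export
generate_subject <- function(params, diagnosis = c("PD", "HC"), seed = 1) {
  diagnosis <- match.arg(diagnosis)
  stopifnot(inherits(params, "phantom_params"))
  with_seed(seed, {
    nuclei <- sample_nuclei(params)
    margin_mm <- 3 * params$spacing
    fov <- params$grid_shape * params$spacing
    for (nu in nuclei) {
      lo <- nu$center - nu$axes
      hi <- nu$center + nu$axes
      if (any(lo < margin_mm) || any(hi > fov - margin_mm))
        stop("nucleus does not fit in the grid with a 3-voxel background ",
             "margin (violated at mm bounds [",
             paste(signif(lo, 3), collapse = ","), "] .. [",
             paste(signif(hi, 3), collapse = ","), "])")
    }
    m <- ellipsoid_support(nuclei, params$grid_shape, params$spacing)
    if (!any(m)) stop("empty reference mask: nuclei too small for the grid")
    distractors <- sample_distractors(params, nuclei)

    mu <- switch(diagnosis,
                 PD = params$pd_mean + rnorm(1) * params$pd_sd,
                 HC = params$hc_mean + rnorm(1) * params$hc_sd)
    vol <- array(params$background_mean, params$grid_shape)
    if (params$background_sd > 0)
      vol <- vol + params$background_sd *
        correlated_noise(params$grid_shape, params$texture_correlation_length,
                         params$spacing)
    if (length(distractors)) {
      dm <- ellipsoid_support(distractors, params$grid_shape, params$spacing)
      dmu <- params$distractor_mean + rnorm(1) * params$distractor_sd
      vol[dm & !m] <- dmu  # nucleus voxels keep nucleus statistics
    }
    interior <- array(mu, params$grid_shape)
    if (params$texture_sd > 0)
      interior <- interior + params$texture_sd *
        correlated_noise(params$grid_shape, params$texture_correlation_length,
                         params$spacing)
    vol[m] <- interior[m]
    if (params$rim_contrast != 0) {
      rim <- interior_rim(m)
      vol[rim] <- vol[rim] + params$rim_contrast
    }
    list(volume = volume_grid(vol, params$spacing),
         mask = binary_mask(array(as.numeric(m), params$grid_shape),
                            params$spacing))
  })
}

#' Generate a synthetic cohort
#'
#' Per-subject seeds are derived deterministically from the master seed, so
#' the same call reproduces the cohort exactly.
#'
#' @param n_pd,n_hc Number of disease / control subjects (each >= 1).
#' @param params A [phantom_params()] object.
#' @param seed Master seed.
#' @return An `sn_cohort`: list with `subjects` (each holding `id`, `volume`,
#'   `mask`, `diagnosis`), plus the generating `params` and `seed`.
#' @export
generate_cohort <- function(n_pd, n_hc, params = phantom_params(), seed = 1) {
  stopifnot(n_pd >= 1, n_hc >= 1)
  ids <- c(sprintf("PD%03d", seq_len(n_pd)), sprintf("HC%03d", seq_len(n_hc)))
  dx <- c(rep("PD", n_pd), rep("HC", n_hc))
  subjects <- lapply(seq_along(ids), function(i) {
    s <- generate_subject(params, dx[i], seed = derive_seed(seed, i))
    list(id = ids[i], volume = s$volume, mask = s$mask, diagnosis = dx[i])
  })
  names(subjects) <- ids
  structure(list(subjects = subjects, params = params, seed = seed),
            class = "sn_cohort")
}

#' @export
print.sn_cohort <- function(x, ...) {
  dx <- vapply(x$subjects, `[[`, "", "diagnosis")
  cat("<sn_cohort>", length(dx), "subjects (", sum(dx == "PD"), "PD /",
      sum(dx == "HC"), "HC ), grid",
      paste(x$params$grid_shape, collapse = "x"), "\n")
  invisible(x)
}

cohort_ids <- function(cohort) names(cohort$subjects)

cohort_diagnoses <- function(cohort) {
  vapply(cohort$subjects, `[[`, "", "diagnosis")
}

#' Persist a cohort as NIfTI files plus a CSV manifest
#'
#' @param cohort An `sn_cohort`.
#' @param directory Output directory (created if needed).
#' @return Path to the written `manifest.csv`.
#' @export
write_cohort <- function(cohort, directory) {
  ok <- dir.exists(directory) ||
    dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  if (!ok || !dir.exists(directory))
    stop("cannot create output directory: ", directory)
  rows <- lapply(cohort$subjects, function(s) {
    vp <- file.path(directory, paste0(s$id, "_qsm.nii.gz"))
    mp <- file.path(directory, paste0(s$id, "_mask.nii.gz"))
    write_volume(s$volume, vp)
    write_volume(s$mask, mp)
    data.frame(subject_id = s$id, volume_path = vp, mask_path = mp,
               diagnosis = s$diagnosis, stringsAsFactors = FALSE)
  })
  manifest <- do.call(rbind, rows)
  mpath <- file.path(directory, "manifest.csv")
  write.csv(manifest, mpath, row.names = FALSE)
  mpath
}

#' Read a cohort back from a manifest written by [write_cohort()]
#'
#' @param manifest_path Path to `manifest.csv`.
#' @return An `sn_cohort` (without generator parameters).
#' @export
read_cohort <- function(manifest_path) {
  man <- read.csv(manifest_path, stringsAsFactors = FALSE)
  subjects <- lapply(seq_len(nrow(man)), function(i) {
    list(id = man$subject_id[i],
         volume = read_volume(man$volume_path[i]),
         mask = read_volume(man$mask_path[i], mask = TRUE),
         diagnosis = man$diagnosis[i])
  })
  names(subjects) <- man$subject_id
  structure(list(subjects = subjects, params = NULL, seed = NULL),
            class = "sn_cohort")
}
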