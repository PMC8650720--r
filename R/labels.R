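#' Random smooth displacement field
#'
#' Componentwise zero-mean Gaussian-smoothed noise, normalized so the maximum
#' displacement magnitude is exactly 1 mm; the magnitude applied to a mask is
#' controlled separately through the `alpha` multiplier of [warp_mask()].
#' Stands in for a registration-derived deformation between a manual and an
#' automatic label set, preserving its two load-bearing properties:
#' smoothness and gradual deviation under scaling.
#'
#' @param shape Integer length-3 grid shape.
#' @param spacing Voxel spacing, mm.
#' @param smoothness_sigma Gaussian smoothing width, mm (> 0).
#' @param seed Integer seed.
#' @return A `displacement_field`: list with `vectors` (array
#'   `shape x 3`, mm), `spacing`, `smoothness_sigma`, `seed`.
#' @export
random_smooth_field <- function(shape, spacing = c(1, 1, 1),
                                smoothness_sigma = 4, seed = 1) {
  stopifnot(smoothness_sigma > 0, length(shape) == 3)
  shape <- as.integer(shape)
  v <- with_seed(seed, {
    comps <- lapply(1:3, function(i) {
      f <- smooth_gaussian3(array(rnorm(prod(shape)), shape),
                            smoothness_sigma, spacing)
      f - mean(f)
    })
    array(unlist(comps), c(shape, 3))
  })
  mag <- sqrt(v[, , , 1]^2 + v[, , , 2]^2 + v[, , , 3]^2)
  mx <- max(mag)
  if (mx > 0) v <- v / mx
  structure(list(vectors = v, spacing = as.numeric(spacing),
                 smoothness_sigma = smoothness_sigma, seed = seed),
            class = "displacement_field")
}

#' Warp a binary mask through a scaled displacement field
#'
#' Backward warp: the output value at voxel `x` is the trilinear
#' interpolation of the input mask at `x + alpha * d(x)` (displacements in
#' mm, converted to voxels via spacing), thresholded at 0.5. `alpha = 0`
#' returns the mask unchanged; samples outside the grid read as background.
#'
#' @param mask `binary_mask` or 0/1 array.
#' @param field A `displacement_field` of the same grid shape.
#' @param alpha Scalar displacement multiplier (mm of maximum displacement
#'   for a unit-normalized field).
#' @return Warped mask of the same type as `mask`.
#' @export
warp_mask <- function(mask, field, alpha) {
  m <- mask_values(mask)
  dims <- dim(m)
  if (!identical(dims, dim(field$vectors)[1:3]))
    stop("warp_mask: mask and field shapes differ")
  if (alpha == 0) return(mask)
  sp <- field$spacing
  g <- as.matrix(expand.grid(x = seq_len(dims[1]) - 1,
                             y = seq_len(dims[2]) - 1,
                             z = seq_len(dims[3]) - 1))
  coords <- cbind(g[, 1] + alpha * as.vector(field$vectors[, , , 1]) / sp[1],
                  g[, 2] + alpha * as.vector(field$vectors[, , , 2]) / sp[2],
                  g[, 3] + alpha * as.vector(field$vectors[, , , 3]) / sp[3])
  s <- cpp_trilinear(as.numeric(m), dims, coords, fill = 0)
  out <- array(as.numeric(s >= 0.5), dims)
  if (inherits(mask, "binary_mask")) binary_mask(out, mask$spacing, mask$origin)
  else out
}

#' Solve the field magnitude that achieves a target Dice
#'
#' Bisection over `alpha` in `[0, alpha_max]` on the (empirically monotone)
#' achieved Dice between the warped and the original mask. If Dice is
#' non-monotone at the bisection resolution the solver falls back to a dense
#' grid search. Because a voxelized mask makes Dice a step function of
#' `alpha`, the solver returns the best bracket value with
#' `converged = FALSE` when the tolerance cannot be hit exactly.
#'
#' @param mask Reference `binary_mask`.
#' @param field A unit-normalized `displacement_field`.
#' @param target_dice Target Dice in `(0, 1)` (the unperturbed reference is
#'   the separate level 1.0).
#' @param tol Dice tolerance (default 0.005).
#' @param alpha_max Largest magnitude tried, mm (default 5).
#' @param max_iter Bisection iteration cap (default 60).
#' @return List with `alpha`, `mask` (warped), `achieved`, `converged`.
#' @export
solve_alpha_for_dice <- function(mask, field, target_dice, tol = 0.005,
                                 alpha_max = 5, max_iter = 60) {
  if (!(target_dice > 0 && target_dice < 1))
    stop("target_dice must lie strictly inside (0, 1); ",
         "the level 1.0 is the unperturbed reference")
  stopifnot(tol > 0)
  dice_at <- function(a) {
    w <- warp_mask(mask, field, a)
    list(mask = w, dice = dice_coefficient(mask, w))
  }
  hi <- dice_at(alpha_max)
  if (hi$dice > target_dice + tol)
    stop("target Dice ", target_dice, " unreachable: Dice at alpha_max = ",
         signif(hi$dice, 4),
         "; increase alpha_max or use a rougher field")
  lo_a <- 0; hi_a <- alpha_max
  best <- list(alpha = alpha_max, mask = hi$mask, achieved = hi$dice)
  for (it in seq_len(max_iter)) {
    mid <- (lo_a + hi_a) / 2
    cur <- dice_at(mid)
    if (abs(cur$dice - target_dice) < abs(best$achieved - target_dice))
      best <- list(alpha = mid, mask = cur$mask, achieved = cur$dice)
    if (abs(cur$dice - target_dice) <= tol)
      return(list(alpha = mid, mask = cur$mask, achieved = cur$dice,
                  converged = TRUE))
    if (cur$dice > target_dice) lo_a <- mid else hi_a <- mid
  }
  # Monotonicity fallback: dense grid search over alpha.
  grid <- seq(0, alpha_max, length.out = 200)[-1]
  for (a in grid) {
    cur <- dice_at(a)
    if (abs(cur$dice - target_dice) < abs(best$achieved - target_dice))
      best <- list(alpha = a, mask = cur$mask, achieved = cur$dice)
    if (abs(best$achieved - target_dice) <= tol) break
  }
  warning("solve_alpha_for_dice: tolerance not reached (best |Dice - target| = ",
          signif(abs(best$achieved - target_dice), 3), ")")
  list(alpha = best$alpha, mask = best$mask, achieved = best$achieved,
       converged = abs(best$achieved - target_dice) <= tol)
}

#' Build an ordered family of perturbed label sets at prescribed Dice levels
#'
#' One smooth random field per subject (seed-derived); all levels of a
#' subject reuse that field with increasing magnitude, so the series is a
#' nested, gradual deviation away from the reference labeling. The
#' unperturbed reference (target 1.0) is prepended automatically.
#'
#' @param cohort An `sn_cohort`.
#' @param targets Strictly decreasing Dice targets in `(0, 1)`.
#' @param tol Per-subject Dice tolerance.
#' @param seed Master seed for the per-subject fields.
#' @param smoothness_sigma Field smoothness, mm.
#' @param alpha_max Passed to [solve_alpha_for_dice()] (default 15 mm: the
#'   field is unit-normalized over the whole grid, so its local magnitude
#'   at the nuclei is typically far below the global maximum).
#' @return A `label_series`: list with `targets` (including 1.0) and
#'   `levels`, each level holding `target`, `source` id (e.g. `"L0.872"`),
#'   per-subject `masks`, `alpha`, `achieved`, and `achieved_mean`.
#' @export
make_label_series <- function(cohort,
                              targets = c(0.975, 0.946, 0.920, 0.897, 0.872),
                              tol = 0.005, seed = 1, smoothness_sigma = 4,
                              alpha_max = 15) {
  stopifnot(all(targets > 0 & targets < 1))
  if (any(diff(targets) >= 0)) stop("targets must be strictly decreasing")
  ids <- cohort_ids(cohort)
  ref <- lapply(cohort$subjects, `[[`, "mask")
  levels <- vector("list", length(targets) + 1)
  levels[[1]] <- list(target = 1.0, source = "L1.000", masks = ref,
                      alpha = stats::setNames(rep(0, length(ids)), ids),
                      achieved = stats::setNames(rep(1, length(ids)), ids),
                      achieved_mean = 1.0)
  per_subject <- lapply(seq_along(ids), function(i) {
    m <- ref[[ids[i]]]
    fld <- random_smooth_field(dim(m$values), m$spacing, smoothness_sigma,
                               seed = derive_seed(seed, i))
    out <- vector("list", length(targets))
    for (j in seq_along(targets)) {
      sol <- tryCatch(
        solve_alpha_for_dice(m, fld, targets[j], tol = tol,
                             alpha_max = alpha_max),
        error = function(e) stop("label forging failed for subject ", ids[i],
                                 " at target ", targets[j], ": ",
                                 conditionMessage(e)))
      out[[j]] <- sol
    }
    out
  })
  for (j in seq_along(targets)) {
    masks <- stats::setNames(lapply(per_subject, function(s) s[[j]]$mask), ids)
    alpha <- vapply(per_subject, function(s) s[[j]]$alpha, 0)
    ach <- vapply(per_subject, function(s) s[[j]]$achieved, 0)
    names(alpha) <- names(ach) <- ids
    levels[[j + 1]] <- list(target = targets[j],
                            source = sprintf("L%.3f", targets[j]),
                            masks = masks, alpha = alpha, achieved = ach,
                            achieved_mean = mean(ach))
  }
  structure(list(targets = c(1.0, targets), levels = levels, seed = seed,
                 smoothness_sigma = smoothness_sigma, tol = tol),
            class = "label_series")
}

#' @export
print.label_series <- function(x, ...) {
  cat("<label_series>", length(x$levels), "levels over",
      length(x$levels[[1]]$masks), "subjects\n")
  for (lv in x$levels)
    cat(sprintf("  %s  target %.3f  achieved %.4f\n", lv$source, lv$target,
                lv$achieved_mean))
  invisible(x)
}

level_sources <- function(series) {
  vapply(series$levels, `[[`, "", "source")
}

series_masks <- function(series, source) {
  for (lv in series$levels) if (lv$source == source) return(lv$masks)
  stop("unknown label source: ", source)
}

#' Persist a label series as per-level NIfTI directories plus JSON metadata
#'
#' @param series A `label_series`.
#' @param directory Output directory.
#' @return Path to the metadata JSON, invisibly.
#' @export
write_label_series <- function(series, directory) {
  if (!dir.exists(directory) &&
      !dir.create(directory, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory: ", directory)
  meta <- list(targets = series$targets, seed = series$seed,
               smoothness_sigma = series$smoothness_sigma, tol = series$tol,
               levels = list())
  for (lv in series$levels) {
    lvdir <- file.path(directory, lv$source)
    dir.create(lvdir, showWarnings = FALSE)
    for (id in names(lv$masks))
      write_volume(lv$masks[[id]], file.path(lvdir, paste0(id, "_mask.nii.gz")))
    meta$levels[[lv$source]] <- list(target = lv$target,
                                     alpha = as.list(lv$alpha),
                                     achieved = as.list(lv$achieved))
  }
  jp <- file.path(directory, "series.json")
  jsonlite::write_json(meta, jp, auto_unbox = TRUE, digits = NA)
  invisible(jp)
}
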