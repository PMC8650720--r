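#' 3D scalar volume on a regular grid
#'
#' Container for QSM-like susceptibility images (parts per billion),
#' probability maps, and distance maps sharing one voxel grid.
#'
#' @param values 3D numeric array; every dimension must be at least 8 and all
#'   values finite.
#' @param spacing Numeric length-3 vector of voxel sizes in mm (all > 0).
#' @param origin Numeric length-3 vector, mm offset of the first voxel center.
#' @return An object of class `volume_grid`.
#' @export
volume_grid <- function(values, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  stopifnot(is.array(values), length(dim(values)) == 3)
  if (any(dim(values) < 8))
    stop("volume_grid requires all three dimensions >= 8")
  if (!all(is.finite(values))) stop("volume_grid values must be finite")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3 || any(spacing <= 0))
    stop("spacing must be three positive numbers")
  structure(list(values = values, spacing = spacing,
                 origin = as.numeric(origin)),
            class = "volume_grid")
}

#' Binary mask on a volume grid
#'
#' @param values 3D array coercible to 0/1.
#' @param spacing,origin Grid geometry, shared with the paired volume.
#' @return An object of class `binary_mask`.
#' @export
binary_mask <- function(values, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  stopifnot(is.array(values), length(dim(values)) == 3)
  v <- array(as.numeric(values != 0), dim(values))
  structure(list(values = v, spacing = as.numeric(spacing),
                 origin = as.numeric(origin)),
            class = "binary_mask")
}

#' @export
print.volume_grid <- function(x, ...) {
  cat("<volume_grid>", paste(dim(x$values), collapse = "x"),
      "voxels, spacing", paste(signif(x$spacing, 3), collapse = "x"), "mm\n")
  cat("  intensity range:", paste(signif(range(x$values), 4), collapse = " .. "),
      "ppb\n")
  invisible(x)
}

#' @export
print.binary_mask <- function(x, ...) {
  cat("<binary_mask>", paste(dim(x$values), collapse = "x"), "voxels,",
      sum(x$values), "foreground\n")
  invisible(x)
}

# Accept a binary_mask, volume_grid or plain array and return the raw array.
mask_values <- function(m) {
  if (inherits(m, "binary_mask") || inherits(m, "volume_grid")) m$values else m
}

grid_spacing <- function(x, default = c(1, 1, 1)) {
  if (inherits(x, "binary_mask") || inherits(x, "volume_grid")) x$spacing
  else attr(x, "spacing") %||% default
}

#' Write a volume or mask to NIfTI
#'
#' Volumes are stored as float64 so that a round trip reproduces the array
#' bit-exactly; masks are stored as uint8.
#'
#' @param x A `volume_grid` or `binary_mask`.
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(x, path) {
  img <- RNifti::asNifti(x$values)
  RNifti::pixdim(img) <- x$spacing
  dtype <- if (inherits(x, "binary_mask")) "uint8" else "double"
  ok <- try(RNifti::writeNifti(img, path, datatype = dtype), silent = TRUE)
  if (inherits(ok, "try-error"))
    stop("failed to write NIfTI file: ", path)
  invisible(path)
}

#' Read a volume or mask from NIfTI
#'
#' @param path NIfTI file path.
#' @param mask Logical; read as `binary_mask` instead of `volume_grid`.
#' @return A `volume_grid` or `binary_mask`.
#' @export
read_volume <- function(path, mask = FALSE) {
  if (!file.exists(path)) stop("no such file: ", path)
  img <- RNifti::readNifti(path)
  vals <- array(as.numeric(img), dim(img))
  sp <- RNifti::pixdim(img)[1:3]
  if (mask) binary_mask(vals, spacing = sp) else volume_grid(vals, spacing = sp)
}
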