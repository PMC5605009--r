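# Class codes for the eight head anatomies. Shared by every module.
CLASS_CODES <- c(air = 0L, body = 1L, eyeball = 2L, lens = 3L, cavity = 4L,
                 ventricle = 5L, brainstem = 6L, bone = 7L)

#' Anatomy class codes
#'
#' Integer codes used in label maps: 0 = air, 1 = body (residual soft
#' tissue), 2 = eyeball, 3 = lens, 4 = cavity (internal air-filled space),
#' 5 = ventricle, 6 = brainstem, 7 = bone.
#'
#' @return Named integer vector of the eight class codes.
#' @export
class_codes <- function() CLASS_CODES

#' Construct a scalar image volume
#'
#' A 3D scalar grid with voxel spacing and world origin. The axis order is
#' fixed as (slice, row, column); indices are 0-based in world-coordinate
#' formulas: the world position of voxel index \code{i} (0-based) is
#' \code{origin + i * spacing} (voxel-center convention).
#'
#' @param values 3D numeric array (MR intensities in arbitrary units, or CT
#'   numbers in HU). Must be finite.
#' @param spacing numeric length-3, per-axis voxel size in mm; all > 0.
#' @param origin numeric length-3, world position (mm) of the center of
#'   voxel (0,0,0).
#' @return An object of class \code{image_volume}.
#' @export
image_volume <- function(values, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  values <- as.array(values)
  if (length(dim(values)) != 3L)
    stop("image_volume: `values` must be a 3D array, got ",
         length(dim(values)), " dimensions", call. = FALSE)
  if (!is.numeric(values))
    stop("image_volume: `values` must be numeric", call. = FALSE)
  if (!all(is.finite(values)))
    stop("image_volume: `values` contains non-finite entries", call. = FALSE)
  spacing <- as.numeric(spacing); origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(spacing <= 0))
    stop("image_volume: `spacing` must be 3 positive numbers", call. = FALSE)
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("image_volume: `origin` must be 3 finite numbers", call. = FALSE)
  storage.mode(values) <- "double"
  structure(list(values = values, spacing = spacing, origin = origin),
            class = "image_volume")
}

#' Construct a label map
#'
#' Per-voxel anatomy class on the same grid contract as
#' \code{\link{image_volume}}. Every voxel carries exactly one code in 0..7
#' (see \code{\link{class_codes}}).
#'
#' @param labels 3D integer array of class codes in 0..7.
#' @inheritParams image_volume
#' @return An object of class \code{label_map}.
#' @export
label_map <- function(labels, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  labels <- as.array(labels)
  if (length(dim(labels)) != 3L)
    stop("label_map: `labels` must be a 3D array", call. = FALSE)
  if (any(!is.finite(labels)) || any(labels != round(labels)))
    stop("label_map: labels must be finite integers", call. = FALSE)
  if (any(labels < 0 | labels > 7))
    stop("label_map: class codes must lie in 0..7", call. = FALSE)
  storage.mode(labels) <- "integer"
  spacing <- as.numeric(spacing); origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(spacing <= 0))
    stop("label_map: `spacing` must be 3 positive numbers", call. = FALSE)
  structure(list(labels = labels, spacing = spacing, origin = origin),
            class = "label_map")
}

#' Construct a binary mask
#'
#' @param mask 3D logical array.
#' @inheritParams image_volume
#' @return An object of class \code{binary_mask}.
#' @export
binary_mask <- function(mask, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  mask <- as.array(mask)
  if (length(dim(mask)) != 3L)
    stop("binary_mask: `mask` must be a 3D array", call. = FALSE)
  if (is.numeric(mask)) {
    if (any(is.na(mask)) || !all(mask %in% c(0, 1)))
      stop("binary_mask: numeric mask must be 0/1", call. = FALSE)
    mask <- array(mask != 0, dim = dim(mask))
  }
  if (!is.logical(mask) || anyNA(mask))
    stop("binary_mask: `mask` must be logical without NA", call. = FALSE)
  structure(list(mask = mask, spacing = as.numeric(spacing),
                 origin = as.numeric(origin)),
            class = "binary_mask")
}

# Uniform access to the grid triple and data array of any grid object.
grid_of <- function(x) {
  list(shape = dim(values_of(x)), spacing = x$spacing, origin = x$origin)
}

values_of <- function(x) {
  if (inherits(x, "image_volume")) x$values
  else if (inherits(x, "label_map")) x$labels
  else if (inherits(x, "binary_mask")) x$mask
  else stop("expected an image_volume, label_map or binary_mask", call. = FALSE)
}

#' Check that two grid objects share a grid
#'
#' Returns invisibly iff shapes are equal, spacings agree within 1e-6 mm and
#' origins within 1e-3 mm; otherwise raises a grid-mismatch error naming the
#' differing field. All two-grid operations in the package call this before
#' computing anything.
#'
#' @param a,b \code{image_volume}, \code{label_map} or \code{binary_mask}.
#' @return Invisibly \code{TRUE} on success.
#' @export
check_same_grid <- function(a, b) {
  ga <- grid_of(a); gb <- grid_of(b)
  if (!identical(ga$shape, gb$shape))
    stop("grid mismatch: shape ", paste(ga$shape, collapse = "x"), " vs ",
         paste(gb$shape, collapse = "x"), call. = FALSE)
  if (any(abs(ga$spacing - gb$spacing) > 1e-6))
    stop("grid mismatch: spacing (", paste(ga$spacing, collapse = ", "),
         ") vs (", paste(gb$spacing, collapse = ", "), ")", call. = FALSE)
  if (any(abs(ga$origin - gb$origin) > 1e-3))
    stop("grid mismatch: origin (", paste(ga$origin, collapse = ", "),
         ") vs (", paste(gb$origin, collapse = ", "), ")", call. = FALSE)
  invisible(TRUE)
}

#' Read a 3D scalar volume from a NIfTI-1 file
#'
#' Spacing and origin are taken from the file header (pixdim and the
#' translation column of the sform/qform). Values are returned as doubles.
#'
#' @param path path to a .nii or .nii.gz file containing a scalar 3D image.
#' @return An \code{\link{image_volume}}.
#' @export
read_volume <- function(path) {
  if (!file.exists(path))
    stop("read_volume: file not found: ", path, call. = FALSE)
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (is.null(d) || length(d) != 3L)
    stop("read_volume: expected a 3D scalar image, got ",
         if (is.null(d)) "no" else length(d), " dimensions in ", path,
         call. = FALSE)
  xf <- RNifti::xform(img)
  image_volume(array(as.numeric(img), dim = d),
               spacing = RNifti::pixdim(img)[1:3],
               origin = as.numeric(xf[1:3, 4]))
}

#' Read a label map from an integer-typed NIfTI-1 file
#'
#' @inheritParams read_volume
#' @return A \code{\link{label_map}}.
#' @export
read_label_map <- function(path) {
  v <- read_volume(path)
  label_map(v$values, spacing = v$spacing, origin = v$origin)
}

#' Write a volume or label map to a NIfTI-1 file
#'
#' Volumes are stored as float64 so that \code{read_volume(write_volume(v))}
#' is an identity up to floating-point representation; label maps are stored
#' as int16, preserved exactly.
#'
#' @param vol an \code{\link{image_volume}} or \code{\link{label_map}}.
#' @param path output path (.nii or .nii.gz); parent directory must exist.
#' @return Invisibly, \code{path}.
#' @export
write_volume <- function(vol, path) {
  if (!dir.exists(dirname(path)))
    stop("write_volume: directory does not exist: ", dirname(path),
         call. = FALSE)
  is_labels <- inherits(vol, "label_map")
  # header edits must precede datatype conversion (writeNifti handles it)
  img <- RNifti::asNifti(values_of(vol))
  RNifti::pixdim(img) <- vol$spacing
  m <- rbind(cbind(diag(vol$spacing), vol$origin), c(0, 0, 0, 1))
  RNifti::sform(img) <- structure(m, code = 2L)
  RNifti::qform(img) <- structure(m, code = 2L)
  RNifti::writeNifti(img, path,
                     datatype = if (is_labels) "int16" else "double")
  invisible(path)
}
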