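# Gamma-index analysis on CT numbers: combined distance-to-agreement and
# value-difference comparison between a reference CT and a synthetic CT.

#' Gamma criteria
#'
#' @param dta_mm distance-to-agreement criterion (mm), > 0.
#' @param dd_percent value-difference criterion as percent of the
#'   normalization value, > 0.
#' @param mode \code{"2d"} (per-axial-slice search, the default) or
#'   \code{"3d"}.
#' @param search_radius_factor search radius as a multiple of
#'   \code{dta_mm}. Any candidate beyond the radius contributes gamma >
#'   this factor from its distance term alone, so gamma values up to the
#'   factor — and the pass/fail decision at gamma <= 1 for any factor
#'   >= 1 — are exact; larger reported values are upper bounds. Use
#'   \code{Inf} for an exhaustive whole-grid search.
#' @param upsample integer in-plane upsampling factor for the evaluated
#'   image (bilinear); 1 = voxel centers only. Only supported in 2d mode.
#' @return Object of class \code{gamma_criteria}.
#' @export
gamma_criteria <- function(dta_mm, dd_percent, mode = c("2d", "3d"),
                           search_radius_factor = 2, upsample = 1L) {
  mode <- match.arg(mode)
  if (dta_mm <= 0 || dd_percent <= 0)
    stop("gamma_criteria: dta_mm and dd_percent must be positive",
         call. = FALSE)
  if (search_radius_factor < 1)
    stop("gamma_criteria: search_radius_factor must be >= 1", call. = FALSE)
  upsample <- as.integer(upsample)
  if (upsample < 1L) stop("gamma_criteria: upsample must be >= 1", call. = FALSE)
  if (upsample > 1L && mode == "3d")
    stop("gamma_criteria: upsampling is only supported in 2d mode",
         call. = FALSE)
  structure(list(dta_mm = dta_mm, dd_percent = dd_percent, mode = mode,
                 search_radius_factor = search_radius_factor,
                 upsample = upsample),
            class = "gamma_criteria")
}

#' Rectangular region of interest
#'
#' Axis-aligned box given as per-axis half-open 0-based index intervals
#' [lo, hi).
#'
#' @param lo,hi integer vectors (length 3), \code{lo} inclusive and
#'   \code{hi} exclusive, with \code{lo < hi}.
#' @return Object of class \code{rect_roi}.
#' @export
rect_roi <- function(lo, hi) {
  lo <- as.integer(lo); hi <- as.integer(hi)
  stopifnot(length(lo) == length(hi))
  if (any(lo < 0) || any(hi <= lo))
    stop("rect_roi: need 0 <= lo < hi per axis", call. = FALSE)
  structure(list(lo = lo, hi = hi), class = "rect_roi")
}

#' Minimum rectangle covering the body
#'
#' In 3d mode, the tightest axis-aligned box containing every body voxel.
#' In 2d mode, one tightest rectangle per axial slice that contains body
#' voxels (empty slices are skipped).
#'
#' @param body a nonempty \code{\link{binary_mask}}.
#' @param mode \code{"2d"} or \code{"3d"}.
#' @return A \code{\link{rect_roi}} (3d) or an object of class
#'   \code{slice_roi_set}: a list of per-slice entries, each with
#'   \code{slice} (0-based index) and in-plane \code{lo}/\code{hi}.
#' @export
roi_from_body <- function(body, mode = c("2d", "3d")) {
  mode <- match.arg(mode)
  stopifnot(inherits(body, "binary_mask"))
  m <- body$mask
  if (!any(m)) stop("roi_from_body: body mask is empty", call. = FALSE)
  if (mode == "3d") {
    idx <- which(m, arr.ind = TRUE)
    return(rect_roi(apply(idx, 2, min) - 1L, apply(idx, 2, max)))
  }
  d <- dim(m)
  slices <- list()
  for (z in seq_len(d[1])) {
    sl <- m[z, , ]
    if (!any(sl)) next
    rows <- which(rowSums(sl) > 0); cols <- which(colSums(sl) > 0)
    slices[[length(slices) + 1L]] <-
      list(slice = z - 1L, lo = c(min(rows), min(cols)) - 1L,
           hi = c(max(rows), max(cols)))
  }
  structure(list(slices = slices, shape = d), class = "slice_roi_set")
}

roi_mask_array <- function(roi, shape) {
  m <- array(FALSE, dim = shape)
  if (inherits(roi, "rect_roi")) {
    if (any(roi$hi > shape))
      stop("ROI extends outside the grid", call. = FALSE)
    m[(roi$lo[1] + 1L):roi$hi[1], (roi$lo[2] + 1L):roi$hi[2],
      (roi$lo[3] + 1L):roi$hi[3]] <- TRUE
  } else if (inherits(roi, "slice_roi_set")) {
    for (s in roi$slices) {
      if (s$slice + 1L > shape[1] || any(s$hi > shape[2:3]))
        stop("ROI extends outside the grid", call. = FALSE)
      m[s$slice + 1L, (s$lo[1] + 1L):s$hi[1], (s$lo[2] + 1L):s$hi[2]] <- TRUE
    }
  } else stop("expected a rect_roi or slice_roi_set", call. = FALSE)
  if (!any(m)) stop("ROI is empty", call. = FALSE)
  m
}

#' Normalization value for the gamma value-difference criterion
#'
#' The dynamic range (max - min) of the reference CT within the ROI; the
#' absolute value-difference criterion is then
#' \code{dd_percent / 100 x normalization value}. The dynamic range
#' handles negative HU without an arbitrary shift.
#'
#' @param reference reference \code{\link{image_volume}}.
#' @param roi a \code{\link{rect_roi}} or \code{slice_roi_set}.
#' @return Scalar HU value (> 0).
#' @export
normalization_value <- function(reference, roi) {
  stopifnot(inherits(reference, "image_volume"))
  v <- reference$values[roi_mask_array(roi, dim(reference$values))]
  rng <- max(v) - min(v)
  if (rng <= 0)
    stop("degenerate normalization: reference is constant in the ROI",
         call. = FALSE)
  rng
}

# shift a 3D array by (dz, dy, dx) voxels, NA outside the grid
shift_na <- function(a, dz, dy, dx) {
  d <- dim(a)
  out <- array(NA_real_, dim = d)
  z <- seq_len(d[1]) + dz; y <- seq_len(d[2]) + dy; x <- seq_len(d[3]) + dx
  okz <- z >= 1 & z <= d[1]; oky <- y >= 1 & y <= d[2]; okx <- x >= 1 & x <= d[3]
  out[okz, oky, okx] <- a[z[okz], y[oky], x[okx]]
  out
}

# candidate offsets within radius_mm; each row (dz, dy, dx, dist2_mm2)
offset_table <- function(spacing, radius_mm, in_plane, shape) {
  lim <- function(s, n) {
    k <- if (is.finite(radius_mm)) floor(radius_mm / s) else Inf
    as.integer(min(k, n - 1L))
  }
  kz <- if (in_plane) 0L else lim(spacing[1], shape[1])
  ky <- lim(spacing[2], shape[2]); kx <- lim(spacing[3], shape[3])
  g <- expand.grid(dz = -kz:kz, dy = -ky:ky, dx = -kx:kx)
  d2 <- (g$dz * spacing[1])^2 + (g$dy * spacing[2])^2 + (g$dx * spacing[3])^2
  keep <- if (is.finite(radius_mm)) d2 <= radius_mm^2 else rep(TRUE, length(d2))
  cbind(as.matrix(g[keep, , drop = FALSE]), dist2 = d2[keep])
}

# bilinear in-plane upsampling of one slice to a ((n-1)f+1)-point fine grid
upsample_slice <- function(sl, f) {
  ny <- nrow(sl); nx <- ncol(sl)
  uy <- seq(1, ny, by = 1 / f); ux <- seq(1, nx, by = 1 / f)
  iy0 <- pmax(pmin(floor(uy), ny - 1L), 1L); wy <- uy - iy0
  ix0 <- pmax(pmin(floor(ux), nx - 1L), 1L); wx <- ux - ix0
  iy1 <- pmin(iy0 + 1L, ny); ix1 <- pmin(ix0 + 1L, nx)
  a <- sl[iy0, ix0, drop = FALSE]; b <- sl[iy1, ix0, drop = FALSE]
  c2 <- sl[iy0, ix1, drop = FALSE]; d2 <- sl[iy1, ix1, drop = FALSE]
  (a * (1 - wy) + b * wy) * rep(1 - wx, each = length(uy)) +
    (c2 * (1 - wy) + d2 * wy) * rep(wx, each = length(uy))
}

#' Compute a gamma map between reference and evaluated CT volumes
#'
#' For each reference voxel r1 inside the ROI,
#' gamma(r1) = min over evaluated positions r2 within the search radius of
#' sqrt(|r1 - r2|^2 / dta^2 + (D2(r2) - D1(r1))^2 / ddabs^2), with
#' distances in mm via the voxel spacing. The search is exhaustive over
#' evaluated voxel centers within the radius (on the bilinearly upsampled
#' in-plane grid when \code{upsample > 1}); in 2d mode it is restricted to
#' the reference voxel's axial slice. Evaluated candidates may lie outside
#' the ROI (but inside the grid).
#'
#' @param reference,evaluated \code{\link{image_volume}}s on one grid.
#' @param criteria a \code{\link{gamma_criteria}}.
#' @param roi a \code{\link{rect_roi}} or \code{slice_roi_set} (see
#'   \code{\link{roi_from_body}}).
#' @param norm_value normalization value in HU; default
#'   \code{\link{normalization_value}} of the reference in the ROI.
#' @return Object of class \code{gamma_map}: \code{gamma} (3D array, NA
#'   outside the ROI), \code{criteria}, \code{norm_value}, \code{dd_abs},
#'   \code{roi}, and \code{capped_above} (values above this are upper
#'   bounds; \code{Inf} when the search was exhaustive).
#' @export
gamma_map <- function(reference, evaluated, criteria, roi,
                      norm_value = NULL) {
  stopifnot(inherits(reference, "image_volume"),
            inherits(evaluated, "image_volume"),
            inherits(criteria, "gamma_criteria"))
  check_same_grid(reference, evaluated)
  d <- dim(reference$values)
  roim <- roi_mask_array(roi, d)
  if (is.null(norm_value)) norm_value <- normalization_value(reference, roi)
  if (norm_value <= 0)
    stop("gamma_map: norm_value must be positive", call. = FALSE)
  dd_abs <- criteria$dd_percent / 100 * norm_value
  dta2 <- criteria$dta_mm^2
  dd2 <- dd_abs^2
  radius <- criteria$search_radius_factor * criteria$dta_mm
  ref <- reference$values
  ev <- evaluated$values
  sp <- reference$spacing
  f <- criteria$upsample

  if (f == 1L) {
    off <- offset_table(sp, radius, in_plane = criteria$mode == "2d",
                        shape = d)
    g2 <- array(Inf, dim = d)
    for (k in seq_len(nrow(off))) {
      evs <- shift_na(ev, off[k, 1], off[k, 2], off[k, 3])
      cand <- off[k, 4] / dta2 + (evs - ref)^2 / dd2
      g2 <- pmin(g2, cand, na.rm = TRUE)
    }
  } else {
    # fine in-plane grid: steps spacing/f, candidates per slice
    if (!is.finite(radius))
      stop("gamma_map: upsampling requires a finite search radius",
           call. = FALSE)
    fs <- sp[2:3] / f
    ky <- floor(radius / fs[1]); kx <- floor(radius / fs[2])
    g <- expand.grid(dy = -ky:ky, dx = -kx:kx)
    d2 <- (g$dy * fs[1])^2 + (g$dx * fs[2])^2
    keep <- d2 <= radius^2
    offs <- cbind(g$dy[keep], g$dx[keep], d2[keep])
    g2 <- array(Inf, dim = d)
    base_y <- (seq_len(d[2]) - 1L) * f + 1L
    base_x <- (seq_len(d[3]) - 1L) * f + 1L
    for (z in seq_len(d[1])) {
      fine <- upsample_slice(matrix(ev[z, , ], d[2], d[3]), f)
      refz <- matrix(ref[z, , ], d[2], d[3])
      gz <- matrix(Inf, d[2], d[3])
      for (k in seq_len(nrow(offs))) {
        yy <- base_y + offs[k, 1]; xx <- base_x + offs[k, 2]
        oky <- yy >= 1 & yy <= nrow(fine); okx <- xx >= 1 & xx <= ncol(fine)
        if (!any(oky) || !any(okx)) next
        cand <- matrix(NA_real_, d[2], d[3])
        cand[oky, okx] <- offs[k, 3] / dta2 +
          (fine[yy[oky], xx[okx], drop = FALSE] - refz[oky, okx])^2 / dd2
        gz <- pmin(gz, cand, na.rm = TRUE)
      }
      g2[z, , ] <- gz
    }
  }
  gamma <- sqrt(g2)
  gamma[!roim] <- NA_real_
  structure(list(gamma = gamma, criteria = criteria,
                 norm_value = norm_value, dd_abs = dd_abs, roi = roi,
                 capped_above = criteria$search_radius_factor),
            class = "gamma_map")
}

#' Gamma pass rate
#'
#' Percentage of ROI voxels with gamma <= 1 (inclusive, the standard
#' convention).
#'
#' @param g a \code{\link{gamma_map}}, or a numeric vector of gamma values.
#' @return Percent in [0, 100].
#' @export
pass_rate <- function(g) {
  v <- if (inherits(g, "gamma_map")) g$gamma[!is.na(g$gamma)] else
    g[!is.na(g)]
  if (length(v) == 0L)
    stop("pass_rate: no evaluated voxels", call. = FALSE)
  100 * sum(v <= 1) / length(v)
}

#' @export
print.gamma_map <- function(x, ...) {
  cat(sprintf("<gamma_map> %s, %g mm / %g%%, norm %.1f HU, pass %.2f%%\n",
              x$criteria$mode, x$criteria$dta_mm, x$criteria$dd_percent,
              x$norm_value, pass_rate(x)))
  invisible(x)
}
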