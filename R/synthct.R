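# Bulk-density HU assignment: label map -> BCT, body mask -> WCT.

#' Bulk HU assignment table
#'
#' Maps each anatomy class to a single representative CT number. Defaults:
#' air -1000, body 0, eyeball 300, lens 300, cavity -1000, ventricle 15,
#' brainstem -50, bone 1000 HU. Values must lie in [-1024, 3071] and every
#' one of the eight classes must have exactly one entry.
#'
#' @param values named numeric vector overriding defaults class-wise
#'   (names among the eight class names).
#' @return Named numeric of length 8, class \code{hu_table}.
#' @export
hu_table <- function(values = NULL) {
  tab <- c(air = -1000, body = 0, eyeball = 300, lens = 300,
           cavity = -1000, ventricle = 15, brainstem = -50, bone = 1000)
  if (!is.null(values)) {
    if (is.null(names(values)) || !all(names(values) %in% names(tab)))
      stop("hu_table: overrides must be named by anatomy class", call. = FALSE)
    tab[names(values)] <- values
  }
  if (any(tab < -1024 | tab > 3071))
    stop("hu_table: CT numbers must lie in [-1024, 3071]", call. = FALSE)
  structure(tab, class = "hu_table")
}

#' Synthesize a bulk-density-assigned CT (BCT)
#'
#' Replaces every voxel's class code with the table's CT number for that
#' class. The output grid equals the input grid and takes at most eight
#' distinct values (fewer when classes share a value, as air/cavity and
#' eyeball/lens do in the default table).
#'
#' @param labels a \code{\link{label_map}}.
#' @param table a \code{\link{hu_table}}; must cover every class code
#'   present in \code{labels}.
#' @return An \code{\link{image_volume}} of CT numbers.
#' @export
synthesize_bct <- function(labels, table = hu_table()) {
  stopifnot(inherits(labels, "label_map"))
  if (!inherits(table, "hu_table")) table <- hu_table(table)
  present <- unique(as.vector(labels$labels))
  covered <- CLASS_CODES[names(table)]
  if (!all(present %in% covered))
    stop("synthesize_bct: HU table missing class code(s) ",
         paste(setdiff(present, covered), collapse = ", "), call. = FALSE)
  lut <- numeric(8L)
  lut[CLASS_CODES[names(table)] + 1L] <- as.numeric(table)
  vals <- array(lut[labels$labels + 1L], dim = dim(labels$labels))
  image_volume(vals, spacing = labels$spacing, origin = labels$origin)
}

#' Synthesize a water-equivalent CT (WCT)
#'
#' Two-class assignment from the body mask alone: 0 HU inside the body,
#' -1000 HU outside. No inhomogeneity information is used.
#'
#' @param body a \code{\link{binary_mask}}.
#' @return An \code{\link{image_volume}} taking values in \{0, -1000\}.
#' @export
synthesize_wct <- function(body) {
  stopifnot(inherits(body, "binary_mask"))
  vals <- array(-1000, dim = dim(body$mask))
  vals[body$mask] <- 0
  image_volume(vals, spacing = body$spacing, origin = body$origin)
}
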