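# Segmentation overlap metrics: Dice similarity coefficient and its
# false-negative / false-positive decomposition, in percent.

#' Overlap scores between a segmentation and its ground truth
#'
#' With A the segmented mask and G the ground truth (and complements taken
#' on the shared grid):
#' \itemize{
#'   \item DSC = 2|A n G| / (|A| + |G|) x 100
#'   \item FND = 2|A' n G| / (|A| + |G|) x 100 (under-segmentation)
#'   \item FPD = 2|A n G'| / (|A| + |G|) x 100 (over-segmentation)
#' }
#' The three satisfy FND + FPD = 200 - 2 DSC identically. FND and FPD can
#' exceed 100 by these definitions (e.g. an empty A against a nonempty G
#' gives FND = 200); no clamping is applied.
#'
#' @param A segmentation \code{\link{binary_mask}}.
#' @param G ground-truth \code{\link{binary_mask}} on the same grid.
#' @return Object of class \code{overlap_scores}: fields \code{dsc},
#'   \code{fnd}, \code{fpd} (percent) and voxel counts \code{size_a},
#'   \code{size_g}, \code{size_intersection}.
#' @export
overlap_scores <- function(A, G) {
  stopifnot(inherits(A, "binary_mask"), inherits(G, "binary_mask"))
  check_same_grid(A, G)
  a <- A$mask; g <- G$mask
  na <- sum(a); ng <- sum(g)
  if (na + ng == 0)
    stop("overlap undefined: both masks are empty", call. = FALSE)
  ni <- sum(a & g)
  denom <- na + ng
  structure(list(dsc = 200 * ni / denom,
                 fnd = 200 * sum(!a & g) / denom,
                 fpd = 200 * sum(a & !g) / denom,
                 size_a = na, size_g = ng, size_intersection = ni),
            class = "overlap_scores")
}

#' @export
print.overlap_scores <- function(x, ...) {
  cat(sprintf("DSC %.2f  FND %.2f  FPD %.2f  (|A|=%d |G|=%d |AnG|=%d)\n",
              x$dsc, x$fnd, x$fpd, x$size_a, x$size_g, x$size_intersection))
  invisible(x)
}

#' Per-class overlap summary over a cohort
#'
#' Scores every (predicted, truth) label-map pair class by class and
#' summarizes with the mean and sample SD (n-1 denominator) across cases.
#' With a single case the SD is reported as 0 and the \code{degenerate_sd}
#' column is set, rather than returning NaN.
#'
#' @param cases list of cases; each case is a list with elements
#'   \code{pred} and \code{truth}, both \code{\link{label_map}}s.
#' @return \code{data.frame} with one row per class: \code{class},
#'   \code{dsc_mean}, \code{dsc_sd}, \code{fnd_mean}, \code{fnd_sd},
#'   \code{fpd_mean}, \code{fpd_sd}, \code{n}, \code{degenerate_sd}.
#' @export
cohort_overlap_table <- function(cases) {
  if (!is.list(cases) || length(cases) == 0L)
    stop("cohort_overlap_table: need at least one case", call. = FALSE)
  n <- length(cases)
  per_class <- lapply(names(CLASS_CODES), function(cls) {
    sc <- vapply(cases, function(cs) {
      pm <- to_masks(cs$pred)[[cls]]
      tm <- to_masks(cs$truth)[[cls]]
      s <- overlap_scores(pm, tm)
      c(s$dsc, s$fnd, s$fpd)
    }, numeric(3))
    sc <- matrix(sc, nrow = 3L)
    msd <- function(x) c(mean(x), if (length(x) > 1L) stats::sd(x) else 0)
    c(msd(sc[1, ]), msd(sc[2, ]), msd(sc[3, ]))
  })
  out <- do.call(rbind, per_class)
  data.frame(class = names(CLASS_CODES),
             dsc_mean = out[, 1], dsc_sd = out[, 2],
             fnd_mean = out[, 3], fnd_sd = out[, 4],
             fpd_mean = out[, 5], fpd_sd = out[, 6],
             n = n, degenerate_sd = n < 2L,
             row.names = NULL)
}
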