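# CT-number histograms and the four global-similarity measures:
# correlation, chi-square, intersection, Bhattacharyya distance.

#' Build a CT-number histogram
#'
#' Counts voxels (optionally restricted to an ROI mask) into \code{n_bins}
#' equal-width bins over \code{range_hu}; values outside the range are
#' clipped into the end bins. Both raw counts and the unit-sum
#' normalization are retained; comparisons use the normalized form.
#'
#' @param vol an \code{\link{image_volume}} of CT numbers.
#' @param roi optional \code{\link{binary_mask}} on the same grid;
#'   \code{NULL} uses the full grid (global similarity).
#' @param n_bins number of bins (>= 2); default 256.
#' @param range_hu length-2 HU interval covered by the bins; the default
#'   [-1000, 1000] spans the bulk HU table.
#' @return Object of class \code{ct_histogram}: \code{edges} (length
#'   n_bins + 1), \code{counts}, \code{prob} (unit-sum), \code{n_voxels}.
#' @export
build_histogram <- function(vol, roi = NULL, n_bins = 256L,
                            range_hu = c(-1000, 1000)) {
  stopifnot(inherits(vol, "image_volume"))
  n_bins <- as.integer(n_bins)
  if (n_bins < 2L)
    stop("build_histogram: n_bins must be >= 2", call. = FALSE)
  if (length(range_hu) != 2L || diff(range_hu) <= 0)
    stop("build_histogram: range_hu must be an increasing interval",
         call. = FALSE)
  v <- vol$values
  if (!is.null(roi)) {
    stopifnot(inherits(roi, "binary_mask"))
    check_same_grid(vol, roi)
    if (!any(roi$mask))
      stop("build_histogram: ROI is empty", call. = FALSE)
    v <- v[roi$mask]
  }
  v <- pmin(pmax(as.vector(v), range_hu[1]), range_hu[2])
  edges <- seq(range_hu[1], range_hu[2], length.out = n_bins + 1L)
  bin <- pmin(findInterval(v, edges, rightmost.closed = TRUE), n_bins)
  counts <- tabulate(bin, nbins = n_bins)
  structure(list(edges = edges, counts = counts,
                 prob = counts / sum(counts), n_voxels = length(v)),
            class = "ct_histogram")
}

check_same_binning <- function(h1, h2) {
  if (length(h1$edges) != length(h2$edges) ||
      any(abs(h1$edges - h2$edges) > 1e-9))
    stop("binning mismatch: histograms use different bin edges",
         call. = FALSE)
  invisible(TRUE)
}

#' Histogram correlation
#'
#' Pearson-style correlation of mean-centered unit-sum histograms:
#' sum(H1' H2') / sqrt(sum(H1'^2) sum(H2'^2)) with H'(i) = H(i) - mean(H).
#' A perfect match gives 1; zero indicates no correlation. Errors on a
#' constant (zero-variance) histogram, where the measure is undefined.
#'
#' @param h1,h2 \code{ct_histogram}s with identical binning.
#' @return Scalar in [-1, 1].
#' @export
hist_correlation <- function(h1, h2) {
  check_same_binning(h1, h2)
  a <- h1$prob - mean(h1$prob)
  b <- h2$prob - mean(h2$prob)
  sa <- sum(a^2); sb <- sum(b^2)
  if (sa == 0 || sb == 0)
    stop("degenerate histogram: zero variance, correlation undefined",
         call. = FALSE)
  sum(a * b) / sqrt(sa * sb)
}

#' Histogram chi-square distance
#'
#' Symmetric form sum (H1 - H2)^2 / (H1 + H2), bins where both are zero
#' contributing 0. Perfect match is 0; mismatch is unbounded.
#'
#' @inheritParams hist_correlation
#' @return Non-negative scalar.
#' @export
hist_chi_square <- function(h1, h2) {
  check_same_binning(h1, h2)
  num <- (h1$prob - h2$prob)^2
  den <- h1$prob + h2$prob
  sum(ifelse(den > 0, num / den, 0))
}

#' Histogram intersection
#'
#' sum min(H1, H2); for unit-sum histograms a perfect match gives 1 and a
#' total mismatch 0.
#'
#' @inheritParams hist_correlation
#' @return Scalar in [0, 1] for unit-sum inputs.
#' @export
hist_intersection <- function(h1, h2) {
  check_same_binning(h1, h2)
  sum(pmin(h1$prob, h2$prob))
}

#' Bhattacharyya (Hellinger) distance
#'
#' sqrt(1 - sum(sqrt(H1 H2)) / sqrt(sum(H1) sum(H2))). Perfect match is 0,
#' total mismatch 1.
#'
#' @inheritParams hist_correlation
#' @return Scalar in [0, 1].
#' @export
hist_bhattacharyya <- function(h1, h2) {
  check_same_binning(h1, h2)
  bc <- sum(sqrt(h1$prob * h2$prob)) / sqrt(sum(h1$prob) * sum(h2$prob))
  sqrt(max(0, 1 - bc))
}

#' All four histogram-similarity scores
#'
#' Computes correlation, chi-square, intersection and Bhattacharyya
#' distance between two identically binned unit-sum histograms. When either
#' histogram has zero variance the correlation is reported as \code{NA}
#' with the \code{degenerate_correlation} field set (the other three scores
#' remain well defined); use \code{\link{hist_correlation}} directly for
#' the erroring behaviour.
#'
#' @inheritParams hist_correlation
#' @return Object of class \code{histogram_scores} with fields
#'   \code{correlation}, \code{chi_square}, \code{intersection},
#'   \code{bhattacharyya}, \code{degenerate_correlation}.
#' @export
compare_histograms <- function(h1, h2) {
  check_same_binning(h1, h2)
  corr <- tryCatch(hist_correlation(h1, h2), error = function(e) NA_real_)
  structure(list(correlation = corr,
                 chi_square = hist_chi_square(h1, h2),
                 intersection = hist_intersection(h1, h2),
                 bhattacharyya = hist_bhattacharyya(h1, h2),
                 degenerate_correlation = is.na(corr)),
            class = "histogram_scores")
}

#' @export
print.histogram_scores <- function(x, ...) {
  cat(sprintf("correlation %.4f  chi-square %.4f  intersection %.4f  Bhattacharyya %.4f\n",
              x$correlation, x$chi_square, x$intersection, x$bhattacharyya))
  invisible(x)
}
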