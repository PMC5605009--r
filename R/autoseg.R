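# Rule-based segmentation of the eight head anatomies from T1/T2/PETRA:
# intensity thresholding + classification, gated by locational priors in a
# body-bounding-box-normalized frame.

#' Default segmentation rule set
#'
#' Intensity rules for the class cascade (order: bone, cavity, ventricle,
#' eyeball, lens, brainstem; residual in-body voxels become body, voxels
#' outside the body mask become air). Each class rule is a conjunction of
#' per-sequence bounds (\code{t1_min}, \code{t1_max}, \code{t2_min},
#' \code{t2_max}, \code{petra_min}, \code{petra_max}); the first matching
#' rule in cascade order wins, which makes tie-breaking deterministic.
#'
#' Bone is PETRA-present but dark on T1/T2; cavity (internal air) is dark on
#' all three sequences; ventricle is T1-dark/T2-bright CSF; the lens is
#' T1-bright/T2-dark inside the eyeball; the brainstem is mid-range on both.
#' Default thresholds are calibrated to the phantom's documented intensity
#' table (see \code{\link{phantom_spec}}); \code{normalization_pct} can be
#' set (e.g. 0.99) to rescale each sequence so that that percentile maps to
#' 100 before the rules are applied — the default applies no rescaling.
#'
#' @param normalization_pct optional percentile in (0, 1] used to rescale
#'   each sequence to a 0-100 scale; \code{NULL} (default) means identity.
#' @param body_threshold_frac body/air threshold as a fraction of the
#'   PETRA reference percentile (\code{body_ref_pct}).
#' @param body_ref_pct percentile of PETRA used as the robust foreground
#'   reference intensity.
#' @param thresholds named list of per-class bound lists, overriding the
#'   defaults class-wise.
#' @param open_radius,close_radius morphological cleanup radii in voxels
#'   applied per class (0 disables; thin structures such as the bone shell
#'   and lens are 1-2 voxels at 2.3-2.5 mm spacing, so the default is off).
#' @param min_component_voxels connected components smaller than this are
#'   relabeled as body; the lens is exempt (it is the smallest structure).
#' @return An object of class \code{seg_ruleset}.
#' @export
default_ruleset <- function(normalization_pct = NULL,
                            body_threshold_frac = 0.5,
                            body_ref_pct = 0.99,
                            thresholds = list(),
                            open_radius = 0L,
                            close_radius = 0L,
                            min_component_voxels = 3L) {
  thr <- list(
    bone      = list(t1_max = 32, t2_max = 32, petra_min = 30),
    cavity    = list(t1_max = 32, t2_max = 32, petra_max = 30),
    ventricle = list(t1_max = 35, t2_min = 70),
    eyeball   = list(t1_max = 50, t2_min = 60),
    lens      = list(t1_min = 65, t2_max = 33),
    brainstem = list(t1_min = 42, t1_max = 65, t2_min = 52, t2_max = 78))
  if (length(thresholds)) {
    unknown <- setdiff(names(thresholds), names(thr))
    if (length(unknown))
      stop("default_ruleset: unknown class(es) in thresholds: ",
           paste(unknown, collapse = ", "), call. = FALSE)
    thr[names(thresholds)] <- thresholds
  }
  structure(list(normalization_pct = normalization_pct,
                 body_threshold_frac = body_threshold_frac,
                 body_ref_pct = body_ref_pct,
                 thresholds = thr,
                 open_radius = as.integer(open_radius),
                 close_radius = as.integer(close_radius),
                 min_component_voxels = as.integer(min_component_voxels)),
            class = "seg_ruleset")
}

#' Default atlas prior
#'
#' Spatial support regions for the localized classes (eyeball, lens,
#' ventricle, brainstem, cavity), expressed as axis-aligned ellipsoids in a
#' normalized head frame: the affine that maps the body-mask bounding box
#' onto the unit cube. Supports are deliberately generous (2-4x the
#' expected structure extent) — they gate the intensity rules rather than
#' delineate anatomy, so no inter-subject registration is needed.
#'
#' @param classes named list overriding per-class support components; each
#'   class maps to a list of components, each a list with \code{center} and
#'   \code{semi} in normalized (slice, row, column) coordinates.
#' @return An object of class \code{atlas_prior}.
#' @export
default_atlas_prior <- function(classes = list()) {
  eyes <- list(list(center = c(0.52, 0.14, 0.327), semi = c(0.20, 0.15, 0.15)),
               list(center = c(0.52, 0.14, 0.673), semi = c(0.20, 0.15, 0.15)))
  # the lens support hugs the anterior pole of each eyeball: it gates a
  # rule whose intensity bounds sit close to the soft-tissue signature
  lenses <- list(list(center = c(0.52, 0.11, 0.327), semi = c(0.10, 0.06, 0.08)),
                 list(center = c(0.52, 0.11, 0.673), semi = c(0.10, 0.06, 0.08)))
  cls <- list(
    eyeball   = eyes,
    lens      = lenses,
    ventricle = list(list(center = c(0.554, 0.474, 0.5),
                          semi = c(0.30, 0.25, 0.33))),
    brainstem = list(list(center = c(0.304, 0.553, 0.5),
                          semi = c(0.22, 0.18, 0.15))),
    cavity    = list(list(center = c(0.337, 0.211, 0.5),
                          semi = c(0.25, 0.25, 0.25))))
  if (length(classes)) cls[names(classes)] <- classes
  structure(list(classes = cls), class = "atlas_prior")
}

# --- connected components ---------------------------------------------------
# 3D labeling built from EBImage's 2D bwlabel per slice, merged across
# adjacent slices with a union-find on overlapping labels.
label_components_3d <- function(mask) {
  d <- dim(mask)
  lab <- array(0L, dim = d)
  offset <- 0L
  for (z in seq_len(d[1])) {
    sl <- EBImage::bwlabel(mask[z, , ] * 1)
    sl <- array(as.integer(sl), dim = d[2:3])
    nz <- max(sl, 0L)
    pos <- sl > 0L
    sl[pos] <- sl[pos] + offset
    offset <- offset + nz
    lab[z, , ] <- sl
  }
  if (offset == 0L) return(lab)
  parent <- seq_len(offset)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  for (z in seq_len(d[1] - 1L)) {
    a <- lab[z, , ]; b <- lab[z + 1L, , ]
    sel <- a > 0L & b > 0L
    if (!any(sel)) next
    pairs <- unique(cbind(a[sel], b[sel]))
    for (k in seq_len(nrow(pairs))) {
      ra <- find(pairs[k, 1]); rb <- find(pairs[k, 2])
      if (ra != rb) parent[rb] <- ra
    }
  }
  roots <- vapply(seq_len(offset), find, integer(1))
  relab <- match(roots, unique(roots))
  pos <- lab > 0L
  lab[pos] <- relab[lab[pos]]
  lab
}

keep_largest_component <- function(mask) {
  lab <- label_components_3d(mask)
  if (max(lab) == 0L)
    stop("segmentation failure: empty foreground", call. = FALSE)
  counts <- tabulate(lab[lab > 0L])
  lab == which.max(counts)
}

fill_holes_slicewise <- function(mask) {
  d <- dim(mask)
  out <- mask
  for (z in seq_len(d[1])) {
    sl <- mask[z, , ]
    if (!any(sl)) next
    filled <- EBImage::fillHull(EBImage::bwlabel(sl * 1))
    out[z, , ] <- array(as.integer(filled) > 0L, dim = d[2:3])
  }
  out
}

# 6-neighborhood binary dilation/erosion by repeated axis shifts.
shift3 <- function(a, dz, dy, dx, fill) {
  d <- dim(a)
  out <- array(fill, dim = d)
  src <- list(seq_len(d[1]) - dz, seq_len(d[2]) - dy, seq_len(d[3]) - dx)
  ok <- lapply(1:3, function(i) src[[i]] >= 1 & src[[i]] <= d[i])
  out[ok[[1]], ok[[2]], ok[[3]]] <-
    a[src[[1]][ok[[1]]], src[[2]][ok[[2]]], src[[3]][ok[[3]]]]
  out
}

dilate3 <- function(m) {
  out <- m
  for (s in list(c(1,0,0), c(-1,0,0), c(0,1,0), c(0,-1,0), c(0,0,1), c(0,0,-1)))
    out <- out | shift3(m, s[1], s[2], s[3], FALSE)
  out
}
erode3 <- function(m) {
  out <- m
  for (s in list(c(1,0,0), c(-1,0,0), c(0,1,0), c(0,-1,0), c(0,0,1), c(0,0,-1)))
    out <- out & shift3(m, s[1], s[2], s[3], TRUE)
  out
}

morph_open <- function(m, r) { for (i in seq_len(r)) m <- erode3(m); for (i in seq_len(r)) m <- dilate3(m); m }
morph_close <- function(m, r) { for (i in seq_len(r)) m <- dilate3(m); for (i in seq_len(r)) m <- erode3(m); m }

# --- operations -------------------------------------------------------------

#' Segment the body from a PETRA volume
#'
#' Thresholds PETRA above background (a fraction of a robust reference
#' percentile), keeps the largest 3D connected component and fills internal
#' holes slice-wise, so air-filled cavities end up inside the body mask.
#'
#' @param petra PETRA \code{\link{image_volume}} (bone retains signal on
#'   this ultrashort-echo-time sequence, so the whole head is foreground).
#' @param rules a \code{\link{default_ruleset}}.
#' @return A \code{\link{binary_mask}} with a single connected component.
#' @export
segment_body <- function(petra, rules = default_ruleset()) {
  stopifnot(inherits(petra, "image_volume"), inherits(rules, "seg_ruleset"))
  v <- petra$values
  thr <- rules$body_threshold_frac *
    stats::quantile(v, rules$body_ref_pct, names = FALSE)
  fg <- v > thr
  if (!any(fg))
    stop("segmentation failure: no voxels above body threshold", call. = FALSE)
  m <- fill_holes_slicewise(keep_largest_component(fg))
  binary_mask(m, spacing = petra$spacing, origin = petra$origin)
}

normalize_seq <- function(v, pct) {
  if (is.null(pct)) return(v)
  ref <- stats::quantile(v, pct, names = FALSE)
  if (ref <= 0) stop("normalization failure: non-positive reference intensity",
                     call. = FALSE)
  v / ref * 100
}

rule_mask <- function(bounds, t1, t2, petra) {
  m <- array(TRUE, dim = dim(t1))
  for (nm in names(bounds)) {
    v <- switch(sub("_(min|max)$", "", nm), t1 = t1, t2 = t2, petra = petra,
                stop("unknown rule bound: ", nm, call. = FALSE))
    m <- m & if (endsWith(nm, "_min")) v > bounds[[nm]] else v < bounds[[nm]]
  }
  m
}

prior_mask <- function(prior, cls, body) {
  comps <- prior$classes[[cls]]
  if (is.null(comps)) return(NULL)
  d <- dim(body)
  idx <- which(body, arr.ind = TRUE)
  lo <- apply(idx, 2, min); hi <- apply(idx, 2, max)
  span <- pmax(hi - lo, 1L)
  u <- lapply(1:3, function(a) (seq_len(d[a]) - lo[a]) / span[a])
  m <- array(FALSE, dim = d)
  for (cp in comps) {
    qz <- ((u[[1]] - cp$center[1]) / cp$semi[1])^2
    qy <- ((u[[2]] - cp$center[2]) / cp$semi[2])^2
    qx <- ((u[[3]] - cp$center[3]) / cp$semi[3])^2
    m <- m | (outer(outer(qz, qy, "+"), qx, "+") <= 1)
  }
  if (!any(m & body))
    stop("atlas prior for class '", cls, "' does not intersect the body",
         call. = FALSE)
  m
}

#' Classify the eight anatomies
#'
#' Applies the rule cascade inside the body mask: bone, cavity, ventricle,
#' eyeball, lens, brainstem (each rule optionally gated by its atlas-prior
#' support), residual in-body voxels become body and everything outside the
#' mask is air. The first matching rule wins. Per-class morphological
#' cleanup and minimum-component filtering follow; removed voxels revert to
#' body.
#'
#' @param t1,t2,petra co-registered \code{\link{image_volume}}s.
#' @param body body \code{\link{binary_mask}} from \code{\link{segment_body}}.
#' @param rules a \code{\link{default_ruleset}}.
#' @param priors a \code{\link{default_atlas_prior}}.
#' @return A \code{\link{label_map}} covering every voxel with one class.
#' @export
classify_tissues <- function(t1, t2, petra, body,
                             rules = default_ruleset(),
                             priors = default_atlas_prior()) {
  check_same_grid(t1, t2); check_same_grid(t1, petra); check_same_grid(t1, body)
  if (!any(body$mask))
    stop("classify_tissues: body mask is empty", call. = FALSE)
  v1 <- normalize_seq(t1$values, rules$normalization_pct)
  v2 <- normalize_seq(t2$values, rules$normalization_pct)
  vp <- normalize_seq(petra$values, rules$normalization_pct)
  B <- body$mask
  lab <- array(CLASS_CODES[["air"]], dim = dim(B))
  unassigned <- B
  cascade <- c("bone", "cavity", "ventricle", "eyeball", "lens", "brainstem")
  for (cls in cascade) {
    m <- rule_mask(rules$thresholds[[cls]], v1, v2, vp)
    pm <- prior_mask(priors, cls, B)
    if (!is.null(pm)) m <- m & pm
    m <- m & unassigned
    lab[m] <- CLASS_CODES[[cls]]
    unassigned <- unassigned & !m
  }
  lab[unassigned] <- CLASS_CODES[["body"]]

  # cleanup: optional open/close, then drop sub-minimum components (-> body)
  for (cls in cascade) {
    code <- CLASS_CODES[[cls]]
    m <- lab == code
    if (!any(m)) next
    if (cls != "lens") {
      if (rules$open_radius > 0L) m <- morph_open(m, rules$open_radius)
      if (rules$close_radius > 0L) m <- morph_close(m, rules$close_radius)
      if (rules$min_component_voxels > 1L) {
        cc <- label_components_3d(m)
        if (max(cc) > 0L) {
          counts <- tabulate(cc[cc > 0L])
          small <- which(counts < rules$min_component_voxels)
          if (length(small)) m[cc %in% small] <- FALSE
        }
      }
    }
    changed <- (lab == code) & !m
    lab[changed] <- CLASS_CODES[["body"]]
    add <- m & (lab != code) & B
    lab[add] <- code
  }
  label_map(lab, spacing = t1$spacing, origin = t1$origin)
}

#' Split a label map into per-class binary masks
#'
#' @param labels a \code{\link{label_map}}.
#' @return Named list of eight pairwise-disjoint \code{\link{binary_mask}}s
#'   whose union covers the grid.
#' @export
to_masks <- function(labels) {
  stopifnot(inherits(labels, "label_map"))
  out <- lapply(names(CLASS_CODES), function(cls)
    binary_mask(labels$labels == CLASS_CODES[[cls]],
                spacing = labels$spacing, origin = labels$origin))
  names(out) <- names(CLASS_CODES)
  out
}
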