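# Shared fixtures: tiny volumes, a small fast phantom spec, and the
# independent brute-force gamma oracle.

random_volume <- function(shape = c(4, 5, 6), spacing = c(2.5, 1.5, 1.5),
                          origin = c(0.5, -3, 12)) {
  image_volume(array(stats::rnorm(prod(shape)), dim = shape),
               spacing = spacing, origin = origin)
}

# quarter-scale phantom: same physics, ~16x fewer voxels than the default
small_spec <- function(..., geometry = list()) {
  geo <- list(head_center = c(30, 74, 74),
              head_semi = c(27, 56, 44),
              eye_center = c(31, 36, NA),
              eye_offset_x = 14,
              eye_radius = 5.5,
              vent_center = c(33, 70, NA),
              vent_offset_x = 10.5,
              vent_semi = c(7, 17.5, 6),
              stem_center = c(19, 80, 74),
              stem_semi = c(6.5, 8, 6.5),
              cavity_center = c(21, 42, 74),
              cavity_semi = c(6, 7, 8))
  geo[names(geometry)] <- geometry
  phantom_spec(shape = c(24L, 64L, 64L), spacing = c(2.5, 2.34, 2.34),
               geometry = geo, ...)
}

# Independent all-pairs gamma: straight-line double loop over every
# reference/evaluated voxel pair of a single-slice volume.
brute_force_gamma_2d <- function(ref, ev, dta_mm, dd_abs, spacing) {
  ny <- nrow(ref); nx <- ncol(ref)
  ys <- (seq_len(ny) - 1) * spacing[1]
  xs <- (seq_len(nx) - 1) * spacing[2]
  dta2 <- dta_mm^2; dd2 <- dd_abs^2
  out <- matrix(NA_real_, ny, nx)
  for (i in seq_len(ny)) for (j in seq_len(nx)) {
    dist2 <- outer((ys - ys[i])^2, (xs - xs[j])^2, "+")
    g2 <- dist2 / dta2 + (ev - ref[i, j])^2 / dd2
    out[i, j] <- sqrt(min(g2))
  }
  out
}
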