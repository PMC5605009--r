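# Digital head phantom: analytic ellipsoid geometry rasterized at voxel
# centers, per-class MR / CT intensity models, seeded per-case jitter.

#' Phantom specification
#'
#' Defines the simulated acquisition and anatomy for a cohort of digital
#' head phantoms: grid geometry (default 40 slices of 128 x 128 at
#' 2.5 x 2.34 x 2.34 mm, i.e. 2.5 mm slices over a ~30 cm field of view),
#' analytic structure geometry (head/skull ellipsoids, paired eyeballs with
#' lenses, lateral ventricles, brainstem, an air-filled sinus cavity),
#' per-class MR intensity means for the three sequences, and the reference
#' CT intensity model.
#'
#' The reference CT is deliberately not the ideal bulk-assigned CT: its
#' per-class HU means differ from the bulk HU table (soft tissue 30 HU
#' rather than 0, bone 970 rather than 1000, ...), and per-voxel noise
#' plus a smooth additive low-frequency artifact field (object-induced, so
#' restricted to the head) are added, so downstream similarity metrics
#' have dynamic range.
#'
#' The MR class means are chosen so that classes are separable at zero
#' noise (rows: air, body, eyeball, lens, cavity, ventricle, brainstem,
#' bone; columns T1/T2/PETRA, arbitrary units):
#' T1 (3, 70, 35, 80, 5, 20, 55, 15); T2 (3, 45, 75, 25, 5, 90, 65, 15);
#' PETRA (3, 55, 50, 50, 5, 50, 55, 45). Bone retains signal on PETRA only;
#' CSF (ventricle) is dark on T1 and bright on T2; lens is the reverse.
#'
#' @param shape integer length-3 grid shape (slices, rows, columns).
#' @param spacing voxel size in mm per axis.
#' @param mr_noise_sd per-sequence Gaussian noise SD (arbitrary units).
#' @param mr_bias_amp amplitude of the smooth multiplicative bias field
#'   (fraction of the class mean).
#' @param ct_noise_sd reference-CT Gaussian noise SD in HU.
#' @param ct_bias_amp_hu amplitude of the smooth additive HU perturbation.
#' @param jitter_frac per-case multiplicative geometry jitter (uniform in
#'   +/- this fraction).
#' @param seed base seed of the cohort's random stream.
#' @param geometry named list overriding default structure geometry (mm).
#' @param mr_means 8 x 3 matrix of class intensity means (T1, T2, PETRA).
#' @param ct_means named numeric of reference-CT class HU means.
#' @return An object of class \code{phantom_spec}.
#' @export
phantom_spec <- function(shape = c(40L, 128L, 128L),
                         spacing = c(2.5, 2.34, 2.34),
                         mr_noise_sd = c(t1 = 3, t2 = 3, petra = 3),
                         mr_bias_amp = 0.05,
                         ct_noise_sd = 10,
                         ct_bias_amp_hu = 30,
                         jitter_frac = 0.04,
                         seed = 42L,
                         geometry = list(),
                         mr_means = NULL,
                         ct_means = NULL) {
  shape <- as.integer(shape)
  stopifnot(length(shape) == 3L, all(shape >= 8L),
            length(spacing) == 3L, all(spacing > 0))
  geo <- list(
    head_center  = c(50, 150, 150),
    head_semi    = c(46, 95, 75),
    bone_outer_frac = 0.92,
    bone_inner_frac = 0.82,
    eye_center   = c(52, 82, NA),   # x filled from eye_offset_x
    eye_offset_x = 26,
    eye_radius   = 9.5,
    lens_radius_frac   = 0.35,      # of eyeball radius
    lens_anterior_frac = 0.60,      # of eyeball radius, toward low y
    vent_center  = c(55, 145, NA),
    vent_offset_x = 18,
    vent_semi    = c(12, 30, 10),
    stem_center  = c(32, 160, 150),
    stem_semi    = c(11, 14, 11),
    cavity_center = c(35, 95, 150),
    cavity_semi   = c(10, 12, 14))
  if (length(geometry)) {
    unknown <- setdiff(names(geometry), names(geo))
    if (length(unknown))
      stop("phantom_spec: unknown geometry field(s): ",
           paste(unknown, collapse = ", "), call. = FALSE)
    geo[names(geometry)] <- geometry
  }
  if (is.null(mr_means)) {
    mr_means <- cbind(
      t1    = c(3, 70, 35, 80, 5, 20, 55, 15),
      t2    = c(3, 45, 75, 25, 5, 90, 65, 15),
      petra = c(3, 55, 50, 50, 5, 50, 55, 45))
    rownames(mr_means) <- names(CLASS_CODES)
  }
  stopifnot(is.matrix(mr_means), nrow(mr_means) == 8L, ncol(mr_means) == 3L)
  if (is.null(ct_means))
    ct_means <- c(air = -1000, body = 30, eyeball = 290, lens = 320,
                  cavity = -980, ventricle = 20, brainstem = -40, bone = 970)
  stopifnot(length(ct_means) == 8L)
  mr_noise_sd <- rep_len(as.numeric(mr_noise_sd), 3L)
  structure(list(shape = shape, spacing = as.numeric(spacing),
                 origin = as.numeric(spacing) / 2,
                 geometry = geo, mr_means = mr_means,
                 mr_noise_sd = mr_noise_sd, mr_bias_amp = mr_bias_amp,
                 ct_means = as.numeric(ct_means), ct_noise_sd = ct_noise_sd,
                 ct_bias_amp_hu = ct_bias_amp_hu,
                 jitter_frac = jitter_frac, seed = as.integer(seed)),
            class = "phantom_spec")
}

# World coordinates of voxel centers along each axis.
axis_coords <- function(spec) {
  lapply(1:3, function(a)
    spec$origin[a] + (seq_len(spec$shape[a]) - 1) * spec$spacing[a])
}

# Logical array of voxels whose centers lie inside an axis-aligned ellipsoid.
rasterize_ellipsoid <- function(coords, center, semi) {
  qz <- ((coords[[1]] - center[1]) / semi[1])^2
  qy <- ((coords[[2]] - center[2]) / semi[2])^2
  qx <- ((coords[[3]] - center[3]) / semi[3])^2
  outer(outer(qz, qy, "+"), qx, "+") <= 1
}

# ~200 quasi-uniform directions on the unit sphere (Fibonacci lattice),
# used for analytic containment checks on jittered geometry.
fib_sphere <- function(n = 200L) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(cos(phi), sin(phi) * sin(theta), sin(phi) * cos(theta))
}

assert_inside <- function(c_in, semi_in, c_out, semi_out, what, within) {
  d <- fib_sphere()
  pts <- sweep(d %*% diag(semi_in), 2, c_in, "+")
  q <- ((pts[, 1] - c_out[1]) / semi_out[1])^2 +
       ((pts[, 2] - c_out[2]) / semi_out[2])^2 +
       ((pts[, 3] - c_out[3]) / semi_out[3])^2
  if (any(q >= 1))
    stop("phantom geometry error: ", what, " not strictly inside ", within,
         call. = FALSE)
  invisible(TRUE)
}

# Smooth low-frequency field in [-1, 1]: one cosine per axis with integer
# frequency and random phase (a stationary random field with a fixed
# amplitude spectrum — its value distribution is the same for every case,
# only the spatial arrangement varies). Draws from the current RNG stream.
smooth_field <- function(shape) {
  u <- lapply(shape, function(n) (seq_len(n) - 1) / max(n - 1, 1))
  freq <- sample(2:3, 3, replace = TRUE)
  phase <- stats::runif(3)
  comp <- lapply(1:3, function(a) cospi(2 * (freq[a] * u[[a]] + phase[a])))
  outer(outer(comp[[1]], comp[[2]], "+"), comp[[3]], "+") / 3
}

case_seed <- function(spec, case_id, offset) {
  as.integer((as.double(spec$seed) * 7919 + as.double(case_id) * 104729 +
              offset * 13) %% 2147483629)
}

#' Generate one phantom case
#'
#' Deterministic for a given (spec, case_id): geometry is jittered by a
#' seeded multiplicative perturbation, then the ground-truth label map is
#' rasterized (paint order: air, body, bone shell, cavity, ventricles,
#' brainstem, eyeballs, lenses — later structures override earlier ones),
#' and the three MR volumes and the reference CT are simulated on it.
#'
#' MR model: class mean x (1 + bias field) + Gaussian noise, clamped at 0.
#' CT model: class HU mean + smooth additive artifact field (inside the
#' head only) + Gaussian noise, clamped at -1000 HU.
#'
#' @param spec a \code{\link{phantom_spec}}.
#' @param case_id non-negative integer case index.
#' @return An object of class \code{phantom_case} with fields \code{truth}
#'   (\code{label_map}), \code{t1}, \code{t2}, \code{petra},
#'   \code{reference_ct} (\code{image_volume}), \code{case_id}, \code{seed}.
#' @export
generate_case <- function(spec, case_id) {
  stopifnot(inherits(spec, "phantom_spec"))
  if (!is.numeric(case_id) || length(case_id) != 1L || case_id < 0 ||
      case_id != round(case_id))
    stop("generate_case: case_id must be a non-negative integer",
         call. = FALSE)
  case_id <- as.integer(case_id)
  if (exists(".Random.seed", envir = globalenv())) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()))
  }

  # --- per-case geometry jitter ------------------------------------------
  set.seed(case_seed(spec, case_id, 0L))
  g <- spec$geometry
  j <- function(x) x * (1 + stats::runif(length(x), -spec$jitter_frac,
                                         spec$jitter_frac))
  head_c <- g$head_center
  head_s <- j(g$head_semi)
  eye_r <- j(g$eye_radius)
  eye_x <- j(g$eye_offset_x)
  eye_zy <- g$eye_center[1:2] + stats::runif(2, -2, 2)
  vent_s <- j(g$vent_semi)
  vent_x <- j(g$vent_offset_x)
  vent_zy <- g$vent_center[1:2] + stats::runif(2, -2, 2)
  stem_c <- g$stem_center + stats::runif(3, -2, 2)
  stem_s <- j(g$stem_semi)
  cav_c <- g$cavity_center + stats::runif(3, -2, 2)
  cav_s <- j(g$cavity_semi)
  lens_r <- g$lens_radius_frac * eye_r
  lens_d <- g$lens_anterior_frac * eye_r

  eye_centers <- list(c(eye_zy, head_c[3] - eye_x), c(eye_zy, head_c[3] + eye_x))
  lens_centers <- lapply(eye_centers, function(ec) ec - c(0, lens_d, 0))
  vent_centers <- list(c(vent_zy, head_c[3] - vent_x), c(vent_zy, head_c[3] + vent_x))

  # --- containment checks -------------------------------------------------
  for (k in 1:2) {
    assert_inside(eye_centers[[k]], rep(eye_r, 3), head_c, head_s,
                  "eyeball", "head")
    assert_inside(lens_centers[[k]], rep(lens_r, 3), eye_centers[[k]],
                  rep(eye_r, 3), "lens", "eyeball")
    assert_inside(vent_centers[[k]], vent_s, head_c, head_s,
                  "ventricle", "head")
  }
  assert_inside(stem_c, stem_s, head_c, head_s, "brainstem", "head")
  assert_inside(cav_c, cav_s, head_c, head_s, "cavity", "head")

  # --- rasterize truth ----------------------------------------------------
  co <- axis_coords(spec)
  lab <- array(CLASS_CODES[["air"]], dim = spec$shape)
  body_m <- rasterize_ellipsoid(co, head_c, head_s)
  lab[body_m] <- CLASS_CODES[["body"]]
  bone_m <- rasterize_ellipsoid(co, head_c, head_s * g$bone_outer_frac) &
            !rasterize_ellipsoid(co, head_c, head_s * g$bone_inner_frac)
  lab[bone_m] <- CLASS_CODES[["bone"]]
  lab[rasterize_ellipsoid(co, cav_c, cav_s)] <- CLASS_CODES[["cavity"]]
  for (vc in vent_centers)
    lab[rasterize_ellipsoid(co, vc, vent_s)] <- CLASS_CODES[["ventricle"]]
  lab[rasterize_ellipsoid(co, stem_c, stem_s)] <- CLASS_CODES[["brainstem"]]
  for (ec in eye_centers)
    lab[rasterize_ellipsoid(co, ec, rep(eye_r, 3))] <- CLASS_CODES[["eyeball"]]
  for (lc in lens_centers)
    lab[rasterize_ellipsoid(co, lc, rep(lens_r, 3))] <- CLASS_CODES[["lens"]]

  present <- sort(unique(as.vector(lab)))
  if (!identical(present, as.integer(0:7)))
    stop("phantom geometry error: rasterized label map is missing class(es) ",
         paste(setdiff(0:7, present), collapse = ", "), call. = FALSE)

  truth <- label_map(lab, spacing = spec$spacing, origin = spec$origin)
  n <- prod(spec$shape)
  idx <- lab + 1L

  # --- MR volumes ---------------------------------------------------------
  seqs <- c("t1", "t2", "petra")
  mr <- vector("list", 3L); names(mr) <- seqs
  for (s in 1:3) {
    set.seed(case_seed(spec, case_id, s))
    bias <- 1 + spec$mr_bias_amp * smooth_field(spec$shape)
    v <- array(spec$mr_means[idx, s], dim = spec$shape) * bias +
      array(stats::rnorm(n, 0, spec$mr_noise_sd[s]), dim = spec$shape)
    mr[[s]] <- image_volume(pmax(v, 0), spacing = spec$spacing,
                            origin = spec$origin)
  }

  # --- reference CT -------------------------------------------------------
  # the smooth HU perturbation is object-induced (beam hardening, scatter)
  # and therefore applied inside the head only; open air carries noise only
  set.seed(case_seed(spec, case_id, 4L))
  pert <- spec$ct_bias_amp_hu * smooth_field(spec$shape)
  pert[lab == CLASS_CODES[["air"]]] <- 0
  ct <- array(spec$ct_means[idx], dim = spec$shape) + pert +
    array(stats::rnorm(n, 0, spec$ct_noise_sd), dim = spec$shape)
  ct <- image_volume(pmax(ct, -1000), spacing = spec$spacing,
                     origin = spec$origin)

  structure(list(truth = truth, t1 = mr$t1, t2 = mr$t2, petra = mr$petra,
                 reference_ct = ct, case_id = case_id, seed = spec$seed),
            class = "phantom_case")
}

#' Generate a cohort of phantom cases
#'
#' @param spec a \code{\link{phantom_spec}}.
#' @param n_cases number of cases (default 20); case ids are 0..n-1 and each
#'   case gets distinct jittered geometry.
#' @return List of \code{phantom_case} objects.
#' @export
generate_cohort <- function(spec, n_cases = 20L) {
  if (!is.numeric(n_cases) || length(n_cases) != 1L || n_cases < 1)
    stop("generate_cohort: n_cases must be >= 1", call. = FALSE)
  lapply(seq_len(n_cases) - 1L, function(i) generate_case(spec, i))
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat("<phantom_spec> grid ", paste(x$shape, collapse = "x"),
      ", spacing ", paste(format(x$spacing), collapse = "/"),
      " mm, seed ", x$seed, "\n", sep = "")
  invisible(x)
}

#' @export
print.phantom_case <- function(x, ...) {
  cat("<phantom_case> id ", x$case_id, ", grid ",
      paste(dim(x$truth$labels), collapse = "x"), "\n", sep = "")
  invisible(x)
}

#' Write a phantom case to NIfTI files
#'
#' Writes truth.nii.gz (int16 label map), t1/t2/petra/ct.nii.gz into
#' \code{dir/case_<id>/}.
#'
#' @param case a \code{phantom_case}.
#' @param dir output directory (created if absent).
#' @return Invisibly, the per-case directory path.
#' @export
write_case <- function(case, dir) {
  stopifnot(inherits(case, "phantom_case"))
  d <- file.path(dir, sprintf("case_%03d", case$case_id))
  dir.create(d, recursive = TRUE, showWarnings = FALSE)
  write_volume(case$truth, file.path(d, "truth.nii.gz"))
  write_volume(case$t1, file.path(d, "t1.nii.gz"))
  write_volume(case$t2, file.path(d, "t2.nii.gz"))
  write_volume(case$petra, file.path(d, "petra.nii.gz"))
  write_volume(case$reference_ct, file.path(d, "ct.nii.gz"))
  invisible(d)
}
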