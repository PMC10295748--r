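#' Linearly interpolated stent lumen profile
#'
#' Factory for the ground-truth lumen profile of a phantom stent: long and
#' short diameters interpolate linearly from the middle-ear (isthmus-facing)
#' end to the pharyngeal end, the long-axis orientation twists at a constant
#' rate, and a fixed fraction of the short diameter lies on the cartilage
#' side. The defaults emulate a self-expanding nitinol stent squeezed toward
#' the isthmus: roughly a threefold area increase from the narrow to the
#' wide end, a total twist of about 20 degrees, and a cartilage-facing part
#' of the short diameter (D1) smaller than the opposite part (D2).
#'
#' @param length_mm stent length (mm).
#' @param dL_mm long diameter at the two ends (middle-ear end first), mm.
#' @param dS_mm short diameter at the two ends, mm.
#' @param theta0_deg orientation of the long axis at the middle-ear end.
#' @param twist_deg_per_mm rotation rate of the long axis along the stent.
#' @param D1_frac fraction of the short diameter on the cartilage side
#'   (0 < D1_frac < 1; below 0.5 reproduces D1 < D2).
#' @return function mapping axial position `s` (mm from the middle-ear end)
#'   to a data frame with columns `dL_mm`, `dS_mm`, `theta_deg`, `D1_frac`.
#' @export
stent_profile_linear <- function(length_mm,
                                 dL_mm = c(1.9, 4.4),
                                 dS_mm = c(1.0, 2.9),
                                 theta0_deg = 0,
                                 twist_deg_per_mm = 1.5,
                                 D1_frac = 0.45) {
  force(length_mm)
  function(s) {
    f <- pmin(pmax(s / length_mm, 0), 1)
    data.frame(dL_mm = dL_mm[1] + f * diff(dL_mm),
               dS_mm = dS_mm[1] + f * diff(dS_mm),
               theta_deg = theta0_deg + twist_deg_per_mm * s,
               D1_frac = rep(D1_frac, length(s)))
  }
}

#' Phantom specification
#'
#' Describes a synthetic epoxy-embedded specimen: a cylindrical block with
#' two non-congruent fiducial grooves cast into its rim, soft tissue with a
#' cartilage band on one side, a tapered tubal lumen collapsed outside the
#' stent, and a stented lumen segment with prescribed diameter/orientation
#' profiles. The block is "ground" into `n_planes` section images; geometry
#' is generated at `true_spacing_mm` per plane while the stack declares
#' `nominal_spacing_mm`, so a grinding-depth error can be injected and later
#' recovered. The stent axis may be tilted against the block axis; the tilt
#' is realized as a linear in-plane drift (shear) of the lumen centre.
#'
#' Intensity model: four to five gray levels on a 0-255 scale (background <
#' epoxy < tissue < cartilage < lumen) plus additive Gaussian noise, the
#' simplest model that makes automatic contrasting nontrivial.
#'
#' @param block_diameter_mm diameter of the epoxy cylinder (mm).
#' @param n_planes number of documented grinding planes.
#' @param pixel_size_mm in-plane pixel edge (mm/px).
#' @param nominal_spacing_mm declared grinding depth per plane (mm).
#' @param true_spacing_mm actually removed depth per plane (mm).
#' @param groove_width_mm widths of the wide and narrow groove (mm); must be
#'   distinct so that every in-plane pose, including flips, is identifiable.
#' @param groove_angle_deg angular rim positions of the two grooves; their
#'   offset must not be 180 degrees.
#' @param stent_extent_mm `(start, end)` of the stented lumen along the
#'   block axis (mm, plane 1 at z = 0).
#' @param stent_profile function of axial position s (mm from the stent's
#'   middle-ear end) as produced by [stent_profile_linear()].
#' @param tube_profile function of block z returning a data frame or list
#'   with `long_mm`, `short_mm`: the tubal lumen calibre, widening from the
#'   isthmus toward the pharynx.
#' @param tilt_deg angle between stent axis and block axis (degrees).
#' @param tilt_dir_deg in-plane direction of the tilt drift.
#' @param misalignment list with `translate_px` and `rotate_deg`: half-widths
#'   of the uniform per-slice misalignment distributions.
#' @param noise_sigma standard deviation of additive Gaussian intensity
#'   noise (0-255 scale).
#' @param ref_spacing_mm z spacing of the rendered reference volume (the
#'   trusted-geometry scan surrogate); defaults to `true_spacing_mm`.
#' @param isthmus_z_mm block-z of the isthmus landmark; defaults to 0.3 mm
#'   before the stent's middle-ear end.
#' @param cartilaginous_length_mm isthmus-to-pharyngeal-ostium length (mm).
#' @param levels named intensity levels (background, epoxy, tissue,
#'   cartilage, lumen).
#' @param seed integer seed driving misalignment and noise draws.
#' @return an object of class `phantom_spec`.
#' @export
phantom_spec <- function(block_diameter_mm = 35,
                         n_planes = 76,
                         pixel_size_mm = 0.02,
                         nominal_spacing_mm = 0.2,
                         true_spacing_mm = nominal_spacing_mm,
                         groove_width_mm = c(3.0, 1.2),
                         groove_angle_deg = c(90, 210),
                         stent_extent_mm = c(1, 14),
                         stent_profile = NULL,
                         tube_profile = NULL,
                         tilt_deg = 8,
                         tilt_dir_deg = 0,
                         misalignment = list(translate_px = 10, rotate_deg = 5),
                         noise_sigma = 5,
                         ref_spacing_mm = NULL,
                         isthmus_z_mm = NULL,
                         cartilaginous_length_mm = 19.6,
                         levels = c(background = 10, epoxy = 70, tissue = 120,
                                    cartilage = 140, lumen = 200),
                         seed = 1L) {
  stopifnot(block_diameter_mm > 0, n_planes >= 1, pixel_size_mm > 0,
            nominal_spacing_mm > 0, true_spacing_mm > 0,
            length(groove_width_mm) == 2, all(groove_width_mm > 0),
            length(groove_angle_deg) == 2,
            length(stent_extent_mm) == 2,
            stent_extent_mm[2] > stent_extent_mm[1])
  if (groove_width_mm[1] <= groove_width_mm[2])
    stop("the first groove must be the wider one (non-congruent pair)")
  if (abs(abs(wrap_delta180(diff(groove_angle_deg))) - 180) < 1e-9)
    stop("groove angular offset of 180 degrees makes flips ambiguous")
  stent_len <- diff(stent_extent_mm)
  if (is.null(stent_profile))
    stent_profile <- stent_profile_linear(stent_len)
  if (is.null(tube_profile)) {
    iso <- if (is.null(isthmus_z_mm)) stent_extent_mm[1] - 0.3 else isthmus_z_mm
    tube_profile <- function(z) {
      w <- pmax(z - iso, 0)
      list(long_mm = pmin(3 + 0.33 * w, 8), short_mm = pmin(2 + 0.25 * w, 6))
    }
  }
  if (is.null(isthmus_z_mm)) isthmus_z_mm <- stent_extent_mm[1] - 0.3
  if (is.null(ref_spacing_mm)) ref_spacing_mm <- true_spacing_mm
  # invariant checks on the profile over the stent
  pr <- stent_profile(seq(0, stent_len, length.out = 25))
  if (any(pr$dS_mm > pr$dL_mm + 1e-9))
    stop("stent profile must satisfy dS <= dL everywhere")
  if (any(pr$D1_frac <= 0 | pr$D1_frac >= 1))
    stop("D1_frac must lie strictly between 0 and 1")
  structure(list(
    block_diameter_mm = block_diameter_mm, n_planes = as.integer(n_planes),
    pixel_size_mm = pixel_size_mm, nominal_spacing_mm = nominal_spacing_mm,
    true_spacing_mm = true_spacing_mm, groove_width_mm = groove_width_mm,
    groove_angle_deg = groove_angle_deg, stent_extent_mm = stent_extent_mm,
    stent_profile = stent_profile, tube_profile = tube_profile,
    tilt_deg = tilt_deg, tilt_dir_deg = tilt_dir_deg,
    misalignment = misalignment, noise_sigma = noise_sigma,
    ref_spacing_mm = ref_spacing_mm, isthmus_z_mm = isthmus_z_mm,
    cartilaginous_length_mm = cartilaginous_length_mm,
    levels = levels, seed = as.integer(seed),
    margin_mm = 1), class = "phantom_spec")
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat(sprintf(paste0(
    "<phantom_spec> block %.4g mm, %d planes @ %.4g mm/px\n",
    "  spacing: nominal %.3f mm, true %.3f mm; stent [%.4g, %.4g] mm, tilt %.4g deg\n"),
    x$block_diameter_mm, x$n_planes, x$pixel_size_mm,
    x$nominal_spacing_mm, x$true_spacing_mm,
    x$stent_extent_mm[1], x$stent_extent_mm[2], x$tilt_deg))
  invisible(x)
}

# raster geometry helpers -----------------------------------------------

phantom_raster_n <- function(spec) {
  round((spec$block_diameter_mm + 2 * spec$margin_mm) / spec$pixel_size_mm)
}

phantom_center_mm <- function(spec) {
  n <- phantom_raster_n(spec)
  rep(n * spec$pixel_size_mm / 2, 2)
}

# in-plane stent/tube centre at block height z (tilt drift / shear)
phantom_center_at_z <- function(spec, z_mm) {
  z_mid <- (spec$n_planes - 1) * spec$true_spacing_mm / 2
  drift <- tan(deg2rad(spec$tilt_deg)) * (z_mm - z_mid)
  dir <- c(cos(deg2rad(spec$tilt_dir_deg)), sin(deg2rad(spec$tilt_dir_deg)))
  phantom_center_mm(spec) + drift * dir
}

#' Analytic fiducial groove positions
#'
#' Rim points at which the two mold grooves are centred, in pixel
#' coordinates of an unperturbed rendered section: the oracle the fiducial
#' detector is tested against. Row 1 is the wide groove, row 2 the narrow.
#'
#' @param spec a [phantom_spec()].
#' @return 2 x 2 matrix of (x, y) pixel coordinates.
#' @export
groove_centroids <- function(spec) {
  ctr <- phantom_center_mm(spec)
  R <- spec$block_diameter_mm / 2
  ang <- deg2rad(spec$groove_angle_deg)
  mm <- cbind(ctr[1] + R * cos(ang), ctr[2] + R * sin(ang))
  mm / spec$pixel_size_mm + 0.5
}

# render one plane at arbitrary block height z (no misalignment, no noise)
render_plane_z <- function(spec, z_mm, with_mask = FALSE) {
  n <- phantom_raster_n(spec)
  px <- spec$pixel_size_mm
  lv <- spec$levels
  coord <- (seq_len(n) - 0.5) * px
  X <- matrix(coord, n, n)
  Y <- matrix(coord, n, n, byrow = TRUE)
  ctr <- phantom_center_mm(spec)
  R <- spec$block_diameter_mm / 2
  img <- matrix(lv[["background"]], n, n)
  block <- (X - ctr[1])^2 + (Y - ctr[2])^2 <= R^2
  img[block] <- lv[["epoxy"]]

  tc <- phantom_center_at_z(spec, z_mm)
  tp <- spec$tube_profile(z_mm)
  tl <- as.numeric(tp$long_mm); ts <- as.numeric(tp$short_mm)
  wall <- 1.5
  XT <- X - tc[1]; YT <- Y - tc[2]
  tissue <- (XT / (tl / 2 + wall))^2 + (YT / (ts / 2 + wall))^2 <= 1
  img[tissue & block] <- lv[["tissue"]]
  # cartilage band on the +y (cartilage) side, hugging the lumen
  cart <- abs(XT) <= tl / 2 + wall &
    YT >= ts / 2 & YT <= ts / 2 + 1.2
  img[cart & block] <- lv[["cartilage"]]

  lumen <- matrix(FALSE, n, n)
  ext <- spec$stent_extent_mm
  if (z_mm >= ext[1] && z_mm <= ext[2]) {
    pr <- spec$stent_profile(z_mm - ext[1])
    th <- deg2rad(pr$theta_deg)
    a <- pr$dL_mm / 2
    b1 <- pr$D1_frac * pr$dS_mm        # cartilage-side semi-axis
    b2 <- (1 - pr$D1_frac) * pr$dS_mm
    U <- cos(th) * XT + sin(th) * YT
    V <- -sin(th) * XT + cos(th) * YT
    # short-axis unit vector; its sign against the cartilage direction (+y)
    sc <- sign(cos(th))
    if (sc == 0) sc <- 1
    B <- ifelse(V * sc >= 0, b1, b2)
    lumen <- (U / a)^2 + (V / B)^2 <= 1
    img[lumen & block] <- lv[["lumen"]]
  } else {
    # unstented tube: collapsed lumen rendered as a dark cleft
    slit <- abs(XT) <= tl / 2 & abs(YT) <= 0.08
    img[slit & block] <- lv[["background"]]
  }

  for (g in 1:2) {
    ga <- deg2rad(spec$groove_angle_deg[g])
    gc <- ctr + R * c(cos(ga), sin(ga))
    notch <- (X - gc[1])^2 + (Y - gc[2])^2 <= (spec$groove_width_mm[g] / 2)^2
    img[notch] <- lv[["background"]]
  }
  if (with_mask) list(raster = img, lumen = lumen & block) else img
}

#' Render one documented grinding plane
#'
#' Draws the phantom section at plane `plane_index` (1-based; plane 1 at
#' block height z = 0, planes `true_spacing_mm` apart): the epoxy disk with
#' both fiducial grooves, the tissue ellipse with its cartilage band, and
#' either the stent lumen (bright, with the ground-truth diameters,
#' orientation and D1/D2 split at that height, drifted per the axis tilt) or
#' the collapsed tubal cleft outside the stent. No misalignment or noise is
#' applied at this level; see [build_phantom()].
#'
#' @param spec a [phantom_spec()].
#' @param plane_index plane number in `1..n_planes`.
#' @return a [section_image()].
#' @export
render_section <- function(spec, plane_index) {
  stopifnot(inherits(spec, "phantom_spec"))
  if (plane_index < 1 || plane_index > spec$n_planes)
    stop(sprintf("plane_index %d outside 1..%d", plane_index, spec$n_planes))
  z <- (plane_index - 1) * spec$true_spacing_mm
  section_image(render_plane_z(spec, z), spec$pixel_size_mm,
                plane_index = plane_index)
}

#' Ground-truth lumen mask volume
#'
#' Binary volume of the stent lumen rendered on the reference grid
#' (unperturbed, true spacing): the oracle for segmentation overlap tests.
#'
#' @param spec a [phantom_spec()].
#' @return a binary [volume()].
#' @export
phantom_truth_lumen <- function(spec) {
  zs <- seq(0, (spec$n_planes - 1) * spec$true_spacing_mm,
            by = spec$ref_spacing_mm)
  n <- phantom_raster_n(spec)
  arr <- array(FALSE, c(n, n, length(zs)))
  for (k in seq_along(zs))
    arr[, , k] <- render_plane_z(spec, zs[k], with_mask = TRUE)$lumen
  volume(arr, spec$pixel_size_mm, spec$ref_spacing_mm)
}

#' Build a full phantom bundle
#'
#' Renders the documented section stack (each plane perturbed by a seeded
#' rigid misalignment and additive Gaussian noise, with the stack declaring
#' the nominal spacing although geometry was generated at the true spacing)
#' together with the unperturbed reference volume on trusted spacing (the
#' surrogate for the reference scan) and the ground truth: the per-plane
#' applied transforms, the analytic stent profile, and the landmark
#' positions.
#'
#' @param spec a [phantom_spec()].
#' @return an object of class `phantom_bundle` with elements `stack`
#'   ([image_stack()]), `reference` ([volume()]) and `truth` (list with
#'   `transforms`, `profile`, `landmarks`, `spec`).
#' @export
build_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(spec$seed)
  mt <- spec$misalignment$translate_px
  mr <- spec$misalignment$rotate_deg
  n <- spec$n_planes
  rots <- if (mr > 0) stats::runif(n, -mr, mr) else numeric(n)
  txs <- if (mt > 0) stats::runif(n, -mt, mt) else numeric(n)
  tys <- if (mt > 0) stats::runif(n, -mt, mt) else numeric(n)
  transforms <- lapply(seq_len(n), function(k)
    rigid_transform(rots[k], txs[k], tys[k]))

  sections <- vector("list", n)
  for (k in seq_len(n)) {
    img <- render_plane_z(spec, (k - 1) * spec$true_spacing_mm)
    tf <- transforms[[k]]
    if (tf$rotation_deg != 0 || tf$tx_px != 0 || tf$ty_px != 0)
      img <- rigid_apply_image(img, tf, outside = spec$levels[["background"]])
    if (spec$noise_sigma > 0)
      img <- img + matrix(stats::rnorm(length(img), 0, spec$noise_sigma),
                          nrow(img), ncol(img))
    sections[[k]] <- section_image(img, spec$pixel_size_mm, plane_index = k)
  }
  stack <- image_stack(sections, spec$nominal_spacing_mm)

  zs <- seq(0, (n - 1) * spec$true_spacing_mm, by = spec$ref_spacing_mm)
  nn <- phantom_raster_n(spec)
  ref <- array(0, c(nn, nn, length(zs)))
  for (k in seq_along(zs)) ref[, , k] <- render_plane_z(spec, zs[k])
  reference <- volume(ref, spec$pixel_size_mm, spec$ref_spacing_mm)

  ext <- spec$stent_extent_mm
  zprof <- seq(ext[1], ext[2], by = spec$true_spacing_mm)
  truth_profile <- ground_truth_profile(spec, zprof)
  iso_z <- spec$isthmus_z_mm
  landmarks <- list(
    isthmus_xyz_mm = c(phantom_center_at_z(spec, iso_z), iso_z),
    pharynx_xyz_mm = c(phantom_center_at_z(
      spec, iso_z + spec$cartilaginous_length_mm),
      iso_z + spec$cartilaginous_length_mm),
    cartilage_dir_xyz = c(0, 1, 0))
  structure(list(stack = stack, reference = reference,
                 truth = list(transforms = transforms,
                              profile = truth_profile,
                              landmarks = landmarks,
                              spec = spec)),
            class = "phantom_bundle")
}

#' @export
print.phantom_bundle <- function(x, ...) {
  cat("<phantom_bundle>\n  ")
  print(x$stack)
  cat("  ")
  print(x$reference)
  invisible(x)
}

#' Ground-truth stent profile
#'
#' Evaluates the phantom's analytic lumen profile at the requested block-z
#' positions: diameters, D1/D2 split, orientation, and elliptical area
#' (pi/4 dL dS). `s_mm` in the result is measured from the stent's
#' middle-ear end, matching the measured profiles.
#'
#' @param spec a [phantom_spec()].
#' @param positions block-axial positions (mm) within the stent extent.
#' @return data frame with columns `s_mm`, `dL_mm`, `dS_mm`, `D1_mm`,
#'   `D2_mm`, `theta_deg`, `area_ellipse_mm2`.
#' @export
ground_truth_profile <- function(spec, positions) {
  stopifnot(inherits(spec, "phantom_spec"))
  ext <- spec$stent_extent_mm
  if (any(positions < ext[1] - 1e-9 | positions > ext[2] + 1e-9))
    stop("positions outside the stent extent")
  s <- positions - ext[1]
  pr <- spec$stent_profile(s)
  data.frame(s_mm = s,
             dL_mm = pr$dL_mm,
             dS_mm = pr$dS_mm,
             D1_mm = pr$D1_frac * pr$dS_mm,
             D2_mm = (1 - pr$D1_frac) * pr$dS_mm,
             theta_deg = wrap_orientation(pr$theta_deg),
             area_ellipse_mm2 = pi / 4 * pr$dL_mm * pr$dS_mm)
}
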