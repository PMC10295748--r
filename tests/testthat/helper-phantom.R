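# shared fixtures, all generated in code at test time

# desk-scale phantom spec used across tests; individual tests override
# fields as needed
small_spec <- function(...) {
  args <- list(
    block_diameter_mm = 10, pixel_size_mm = 0.05, n_planes = 30,
    stent_extent_mm = c(1, 5),
    stent_profile = stent_profile_linear(4, dL_mm = c(2, 3.5),
                                         dS_mm = c(1.2, 2.5)),
    groove_width_mm = c(1.6, 0.7), tilt_deg = 5, seed = 42)
  args[names(list(...))] <- list(...)
  do.call(phantom_spec, args)
}

# analytic lumen mask: union of two half-ellipses sharing the long axis
# (cartilage-side semi-axis b1, opposite b2), rotated by theta
ellipse_section <- function(a, b1, b2, theta_deg = 0, px = 0.02, half = 4,
                            cartilage_side = c(0, 1)) {
  n <- 2L * round(half / px) + 1L
  g <- (seq_len(n) - (n + 1) / 2) * px
  X <- matrix(g, n, n)
  Y <- matrix(g, n, n, byrow = TRUE)
  th <- theta_deg * pi / 180
  U <- cos(th) * X + sin(th) * Y
  V <- -sin(th) * X + cos(th) * Y
  sc <- sign(cos(th)); if (sc == 0) sc <- 1
  B <- ifelse(V * sc >= 0, b1, b2)
  cross_section((U / a)^2 + (V / B)^2 <= 1, px, 0,
                cartilage_side = cartilage_side)
}

# analytically voxelized cylinder of radius r tilted by alpha about y
# (axis drifts in x with z); circular cross-section perpendicular to its
# own axis, elliptical in the z slices
tilted_cylinder <- function(r = 1.5, alpha_deg = 20, px = 0.05, dz = 0.1,
                            nx = 161, nz = 120) {
  alpha <- alpha_deg * pi / 180
  arr <- array(FALSE, c(nx, nx, nz))
  cx <- nx * px / 2
  g <- (seq_len(nx) - 0.5) * px
  X <- matrix(g, nx, nx)
  Y <- matrix(g, nx, nx, byrow = TRUE)
  for (k in seq_len(nz)) {
    z <- (k - 1) * dz
    xc <- cx + tan(alpha) * (z - (nz - 1) * dz / 2)
    arr[, , k] <- ((X - xc) * cos(alpha))^2 + (Y - cx)^2 <= r^2
  }
  volume(arr, px, dz)
}

# minimal profile object for metric tests (no imaging involved)
fake_profile <- function(s_mm, step_mm = 0.2, area_ellipse = NULL,
                         area_pixel = NULL, D1 = NULL, D2 = NULL) {
  n <- length(s_mm)
  prof <- data.frame(
    s_mm = s_mm,
    dL_mm = rep(3, n), dS_mm = rep(2, n),
    D1_mm = if (is.null(D1)) rep(0.9, n) else D1,
    D2_mm = if (is.null(D2)) rep(1.1, n) else D2,
    theta_deg = rep(0, n),
    area_ellipse_mm2 = if (is.null(area_ellipse)) rep(4.7, n)
      else area_ellipse,
    area_pixel_mm2 = if (is.null(area_pixel)) rep(4.7, n) else area_pixel,
    midpoint_flag = rep(FALSE, n),
    theta_rel_deg = rep(0, n), theta_rel_raw_deg = rep(0, n),
    swap_flag = rep(FALSE, n))
  attr(prof, "step_mm") <- step_mm
  attr(prof, "stent_length_mm") <-
    if (n) max(s_mm) - min(s_mm) + step_mm else NA_real_
  class(prof) <- c("stent_profile", "data.frame")
  prof
}

# one full pipeline run shared by several test files (built lazily once):
# tapered, twisted, cartilage-compressed stent at 0.04 mm/px
.pipeline_cache <- new.env(parent = emptyenv())
pipeline_fixture <- function() {
  if (!is.null(.pipeline_cache$fx)) return(.pipeline_cache$fx)
  spec <- phantom_spec(
    block_diameter_mm = 10, pixel_size_mm = 0.04, n_planes = 40,
    stent_extent_mm = c(1, 7),
    stent_profile = stent_profile_linear(6, dL_mm = c(2, 3.6),
                                         dS_mm = c(1.2, 2.6),
                                         twist_deg_per_mm = 3,
                                         D1_frac = 0.42),
    groove_width_mm = c(1.6, 0.7), tilt_deg = 8, seed = 11)
  bundle <- build_phantom(spec)
  aligned <- align_stack(bundle$stack)
  vol <- build_volume(aligned$stack)
  excess <- estimate_plane_excess(vol, bundle$reference)
  vol <- apply_spacing_correction(vol, as.numeric(excess))
  lumen <- segment_lumen(vol)
  axis <- fit_axis(lumen, orientation_hint = bundle$truth$landmarks)
  sections <- extract_cross_sections(
    lumen, axis, step_mm = 0.25,
    cartilage_dir_xyz = bundle$truth$landmarks$cartilage_dir_xyz)
  profile <- measure_stent(sections)
  # register the measured s grid to the ground truth: the axial origin of
  # the measured profile (first kept section) is a nuisance offset,
  # estimated once on the long-diameter profile
  offs <- seq(0.5, 2.5, by = 0.01)
  fit <- vapply(offs, function(o) {
    gt <- ground_truth_profile(spec, pmin(pmax(profile$s_mm + o, 1), 7))
    mean(abs(profile$dL_mm - gt$dL_mm))
  }, numeric(1))
  off <- offs[which.min(fit)]
  truth <- ground_truth_profile(spec, pmin(pmax(profile$s_mm + off, 1), 7))
  .pipeline_cache$fx <- list(spec = spec, bundle = bundle, aligned = aligned,
                             lumen = lumen, axis = axis, sections = sections,
                             profile = profile, truth = truth,
                             excess = as.numeric(excess))
  .pipeline_cache$fx
}

# smallest circular distance between two orientations in degrees
theta_dist <- function(a, b) abs(((a - b + 90) %% 180) - 90)
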