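#' Stack aligned sections into a volume
#'
#' Assembles an aligned [image_stack()] into a [volume()] at a uniform
#' through-plane spacing, optionally restricted to a window of planes (the
#' region ground at the fine depth increment). The spacing is metadata:
#' rebuilding the same stack at a different spacing changes only the z
#' calibration, never the raster.
#'
#' @param stack an [image_stack()] (normally the output of [align_stack()]).
#' @param spacing_mm through-plane spacing; defaults to the stack's nominal
#'   spacing.
#' @param window optional `c(first, last)` plane positions (1-based indices
#'   into the stack) to include.
#' @return a [volume()].
#' @export
build_volume <- function(stack, spacing_mm = NULL, window = NULL) {
  stopifnot(inherits(stack, "image_stack"))
  if (is.null(spacing_mm)) spacing_mm <- stack$nominal_spacing_mm
  stopifnot(spacing_mm > 0)
  secs <- stack$sections
  if (!is.null(window)) {
    stopifnot(length(window) == 2, window[1] >= 1,
              window[2] <= length(secs), window[1] <= window[2])
    secs <- secs[window[1]:window[2]]
  }
  if (!length(secs)) stop("empty stack")
  d <- dim(secs[[1]]$raster)
  arr <- array(0, c(d[1], d[2], length(secs)))
  for (k in seq_along(secs)) arr[, , k] <- secs[[k]]$raster
  volume(arr, secs[[1]]$pixel_size_mm, spacing_mm)
}

# per-plane lumen area profile (mm^2) of a volume
lumen_area_profile <- function(vol, ...) {
  lum <- if (is.logical(vol$raster)) vol else segment_lumen(vol, ...)
  counts <- apply(lum$raster, 3, sum)
  counts * vol$in_plane_spacing_mm^2
}

#' Estimate the average per-plane grinding-depth excess
#'
#' The grinding process may remove more (or less) material per plane than
#' the declared nominal depth, which stretches (or compresses) the
#' reconstruction along z. Fusing with a reference volume of trusted
#' geometry exposes the error. The estimator segments the stent lumen in
#' both volumes, reduces each to its axial lumen-area profile (open area as
#' a function of z -- a quantity invariant to any in-plane pose, so
#' residual in-plane registration does not bias it), and searches for the
#' single uniform per-plane excess delta that best superimposes the stack's
#' profile, laid out at `nominal + delta` per plane, on the reference
#' profile (sum of squared area differences after aligning the area-weighted
#' centroids; golden-section search to 1 micrometre). Matching the profile
#' rather than the raw endpoint extent gives sub-plane precision: the
#' profile's support is the lumen extent, but its shape constrains the
#' scaling much more tightly than two quantized endpoints.
#'
#' @param stack_volume grayscale or binary [volume()] of the aligned stack,
#'   carrying the nominal spacing.
#' @param reference grayscale or binary [volume()] on trusted spacing.
#' @param nominal_spacing_mm nominal per-plane depth; defaults to the stack
#'   volume's through-plane spacing.
#' @param interval search interval for delta (mm), default spans
#'   `(-0.9, 2) * nominal`.
#' @param ... passed to [segment_lumen()] (e.g. `polarity`, `threshold`).
#' @return the signed excess delta in mm/plane (negative = less removal
#'   than nominal), with the matched profiles attached as attribute
#'   `"profiles"`.
#' @export
estimate_plane_excess <- function(stack_volume, reference,
                                  nominal_spacing_mm = NULL,
                                  interval = NULL, ...) {
  stopifnot(inherits(stack_volume, "volume"), inherits(reference, "volume"))
  if (is.null(nominal_spacing_mm))
    nominal_spacing_mm <- stack_volume$through_plane_spacing_mm
  if (is.null(interval))
    interval <- c(-0.9, 2) * nominal_spacing_mm
  a_stack <- lumen_area_profile(stack_volume, ...)
  a_ref <- lumen_area_profile(reference, ...)
  if (!any(a_stack > 0) || !any(a_ref > 0))
    stop("stent lumen absent in stack or reference volume")
  z_ref <- volume_z(reference)
  keep <- a_ref > 0
  zc_ref <- sum(z_ref[keep] * a_ref[keep]) / sum(a_ref[keep])
  f_ref <- stats::approxfun(z_ref - zc_ref, a_ref, yleft = 0, yright = 0)
  k <- seq_along(a_stack) - 1
  sel <- a_stack > 0
  objective <- function(delta) {
    s <- nominal_spacing_mm + delta
    z <- k * s
    zc <- sum(z[sel] * a_stack[sel]) / sum(a_stack[sel])
    sum((a_stack - f_ref(z - zc))^2)
  }
  opt <- stats::optimize(objective, interval = interval, tol = 1e-6)
  delta <- opt$minimum
  structure(delta,
            profiles = list(stack_area_mm2 = a_stack,
                            reference_area_mm2 = a_ref,
                            reference_z_mm = z_ref,
                            objective = opt$objective))
}

#' Apply a uniform spacing correction
#'
#' Sets the volume's through-plane spacing to `nominal + excess`, the one
#' average value applied to all planes; the raster itself is unchanged.
#'
#' @param vol a [volume()].
#' @param excess_mm signed per-plane excess (mm), e.g. from
#'   [estimate_plane_excess()].
#' @param nominal_spacing_mm nominal spacing; defaults to the volume's
#'   current through-plane spacing.
#' @return the corrected [volume()].
#' @export
apply_spacing_correction <- function(vol, excess_mm,
                                     nominal_spacing_mm = NULL) {
  stopifnot(inherits(vol, "volume"))
  if (is.null(nominal_spacing_mm))
    nominal_spacing_mm <- vol$through_plane_spacing_mm
  corrected <- nominal_spacing_mm + excess_mm
  if (corrected <= 0)
    stop(sprintf("corrected spacing %.4g mm is not positive", corrected))
  vol$through_plane_spacing_mm <- corrected
  vol
}
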