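#' Segment the open stent lumen
#'
#' Automatic contrasting of the lumen: the intensity histogram is quantized
#' into `k` classes by minimizing within-class variance (the k-class
#' generalization of Otsu's threshold, computed as deterministic 1-D
#' k-means; `k = 2` is the classic binary Otsu), and the threshold is placed
#' midway between the two brightest class centres. The binary result is
#' reduced to its largest 6-connected 3-D component, which removes specks
#' and disconnected debris. Polarity is configurable for data in which the
#' lumen is darker than its surroundings, and an explicit threshold
#' overrides the automatic choice.
#'
#' @param vol grayscale [volume()].
#' @param polarity `"bright"` (lumen brighter than surroundings, default)
#'   or `"dark"`.
#' @param threshold optional manual intensity threshold.
#' @param k number of intensity classes for the automatic threshold.
#' @return binary [volume()] of the open lumen.
#' @export
segment_lumen <- function(vol, polarity = c("bright", "dark"),
                          threshold = NULL, k = 5) {
  stopifnot(inherits(vol, "volume"))
  polarity <- match.arg(polarity)
  v <- vol$raster
  if (polarity == "dark") v <- -v
  if (is.null(threshold)) {
    centers <- kmeans_1d(subsample_values(v), k)
    if (length(centers) < 2)
      stop("intensity histogram has a single class; supply `threshold`")
    nc <- length(centers)
    threshold <- mean(centers[c(nc - 1, nc)])
  } else if (polarity == "dark") {
    threshold <- -threshold
  }
  mask <- v > threshold
  if (!any(mask)) stop("empty lumen segmentation")
  vol$raster <- largest_component_3d(mask)
  vol
}

#' Fit the stent main axis
#'
#' Least-squares 3-D line through the per-plane lumen centroids (the first
#' principal direction of the centroid cloud). Centroids rather than the
#' full voxel mask are used so that the strong variation of the lumen
#' calibre along the stent cannot bias the direction. The sign of the
#' direction is chosen so that the axial coordinate s increases from the
#' middle-ear-facing stent end toward the pharynx, using the landmark
#' ordering as hint.
#'
#' @param lumen binary [volume()] from [segment_lumen()].
#' @param orientation_hint either a 3-vector pointing toward the pharynx, or
#'   a landmark list with `isthmus_xyz_mm` and `pharynx_xyz_mm`; default
#'   `c(0, 0, 1)` (grinding order runs toward the pharynx).
#' @return an object of class `stent_axis` with unit `direction`, a `point`
#'   on the axis (mm), and the fitted per-plane centroids.
#' @export
fit_axis <- function(lumen, orientation_hint = c(0, 0, 1)) {
  stopifnot(inherits(lumen, "volume"), is.logical(lumen$raster))
  px <- lumen$in_plane_spacing_mm
  zs <- volume_z(lumen)
  cents <- lapply(seq_along(zs), function(k) {
    sl <- lumen$raster[, , k]
    if (!any(sl)) return(NULL)
    idx <- which(sl, arr.ind = TRUE)
    c((mean(idx[, 1]) - 0.5) * px, (mean(idx[, 2]) - 0.5) * px, zs[k])
  })
  cents <- do.call(rbind, cents)
  if (is.null(cents) || nrow(cents) < 2)
    stop("degenerate lumen: axis fit needs the lumen on at least 2 planes")
  ctr <- colMeans(cents)
  pc <- stats::prcomp(cents, center = TRUE, scale. = FALSE)
  dir <- pc$rotation[, 1]
  dir <- dir / sqrt(sum(dir^2))
  if (is.list(orientation_hint))
    orientation_hint <- orientation_hint$pharynx_xyz_mm -
      orientation_hint$isthmus_xyz_mm
  if (sum(dir * orientation_hint) < 0) dir <- -dir
  structure(list(point = ctr, direction = dir, centroids = cents),
            class = "stent_axis")
}

#' @export
print.stent_axis <- function(x, ...) {
  cat(sprintf(
    "<stent_axis> through (%.2f, %.2f, %.2f) mm, direction (%.3f, %.3f, %.3f)\n",
    x$point[1], x$point[2], x$point[3],
    x$direction[1], x$direction[2], x$direction[3]))
  invisible(x)
}

# signed in-plane distance field (mm) of a binary volume, slice-wise:
# positive inside the lumen, negative outside; slices without lumen get a
# large negative constant.
signed_distance_stack <- function(lumen) {
  px <- lumen$in_plane_spacing_mm
  d <- dim(lumen$raster)
  sd <- array(-10 * max(d[1] * px, 1), d)
  for (k in seq_len(d[3])) {
    sl <- lumen$raster[, , k]
    if (!any(sl)) next
    m <- sl * 1
    sd[, , k] <- (as.matrix(EBImage::distmap(m)) -
                    as.matrix(EBImage::distmap(1 - m))) * px
  }
  sd
}

# orthonormal in-plane basis (u, v) for a plane perpendicular to dir,
# chosen so that for an untilted axis (0,0,1) u = x and v = y
plane_basis <- function(dir) {
  e <- if (abs(dir[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  u <- e - sum(e * dir) * dir
  u <- u / sqrt(sum(u^2))
  v <- c(dir[2] * u[3] - dir[3] * u[2],
         dir[3] * u[1] - dir[1] * u[3],
         dir[1] * u[2] - dir[2] * u[1])
  list(u = u, v = v)
}

#' Extract cross-sections perpendicular to the stent axis
#'
#' Resamples the binary lumen on planes perpendicular to the fitted stent
#' axis at s = 0, step, 2 step, ... (s = 0 at the middle-ear-facing stent
#' end). The lumen surface is interpolated through a slice-wise signed
#' Euclidean distance field (trilinear across planes, thresholded at zero),
#' which avoids the stair-casing a nearest-neighbour lookup would produce
#' on tilted planes. This is the correction for the tilt between block and
#' stent axis: sections of a tilted cylinder taken perpendicular to its
#' axis recover the true diameter, whereas grinding-plane sections inflate
#' it by 1/cos(tilt).
#'
#' @param lumen binary [volume()] from [segment_lumen()].
#' @param axis a [fit_axis()] result.
#' @param step_mm spacing of the sections along the axis (default 0.2,
#'   matching the fine grinding increment).
#' @param cartilage_dir_xyz 3-vector pointing toward the tubal cartilage
#'   (from the landmark file); propagated into each section plane.
#' @param pixel_size_mm in-plane sampling pitch of the sections; defaults
#'   to the volume's in-plane spacing.
#' @return list of [cross_section()]s.
#' @export
extract_cross_sections <- function(lumen, axis, step_mm = 0.2,
                                   cartilage_dir_xyz = c(0, 1, 0),
                                   pixel_size_mm = NULL) {
  stopifnot(inherits(lumen, "volume"), inherits(axis, "stent_axis"),
            step_mm > 0)
  if (is.null(pixel_size_mm)) pixel_size_mm <- lumen$in_plane_spacing_mm
  px <- lumen$in_plane_spacing_mm
  dz <- lumen$through_plane_spacing_mm
  d <- dim(lumen$raster)
  idx <- which(lumen$raster)
  if (!length(idx)) stop("empty lumen volume")
  ai <- arrayInd(idx, d)
  pts <- cbind((ai[, 1] - 0.5) * px, (ai[, 2] - 0.5) * px,
               (ai[, 3] - 1) * dz + lumen$origin[3])
  rel <- sweep(pts, 2, axis$point)
  s_all <- rel %*% axis$direction
  s0 <- min(s_all); s1 <- max(s_all)
  if (s1 - s0 < step_mm)
    stop("lumen axial extent shorter than one section step")
  # in-plane radius of the lumen around the axis, for the sampling window
  rad <- sqrt(rowSums((rel - s_all %*% t(axis$direction))^2))
  half <- max(rad) + 1
  ng <- 2L * as.integer(ceiling(half / pixel_size_mm)) + 1L
  g <- (seq_len(ng) - (ng + 1) / 2) * pixel_size_mm
  GU <- matrix(g, ng, ng)
  GV <- matrix(g, ng, ng, byrow = TRUE)
  basis <- plane_basis(axis$direction)
  cart2 <- c(sum(cartilage_dir_xyz * basis$u), sum(cartilage_dir_xyz * basis$v))
  if (sqrt(sum(cart2^2)) < 1e-9)
    stop("cartilage direction is parallel to the stent axis")
  sdf <- signed_distance_stack(lumen)
  svals <- seq(s0, s1 + step_mm * 1e-6, by = step_mm)
  out <- vector("list", length(svals))
  for (i in seq_along(svals)) {
    cs <- axis$point + svals[i] * axis$direction
    Px <- cs[1] + GU * basis$u[1] + GV * basis$v[1]
    Py <- cs[2] + GU * basis$u[2] + GV * basis$v[2]
    Pz <- cs[3] + GU * basis$u[3] + GV * basis$v[3]
    sd <- trilinear_sample(sdf, Px / px + 0.5, Py / px + 0.5,
                           (Pz - lumen$origin[3]) / dz + 1,
                           outside = -half)
    out[[i]] <- cross_section(matrix(sd > 0, ng, ng), pixel_size_mm,
                              s_mm = svals[i] - s0,
                              cartilage_side = cart2)
  }
  # on a tilted axis the outermost planes cross the lumen's end faces and
  # see truncated slivers: drop empty sections, then trim sections closer
  # to either axial end than their own in-plane radius times sin(tilt),
  # the geometric reach of a perpendicular plane past an end face
  keep <- vapply(out, function(cs) any(cs$mask), logical(1))
  out <- out[keep]
  if (!length(out)) stop("no populated cross-sections along the axis")
  sin_tilt <- sqrt(max(0, 1 - axis$direction[3]^2))
  radius <- vapply(out, function(cs) {
    fg <- which(cs$mask, arr.ind = TRUE)
    ctr <- (ng + 1) / 2
    max(sqrt((fg[, 1] - ctr)^2 + (fg[, 2] - ctr)^2)) * cs$pixel_size_mm
  }, numeric(1))
  s_rel <- vapply(out, function(cs) cs$s_mm, numeric(1))
  s_end <- max(s_rel)
  # the projected s extremes already overshoot the end faces by r sin(tilt)
  # (corner voxels), so the reach past a face is twice that
  margin_ok <- s_rel >= 2 * radius * sin_tilt &
    s_rel <= s_end - 2 * radius * sin_tilt
  if (any(margin_ok)) out <- out[margin_ok]
  s_first <- out[[1]]$s_mm
  lapply(out, function(cs) { cs$s_mm <- cs$s_mm - s_first; cs })
}

#' Cross-sections in the grinding planes
#'
#' Returns the lumen masks slice-by-slice, i.e. sections in the original
#' grinding planes rather than perpendicular to the stent axis, with `s_mm`
#' equal to the block z of each slice (offset to 0 at the first lumen
#' plane). Useful to contrast grinding-plane measurements with
#' axis-perpendicular ones: on a tilted cylinder the former inflate the
#' tilt-direction diameter by 1/cos(tilt).
#'
#' @param lumen binary [volume()].
#' @param cartilage_dir_xyz 3-vector toward the tubal cartilage.
#' @return list of [cross_section()]s.
#' @export
grinding_plane_sections <- function(lumen, cartilage_dir_xyz = c(0, 1, 0)) {
  stopifnot(inherits(lumen, "volume"), is.logical(lumen$raster))
  zs <- volume_z(lumen)
  keep <- which(apply(lumen$raster, 3, any))
  if (!length(keep)) stop("empty lumen volume")
  cart2 <- cartilage_dir_xyz[1:2]
  lapply(keep, function(k)
    cross_section(lumen$raster[, , k], lumen$in_plane_spacing_mm,
                  s_mm = zs[k] - zs[keep[1]], cartilage_side = cart2))
}
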