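#' Section image
#'
#' One documented grinding plane: a 2-D grayscale raster with its pixel size
#' and position (plane index) in the grinding order. Rasters are numeric
#' matrices indexed `[x, y]`; the centre of pixel `(i, j)` sits at
#' `((i - 0.5) * pixel_size, (j - 0.5) * pixel_size)` mm.
#'
#' @param raster numeric matrix (grayscale intensities).
#' @param pixel_size_mm in-plane pixel edge length in mm.
#' @param plane_index 1-based position of this plane in the grinding order.
#' @return an object of class `section_image`.
#' @export
section_image <- function(raster, pixel_size_mm, plane_index = 1L) {
  stopifnot(is.matrix(raster), length(raster) > 0,
            is.numeric(pixel_size_mm), pixel_size_mm > 0)
  structure(list(raster = raster,
                 pixel_size_mm = as.numeric(pixel_size_mm),
                 plane_index = as.integer(plane_index)),
            class = "section_image")
}

#' @export
print.section_image <- function(x, ...) {
  cat(sprintf("<section_image> plane %d, %d x %d px @ %.4g mm/px\n",
              x$plane_index, nrow(x$raster), ncol(x$raster), x$pixel_size_mm))
  invisible(x)
}

#' Image stack
#'
#' An ordered set of section images sharing pixel size and raster shape,
#' with the nominal (declared) through-plane spacing of the grinding
#' process. The actual material removed per plane may differ; see
#' [estimate_plane_excess()].
#'
#' @param sections list of [section_image()] objects with strictly
#'   increasing `plane_index`.
#' @param nominal_spacing_mm declared through-plane spacing in mm.
#' @return an object of class `image_stack`.
#' @export
image_stack <- function(sections, nominal_spacing_mm) {
  stopifnot(is.list(sections), length(sections) > 0,
            nominal_spacing_mm > 0)
  px <- vapply(sections, function(s) s$pixel_size_mm, numeric(1))
  dims <- vapply(sections, function(s) dim(s$raster), integer(2))
  idx <- vapply(sections, function(s) s$plane_index, integer(1))
  if (length(unique(px)) != 1)
    stop("all sections must share one pixel size")
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("all sections must share one raster shape")
  if (any(diff(idx) <= 0))
    stop("plane_index must be strictly increasing")
  structure(list(sections = sections,
                 nominal_spacing_mm = as.numeric(nominal_spacing_mm)),
            class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  s1 <- x$sections[[1]]
  cat(sprintf(
    "<image_stack> %d planes, %d x %d px @ %.4g mm/px, nominal spacing %.4g mm\n",
    length(x$sections), nrow(s1$raster), ncol(s1$raster),
    s1$pixel_size_mm, x$nominal_spacing_mm))
  invisible(x)
}

#' @export
length.image_stack <- function(x) length(x$sections)

#' Volume
#'
#' A 3-D raster with anisotropic spacing: `x` and `y` are in-plane, `z` is
#' through-plane and increases with grinding order. Plane `k` sits at
#' `z = (k - 1) * through_plane_spacing_mm + origin[3]`.
#'
#' @param raster 3-D numeric or logical array `[x, y, z]`.
#' @param in_plane_spacing_mm in-plane voxel edge (mm).
#' @param through_plane_spacing_mm plane-to-plane distance (mm).
#' @param origin 3-vector, mm position of the centre of voxel `(1, 1, 1)`.
#' @return an object of class `volume`.
#' @export
volume <- function(raster, in_plane_spacing_mm, through_plane_spacing_mm,
                   origin = c(0, 0, 0)) {
  stopifnot(is.array(raster), length(dim(raster)) == 3,
            in_plane_spacing_mm > 0, through_plane_spacing_mm > 0,
            length(origin) == 3)
  structure(list(raster = raster,
                 in_plane_spacing_mm = as.numeric(in_plane_spacing_mm),
                 through_plane_spacing_mm = as.numeric(through_plane_spacing_mm),
                 origin = as.numeric(origin)),
            class = "volume")
}

#' @export
print.volume <- function(x, ...) {
  d <- dim(x$raster)
  cat(sprintf(
    "<volume> %d x %d x %d vx @ %.4g mm in-plane, %.4g mm through-plane\n",
    d[1], d[2], d[3], x$in_plane_spacing_mm, x$through_plane_spacing_mm))
  invisible(x)
}

# z coordinate (mm) of each plane of a volume
volume_z <- function(vol) {
  (seq_len(dim(vol$raster)[3]) - 1) * vol$through_plane_spacing_mm +
    vol$origin[3]
}

#' Cross-section of the stent lumen
#'
#' A binary lumen mask in a plane perpendicular to the stent axis, at signed
#' axial position `s_mm` (0 at the middle-ear-facing stent end, increasing
#' toward the pharynx). `cartilage_side` is the in-plane unit vector pointing
#' toward the tubal cartilage, used to assign D1 vs D2.
#'
#' @param mask logical matrix `[x, y]`.
#' @param pixel_size_mm in-plane pixel edge (mm).
#' @param s_mm signed axial position (mm).
#' @param cartilage_side length-2 unit vector in the section plane.
#' @return an object of class `cross_section`.
#' @export
cross_section <- function(mask, pixel_size_mm, s_mm,
                          cartilage_side = c(0, 1)) {
  stopifnot(is.matrix(mask), pixel_size_mm > 0, length(cartilage_side) == 2)
  n <- sqrt(sum(cartilage_side^2))
  if (n < 1e-12) stop("cartilage_side must be a nonzero vector")
  structure(list(mask = mask != 0,
                 pixel_size_mm = as.numeric(pixel_size_mm),
                 s_mm = as.numeric(s_mm),
                 cartilage_side = as.numeric(cartilage_side) / n),
            class = "cross_section")
}

#' @export
print.cross_section <- function(x, ...) {
  cat(sprintf("<cross_section> s = %.2f mm, %d foreground px @ %.4g mm/px\n",
              x$s_mm, sum(x$mask), x$pixel_size_mm))
  invisible(x)
}

# rigid 2-D transforms ---------------------------------------------------

#' Rigid in-plane transform
#'
#' Rotation (counter-clockwise, degrees) about a fixed pivot followed by a
#' translation in pixels: `x' = R(theta) (x - pivot) + pivot + t`. The pivot
#' is supplied when the transform is applied (by convention the image
#' centre), so transforms from images of equal shape compose cleanly.
#'
#' @param rotation_deg rotation angle in degrees.
#' @param tx_px,ty_px translation components in pixels.
#' @return an object of class `rigid_transform2d`.
#' @export
rigid_transform <- function(rotation_deg = 0, tx_px = 0, ty_px = 0) {
  structure(list(rotation_deg = as.numeric(rotation_deg),
                 tx_px = as.numeric(tx_px), ty_px = as.numeric(ty_px)),
            class = "rigid_transform2d")
}

#' @export
print.rigid_transform2d <- function(x, ...) {
  cat(sprintf("<rigid_transform2d> rot %.3f deg, t = (%.3f, %.3f) px\n",
              x$rotation_deg, x$tx_px, x$ty_px))
  invisible(x)
}

rot_matrix <- function(theta_deg) {
  th <- deg2rad(theta_deg)
  matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
}

#' Apply a rigid transform to points
#'
#' @param tf a [rigid_transform()].
#' @param pts n x 2 matrix of (x, y) pixel coordinates.
#' @param pivot length-2 pivot point (pixel coordinates).
#' @return n x 2 matrix of transformed coordinates.
#' @export
rigid_apply_points <- function(tf, pts, pivot) {
  pts <- rbind(pts)
  R <- rot_matrix(tf$rotation_deg)
  sweep(sweep(pts, 2, pivot) %*% t(R), 2,
        pivot + c(tf$tx_px, tf$ty_px), "+")
}

#' Invert a rigid transform
#' @param tf a [rigid_transform()].
#' @return the inverse transform (same pivot convention).
#' @export
rigid_invert <- function(tf) {
  R <- rot_matrix(-tf$rotation_deg)
  t_inv <- -as.vector(R %*% c(tf$tx_px, tf$ty_px))
  rigid_transform(-tf$rotation_deg, t_inv[1], t_inv[2])
}

#' Compose rigid transforms
#'
#' `rigid_compose(b, a)` is the transform "apply `a`, then `b`".
#' @param b,a [rigid_transform()] objects.
#' @return the composed transform.
#' @export
rigid_compose <- function(b, a) {
  Rb <- rot_matrix(b$rotation_deg)
  t_ab <- as.vector(Rb %*% c(a$tx_px, a$ty_px)) + c(b$tx_px, b$ty_px)
  rigid_transform(a$rotation_deg + b$rotation_deg, t_ab[1], t_ab[2])
}

#' Resample an image under a rigid transform
#'
#' Returns the image of `img` under `tf` (pivot at the image centre), using
#' a single bilinear interpolation pass (or nearest-neighbour for label
#' rasters). Pixels mapped from outside the source get `outside`.
#'
#' @param img numeric matrix.
#' @param tf a [rigid_transform()].
#' @param interp `"bilinear"` or `"nearest"`.
#' @param outside fill value for out-of-source pixels.
#' @return transformed matrix of the same shape.
#' @export
rigid_apply_image <- function(img, tf, interp = c("bilinear", "nearest"),
                              outside = 0) {
  interp <- match.arg(interp)
  nx <- nrow(img); ny <- ncol(img)
  pivot <- c((nx + 1) / 2, (ny + 1) / 2)
  grid <- cbind(rep(seq_len(nx), ny), rep(seq_len(ny), each = nx))
  src <- rigid_apply_points(rigid_invert(tf), grid, pivot)
  if (interp == "nearest") {
    xs <- round(src[, 1]); ys <- round(src[, 2])
    ok <- xs >= 1 & xs <= nx & ys >= 1 & ys <= ny
    vals <- rep(as.numeric(outside), nrow(grid))
    vals[ok] <- img[cbind(xs[ok], ys[ok])]
  } else {
    vals <- bilinear_sample(img, src[, 1], src[, 2], outside = outside)
  }
  matrix(vals, nx, ny)
}
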