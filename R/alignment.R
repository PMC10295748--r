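#' Detect the fiducial grooves in a section image
#'
#' The embedding mold casts two non-congruent grooves into the rim of the
#' epoxy cylinder; they are visible in every documented plane and carry the
#' in-plane pose. Detection proceeds by (1) separating the block from the
#' background with a two-class intensity threshold, (2) keeping the largest
#' connected component and filling interior holes, (3) estimating the block
#' centre and radius from that disk, (4) taking the two largest notch
#' components of (analytic disk) minus (observed disk), and (5) reporting
#' each groove as its notch centroid projected radially onto the rim circle
#' (the projection cancels the radial bias that thresholding and resampling
#' introduce). Identity is assigned by notch area: groove "a" is the wide
#' one.
#'
#' @param image a [section_image()].
#' @param min_area_mm2 smallest notch area considered a groove candidate.
#' @return an object of class `fiducial_pair`: `groove_a_xy`, `groove_b_xy`
#'   (pixel coordinates of the wide/narrow groove rim points),
#'   `center_xy`, `radius_px`, `areas_px`.
#' @export
detect_fiducials <- function(image, min_area_mm2 = 0.15) {
  stopifnot(inherits(image, "section_image"))
  img <- image$raster
  # block-vs-background threshold anchored on the border intensity: the
  # embedding block fills the image centre, the border is background
  border <- c(img[c(1:3, nrow(img) - 0:2), ], img[, c(1:3, ncol(img) - 0:2)])
  bg <- stats::median(border)
  thr <- bg + 0.25 * (stats::quantile(img, 0.999, names = FALSE) - bg)
  mask <- img > thr
  if (!any(mask))
    fiducial_error(image$plane_index, 0)
  lab <- EBImage::bwlabel(mask)
  tab <- tabulate(lab[lab > 0])
  mask <- lab == which.max(tab)
  mask <- EBImage::fillHull(mask) > 0
  idx <- which(mask, arr.ind = TRUE)
  ctr <- colMeans(idx)
  dist <- sqrt((idx[, 1] - ctr[1])^2 + (idx[, 2] - ctr[2])^2)
  r_max <- max(dist)
  # notch candidates: inside the block disk (clipped 2 px below the rim to
  # suppress thin resampling crescents) but not in the block
  n <- nrow(img); m <- ncol(img)
  X <- matrix(seq_len(n), n, m)
  Y <- matrix(seq_len(m), n, m, byrow = TRUE)
  rad2 <- (X - ctr[1])^2 + (Y - ctr[2])^2
  notch <- rad2 <= (r_max - 2)^2 & !mask
  lab <- EBImage::bwlabel(notch)
  if (max(lab) == 0) fiducial_error(image$plane_index, 0)
  areas <- tabulate(lab[lab > 0])
  min_px <- min_area_mm2 / image$pixel_size_mm^2
  # a groove must also cut radially into the rim, unlike edge slivers
  min_depth_px <- max(3, 0.2 / image$pixel_size_mm)
  depth_ok <- vapply(seq_along(areas), function(id) {
    if (areas[id] < min_px) return(FALSE)
    pix <- which(lab == id, arr.ind = TRUE)
    dmin <- sqrt(min((pix[, 1] - ctr[1])^2 + (pix[, 2] - ctr[2])^2))
    (r_max - dmin) >= min_depth_px
  }, logical(1))
  cand <- which(depth_ok)
  if (length(cand) < 2)
    fiducial_error(image$plane_index, length(cand))
  cand <- cand[order(areas[cand], decreasing = TRUE)][1:2]
  # refine the circle on the notch-filled disk (unbiased centre and radius)
  filled <- mask | lab == cand[1] | lab == cand[2]
  idx <- which(filled, arr.ind = TRUE)
  ctr <- colMeans(idx)
  r <- sqrt(nrow(idx) / pi)
  rim_point <- function(id) {
    pix <- which(lab == id, arr.ind = TRUE)
    cen <- colMeans(pix)
    v <- cen - ctr
    unname(ctr + r * v / sqrt(sum(v^2)))
  }
  structure(list(groove_a_xy = rim_point(cand[1]),
                 groove_b_xy = rim_point(cand[2]),
                 center_xy = unname(ctr), radius_px = r,
                 areas_px = areas[cand]),
            class = "fiducial_pair")
}

fiducial_error <- function(plane, found) {
  stop(sprintf(
    "fiducial detection failed at plane %d: %d groove candidate(s) found (2 required)",
    plane, found), call. = FALSE)
}

# deterministic intensity subsample for threshold estimation
subsample_values <- function(x, n_max = 100000L) {
  v <- as.vector(x)
  if (length(v) > n_max)
    v <- v[seq(1L, length(v), length.out = n_max)]
  v
}

#' @export
print.fiducial_pair <- function(x, ...) {
  cat(sprintf(
    "<fiducial_pair> a (wide) = (%.2f, %.2f), b = (%.2f, %.2f) px\n",
    x$groove_a_xy[1], x$groove_a_xy[2], x$groove_b_xy[1], x$groove_b_xy[2]))
  invisible(x)
}

# rigid transform taking the fiducial pair of `from` onto that of `to`
# (pivot at the image centre); least-squares over both points
fiducial_transform <- function(from, to, img_dim) {
  ang <- function(p) atan2(p[2], p[1])
  v_from <- from$groove_b_xy - from$groove_a_xy
  v_to <- to$groove_b_xy - to$groove_a_xy
  rot <- rad2deg(ang(v_to) - ang(v_from))
  rot <- wrap_delta180(rot)
  pivot <- (img_dim + 1) / 2
  R <- rot_matrix(rot)
  src <- rbind(from$groove_a_xy, from$groove_b_xy)
  dst <- rbind(to$groove_a_xy, to$groove_b_xy)
  rot_src <- sweep(sweep(src, 2, pivot) %*% t(R), 2, pivot, "+")
  t_ls <- colMeans(dst - rot_src)
  rigid_transform(rot, t_ls[1], t_ls[2])
}

#' Rigidly align an image stack on its fiducial grooves
#'
#' Registers every section into the in-plane frame of a reference plane by
#' matching the detected groove rim points, then resamples each section in
#' a single bilinear pass (nearest-neighbour for label rasters). The model
#' is rotation + translation only: the documentation magnification is fixed,
#' so scale is constant across planes. Because the two grooves are
#' distinguishable (wide vs narrow), the pose is unique and a section
#' flipped by 180 degrees is corrected, not silently accepted.
#'
#' @param stack an [image_stack()].
#' @param reference_plane index (into the stack) of the plane whose frame
#'   all others are mapped into; defaults to the middle plane, which
#'   minimizes the maximum resampling path.
#' @param interp `"bilinear"` or `"nearest"`.
#' @return list with `stack` (the aligned [image_stack()]) and `transforms`
#'   (per-plane [rigid_transform()]s that were applied).
#' @export
align_stack <- function(stack, reference_plane = NULL,
                        interp = c("bilinear", "nearest")) {
  stopifnot(inherits(stack, "image_stack"))
  interp <- match.arg(interp)
  ns <- length(stack$sections)
  if (is.null(reference_plane)) reference_plane <- (ns + 1L) %/% 2L
  if (reference_plane < 1 || reference_plane > ns)
    stop(sprintf("reference_plane %d outside 1..%d", reference_plane, ns))
  fids <- lapply(stack$sections, detect_fiducials)
  ref <- fids[[reference_plane]]
  dims <- dim(stack$sections[[1]]$raster)
  out <- vector("list", ns)
  tfs <- vector("list", ns)
  for (k in seq_len(ns)) {
    tf <- fiducial_transform(fids[[k]], ref, dims)
    img <- stack$sections[[k]]$raster
    bg <- stats::median(img[c(1:3, nrow(img) - 0:2), c(1:3, ncol(img) - 0:2)])
    out[[k]] <- section_image(
      rigid_apply_image(img, tf, interp = interp, outside = bg),
      stack$sections[[k]]$pixel_size_mm,
      stack$sections[[k]]$plane_index)
    tfs[[k]] <- tf
  }
  list(stack = image_stack(out, stack$nominal_spacing_mm), transforms = tfs)
}
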