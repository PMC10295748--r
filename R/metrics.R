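#' Axial landmarks
#'
#' Positions of the isthmus and the pharyngeal ostium on the stent-axis
#' coordinate s (same frame as a measured profile: s = 0 at the
#' middle-ear-facing stent end, increasing toward the pharynx), plus the
#' in-plane cartilage direction. The cartilaginous Eustachian tube runs
#' from the isthmus to the pharyngeal ostium, so `pharynx_s > isthmus_s`.
#'
#' @param isthmus_s_mm axial position of the isthmus (mm).
#' @param pharynx_s_mm axial position of the pharyngeal ostium (mm).
#' @param cartilage_side length-2 unit vector toward the tubal cartilage.
#' @return an object of class `landmarks`.
#' @export
landmarks <- function(isthmus_s_mm, pharynx_s_mm, cartilage_side = c(0, 1)) {
  if (pharynx_s_mm <= isthmus_s_mm)
    stop("pharynx must lie beyond the isthmus (pharynx_s > isthmus_s)")
  structure(list(isthmus_s_mm = as.numeric(isthmus_s_mm),
                 pharynx_s_mm = as.numeric(pharynx_s_mm),
                 cartilage_side = cartilage_side / sqrt(sum(cartilage_side^2))),
            class = "landmarks")
}

#' Project 3-D landmark points onto the stent axis
#'
#' Converts landmark points given in volume coordinates (mm) into the axial
#' s frame of the cross-sections extracted from `lumen` along `axis`
#' (s = 0 at the middle-ear-facing lumen end).
#'
#' @param lm list with `isthmus_xyz_mm`, `pharynx_xyz_mm` and
#'   `cartilage_dir_xyz` (as read by [read_landmarks()]).
#' @param axis a [fit_axis()] result.
#' @param lumen the binary lumen [volume()] the sections were extracted from.
#' @return a [landmarks()] object.
#' @export
project_landmarks <- function(lm, axis, lumen) {
  stopifnot(inherits(axis, "stent_axis"), inherits(lumen, "volume"))
  px <- lumen$in_plane_spacing_mm
  dz <- lumen$through_plane_spacing_mm
  idx <- which(lumen$raster)
  ai <- arrayInd(idx, dim(lumen$raster))
  pts <- cbind((ai[, 1] - 0.5) * px, (ai[, 2] - 0.5) * px,
               (ai[, 3] - 1) * dz + lumen$origin[3])
  s0 <- min(sweep(pts, 2, axis$point) %*% axis$direction)
  proj <- function(p) sum((p - axis$point) * axis$direction) - s0
  basis <- plane_basis(axis$direction)
  cart2 <- c(sum(lm$cartilage_dir_xyz * basis$u),
             sum(lm$cartilage_dir_xyz * basis$v))
  landmarks(proj(lm$isthmus_xyz_mm), proj(lm$pharynx_xyz_mm), cart2)
}

#' Span metrics
#'
#' Stent length and its signed distances to the isthmus and the pharyngeal
#' ostium. Negative distances mean the stent passes through the isthmus or
#' protrudes into the pharyngeal space. In isthmus-referenced coordinates
#' the identity `dist_isthmus + stent_length + dist_pharynx =
#' cartilaginous_length` holds exactly; the constructor enforces it when a
#' cartilaginous length is supplied.
#'
#' @param stent_length_mm measured stent length (mm).
#' @param dist_isthmus_mm signed distance from the isthmus to the stent's
#'   isthmus-side end.
#' @param dist_pharynx_mm signed distance from the stent's pharyngeal end
#'   to the pharyngeal ostium.
#' @param cartilaginous_length_mm optional isthmus-to-ostium length; if
#'   omitted it is derived from the identity.
#' @param tol_mm tolerance on the identity check.
#' @return an object of class `span_metrics`.
#' @export
span_metrics <- function(stent_length_mm, dist_isthmus_mm, dist_pharynx_mm,
                         cartilaginous_length_mm = NULL, tol_mm = 0.05) {
  total <- dist_isthmus_mm + stent_length_mm + dist_pharynx_mm
  if (is.null(cartilaginous_length_mm)) {
    cartilaginous_length_mm <- total
  } else if (abs(total - cartilaginous_length_mm) > tol_mm) {
    stop(sprintf(
      "span identity violated: %.3f + %.3f + %.3f = %.3f != %.3f",
      dist_isthmus_mm, stent_length_mm, dist_pharynx_mm, total,
      cartilaginous_length_mm))
  }
  structure(list(stent_length_mm = stent_length_mm,
                 dist_isthmus_mm = dist_isthmus_mm,
                 dist_pharynx_mm = dist_pharynx_mm,
                 cartilaginous_length_mm = cartilaginous_length_mm),
            class = "span_metrics")
}

#' @export
print.span_metrics <- function(x, ...) {
  cat(sprintf(
    "<span_metrics> stent %.1f mm; to isthmus %.1f mm, to pharynx %.1f mm; cartilaginous ET %.1f mm\n",
    round_report(x$stent_length_mm), round_report(x$dist_isthmus_mm),
    round_report(x$dist_pharynx_mm), round_report(x$cartilaginous_length_mm)))
  invisible(x)
}

#' Position of a measured stent within the tube
#'
#' Computes the signed distances of the stent ends to the isthmus and the
#' pharyngeal ostium from a measured profile and the landmarks, in the
#' shared axial frame. The stent's isthmus-side end is the profile's first
#' section; its pharyngeal end is the first section plus the stent length
#' (`s_last - s_first + step`).
#'
#' @param profile a [measure_stent()] profile.
#' @param lm a [landmarks()] object in the same s frame.
#' @return a [span_metrics()] object.
#' @export
stent_span <- function(profile, lm) {
  stopifnot(inherits(profile, "stent_profile"), inherits(lm, "landmarks"))
  start <- min(profile$s_mm)
  len <- attr(profile, "stent_length_mm")
  if (is.na(len)) len <- max(profile$s_mm) - start
  end <- start + len
  span_metrics(stent_length_mm = len,
               dist_isthmus_mm = start - lm$isthmus_s_mm,
               dist_pharynx_mm = lm$pharynx_s_mm - end)
}

# isthmus-referenced interval covered by a stent
span_interval <- function(span) {
  stopifnot(inherits(span, "span_metrics"))
  c(span$dist_isthmus_mm, span$dist_isthmus_mm + span$stent_length_mm)
}

#' Region covered by all stents
#'
#' Intersection of stent spans in isthmus-referenced coordinates (x = 0 at
#' the isthmus, positive toward the pharynx): the tube region every stent
#' prototype covered, within which prototypes can be compared at identical
#' anatomical positions.
#'
#' @param spans a list of `c(start, end)` intervals or [span_metrics()]
#'   objects, or an n x 2 matrix.
#' @return list with `interval` (`c(start, end)` of the intersection) and
#'   `length_mm` (0 if the intersection is empty).
#' @export
coverage_overlap <- function(spans) {
  if (inherits(spans, "span_metrics")) spans <- list(spans)
  if (is.list(spans))
    spans <- do.call(rbind, lapply(spans, function(s)
      if (inherits(s, "span_metrics")) span_interval(s) else as.numeric(s)))
  spans <- rbind(spans)
  if (!nrow(spans)) stop("at least one span required")
  lo <- max(spans[, 1]); hi <- min(spans[, 2])
  list(interval = c(lo, hi), length_mm = max(0, hi - lo))
}

#' Nominal maximum cross-sectional area
#'
#' Open area of a fully expanded stent of nominal diameter d: `pi (d/2)^2`.
#'
#' @param diameter_mm nominal stent diameter (mm).
#' @return area in mm^2.
#' @export
#' @examples
#' round_report(nominal_area(5))   # 19.6
#' round_report(nominal_area(3))   # 7.1
#' round_report(nominal_area(3.5)) # 9.6
nominal_area <- function(diameter_mm) {
  if (any(diameter_mm <= 0)) stop("diameter must be positive")
  pi * (diameter_mm / 2)^2
}

#' Agreement between elliptical and measured areas
#'
#' Validates the ellipse approximation against the directly measured
#' (pixel-counted) areas over a profile: signed mean deviation
#' (ellipse - measured) plus the smallest and largest absolute deviations.
#'
#' @param profile a [measure_stent()] profile carrying `area_pixel_mm2`.
#' @return list with `mean_dev_mm2`, `min_abs_dev_mm2`, `max_abs_dev_mm2`,
#'   `n`.
#' @export
area_agreement <- function(profile) {
  stopifnot(inherits(profile, "stent_profile"))
  if (is.null(profile$area_pixel_mm2) || all(is.na(profile$area_pixel_mm2)))
    stop("profile carries no pixel-counted areas")
  dev <- profile$area_ellipse_mm2 - profile$area_pixel_mm2
  list(mean_dev_mm2 = mean(dev),
       min_abs_dev_mm2 = min(abs(dev)),
       max_abs_dev_mm2 = max(abs(dev)),
       n = length(dev))
}

#' Profile row at an isthmus-referenced position
#'
#' Looks up the profile row nearest to a given distance from the isthmus
#' (default 6 mm, a position covered by all stents and therefore suited for
#' cross-stent comparison).
#'
#' @param profile a [measure_stent()] profile.
#' @param lm a [landmarks()] object in the same s frame.
#' @param at_mm isthmus-referenced position (mm).
#' @return the nearest profile row, with its isthmus-referenced position in
#'   column `x_isthmus_mm`.
#' @export
profile_at_position <- function(profile, lm, at_mm = 6) {
  stopifnot(inherits(profile, "stent_profile"), inherits(lm, "landmarks"))
  x <- profile$s_mm - lm$isthmus_s_mm
  i <- which.min(abs(x - at_mm))
  out <- as.data.frame(profile)[i, , drop = FALSE]
  out$x_isthmus_mm <- x[i]
  out
}

#' Cohort summary
#'
#' Per-stent averages (elliptical area, D1, D2) and the cohort mean
#' cartilaginous tube length, reported at one decimal place.
#'
#' @param spans list of [span_metrics()].
#' @param profiles list of [measure_stent()] profiles (same order/names).
#' @return list with `per_stent` (data frame) and
#'   `mean_cartilaginous_length_mm`.
#' @export
summarize_cohort <- function(spans, profiles = NULL) {
  if (!length(spans)) stop("empty cohort")
  if (inherits(spans, "span_metrics")) spans <- list(spans)
  cl <- vapply(spans, function(s) s$cartilaginous_length_mm, numeric(1))
  per <- NULL
  if (!is.null(profiles)) {
    if (inherits(profiles, "stent_profile")) profiles <- list(profiles)
    per <- do.call(rbind, lapply(seq_along(profiles), function(i) {
      p <- profiles[[i]]
      data.frame(stent = if (!is.null(names(profiles)))
        names(profiles)[i] else as.character(i),
        mean_area_mm2 = round_report(mean(p$area_ellipse_mm2)),
        mean_D1_mm = round_report(mean(p$D1_mm)),
        mean_D2_mm = round_report(mean(p$D2_mm)),
        stent_length_mm = round_report(attr(p, "stent_length_mm")))
    }))
  }
  list(per_stent = per,
       mean_cartilaginous_length_mm = round_report(mean(cl)))
}
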