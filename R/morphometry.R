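#' Longest diameter of a lumen cross-section
#'
#' The point-set diameter of the mask: the chord between the two boundary
#' points at maximum Euclidean separation, found exactly on the convex hull
#' (the diameter of a point set is attained at hull vertices). The chord is
#' a ruler-style measurement and may cross background in concave lumens.
#' Ties are broken toward the smaller orientation angle.
#'
#' @param section a [cross_section()].
#' @return an object of class `chord`: endpoints `p1_mm`, `p2_mm`,
#'   `length_mm`, and `theta_deg` (orientation in `[0, 180)`).
#' @export
long_diameter <- function(section) {
  stopifnot(inherits(section, "cross_section"))
  px <- section$pixel_size_mm
  idx <- which(section$mask, arr.ind = TRUE)
  if (!nrow(idx)) stop("empty mask: no longest diameter")
  pts <- (idx - 0.5) * px
  hull <- pts[unique(grDevices::chull(pts)), , drop = FALSE]
  if (nrow(hull) == 1) hull <- rbind(hull, hull)
  dmat <- as.matrix(stats::dist(hull))
  dmax <- max(dmat)
  cand <- which(dmat >= dmax - 1e-9, arr.ind = TRUE)
  cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
  if (!nrow(cand)) cand <- matrix(c(1L, 1L), 1)
  thetas <- apply(cand, 1, function(ij) {
    d <- hull[ij[2], ] - hull[ij[1], ]
    wrap_orientation(rad2deg(atan2(d[2], d[1])))
  })
  best <- cand[which.min(thetas), ]
  dir <- hull[best[2], ] - hull[best[1], ]
  # orientation refinement: a single extremal pixel pair leaves the chord
  # angle noisy on blunt-ended lumens, so for clearly elongated masks the
  # direction is taken from the second central moments (exact for
  # elliptical lumens, including unequal D1/D2 halves)
  if (nrow(pts) >= 3 && dmax > 0) {
    ev <- eigen(stats::cov(pts), symmetric = TRUE)
    if (ev$values[2] > 0 && ev$values[1] / ev$values[2] >= 1.05)
      dir <- ev$vectors[, 1]
  }
  dir <- dir / sqrt(sum(dir^2))
  theta <- wrap_orientation(rad2deg(atan2(dir[2], dir[1])))
  if (abs(theta - 180) < 1e-9) { dir <- -dir; theta <- 0 }
  # midpoint: the chord line sits where the across-chord coordinate of the
  # shape apexes. On lumens with unequal halves (D1 != D2) the extreme
  # pixel strips spread asymmetrically across the chord, so neither their
  # mean nor the single maximal pair is unbiased; for an elliptical
  # boundary the apex offset follows in closed form from the strip and
  # whole-mask across-chord extents, with the maximal-pair midpoint as
  # fallback for degenerate strips
  nrm <- c(-dir[2], dir[1])
  uu <- as.vector(pts %*% dir)
  vv <- as.vector(pts %*% nrm)
  v_all <- range(vv)
  apex_v <- function(strip) {
    if (!any(strip)) return(NA_real_)
    vs <- range(vv[strip])
    den <- vs[2] + v_all[1] - v_all[2] - vs[1]
    if (abs(den) < px / 2) return(NA_real_)
    (vs[2] * v_all[1] - v_all[2] * vs[1]) / den
  }
  v0 <- mean(c(apex_v(uu >= max(uu) - px), apex_v(uu <= min(uu) + px)),
             na.rm = TRUE)
  # the estimator is a sub-pixel de-bias; keep it within 1.5 px of the
  # maximal pair's own midpoint so non-elliptical shapes cannot drag it off
  v_pair <- sum(((hull[best[1], ] + hull[best[2], ]) / 2) * nrm)
  if (!is.finite(v0)) v0 <- v_pair
  v0 <- min(max(v0, v_pair - 1.5 * px), v_pair + 1.5 * px)
  mid <- (max(uu) + min(uu)) / 2 * dir + v0 * nrm
  structure(list(p1_mm = mid - dmax / 2 * dir,
                 p2_mm = mid + dmax / 2 * dir,
                 length_mm = dmax,
                 theta_deg = theta),
            class = "chord")
}

#' @export
print.chord <- function(x, ...) {
  cat(sprintf("<chord> %.3f mm at %.2f deg\n", x$length_mm, x$theta_deg))
  invisible(x)
}

#' Short diameter and its cartilage-side split
#'
#' Casts two rays from the midpoint of the longest diameter, perpendicular
#' to it: D1 is the distance to the last foreground pixel along the ray
#' toward the tubal cartilage, D2 along the opposite ray, and the short
#' diameter is their sum, so `D1 + D2 = dS` holds by construction.
#' Sidedness comes from the sign of the ray against the section's
#' `cartilage_side` vector. If the chord midpoint falls outside the mask
#' (strongly concave lumen), the rays are cast from the nearest in-mask
#' point on the long chord and the result is flagged.
#'
#' @param section a [cross_section()].
#' @param long the section's [long_diameter()] chord.
#' @return list with `dS_mm`, `D1_mm`, `D2_mm`, `flagged`.
#' @export
short_diameter <- function(section, long) {
  stopifnot(inherits(section, "cross_section"), inherits(long, "chord"))
  px <- section$pixel_size_mm
  mask <- section$mask
  in_mask <- function(p) {
    i <- round(p[1] / px + 0.5); j <- round(p[2] / px + 0.5)
    i >= 1 && j >= 1 && i <= nrow(mask) && j <= ncol(mask) && mask[i, j]
  }
  mid <- (long$p1_mm + long$p2_mm) / 2
  flagged <- FALSE
  if (!in_mask(mid)) {
    # nearest in-mask point on the long chord
    tt <- seq(0, 1, by = px / (4 * max(long$length_mm, px)))
    cand <- cbind(long$p1_mm[1] + tt * (long$p2_mm[1] - long$p1_mm[1]),
                  long$p1_mm[2] + tt * (long$p2_mm[2] - long$p1_mm[2]))
    inm <- apply(cand, 1, in_mask)
    if (!any(inm)) stop("long chord does not intersect the mask")
    dmid <- sqrt((cand[, 1] - mid[1])^2 + (cand[, 2] - mid[2])^2)
    dmid[!inm] <- Inf
    mid <- cand[which.min(dmid), ]
    flagged <- TRUE
  }
  th <- deg2rad(long$theta_deg)
  nrm <- c(-sin(th), cos(th))
  sc <- sign(sum(nrm * section$cartilage_side))
  if (sc == 0) sc <- 1
  mnum <- mask * 1
  ray_extent <- function(dir) {
    tmax <- max(dim(mask)) * px
    dt <- px / 4
    tt <- seq(0, tmax, by = dt)
    v <- bilinear_sample(mnum, (mid[1] + tt * dir[1]) / px + 0.5,
                         (mid[2] + tt * dir[2]) / px + 0.5, outside = 0)
    fg <- v >= 0.5
    if (!any(fg)) return(0)
    i <- max(which(fg))
    # sub-pixel boundary: interpolate the 0.5 crossing past the last
    # foreground sample
    if (i < length(tt) && v[i] > v[i + 1])
      tt[i] + dt * (v[i] - 0.5) / (v[i] - v[i + 1])
    else tt[i]
  }
  D1 <- ray_extent(sc * nrm)
  D2 <- ray_extent(-sc * nrm)
  list(dS_mm = D1 + D2, D1_mm = D1, D2_mm = D2, flagged = flagged)
}

#' Elliptical area from the two diameters
#'
#' The lumen area in an axis-perpendicular virtual plane cannot be measured
#' by automatic contrasting and is approximated by the ellipse spanned by
#' the longest diameter and the perpendicular short diameter:
#' `pi/4 * dL * dS`.
#'
#' @param dL_mm longest diameter (mm).
#' @param dS_mm perpendicular short diameter (mm), `dS <= dL`.
#' @return area in mm^2 (full precision; round with [round_report()] when
#'   reporting).
#' @export
#' @examples
#' round_report(ellipse_area(3.3, 2.2))  # 5.7
ellipse_area <- function(dL_mm, dS_mm) {
  if (any(dL_mm < 0) || any(dS_mm < 0))
    stop("diameters must be non-negative")
  pi / 4 * dL_mm * dS_mm
}

#' Pixel-counted area of a cross-section
#'
#' The directly measured open area: foreground pixel count times the pixel
#' area. This is the automatic-contrasting measurement available in the
#' grinding planes, against which the ellipse approximation is validated.
#'
#' @param section a [cross_section()].
#' @return area in mm^2.
#' @export
pixel_area <- function(section) {
  stopifnot(inherits(section, "cross_section"))
  sum(section$mask) * section$pixel_size_mm^2
}

#' Rotation profile of the long axis with swap correction
#'
#' Follows the orientation of the longest diameter from section to section.
#' The first section is the origin (`theta_rel = 0`); successive orientation
#' differences are taken modulo 180 degrees and mapped into (-90, 90] (the
#' minimal undirected rotation), then accumulated. Where a step is close to
#' 90 degrees *and* the long and short diameters swap between the two rows
#' (long approximately equal to the previous short and vice versa), the
#' jump is not a physical rotation but an exchange of the two axes of a
#' near-degenerate lumen: the event is flagged and a discrete 90-degree
#' correction is applied in the corrected series, while the uncorrected
#' series is kept alongside.
#'
#' @param chords list of [long_diameter()] chords ordered by s.
#' @param dLdS optional n x 2 matrix of (long, short) diameters per
#'   section, enabling the diameter-swap test; without it only the angle
#'   criterion is used.
#' @param swap_angle_tol_deg a step counts as a candidate swap when its
#'   magnitude is within this tolerance of 90 degrees (default 15).
#' @param swap_diam_rel_tol relative tolerance for "long equals previous
#'   short" in the swap test (default 0.2).
#' @return data frame with `theta_rel_deg` (corrected), `theta_rel_raw_deg`
#'   (uncorrected), `swap_flag`.
#' @export
rotation_profile <- function(chords, dLdS = NULL,
                             swap_angle_tol_deg = 15,
                             swap_diam_rel_tol = 0.2) {
  n <- length(chords)
  if (n < 2) stop("rotation profile needs at least 2 sections")
  theta <- vapply(chords, function(ch) ch$theta_deg, numeric(1))
  d_raw <- wrap_delta90(diff(theta))
  near90 <- abs(abs(d_raw) - 90) <= swap_angle_tol_deg
  if (!is.null(dLdS)) {
    dLdS <- as.matrix(dLdS)
    stopifnot(nrow(dLdS) == n, ncol(dLdS) == 2)
    prev <- dLdS[-n, , drop = FALSE]
    cur <- dLdS[-1, , drop = FALSE]
    swapped <- abs(cur[, 1] - prev[, 2]) <= swap_diam_rel_tol * prev[, 2] &
      abs(cur[, 2] - prev[, 1]) <= swap_diam_rel_tol * prev[, 1]
    event <- near90 & swapped
  } else {
    event <- near90
  }
  d_corr <- d_raw
  d_corr[event] <- d_raw[event] - 90 * sign(d_raw[event])
  data.frame(theta_rel_deg = c(0, cumsum(d_corr)),
             theta_rel_raw_deg = c(0, cumsum(d_raw)),
             swap_flag = c(FALSE, event))
}

#' Measure a full stent profile
#'
#' Runs the per-section measurements over an ordered list of
#' axis-perpendicular cross-sections: longest diameter, perpendicular short
#' diameter with its D1/D2 split toward the cartilage, elliptical and
#' pixel-counted areas, and the rotation profile of the long axis with
#' 90-degree swap correction. All values are kept at full precision;
#' reports round lengths and areas to one decimal place.
#'
#' @param sections list of [cross_section()]s ordered by s, e.g. from
#'   [extract_cross_sections()].
#' @return a data frame of class `stent_profile` with columns `s_mm`,
#'   `dL_mm`, `dS_mm`, `D1_mm`, `D2_mm`, `theta_deg`, `theta_rel_deg`,
#'   `theta_rel_raw_deg`, `swap_flag`, `area_ellipse_mm2`,
#'   `area_pixel_mm2`, `midpoint_flag`; attributes `step_mm` and
#'   `stent_length_mm` (`s_last - s_first + step`).
#' @export
measure_stent <- function(sections) {
  if (!length(sections)) stop("empty section list")
  rows <- vector("list", length(sections))
  chords <- vector("list", length(sections))
  for (i in seq_along(sections)) {
    sec <- sections[[i]]
    ch <- tryCatch(long_diameter(sec),
                   error = function(e)
                     stop(sprintf("section %d (s = %.2f mm): %s",
                                  i, sec$s_mm, conditionMessage(e)),
                          call. = FALSE))
    sh <- short_diameter(sec, ch)
    chords[[i]] <- ch
    rows[[i]] <- data.frame(
      s_mm = sec$s_mm, dL_mm = ch$length_mm, dS_mm = sh$dS_mm,
      D1_mm = sh$D1_mm, D2_mm = sh$D2_mm, theta_deg = ch$theta_deg,
      area_ellipse_mm2 = ellipse_area(ch$length_mm, sh$dS_mm),
      area_pixel_mm2 = pixel_area(sec),
      midpoint_flag = sh$flagged)
  }
  prof <- do.call(rbind, rows)
  if (length(sections) >= 2) {
    rot <- rotation_profile(chords, dLdS = cbind(prof$dL_mm, prof$dS_mm))
    prof$theta_rel_deg <- rot$theta_rel_deg
    prof$theta_rel_raw_deg <- rot$theta_rel_raw_deg
    prof$swap_flag <- rot$swap_flag
  } else {
    prof$theta_rel_deg <- 0
    prof$theta_rel_raw_deg <- 0
    prof$swap_flag <- FALSE
  }
  step <- if (nrow(prof) >= 2) stats::median(diff(prof$s_mm)) else NA_real_
  attr(prof, "step_mm") <- step
  attr(prof, "stent_length_mm") <-
    if (is.na(step)) NA_real_ else max(prof$s_mm) - min(prof$s_mm) + step
  class(prof) <- c("stent_profile", "data.frame")
  prof
}

#' @export
print.stent_profile <- function(x, ...) {
  cat(sprintf(
    "<stent_profile> %d sections, s in [%.1f, %.1f] mm, stent length %.1f mm\n",
    nrow(x), min(x$s_mm), max(x$s_mm), attr(x, "stent_length_mm")))
  df <- as.data.frame(x)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], round_report)
  print(utils::head(df, 10))
  if (nrow(df) > 10) cat(sprintf("... %d more rows\n", nrow(df) - 10))
  invisible(x)
}
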