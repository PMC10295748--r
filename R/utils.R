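#' Round half-up for reports
#'
#' Reported lengths and areas are given with one decimal place, rounding
#' halves away from zero (so 7.75 -> 7.8), unlike [base::round()] which
#' rounds halves to even. Internal computation always keeps full precision;
#' this is applied only when numbers are reported.
#'
#' @param x numeric vector.
#' @param digits number of decimal places (default 1).
#' @return rounded numeric vector.
#' @export
#' @examples
#' round_report(7.75)  # 7.8
round_report <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# angle helpers ---------------------------------------------------------

deg2rad <- function(d) d * pi / 180
rad2deg <- function(r) r * 180 / pi

# map an undirected orientation to [0, 180)
wrap_orientation <- function(theta_deg) {
  out <- theta_deg %% 180
  out[out < 0] <- out[out < 0] + 180
  out
}

# minimal undirected rotation between two orientations, in (-90, 90]
wrap_delta90 <- function(delta_deg) {
  d <- ((delta_deg + 90) %% 180) - 90
  d[d <= -90] <- d[d <= -90] + 180
  d
}

# signed angle in (-180, 180]
wrap_delta180 <- function(delta_deg) {
  d <- ((delta_deg + 180) %% 360) - 180
  d[d <= -180] <- d[d <= -180] + 360
  d
}

# sampling --------------------------------------------------------------

# Bilinear sampling of matrix `img` at fractional 1-based coordinates
# (x, y) (first/second array index). Points outside the raster return
# `outside`. Vectorized over x, y.
bilinear_sample <- function(img, x, y, outside = 0) {
  nx <- nrow(img); ny <- ncol(img)
  x0 <- pmin(floor(x), nx - 1); y0 <- pmin(floor(y), ny - 1)
  fx <- x - x0;   fy <- y - y0
  ok <- x >= 1 & y >= 1 & x <= nx & y <= ny & x0 >= 1 & y0 >= 1
  out <- rep(as.numeric(outside), length(x))
  if (any(ok)) {
    x0k <- x0[ok]; y0k <- y0[ok]; fxk <- fx[ok]; fyk <- fy[ok]
    i00 <- cbind(x0k,     y0k)
    i10 <- cbind(x0k + 1, y0k)
    i01 <- cbind(x0k,     y0k + 1)
    i11 <- cbind(x0k + 1, y0k + 1)
    out[ok] <- img[i00] * (1 - fxk) * (1 - fyk) +
               img[i10] * fxk       * (1 - fyk) +
               img[i01] * (1 - fxk) * fyk +
               img[i11] * fxk       * fyk
  }
  out
}

# Trilinear sampling of 3-D array `vol` at fractional 1-based (x, y, z).
trilinear_sample <- function(vol, x, y, z, outside = 0) {
  d <- dim(vol)
  x0 <- pmin(floor(x), d[1] - 1)
  y0 <- pmin(floor(y), d[2] - 1)
  z0 <- pmin(floor(z), d[3] - 1)
  fx <- x - x0;   fy <- y - y0;   fz <- z - z0
  ok <- x >= 1 & y >= 1 & z >= 1 & x <= d[1] & y <= d[2] & z <= d[3] &
        x0 >= 1 & y0 >= 1 & z0 >= 1
  out <- rep(as.numeric(outside), length(x))
  if (any(ok)) {
    x0k <- x0[ok]; y0k <- y0[ok]; z0k <- z0[ok]
    fxk <- fx[ok]; fyk <- fy[ok]; fzk <- fz[ok]
    v <- 0
    for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
      w <- (if (dx) fxk else 1 - fxk) *
           (if (dy) fyk else 1 - fyk) *
           (if (dz) fzk else 1 - fzk)
      v <- v + w * vol[cbind(x0k + dx, y0k + dy, z0k + dz)]
    }
    out[ok] <- v
  }
  out
}

# thresholding ----------------------------------------------------------

# Multi-level Otsu threshold by 1-D k-means (Lloyd iterations with
# deterministic quantile initialization; Otsu's criterion is the k = 2
# special case of within-class variance minimization). Returns the sorted
# class centers.
kmeans_1d <- function(x, k, max_iter = 60L) {
  ux <- sort(unique(x))
  k <- min(k, length(ux))
  if (k == 1) return(mean(x))
  centers <- stats::quantile(ux, probs = seq(0, 1, length.out = k),
                             names = FALSE, type = 7)
  centers <- sort(unique(centers))
  k <- length(centers)
  for (it in seq_len(max_iter)) {
    cuts <- (centers[-1] + centers[-k]) / 2
    cls <- findInterval(x, cuts) + 1L
    new_centers <- vapply(seq_len(k), function(i) {
      xi <- x[cls == i]
      if (length(xi)) mean(xi) else centers[i]
    }, numeric(1))
    if (max(abs(new_centers - centers)) < 1e-10) { centers <- new_centers; break }
    centers <- sort(new_centers)
  }
  centers
}

# connected components ---------------------------------------------------

# Largest 6-connected component of a 3-D logical array, via igraph.
largest_component_3d <- function(mask) {
  d <- dim(mask)
  idx <- which(mask)
  if (!length(idx)) return(mask)
  node <- integer(prod(d))
  node[idx] <- seq_along(idx)
  edges <- list()
  strides <- c(1L, d[1], d[1] * d[2])
  ai <- arrayInd(idx, d)
  for (axis in 1:3) {
    keep <- ai[, axis] < d[axis]
    nb <- idx[keep] + strides[axis]
    has <- node[nb] > 0L
    if (any(has)) {
      edges[[length(edges) + 1L]] <-
        cbind(node[idx[keep][has]], node[nb[has]])
    }
  }
  g <- igraph::make_empty_graph(n = length(idx), directed = FALSE)
  if (length(edges)) {
    e <- do.call(rbind, edges)
    g <- igraph::add_edges(g, t(e))
  }
  comp <- igraph::components(g)
  big <- which.max(comp$csize)
  out <- array(FALSE, d)
  out[idx[comp$membership == big]] <- TRUE
  out
}
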