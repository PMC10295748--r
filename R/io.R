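#' Write an image stack to a directory
#'
#' Writes numbered TIFF files (`plane_0001.tif`, ...) plus a YAML sidecar
#' (`stack.yaml`) carrying pixel size, nominal spacing and the intensity
#' scale. Rasters are stored as 32-bit float samples scaled by
#' `intensity_scale`, so values round-trip at single precision.
#'
#' @param stack an [image_stack()].
#' @param dir output directory (created if missing).
#' @param intensity_scale divisor applied before writing (default 255,
#'   mapping the 0-255 working scale onto TIFF's 0-1).
#' @return `dir`, invisibly.
#' @export
write_stack <- function(stack, dir, intensity_scale = 255) {
  stopifnot(inherits(stack, "image_stack"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (s in stack$sections) {
    f <- file.path(dir, sprintf("plane_%04d.tif", s$plane_index))
    v <- pmin(pmax(s$raster / intensity_scale, 0), 1)
    tiff::writeTIFF(t(v), f, bits.per.sample = 32)
  }
  sidecar <- list(pixel_size_mm = stack$sections[[1]]$pixel_size_mm,
                  nominal_spacing_mm = stack$nominal_spacing_mm,
                  intensity_scale = intensity_scale,
                  n_planes = length(stack$sections))
  yaml::write_yaml(sidecar, file.path(dir, "stack.yaml"))
  invisible(dir)
}

#' Read an image stack from a directory
#'
#' Reads numbered TIFF or PNG section images plus the YAML sidecar written
#' by [write_stack()] (fields `pixel_size_mm` and `nominal_spacing_mm` are
#' required). Files are ordered by the zero-padded index embedded in their
#' names, so shuffled listings do not change the stack order; inconsistent
#' raster shapes are reported with the offending file name.
#'
#' @param dir directory containing the images and `stack.yaml`.
#' @return an [image_stack()].
#' @export
read_stack <- function(dir) {
  sidecar_path <- file.path(dir, "stack.yaml")
  if (!file.exists(sidecar_path))
    stop(sprintf("missing sidecar %s", sidecar_path))
  sc <- yaml::read_yaml(sidecar_path)
  for (f in c("pixel_size_mm", "nominal_spacing_mm"))
    if (is.null(sc[[f]]))
      stop(sprintf("sidecar %s lacks required field '%s'", sidecar_path, f))
  scale <- if (is.null(sc$intensity_scale)) 1 else sc$intensity_scale
  files <- list.files(dir, pattern = "^plane_[0-9]+\\.(tif|tiff|png)$",
                      full.names = TRUE)
  if (!length(files)) stop(sprintf("no section images found in %s", dir))
  idx <- as.integer(sub("^plane_([0-9]+)\\..*$", "\\1", basename(files)))
  files <- files[order(idx)]
  idx <- sort(idx)
  sections <- vector("list", length(files))
  shape <- NULL
  for (k in seq_along(files)) {
    r <- if (grepl("png$", files[k])) {
      if (!requireNamespace("png", quietly = TRUE))
        stop("reading PNG sections requires the 'png' package")
      png::readPNG(files[k])
    } else {
      tiff::readTIFF(files[k])
    }
    if (length(dim(r)) == 3) r <- r[, , 1]
    r <- t(r) * scale
    if (is.null(shape)) shape <- dim(r)
    if (!identical(dim(r), shape))
      stop(sprintf("raster shape of %s (%d x %d) differs from %d x %d",
                   basename(files[k]), dim(r)[1], dim(r)[2],
                   shape[1], shape[2]))
    sections[[k]] <- section_image(r, sc$pixel_size_mm, plane_index = idx[k])
  }
  image_stack(sections, sc$nominal_spacing_mm)
}

#' Write a volume as NIfTI
#'
#' @param vol a [volume()].
#' @param path output path (`.nii` or `.nii.gz`; plain `.nii` keeps the
#'   deliverable text-friendly).
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path) {
  stopifnot(inherits(vol, "volume"))
  img <- RNifti::asNifti(vol$raster * 1)
  RNifti::pixdim(img) <- c(vol$in_plane_spacing_mm, vol$in_plane_spacing_mm,
                           vol$through_plane_spacing_mm)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a volume from NIfTI
#'
#' @param path NIfTI file with isotropic in-plane spacing in its pixdim.
#' @return a [volume()].
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  pd <- RNifti::pixdim(img)
  if (length(pd) < 3) stop(sprintf("%s lacks 3-D pixdim spacing", path))
  if (abs(pd[1] - pd[2]) > 1e-6)
    stop("anisotropic in-plane spacing is not supported")
  arr <- as.array(img)
  if (length(dim(arr)) != 3) stop(sprintf("%s is not a 3-D volume", path))
  volume(arr, pd[1], pd[3])
}

#' Read / write landmark annotations
#'
#' Landmark files are JSON objects with `isthmus_xyz_mm`, `pharynx_xyz_mm`
#' (3-vectors, volume coordinates in mm) and `cartilage_dir_xyz` (unit
#' 3-vector toward the tubal cartilage).
#'
#' @param path JSON file path.
#' @return for `read_landmarks`, a list with the three fields.
#' @export
read_landmarks <- function(path) {
  lm <- jsonlite::read_json(path, simplifyVector = TRUE)
  need <- c("isthmus_xyz_mm", "pharynx_xyz_mm", "cartilage_dir_xyz")
  for (f in need)
    if (is.null(lm[[f]]) || length(lm[[f]]) != 3)
      stop(sprintf("landmark file %s lacks 3-vector field '%s'", path, f))
  lm[need]
}

#' @rdname read_landmarks
#' @param lm landmark list (see `read_landmarks`).
#' @export
write_landmarks <- function(lm, path) {
  jsonlite::write_json(lm, path, auto_unbox = FALSE, digits = NA)
  invisible(path)
}

#' Write a measured profile as CSV
#'
#' Fixed column order; lengths, areas and angles are written with one
#' decimal place (the reporting precision), flags as 0/1. With
#' `full_precision = TRUE` a companion set of `*_full` columns carries the
#' unrounded values.
#'
#' @param profile a [measure_stent()] profile.
#' @param path output CSV path.
#' @param full_precision also write unrounded companion columns.
#' @return `path`, invisibly.
#' @export
write_profile <- function(profile, path, full_precision = FALSE) {
  stopifnot(inherits(profile, "stent_profile"))
  cols <- c("s_mm", "dL_mm", "dS_mm", "D1_mm", "D2_mm", "theta_rel_deg",
            "area_ellipse_mm2", "area_pixel_mm2", "swap_flag")
  df <- as.data.frame(profile)
  out <- data.frame(row.names = seq_len(nrow(df)))
  for (cn in cols) {
    v <- df[[cn]]
    out[[cn]] <- if (is.logical(v)) as.integer(v)
      else formatC(round_report(v), format = "f", digits = 1)
  }
  if (full_precision)
    for (cn in setdiff(cols, "swap_flag"))
      out[[paste0(cn, "_full")]] <- df[[cn]]
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a profile CSV written by [write_profile()]
#'
#' @param path CSV path.
#' @return a `stent_profile` data frame (at the stored precision).
#' @export
read_profile <- function(path) {
  df <- utils::read.csv(path)
  df$swap_flag <- df$swap_flag != 0
  step <- if (nrow(df) >= 2) stats::median(diff(df$s_mm)) else NA_real_
  attr(df, "step_mm") <- step
  attr(df, "stent_length_mm") <-
    if (is.na(step)) NA_real_ else max(df$s_mm) - min(df$s_mm) + step
  class(df) <- c("stent_profile", "data.frame")
  df
}

#' Write per-plane alignment transforms as CSV
#'
#' @param transforms list of [rigid_transform()] (e.g. from
#'   [align_stack()]).
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_transforms <- function(transforms, path) {
  df <- do.call(rbind, lapply(seq_along(transforms), function(k)
    data.frame(plane = k,
               rot_deg = transforms[[k]]$rotation_deg,
               tx_px = transforms[[k]]$tx_px,
               ty_px = transforms[[k]]$ty_px)))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Reported measurements of the six stent prototypes
#'
#' Position and calibre measurements reported for six stent prototypes
#' (nitinol, cobalt-chromium and polymeric designs) implanted ex vivo in
#' the cartilaginous Eustachian tube of human body donors, shipped as
#' plain CSVs. Three tables are returned: `positions` (measured stent
#' length, signed distances to pharynx and isthmus, cartilaginous tube
#' length; negative distances mean the stent passes through the isthmus or
#' protrudes into the pharynx), `ends` (areas and diameters at the
#' pharyngeal and isthmus ends plus average D1/D2), and `at6mm` (area and
#' diameters at the 6 mm comparison position every stent covers).
#'
#' @return list of data frames `positions`, `ends`, `at6mm`.
#' @export
stent_reference_tables <- function() {
  rd <- function(f) utils::read.csv(
    system.file("extdata", f, package = "stentmorph"), check.names = FALSE)
  list(positions = rd("stent_positions.csv"),
       ends = rd("stent_end_measurements.csv"),
       at6mm = rd("stent_at_6mm.csv"))
}
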