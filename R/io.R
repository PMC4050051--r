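#' Write an OCT volume to disk
#'
#' Volumes are written either as NIfTI-1 (`.nii`, float64, lossless) or as a
#' multi-page TIFF (`.tif`/`.tiff`, one page per B-scan, 32-bit float,
#' range-normalized to `[0, 1]`). A flat YAML sidecar `<path>.geom.yaml`
#' records the scan geometry (and, for TIFF, the intensity range used for
#' normalization), so a volume re-reads without external information.
#'
#' @param vol An [oct_volume()].
#' @param path Output path; the extension selects the format.
#' @return `path`, invisibly.
#' @seealso [read_volume()]
#' @export
write_volume <- function(vol, path) {
  stopifnot(inherits(vol, "oct_volume"))
  dir <- dirname(path)
  if (!dir.exists(dir)) stop(sprintf("directory does not exist: %s", dir))
  ext <- tolower(tools::file_ext(path))
  g <- vol$geometry
  side <- list(n_depth = g$n_depth, n_fast = g$n_fast, n_slow = g$n_slow,
               field_deg_x = g$field_deg_x, field_deg_y = g$field_deg_y,
               axial_sampling_um = g$axial_sampling_um,
               refractive_index = g$refractive_index,
               mm_per_degree = g$mm_per_degree, laterality = g$laterality)
  if (ext %in% c("tif", "tiff")) {
    rng <- range(vol$intensity)
    scale <- if (diff(rng) > 0) diff(rng) else 1
    pages <- lapply(seq_len(g$n_slow), function(j)
      (vol$intensity[, , j] - rng[1]) / scale)
    tiff::writeTIFF(pages, path, bits.per.sample = 32L)
    side$intensity_min <- rng[1]
    side$intensity_max <- rng[2]
  } else if (ext == "nii" || grepl("\\.nii\\.gz$", path)) {
    RNifti::writeNifti(RNifti::asNifti(vol$intensity, datatype = "double"), path)
  } else {
    stop(sprintf("unknown volume format '%s' (use .tif/.tiff or .nii)", ext))
  }
  yaml::write_yaml(side, paste0(path, ".geom.yaml"))
  cl_log("wrote volume %s (%d x %d x %d)", path, g$n_depth, g$n_fast, g$n_slow)
  invisible(path)
}

#' Read an OCT volume from disk
#'
#' Reads a multi-page TIFF or a NIfTI-1 file written by [write_volume()] (or
#' produced externally) into the package's `[z, x, y]` axis order. The stored
#' shape must match the supplied geometry; when `geometry` is `NULL` it is
#' taken from the `<path>.geom.yaml` sidecar.
#'
#' @param path File path (`.tif`/`.tiff` or `.nii`).
#' @param geometry A [scan_geometry()], or `NULL` to read the sidecar.
#' @return An [oct_volume()].
#' @export
read_volume <- function(path, geometry = NULL) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  side_path <- paste0(path, ".geom.yaml")
  side <- if (file.exists(side_path)) yaml::read_yaml(side_path) else NULL
  if (is.null(geometry)) {
    if (is.null(side))
      stop(sprintf("no geometry given and no sidecar found at %s", side_path))
    geometry <- scan_geometry(side$n_depth, side$n_fast, side$n_slow,
                              side$field_deg_x, side$field_deg_y,
                              side$axial_sampling_um, side$refractive_index,
                              side$mm_per_degree, side$laterality)
  }
  ext <- tolower(tools::file_ext(path))
  want <- c(geometry$n_depth, geometry$n_fast, geometry$n_slow)
  if (ext %in% c("tif", "tiff")) {
    pages <- tiff::readTIFF(path, all = TRUE)
    if (!is.list(pages)) pages <- list(pages)
    got <- c(nrow(pages[[1]]), ncol(pages[[1]]), length(pages))
    if (any(got != want))
      stop(sprintf("volume shape (%s) does not match geometry (%s)",
                   paste(got, collapse = "x"), paste(want, collapse = "x")))
    arr <- array(0, dim = want)
    for (j in seq_along(pages)) arr[, , j] <- pages[[j]]
    if (!is.null(side) && !is.null(side$intensity_min)) {
      scale <- side$intensity_max - side$intensity_min
      if (scale <= 0) scale <- 1
      arr <- arr * scale + side$intensity_min
    }
  } else if (ext == "nii" || grepl("\\.nii\\.gz$", path)) {
    img <- RNifti::readNifti(path)
    arr <- array(as.numeric(img), dim = dim(img))
    if (length(dim(arr)) != 3L || any(dim(arr) != want))
      stop(sprintf("volume shape (%s) does not match geometry (%s)",
                   paste(dim(arr), collapse = "x"),
                   paste(want, collapse = "x")))
  } else {
    stop(sprintf("unknown volume format '%s'", ext))
  }
  if (!is.numeric(arr)) stop("non-numeric voxel data")
  oct_volume(arr, geometry)
}

#' Write a thickness map to CSV or PNG
#'
#' CSV holds the full-precision values (RFC-4180, '.' decimal separator) with
#' undefined cells left empty. PNG renders the map through a viridis-like
#' color ramp; the value range of the rendering is recorded in a
#' `<path>.range.txt` text note so the image remains interpretable.
#'
#' @param map A [thickness_map()].
#' @param path Output path.
#' @param format `"csv"` or `"png"`.
#' @return `path`, invisibly.
#' @export
write_map <- function(map, path, format = c("csv", "png")) {
  stopifnot(inherits(map, "thickness_map"))
  format <- match.arg(format)
  if (format == "csv") {
    utils::write.table(map$values, path, sep = ",", row.names = FALSE,
                       col.names = FALSE, na = "")
  } else {
    v <- map$values
    rng <- range(v, na.rm = TRUE)
    if (!all(is.finite(rng))) rng <- c(0, 1)
    denom <- if (diff(rng) > 0) diff(rng) else 1
    u <- (v - rng[1]) / denom
    ramp <- grDevices::colorRamp(c("#440154", "#31688E", "#35B779", "#FDE725"))
    rgbv <- matrix(0, length(u), 3)
    ok <- is.finite(u)
    if (any(ok)) rgbv[ok, ] <- ramp(u[ok]) / 255
    img <- array(0, dim = c(ncol(v), nrow(v), 4))  # PNG rows = y
    for (ch in 1:3) img[, , ch] <- t(matrix(rgbv[, ch], nrow(v), ncol(v)))
    img[, , 4] <- t(matrix(as.numeric(ok), nrow(v), ncol(v)))
    png::writePNG(img, path)
    cat(sprintf("value range: [%g, %g] %s\n", rng[1], rng[2], map$unit),
        file = paste0(path, ".range.txt"))
  }
  invisible(path)
}

#' Read a CSV thickness map written by [write_map()]
#'
#' @param path CSV path.
#' @param mm_per_cell_x,mm_per_cell_y Physical cell size, mm.
#' @return A [thickness_map()].
#' @export
read_map <- function(path, mm_per_cell_x = 1, mm_per_cell_y = 1) {
  v <- as.matrix(utils::read.table(path, sep = ",", header = FALSE,
                                   na.strings = ""))
  dimnames(v) <- NULL
  thickness_map(v, mm_per_cell_x, mm_per_cell_y)
}

## ---- run configuration ----------------------------------------------------

## registry of configuration keys: default value and admissible range.
## Anything not listed here is rejected by load_config().
config_registry <- function() {
  num <- function(default, min, max) list(default = default, min = min, max = max)
  list(
    ## scan geometry
    n_depth = num(512L, 8, 4096), n_fast = num(512L, 8, 4096),
    n_slow = num(512L, 8, 4096),
    field_deg_x = num(36, 0.5, 90), field_deg_y = num(36, 0.5, 90),
    axial_sampling_um = num(3.5, 0.1, 100),
    refractive_index = num(1.4, 1, 2),
    mm_per_degree = num(0.289, 0.05, 1),
    laterality = list(default = "right", choices = c("right", "left")),
    ## surface detection
    lambda_smooth = num(2, 0, Inf),
    surface_smooth_xy = num(7L, 0, 64),
    ## vessel segmentation
    denoise_radius = num(1L, 0, 8),
    candidate_percentile = num(35, 1e-6, 100 - 1e-6),
    cone_theta_deg = num(30, 1e-3, 90 - 1e-3),
    cone_length = num(12L, 1, 128),
    gradient_percentile = num(60, 0, 100),
    core_quantile = num(60, 1e-6, 100 - 1e-6),
    dilate_max_iter = num(1000L, 0, 1e6),
    caliber_percentile = num(60, 1e-6, 100 - 1e-6),
    caliber_iter = num(2L, 0, 64),
    min_component_size = num(2L, 1, 1e6),
    ## sublayer profiling
    tile_deg = num(1, 1e-3, 90),
    smooth_w = num(5L, 1, 99),
    noise_floor = num(1.05, 0, 10),
    valley_prominence = num(0.25, 0, 10),
    ## ETDRS grid
    etdrs_center_diameter_mm = num(1.5, 0.1, 10),
    etdrs_inner_diameter_mm = num(3, 0.1, 20),
    etdrs_outer_diameter_mm = num(6, 0.1, 30),
    ## phantom anatomy and noise
    phantom_rbc_depth = num(60, 8, 2048),
    phantom_choroid_thickness_um = num(270, 50, 2000),
    phantom_surface_amplitude = num(6, 0, 64),
    phantom_haller_thickness_um = num(140, 10, 1000),
    phantom_sattler_thickness_um = num(90, 0, 1000),
    phantom_sattler_radius_um_min = num(12, 1, 500),
    phantom_sattler_radius_um_max = num(30, 1, 500),
    phantom_haller_radius_um_min = num(40, 1, 500),
    phantom_haller_radius_um_max = num(100, 1, 500),
    phantom_n_sattler = num(34L, 0, 1e4),
    phantom_n_haller = num(14L, 0, 1e4),
    phantom_border_jitter = num(0.5, 0, 32),
    phantom_tau = num(250, -1, 1e6),          # -1 (or Inf) disables attenuation
    phantom_speckle_shape = num(25, -1, 1e9), # -1 (or Inf) disables speckle
    phantom_background_level = num(0.2, 0, 10),
    phantom_stroma_level = num(1.0, 0, 10),
    phantom_vessel_level = num(0.25, 0, 10)
  )
}

#' Default run configuration
#'
#' @return Named list of every configuration key at its documented default.
#' @export
default_config <- function() {
  lapply(config_registry(), function(e) e$default)
}

#' Load a run configuration file
#'
#' Reads a flat YAML file of `key: value` pairs, fills in the documented
#' defaults for absent keys, rejects unknown keys and out-of-range values,
#' and logs the effective configuration.
#'
#' @param path Path to the configuration file, or `NULL` for pure defaults.
#' @return Named list with all configuration keys.
#' @export
load_config <- function(path = NULL) {
  reg <- config_registry()
  cfg <- default_config()
  if (!is.null(path)) {
    if (!file.exists(path)) stop(sprintf("config file not found: %s", path))
    user <- yaml::read_yaml(path)
    if (is.null(user)) user <- list()
    if (!is.list(user)) stop("config must be a flat mapping of key: value pairs")
    unknown <- setdiff(names(user), names(reg))
    if (length(unknown))
      stop(sprintf("unknown config key(s): %s", paste(unknown, collapse = ", ")))
    for (k in names(user)) cfg[[k]] <- user[[k]]
  }
  for (k in names(cfg)) {
    e <- reg[[k]]
    v <- cfg[[k]]
    if (!is.null(e$choices)) {
      if (!is.character(v) || !(v %in% e$choices))
        stop(sprintf("config key '%s' must be one of: %s", k,
                     paste(e$choices, collapse = ", ")))
    } else {
      if (!is.numeric(v) || length(v) != 1L || is.na(v))
        stop(sprintf("config key '%s' must be a single number", k))
      if (v < e$min || v > e$max)
        stop(sprintf("config key '%s' = %g out of range [%g, %g]",
                     k, v, e$min, e$max))
      if (is.integer(e$default)) cfg[[k]] <- as.integer(round(v))
    }
  }
  cl_log("effective configuration: %s",
         paste(sprintf("%s=%s", names(cfg), unlist(cfg)), collapse = " "))
  cfg
}

#' Build a [scan_geometry()] from a configuration list
#'
#' @param cfg Configuration list from [load_config()] / [default_config()].
#' @return A [scan_geometry()].
#' @export
config_geometry <- function(cfg) {
  scan_geometry(cfg$n_depth, cfg$n_fast, cfg$n_slow, cfg$field_deg_x,
                cfg$field_deg_y, cfg$axial_sampling_um, cfg$refractive_index,
                cfg$mm_per_degree, cfg$laterality)
}
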