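## End-to-end orchestration: volume -> boundaries -> vessel mask -> sublayer
## maps -> grid summaries, plus the synthetic repeatability experiment.

#' Analyze one OCT volume
#'
#' Runs the full measurement chain on a volume: median denoising, RBC and
#' CSI detection, choroid region and total thickness, vessel segmentation,
#' sublayer border detection, tile-resolution and upsampled thickness maps,
#' and grid summaries (CSM and total field). The grid's outer diameter is
#' capped to the mapped field when a 6 mm disc does not fit (narrow-field
#' scans), which is logged.
#'
#' @param vol An [oct_volume()].
#' @param cfg Configuration list (see [default_config()]).
#' @param region Optional precomputed `choroid_region` (skips surface
#'   detection; used for oracle-driven validation).
#' @return List: `region`, `vessel_mask`, `borders`, `maps` (tile
#'   resolution), `maps_fine` (A-scan resolution), `total_map`, `grid`,
#'   `summaries` (per layer `etdrs_summary`).
#' @export
analyze_volume <- function(vol, cfg = default_config(), region = NULL) {
  g <- vol$geometry
  tiling <- tile_volume(g, cfg$tile_deg)
  dvol <- denoise(vol, cfg$denoise_radius)
  if (is.null(region)) {
    rbc <- detect_surface(dvol, "rbc", cfg$lambda_smooth, cfg$surface_smooth_xy)
    csi <- detect_surface(dvol, "csi", cfg$lambda_smooth, cfg$surface_smooth_xy)
    region <- choroid_region(rbc, csi)
  }
  cfg_seg <- cfg
  cfg_seg$denoise_radius <- 0L  # already denoised
  vm <- segment_vessels(dvol, region, cfg_seg, tiling)
  borders <- sublayer_borders(vm, region, tiling, cfg$smooth_w,
                              cfg$noise_floor, cfg$valley_prominence)
  maps <- borders_to_thickness(borders, g)
  total_map <- choroid_thickness_map(region, g)
  maps_fine <- lapply(maps, upsample_map, nx = g$n_fast, ny = g$n_slow)
  tmm <- transverse_mm_per_voxel(g)
  field_mm <- min(g$n_fast * tmm["x"], g$n_slow * tmm["y"])
  outer_mm <- cfg$etdrs_outer_diameter_mm
  if (outer_mm > field_mm) {
    outer_mm <- field_mm * 0.999
    cl_log("analyze_volume: outer grid disc capped to %.2f mm (field %.2f mm)",
           outer_mm, field_mm)
  }
  inner_mm <- min(cfg$etdrs_inner_diameter_mm,
                  (cfg$etdrs_center_diameter_mm + outer_mm) / 2)
  grid <- etdrs_grid_for_map(maps_fine$haller, laterality = g$laterality,
                             diameters_mm = c(cfg$etdrs_center_diameter_mm,
                                              inner_mm, outer_mm))
  summaries <- list(sattler = subfield_means(maps_fine$sattler, grid),
                    haller = subfield_means(maps_fine$haller, grid),
                    choroid = subfield_means(total_map, grid))
  list(region = region, vessel_mask = vm, borders = borders, maps = maps,
       maps_fine = maps_fine, total_map = total_map, grid = grid,
       summaries = summaries, tiling = tiling)
}

## summary value accessor: mean of a named field row
summary_value <- function(summary, field) {
  summary$mean[summary$field == field]
}

#' Run the full synthetic workflow and write its artifacts
#'
#' Generates a phantom from the configuration, analyzes it, and writes the
#' volume, surfaces, component table, border table, thickness maps
#' (CSV + PNG), grid summaries, truth tables and a run manifest into
#' `out_dir`. Identical configuration and seed give identical CSV outputs.
#'
#' @param cfg Configuration list (see [phantom_config()]).
#' @param seed Integer seed.
#' @param out_dir Output directory (created if missing).
#' @return `out_dir`, invisibly; artifacts on disk.
#' @export
run_all <- function(cfg = phantom_config(), seed = 1L, out_dir = tempfile("run")) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cl_log_file(file.path(out_dir, "run.log"))
  on.exit(.cl_env$log_file <- NULL)
  cl_log("run_all: seed %d", seed)
  ph <- generate_phantom(cfg, seed = seed)
  g <- ph$volume$geometry
  write_volume(ph$volume, file.path(out_dir, "volume.nii"))
  res <- analyze_volume(ph$volume, cfg)
  ## detected surfaces and region
  utils::write.table(res$region$rbc, file.path(out_dir, "surface_rbc.csv"),
                     sep = ",", row.names = FALSE, col.names = FALSE)
  utils::write.table(res$region$csi, file.path(out_dir, "surface_csi.csv"),
                     sep = ",", row.names = FALSE, col.names = FALSE)
  write.csv(res$vessel_mask$components,
            file.path(out_dir, "components.csv"), row.names = FALSE)
  ## borders and maps
  utils::write.table(res$borders$haller_sattler,
                     file.path(out_dir, "border_haller_sattler.csv"),
                     sep = ",", row.names = FALSE, col.names = FALSE, na = "")
  write_map(res$maps$sattler, file.path(out_dir, "sattler_tiles.csv"))
  write_map(res$maps$haller, file.path(out_dir, "haller_tiles.csv"))
  write_map(res$maps_fine$sattler, file.path(out_dir, "sattler.png"), "png")
  write_map(res$maps_fine$haller, file.path(out_dir, "haller.png"), "png")
  write_map(res$total_map, file.path(out_dir, "choroid_total.csv"))
  for (layer in names(res$summaries))
    write.csv(res$summaries[[layer]],
              file.path(out_dir, sprintf("summary_%s.csv", layer)),
              row.names = FALSE)
  ## ground truth
  tiling <- res$tiling
  truth <- true_tile_summary(ph$truth, tiling)
  write_map(truth$sattler, file.path(out_dir, "truth_sattler_tiles.csv"))
  write_map(truth$haller, file.path(out_dir, "truth_haller_tiles.csv"))
  ## manifest
  files <- list.files(out_dir, pattern = "\\.csv$", full.names = TRUE)
  manifest <- c(sprintf("seed: %d", seed),
                sprintf("timestamp: %s", format(Sys.time())),
                sprintf("r_version: %s", R.version.string),
                "config:",
                sprintf("  %s: %s", names(cfg), unlist(cfg)),
                "hashes:",
                sprintf("  %s: %s", basename(files), tools::md5sum(files)))
  writeLines(manifest, file.path(out_dir, "manifest.yaml"))
  cl_log("run_all: complete, %d files", length(list.files(out_dir)))
  invisible(out_dir)
}

#' Synthetic repeatability experiment
#'
#' Generates `n_eyes` phantom eyes with per-eye anatomy drawn around the
#' healthy population values (Haller's and Sattler's CSM thickness varying
#' across eyes), re-renders each eye once per session with fresh speckle and
#' a small axial positioning jitter (fixed anatomy), analyzes every
#' rendering with the full pipeline, and feeds the CSM and total-field
#' thickness values into [build_report()].
#'
#' @param cfg Base configuration (see [phantom_config()]).
#' @param n_eyes Number of synthetic eyes (>= 2).
#' @param n_sessions Number of imaging sessions per eye (>= 2).
#' @param seed Integer master seed; all per-eye and per-session seeds derive
#'   from it.
#' @param max_jitter Session-to-session axial positioning jitter bound,
#'   voxels.
#' @param session_seeds Optional fixed per-session noise seeds (identical
#'   seeds with `max_jitter = 0` make sessions byte-identical, giving
#'   perfect agreement).
#' @return List: `report` (a `repeatability_report`), `measurements`
#'   (long-format data frame), `anatomy` (per-eye true parameters).
#' @export
run_repeatability_experiment <- function(cfg = phantom_config(), n_eyes = 10L,
                                         n_sessions = 3L, seed = 1L,
                                         max_jitter = 2,
                                         session_seeds = NULL) {
  stopifnot(n_eyes >= 2, n_sessions >= 2)
  if (!is.null(session_seeds)) stopifnot(length(session_seeds) == n_sessions)
  rows <- list()
  anatomy <- list()
  for (e in seq_len(n_eyes)) {
    eye_seed <- (seed * 1000L + e) %% 2147483647L
    cfg_e <- cfg
    an <- with_seed(eye_seed, {
      list(haller_um = min(max(rnorm(1, 140, 40), 70), 230),
           sattler_um = min(max(rnorm(1, 90, 25), 45), 150))
    })
    cfg_e$phantom_haller_thickness_um <- an$haller_um
    cfg_e$phantom_sattler_thickness_um <- an$sattler_um
    cfg_e$phantom_choroid_thickness_um <-
      an$haller_um + an$sattler_um + 40
    anatomy[[e]] <- an
    for (s in seq_len(n_sessions)) {
      sess_seed <- if (is.null(session_seeds))
        (eye_seed * 13L + s) %% 2147483647L else session_seeds[s]
      offset <- with_seed(sess_seed, runif(1, -max_jitter, max_jitter))
      ph <- generate_phantom(cfg_e, seed = eye_seed, depth_offset = offset,
                             noise_seed = sess_seed)
      res <- analyze_volume(ph$volume, cfg_e)
      for (layer in c("sattler", "haller"))
        for (field in c("csm", "total")) {
          rows[[length(rows) + 1L]] <- data.frame(
            subject = sprintf("eye%02d", e), session = sprintf("R%d", s),
            layer = layer, field = field,
            value = summary_value(res$summaries[[layer]], field))
        }
      cl_log("repeatability: eye %d session %d done", e, s)
    }
  }
  measurements <- do.call(rbind, rows)
  report <- build_report(measurements)
  list(report = report, measurements = measurements,
       anatomy = do.call(rbind, lapply(anatomy, as.data.frame)))
}
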