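#' Run configuration
#'
#' A complete experiment description, loadable from YAML. Unknown keys are
#' rejected and cross-field constraints (pupil fits the grid, segment count
#' compatible with the pupil tiling) are validated before any computation.
#'
#' @name run-config
NULL

config_defaults <- function() {
  list(
    optics = list(wavelength_um = 0.589, na = 0.1, grid_n = 256L,
                  pupil_diameter_px = 128, pupil_scale = 1),
    layout_n = 32L,
    medium = list(form = "phase_screen", tau = Inf, strength = 2 * pi,
                  correlation_length = 2, seed = 1L, n_out = 4096L),
    dither = list(scheme = "checkerboard", seed = 1L, pattern_dwell = 1e-3,
                  iterations = 1L),
    aperture = list(center_um = c(0, 0), shape = "disk", radius_um = NULL),
    noise = list(model = "off", photons_per_unit = 1e4, read_sd = 0),
    protocol = list(stim_duration_s = 0.2, period_s = 5, n_stims = 9L,
                    frame_rate_hz = 10, pre_s = 5),
    out_dir = "fcoat-out"
  )
}

merge_config <- function(defaults, user, path = "") {
  for (key in names(user)) {
    full <- if (path == "") key else paste0(path, ".", key)
    if (!key %in% names(defaults))
      stop("unknown configuration key: `", full, "`")
    if (is.list(defaults[[key]]) && !is.null(names(defaults[[key]]))) {
      if (!is.list(user[[key]]))
        stop("configuration key `", full, "` must be a mapping")
      defaults[[key]] <- merge_config(defaults[[key]], user[[key]], full)
    } else {
      defaults[[key]] <- user[[key]]
    }
  }
  defaults
}

#' Load and validate a run configuration
#'
#' @param path YAML file; keys absent from the file take their defaults
#'   (589 nm, NA 0.1, 256-px grid with a 128-px pupil, 32 x 32 segments,
#'   static strong phase screen, checkerboard dither, single-pixel disk
#'   aperture, noiseless detector).
#' @return A validated `fcoat_config` list.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("configuration file not found: ", path)
  user <- yaml::read_yaml(path)
  if (is.null(user)) user <- list()
  cfg <- merge_config(config_defaults(), user)
  validate_config(cfg)
}

#' @rdname load_config
#' @param cfg a configuration list to validate (as from [load_config()]).
#' @export
validate_config <- function(cfg) {
  o <- cfg$optics
  if (is.character(cfg$medium$tau))  # YAML "Inf"
    cfg$medium$tau <- as.numeric(cfg$medium$tau)
  if (o$pupil_diameter_px > o$grid_n / 2)
    stop("invalid `optics.pupil_diameter_px`: must be <= grid_n/2")
  if (o$pupil_scale <= 0 || o$pupil_scale > 1)
    stop("invalid `optics.pupil_scale`: must be in (0, 1]")
  n <- cfg$layout_n
  if (n < 4 || n %% 2 != 0)
    stop("invalid `layout_n`: must be even and >= 4")
  if (floor(o$pupil_diameter_px / n) < 1)
    stop("invalid `layout_n`: more segments per side than pupil pixels")
  if (!cfg$medium$form %in% c("phase_screen", "matrix"))
    stop("invalid `medium.form`: must be phase_screen or matrix")
  if (!is.numeric(cfg$medium$tau) || cfg$medium$tau <= 0)
    stop("invalid `medium.tau`: must be > 0 (Inf for static)")
  if (!cfg$dither$scheme %in% c("checkerboard", "random"))
    stop("invalid `dither.scheme`")
  if (!cfg$noise$model %in% c("off", "poisson"))
    stop("invalid `noise.model`: must be off or poisson")
  if (cfg$protocol$period_s <= cfg$protocol$stim_duration_s)
    stop("invalid `protocol`: period_s must exceed stim_duration_s")
  structure(cfg, class = "fcoat_config")
}

#' @rdname load_config
#' @export
save_config <- function(cfg, path) {
  x <- unclass(cfg)
  x$medium$tau <- if (is.finite(x$medium$tau)) x$medium$tau else "Inf"
  yaml::write_yaml(x, path, precision = 15)
  invisible(path)
}

# instantiate the model objects a config describes
build_from_config <- function(cfg) {
  optics <- optical_config(cfg$optics$wavelength_um, cfg$optics$na,
                           cfg$optics$grid_n, cfg$optics$pupil_diameter_px,
                           cfg$optics$pupil_scale)
  layout <- build_segment_grid(optics, cfg$layout_n)
  medium <- if (cfg$medium$form == "phase_screen") {
    make_phase_screen(cfg$optics$grid_n, cfg$medium$correlation_length,
                      cfg$medium$strength, cfg$medium$seed, tau = cfg$medium$tau)
  } else {
    make_transmission_matrix(cfg$medium$n_out, layout$M, cfg$medium$seed,
                             tau = cfg$medium$tau)
  }
  aperture <- if (cfg$medium$form == "matrix") 1L else
    detection_aperture(optics, center_um = as.numeric(cfg$aperture$center_um),
                       shape = cfg$aperture$shape,
                       radius_um = cfg$aperture$radius_um %||%
                         (optics$focal_pixel_pitch / 2))
  noise <- if (cfg$noise$model == "poisson")
    noise_model(cfg$noise$photons_per_unit, cfg$noise$read_sd) else NULL
  list(optics = optics, layout = layout, medium = medium,
       aperture = aperture, noise = noise)
}

# write an intensity image as a normalized 32-bit float TIFF; returns the
# scale factor so absolute units can be recovered from the sidecar metadata
write_image_tiff <- function(image, path) {
  scale <- max(image, 1e-300)
  tiff::writeTIFF(image / scale, path, bits.per.sample = 32L)
  scale
}

#' Save the artifacts of a correction run
#'
#' Writes the before/after focal images (32-bit TIFF, peak-normalized with
#' the scale recorded in the manifest), the binary mask (TIFF phase map and
#' JSON), the per-half intensity traces (CSV), the focus report (JSON), and
#' a manifest with the configuration, its MD5 hash, all seeds, and the
#' measurement count — enough to reproduce the run bit-exactly.
#'
#' @param result an [run_fcoat()] result.
#' @param report an [focus_report()] for the corrected image (optional).
#' @param dir output directory (created if missing).
#' @param config the `fcoat_config` used (optional, echoed into the
#'   manifest).
#' @param before,after focal intensity images (optional).
#' @return Invisibly, the manifest list.
#' @export
save_artifacts <- function(result, report = NULL, dir, config = NULL,
                           before = NULL, after = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(
    package_version = as.character(utils::packageVersion("fcoat")),
    measurement_count = result$measurement_count,
    seeds = list(dither = result$seed, medium = result$medium$seed),
    mask_pi_fraction = mean(result$mask == pi),
    intensity_before = result$intensity_before,
    intensity_after = result$intensity_after)
  if (!is.null(before))
    manifest$before_scale <- write_image_tiff(before, file.path(dir, "before.tif"))
  if (!is.null(after))
    manifest$after_scale <- write_image_tiff(after, file.path(dir, "after.tif"))
  n_side <- result$layout$n_side
  mask_grid <- matrix(0, n_side, n_side)
  mask_grid[!is.na(result$layout$seg_id)] <-
    result$mask[result$layout$seg_id[!is.na(result$layout$seg_id)]]
  tiff::writeTIFF(mask_grid / pi, file.path(dir, "mask.tif"),
                  bits.per.sample = 32L)
  jsonlite::write_json(list(mask = result$mask, n_side = n_side),
                       file.path(dir, "mask.json"), digits = NA)
  utils::write.csv(
    data.frame(sample = seq_along(result$trace_first),
               first_half = result$trace_first,
               second_half = result$trace_second),
    file.path(dir, "traces.csv"), row.names = FALSE)
  if (!is.null(report))
    jsonlite::write_json(unclass(report), file.path(dir, "report.json"),
                         auto_unbox = TRUE, digits = NA)
  if (!is.null(config)) {
    cfg_path <- file.path(dir, "config.yaml")
    save_config(config, cfg_path)
    manifest$config_md5 <- unname(tools::md5sum(cfg_path))
  }
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
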