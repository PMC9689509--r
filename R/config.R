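# YAML-style configuration for the scene, the colour ranges and the
# detector, so simulated sessions and measurements are reproducible from a
# single plain-text file.

#' Default pipeline configuration
#'
#' @param girth_cm Cross-section circumference in cm (default 75: the
#'   30-interval checkerboard suit).
#' @param aspect Cross-section aspect ratio `b/a`.
#' @param noise_sigma Pixel noise (8-bit scale).
#' @param seed Session seed.
#' @param angles Turntable angles (degrees).
#' @return Nested configuration list.
#' @export
default_config <- function(girth_cm = 75, aspect = 0.8, noise_sigma = 0,
                           seed = 0L, angles = c(0, 90, 180, 270)) {
  list(scene = list(girth_cm = girth_cm, aspect = aspect,
                    interval = 0.025, height_range = c(-0.085, 0.085),
                    marker_horizontal = c(8, 7, 8, 7),
                    marker_vertical = c(-1, 1, -1, 1),
                    marker_radius = 0.006,
                    angles = angles, noise_sigma = noise_sigma,
                    supersample = 3L, seed = seed),
       rig = list(focal = 1100, width = 320L, height = 240L,
                  baseline = 0.3, D = 2.4, verged = TRUE),
       detector = list(quality = 0.05, min_distance = 5, window_size = 5L,
                       sigma = 1.0, refine_window = 5L),
       hsv = list(white_v_max = 255))
}

#' Read / write the pipeline configuration
#' @param path YAML file path.
#' @return `read_config` returns the configuration list.
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  base <- default_config()
  for (sec in names(base))
    for (k in names(base[[sec]]))
      if (is.null(cfg[[sec]][[k]])) cfg[[sec]][[k]] <- base[[sec]][[k]]
  cfg
}

#' @rdname read_config
#' @param config Configuration list.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(config, path, precision = 12)
  invisible(path)
}

#' Instantiate scene objects from a configuration
#'
#' @param config Configuration list from [default_config()] /
#'   [read_config()].
#' @return List with `model`, `layout`, `rig`, `detector` (a
#'   [detector_params()] list), `ranges`, `angles`, `noise_sigma`,
#'   `supersample`, `seed`.
#' @export
build_scene <- function(config = default_config()) {
  sc <- config$scene
  ax <- ellipse_axes_for_girth(sc$girth_cm / 100, sc$aspect)
  model <- body_segment_model(ax[1], ax[2],
                              height_range = unlist(sc$height_range),
                              checkerboard_interval = sc$interval)
  layout <- marker_layout(unlist(sc$marker_horizontal),
                          unlist(sc$marker_vertical), sc$marker_radius)
  rg <- config$rig
  rig <- make_default_rig(rg$focal, rg$width, rg$height, rg$baseline, rg$D,
                          rg$verged)
  dt <- config$detector
  list(model = model, layout = layout, rig = rig,
       detector = detector_params(dt$quality, dt$min_distance,
                                  dt$window_size, dt$sigma,
                                  dt$refine_window),
       ranges = hsv_ranges(config$hsv$white_v_max),
       angles = unlist(sc$angles), noise_sigma = sc$noise_sigma,
       supersample = sc$supersample, seed = sc$seed)
}

#' Write images / masks of a session as PNG files
#'
#' @param session A `measurement_session`.
#' @param dir Output directory (created if missing).
#' @return The directory, invisibly.
#' @export
write_session_png <- function(session, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (k in seq_along(session$views)) {
    v <- session$views[[k]]
    png::writePNG(v$left, file.path(dir, sprintf("view%d_left.png", k)))
    png::writePNG(v$right, file.path(dir, sprintf("view%d_right.png", k)))
    png::writePNG(v$mask_left + 0, file.path(dir, sprintf("view%d_mask_left.png", k)))
    png::writePNG(v$mask_right + 0, file.path(dir, sprintf("view%d_mask_right.png", k)))
  }
  invisible(dir)
}
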