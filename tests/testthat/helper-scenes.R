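# Shared synthetic scenes, cached across test files (rendering a full
# 4-view session takes a few seconds).

.scene_cache <- new.env(parent = emptyenv())

cached_session <- function(seed = 1L, noise = 0, girth = 75, aspect = 0.8) {
  key <- paste("s", seed, noise, girth, aspect, sep = "_")
  if (is.null(.scene_cache[[key]])) {
    cfg <- default_config(girth_cm = girth, aspect = aspect,
                          noise_sigma = noise, seed = seed)
    if (girth == 100) cfg$scene$marker_horizontal <- c(10, 10, 10, 10)
    sc <- build_scene(cfg)
    .scene_cache[[key]] <- generate_measurement_session(
      sc$model, sc$layout, sc$rig, seed = seed, noise_sigma = noise)
  }
  .scene_cache[[key]]
}

default_scene_objects <- function() {
  if (is.null(.scene_cache$objs))
    .scene_cache$objs <- build_scene(default_config())
  .scene_cache$objs
}

# a random proper rotation matrix
random_rotation <- function() {
  ax <- stats::rnorm(3); ax <- ax / sqrt(sum(ax^2))
  rotation_about_axis(stats::runif(1, 0, 360), ax)
}
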