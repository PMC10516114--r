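# Shared fixtures: small populations, compact encoder configs, and a cached
# dataset builder so expensive generation runs once per test file.

tiny_geom <- function() channel_geometry()

# mechanics-separable, images class-free (visual overlap 1)
mech_pop <- function(n = 40L) {
  population_config(n = c(n, n),
                    diameter_mean = c(14.2, 14.2), diameter_sd = c(3, 3),
                    stiffness_mean = c(2, 4), stiffness_sd = c(0.6, 1.2),
                    texture_overlap = 1, shape_source = "class_free")
}

# images-separable (visual overlap 0), mechanics uninformative
visual_pop <- function(n = 40L) {
  population_config(n = c(n, n),
                    diameter_mean = c(14.2, 14.2), diameter_sd = c(3, 3),
                    stiffness_mean = c(3, 3), stiffness_sd = c(0.8, 0.8),
                    texture_overlap = 0, shape_source = "trace")
}

small_encoder_cfg <- function(input_size = 32L, head = "classifier") {
  encoder_config(base_filters = 4L, blocks_per_stage = 1L,
                 input_size = input_size, head = head)
}

.ds_cache <- new.env(parent = emptyenv())

cached_dataset <- function(pop, seed, spec = image_spec(), tag = "ds") {
  key <- paste(tag, seed, spec$height, spec$pixel_scale, sep = "_")
  if (is.null(.ds_cache[[key]])) {
    dir <- file.path(tempdir(), paste0("cellmiml_", key))
    ds <- make_dataset(pop, channel_geometry(), spec, out_dir = dir, seed = seed)
    .ds_cache[[key]] <- read_manifest(ds$manifest_path)
  }
  .ds_cache[[key]]
}

# minimal hand-built trace for unit tests of the trace-derived features
fake_trace <- function(centroid, dt = 0.5, entry = 10L, exit = 30L,
                       a = NULL, b = NULL) {
  n <- length(centroid)
  if (is.null(a)) a <- rep(10, n)
  if (is.null(b)) b <- rep(10, n)
  structure(list(times = (seq_len(n) - 1) * dt, dt = dt,
                 centroid_x = centroid, a = a, b = b,
                 velocity = c(diff(centroid) / dt, 0),
                 entry_index = entry, exit_index = exit,
                 cell = list(diameter = 10, stiffness = 1),
                 geom = channel_geometry()),
            class = "miml_trace")
}

# analytic binary mask of a rotated ellipse (full axes a, b in px)
ellipse_mask <- function(a, b, theta = 0, H = 64L, W = 64L) {
  cy <- (H + 1) / 2; cx <- (W + 1) / 2
  yy <- matrix(seq_len(H) - cy, H, W)
  xx <- matrix(seq_len(W) - cx, H, W, byrow = TRUE)
  u <- xx * cos(theta) + yy * sin(theta)
  v <- -xx * sin(theta) + yy * cos(theta)
  (u / (a / 2))^2 + (v / (b / 2))^2 <= 1
}
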