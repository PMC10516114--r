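#' Generate a complete synthetic transit dataset on disk
#'
#' Samples a population, simulates each cell's constriction transit, computes
#' its ground-truth mechanical features from the trace, renders the two
#' per-cell frames (entry and maximally squeezed) as 8-bit grayscale PNGs and
#' writes a manifest CSV. With `config$shape_source = "class_free"` the
#' rendered shapes come from a transit whose stiffness is resampled from the
#' pooled class mixture, so images carry no class signal while the manifest
#' features still reflect the true mechanics.
#'
#' @param config A [population_config()].
#' @param geom A [channel_geometry()].
#' @param spec An [image_spec()].
#' @param out_dir Output directory (created if needed).
#' @param seed Integer seed; the whole dataset is a pure function of
#'   (config, geom, spec, seed).
#' @param dt Simulation time step, ms.
#' @return Invisibly, a list with `manifest` (data.frame), `manifest_path`,
#'   and `counts` per class.
#' @export
make_dataset <- function(config, geom = channel_geometry(), spec = image_spec(),
                         out_dir, seed = 1L, dt = 0.1) {
  stopifnot(inherits(config, "miml_population_config"))
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok && !dir.exists(out_dir)) stop("cannot create out_dir: ", out_dir)
  }
  cells <- sample_population(config, seed)
  # class-free shape stiffness: resample from the pooled mixture, independent
  # of each cell's own class
  if (config$shape_source == "class_free") {
    set.seed(derive_seed(seed, "class_free_shapes"))
    ncell <- nrow(cells)
    comp <- sample(seq_along(config$classes), ncell, replace = TRUE,
                   prob = config$n / sum(config$n))
    shape_stiff <- rtrunc_norm(ncell, config$stiffness_mean[comp],
                               config$stiffness_sd[comp], 0.05)
  }
  rows <- vector("list", nrow(cells))
  for (i in seq_len(nrow(cells))) {
    cell <- cells[i, ]
    trace <- simulate_transit(cell, geom, dt = dt)
    feats <- features_from_trace(trace, geom)
    render_trace <- trace
    if (config$shape_source == "class_free") {
      rcell <- cell
      rcell$stiffness <- shape_stiff[i]
      render_trace <- simulate_transit(rcell, geom, dt = dt)
    }
    fr <- render_frames(render_trace, cell, spec, which = c("entry", "squeezed"),
                        texture_overlap = config$texture_overlap,
                        texture_mode = config$texture_mode %||% "granularity",
                        seed = seed)
    f_entry <- paste0(cell$cell_id, "_entry.png")
    f_squee <- paste0(cell$cell_id, "_squeezed.png")
    write_gray_png(fr$frames[[1]], file.path(out_dir, f_entry))
    write_gray_png(fr$frames[[2]], file.path(out_dir, f_squee))
    rows[[i]] <- data.frame(cell_id = cell$cell_id, class = cell$class,
                            di = feats$di, tt_ms = feats$tt_ms,
                            vmax_norm = feats$vmax_norm,
                            dir_per_ms = feats$dir_per_ms,
                            img_entry = f_entry, img_squeezed = f_squee,
                            stringsAsFactors = FALSE)
  }
  manifest <- do.call(rbind, rows)
  path <- file.path(out_dir, "manifest.csv")
  write_manifest(manifest, path)
  invisible(list(manifest = manifest, manifest_path = path,
                 counts = table(manifest$class)))
}

write_gray_png <- function(img, path) {
  ok <- tryCatch({
    png::writePNG(img, target = path)
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) stop("failed to write image ", path, ": ", conditionMessage(ok))
  invisible(path)
}

read_gray_png <- function(path) {
  if (!file.exists(path)) stop("image file not found: ", path)
  img <- png::readPNG(path)
  if (length(dim(img)) == 3) img <- img[, , 1]
  img
}
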