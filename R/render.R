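#' Image rendering specification
#'
#' @param height,width Frame size in pixels.
#' @param pixel_scale Microns per pixel.
#' @param background Background intensity in \[0,1\].
#' @param noise_sd Additive Gaussian pixel noise sd.
#' @param jitter_px Maximum uniform offset of the cell from the frame centre
#'   (imperfect detector crops); default 1/12 of the frame side.
#' @return An object of class `miml_image_spec`.
#' @export
image_spec <- function(height = 64L, width = 64L, pixel_scale = 1.5,
                       background = 0.08, noise_sd = 0.02,
                       jitter_px = round(min(height, width) / 12)) {
  if (height < 8 || width < 8) stop("frame too small")
  if (pixel_scale <= 0) stop("pixel_scale must be positive")
  structure(list(height = as.integer(height), width = as.integer(width),
                 pixel_scale = pixel_scale, background = background,
                 noise_sd = noise_sd, jitter_px = jitter_px),
            class = "miml_image_spec")
}

# Anti-aliased coverage map of an axis-aligned ellipse (full axes a_px, b_px,
# a along image columns) in an H x W frame, centred at the frame centre plus
# (dy, dx); 4x4 subpixel sampling.
ellipse_coverage <- function(a_px, b_px, height, width, dy = 0, dx = 0) {
  ss <- 4L
  cy <- (height + 1) / 2 + dy
  cx <- (width + 1) / 2 + dx
  off <- (seq_len(ss) - (ss + 1) / 2) / ss
  ys <- rep(seq_len(height), each = ss) + rep(off, height)  # subsample rows
  xs <- rep(seq_len(width), each = ss) + rep(off, width)
  ry <- (ys - cy) / (b_px / 2)
  rx <- (xs - cx) / (a_px / 2)
  inside <- outer(ry^2, rx^2, "+") <= 1
  # average ss x ss blocks
  m <- matrix(0, height, width)
  dim(inside) <- c(ss, height, ss * width)
  colsum <- colSums(inside)            # (height) x (ss*width)
  dim(colsum) <- c(height, ss, width)
  m <- apply(colsum, c(1, 3), sum) / (ss * ss)
  m
}

# One rendered grayscale frame: background + textured cell + noise.
# `texture_mu` is the class-and-overlap-dependent mean cell intensity.
render_frame <- function(a_um, b_um, spec, texture_mu, texture_sd,
                         label = "frame", dy = 0, dx = 0) {
  a_px <- a_um / spec$pixel_scale
  b_px <- b_um / spec$pixel_scale
  if (a_px + 2 * abs(dx) >= spec$width - 2 || b_px + 2 * abs(dy) >= spec$height - 2)
    stop("ellipse exceeds frame bounds in ", label,
         " (a = ", round(a_px, 1), " px, b = ", round(b_px, 1),
         " px, frame ", spec$height, "x", spec$width, ")")
  cov <- ellipse_coverage(a_px, b_px, spec$height, spec$width, dy, dx)
  tex <- matrix(stats::rnorm(spec$height * spec$width, texture_mu, texture_sd),
                spec$height, spec$width)
  img <- spec$background + cov * (tex - spec$background)
  img <- img + matrix(stats::rnorm(spec$height * spec$width, 0, spec$noise_sd),
                      spec$height, spec$width)
  structure(pmin(pmax(img, 0), 1), coverage = cov)
}

# Class texture under the visual-overlap dial. Two kinds of visual class
# signal are supported: "granularity" separates the intra-cell speckle scale
# at equal mean brightness (chromatin-like texture; keeps the class evidence
# spatially inside the cell, which class-activation diagnostics need), while
# "brightness" offsets the mean interior intensity (a coarser cue that
# remains learnable at low resolutions). overlap = 1 makes the classes
# visually identical in either mode.
class_texture <- function(class_idx, overlap,
                          mode = c("granularity", "brightness"),
                          base_mu = 0.65, base_sd = 0.05,
                          sd_spread = 0.045, mu_spread = 0.15) {
  mode <- match.arg(mode)
  sgn <- if (class_idx %% 2 == 0) 1 else -1
  if (mode == "granularity") {
    list(mu = base_mu, sd = base_sd + sgn * (1 - overlap) * sd_spread)
  } else {
    list(mu = base_mu + sgn * (1 - overlap) * mu_spread, sd = base_sd)
  }
}

#' Render grayscale frames from a transit trace
#'
#' Draws an anti-aliased filled ellipse with the trace's instantaneous axes
#' near the frame centre (the virtual camera follows the centroid up to a
#' small deterministic crop jitter), with class-overlap-controlled texture
#' and additive noise. `which = "entry"` and `"squeezed"` mirror the
#' two-image acquisition protocol: one frame as the cell enters the
#' constriction and one at maximal squeeze. The per-frame ground-truth
#' coverage maps are returned alongside the frames.
#'
#' @param trace A `miml_trace` from [simulate_transit()].
#' @param cell The corresponding cell row (uses `class_idx`, `texture_seed`).
#' @param spec An [image_spec()].
#' @param which `"entry"`, `"squeezed"`, or `"all"` (every trace step).
#' @param texture_overlap Visual overlap dial in \[0,1\].
#' @param texture_mode Kind of visual class signal: `"granularity"`
#'   (speckle scale, equal brightness) or `"brightness"` (mean-intensity
#'   offset).
#' @param seed Integer seed; frames are bit-identical for identical inputs.
#' @return Object of class `miml_frames`: list of H x W matrices in \[0,1\],
#'   `frame_indices` into the trace, and `pixel_scale`.
#' @export
render_frames <- function(trace, cell, spec = image_spec(),
                          which = c("entry", "squeezed"),
                          texture_overlap = 1,
                          texture_mode = c("granularity", "brightness"),
                          seed = 1L) {
  texture_mode <- match.arg(texture_mode)
  stopifnot(inherits(trace, "miml_trace"), inherits(spec, "miml_image_spec"))
  which <- match.arg(which, c("entry", "squeezed", "all"), several.ok = TRUE)
  if ("all" %in% which) {
    idx <- seq_along(trace$times)
  } else {
    idx <- vapply(which, function(w) {
      switch(w,
             # last step before the entry plane: the still-undeformed cell
             entry = max(trace$entry_index - 1L, 1L),
             squeezed = squeeze_step(trace))
    }, 1L)
  }
  if (anyNA(idx) || any(idx < 1) || any(idx > length(trace$times)))
    stop("requested frame indices do not exist in trace")
  class_idx <- if (!is.null(cell$class_idx)) cell$class_idx else 0L
  tseed <- if (!is.null(cell$texture_seed)) cell$texture_seed else 0L
  tex <- class_texture(class_idx, texture_overlap, texture_mode)
  frames <- vector("list", length(idx))
  coverage <- vector("list", length(idx))
  for (j in seq_along(idx)) {
    i <- idx[j]
    set.seed(derive_seed(seed + as.integer(tseed %% 100000L), paste0("frame", i)))
    jit <- stats::runif(2, -spec$jitter_px, spec$jitter_px)
    f <- render_frame(trace$a[i], trace$b[i], spec,
                      texture_mu = tex$mu, texture_sd = tex$sd,
                      label = paste0("frame ", i), dy = jit[1], dx = jit[2])
    coverage[[j]] <- attr(f, "coverage")
    attr(f, "coverage") <- NULL
    frames[[j]] <- f
  }
  structure(list(frames = frames, frame_indices = idx, coverage = coverage,
                 pixel_scale = spec$pixel_scale,
                 height = spec$height, width = spec$width),
            class = "miml_frames")
}
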