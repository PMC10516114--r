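#' Deformation index
#'
#' `DI = (a - b) / (a + b)` for a cell's major and minor axes: 0 for a
#' perfect circle, approaching 1 as the minor axis vanishes. Scale-invariant.
#' Inputs given out of order are swapped.
#'
#' @param a,b Major and minor axis lengths (any common unit).
#' @return Dimensionless DI in [0, 1).
#' @export
compute_di <- function(a, b) {
  if (any(a + b <= 0)) stop("deformation index undefined: a + b must be positive")
  hi <- pmax(a, b)
  lo <- pmin(a, b)
  (hi - lo) / (hi + lo)
}

#' Transition time through the constriction
#'
#' Time for the centroid to traverse from the constriction entry plane to the
#' exit plane: `(exit_index - entry_index) * dt`.
#'
#' @param trace A `miml_trace`.
#' @return Time in ms.
#' @export
compute_transition_time <- function(trace) {
  if (is.na(trace$exit_index)) stop("incomplete transit: cell never exits within trace")
  if (trace$entry_index >= trace$exit_index) stop("entry_index must precede exit_index")
  (trace$exit_index - trace$entry_index) * trace$dt
}

#' Peak normalized velocity inside the constriction
#'
#' Maximum centroid displacement rate over the steps between the entry and
#' exit planes, normalized by the imposed flow velocity.
#'
#' @param trace A `miml_trace`.
#' @param u_flow Imposed flow velocity (um/ms); defaults to the trace's
#'   geometry.
#' @return Dimensionless peak velocity (1 in the free-advection limit).
#' @export
compute_vmax <- function(trace, u_flow = trace$geom$flow_velocity) {
  if (u_flow <= 0) stop("u_flow must be positive")
  if (is.na(trace$exit_index)) stop("incomplete transit: cell never exits within trace")
  i0 <- trace$entry_index
  i1 <- trace$exit_index
  x <- trace$centroid_x[i0:i1]
  if (length(x) < 2) return(trace$velocity[i0] / u_flow)
  max(diff(x) / trace$dt) / u_flow
}

#' Deformation-index rate
#'
#' Mean absolute rate of change of the deformation index over the
#' deformation-and-recovery window (by default the full series). A signed
#' mean would cancel over a symmetric squeeze-recover cycle, so the absolute
#' rate is used.
#'
#' @param di_series Numeric DI sequence.
#' @param dt Time step, ms.
#' @return Rate in 1/ms.
#' @export
compute_dir <- function(di_series, dt) {
  if (length(di_series) < 2) stop("DI series must have length >= 2")
  if (dt <= 0) stop("dt must be positive")
  mean(abs(diff(di_series))) / dt
}

#' All mechanical features of one transit trace
#'
#' @param trace A `miml_trace`.
#' @param geom The channel geometry (defaults to the trace's).
#' @return List with `di` (max over trace), `tt_ms`, `vmax_norm`,
#'   `dir_per_ms`.
#' @export
features_from_trace <- function(trace, geom = trace$geom) {
  di_series <- trace_di_series(trace)
  list(di = max(di_series),
       tt_ms = compute_transition_time(trace),
       vmax_norm = compute_vmax(trace, geom$flow_velocity),
       dir_per_ms = compute_dir(di_series, trace$dt))
}

## ---- segmentation and ellipse fitting --------------------------------------

otsu_threshold <- function(img, breaks = 256L) {
  h <- tabulate(pmin(pmax(floor(img * breaks) + 1L, 1L), breaks), breaks)
  p <- h / sum(h)
  mids <- (seq_len(breaks) - 0.5) / breaks
  w0 <- cumsum(p)
  mu <- cumsum(p * mids)
  mu_t <- mu[breaks]
  between <- (mu_t * w0 - mu)^2 / (w0 * (1 - w0))
  between[!is.finite(between)] <- 0
  # threshold at the upper edge of the best bin: foreground is strictly above
  which.max(between) / breaks
}

dilate3 <- function(m) {
  H <- nrow(m); W <- ncol(m)
  out <- m
  pad <- matrix(FALSE, H + 2, W + 2)
  pad[2:(H + 1), 2:(W + 1)] <- m
  for (di in -1:1) for (dj in -1:1) {
    if (di == 0 && dj == 0) next
    out <- out | pad[(2 + di):(H + 1 + di), (2 + dj):(W + 1 + dj)]
  }
  out
}

erode3 <- function(m) !dilate3(!m)

#' Segment the cell in a grayscale frame
#'
#' Global Otsu threshold (cells are rendered brighter than background),
#' morphological closing with a 3x3 structuring element, then retention of
#' the largest 8-connected foreground component.
#'
#' @param image H x W numeric matrix in \[0,1\].
#' @return Object of class `miml_mask`: logical matrix `mask` and
#'   `component_count` found before filtering.
#' @export
segment_cell <- function(image) {
  if (!is.matrix(image) || !length(image)) stop("image must be a non-empty matrix")
  if (diff(range(image)) < 0.05) stop("no cell detected")  # contrast-free frame
  thr <- otsu_threshold(image)
  fg <- image > thr
  if (!any(fg)) stop("no cell detected")
  fg <- erode3(dilate3(fg))  # closing
  if (!any(fg)) stop("no cell detected")
  lab <- cpp_label_components(matrix(as.integer(fg), nrow(fg)))
  sizes <- tabulate(lab[lab > 0])
  keep <- which.max(sizes)
  structure(list(mask = lab == keep, component_count = length(sizes)),
            class = "miml_mask")
}

#' Fit an ellipse to a segmentation mask by image moments
#'
#' Axes come from the eigenvalues of the second-order central moment matrix
#' of the foreground pixel coordinates: for a filled ellipse with full axes
#' `a >= b`, the principal second moments are `(a/4)^2` and `(b/4)^2`. A
#' -1/12 discretization correction is applied before the square root.
#'
#' @param mask A `miml_mask` (or logical matrix).
#' @param pixel_scale Microns per pixel.
#' @param weights Optional non-negative weight matrix (e.g. anti-aliased
#'   coverage estimated from intensities); restores subpixel accuracy that a
#'   binary mask quantizes away.
#' @return Object of class `miml_ellipse`: `a`, `b` (um, `a >= b`),
#'   `centroid` (px), `orientation` (radians).
#' @export
fit_ellipse <- function(mask, pixel_scale = 1, weights = NULL) {
  m <- if (inherits(mask, "miml_mask")) mask$mask else mask
  # binary pixel-center masses miss the within-pixel spread (+1/12); an
  # anti-aliased coverage field is the indicator already box-smoothed by one
  # pixel, so its second moment carries an extra +1/12 to remove
  corr <- if (is.null(weights)) 1 / 12 else -1 / 12
  if (is.null(weights)) weights <- matrix(as.numeric(m), nrow(m))
  idx <- which(weights > 0, arr.ind = TRUE)
  if (nrow(idx) < 4) stop("component too small to fit an ellipse")
  y <- idx[, 1]; x <- idx[, 2]
  w <- weights[weights > 0]
  w <- w / sum(w)
  cx <- sum(w * x); cy <- sum(w * y)
  mxx <- sum(w * (x - cx)^2) + corr
  myy <- sum(w * (y - cy)^2) + corr
  mxy <- sum(w * (x - cx) * (y - cy))
  tr <- mxx + myy
  det_ <- mxx * myy - mxy^2
  disc <- sqrt(max(tr^2 / 4 - det_, 0))
  l1 <- tr / 2 + disc
  l2 <- tr / 2 - disc
  # a 2-px-wide component has principal moment (2/4)^2 = 0.25
  if (l2 < 0.2) stop("component thinner than 2 px: axes unresolvable")
  a <- 4 * sqrt(l1)
  b <- 4 * sqrt(l2)
  ang <- 0.5 * atan2(2 * mxy, mxx - myy)
  structure(list(a = a * pixel_scale, b = b * pixel_scale,
                 centroid = c(x = cx, y = cy), orientation = ang),
            class = "miml_ellipse")
}

#' Deformation index measured from a rendered frame
#'
#' Segments the frame, estimates per-pixel cell coverage from intensities
#' (anti-aliased boundary pixels carry subpixel shape information), fits an
#' ellipse by weighted moments and returns its deformation index.
#'
#' @param image H x W numeric matrix in \[0,1\].
#' @return Dimensionless DI.
#' @export
di_from_image <- function(image) {
  seg <- segment_cell(image)
  support <- dilate3(seg$mask)
  core <- erode3(seg$mask)
  if (!any(core)) core <- seg$mask
  fg <- mean(image[core])
  ring <- !dilate3(support)
  bg <- if (any(ring)) mean(image[ring]) else 0
  w <- pmin(pmax((image - bg) / max(fg - bg, 1e-6), 0), 1)
  w[!support] <- 0
  e <- fit_ellipse(seg, weights = w)
  compute_di(e$a, e$b)
}

## ---- normalization ----------------------------------------------------------

#' Fit 0-1 normalization bounds on a training split
#'
#' @param values Numeric vector (training split only).
#' @return List `(lo, hi)` usable as `bounds` in [minmax_normalize()].
#' @export
fit_minmax <- function(values) {
  lo <- min(values); hi <- max(values)
  if (hi <= lo) {
    warning("constant vector: normalization will map everything to 0")
    hi <- lo  # degenerate; minmax_normalize handles it
  }
  list(lo = lo, hi = hi)
}

#' Min-max normalize to \[0, 1\]
#'
#' `(x - lo) / (hi - lo)`, clipped to \[0,1\]. When `bounds` is omitted the
#' bounds are fitted from `values` itself -- only do this on a training
#' split, then reuse the returned bounds (attribute `"bounds"`) on
#' validation/test data to avoid leakage.
#'
#' @param values Numeric vector.
#' @param bounds Optional list `(lo, hi)` from [fit_minmax()].
#' @return Normalized vector with attribute `"bounds"`.
#' @export
minmax_normalize <- function(values, bounds = NULL) {
  if (is.null(bounds)) bounds <- fit_minmax(values)
  if (!is.null(bounds$hi) && !is.null(bounds$lo) && bounds$hi < bounds$lo)
    stop("bounds: hi must be >= lo")
  rng <- bounds$hi - bounds$lo
  out <- if (rng <= 0) rep(0, length(values)) else (values - bounds$lo) / rng
  out <- pmin(pmax(out, 0), 1)
  attr(out, "bounds") <- bounds
  out
}

# Normalized feature matrix (cells x features) from a manifest, with bounds
# fitted on the training cell ids only. Features: di (already 0-1),
# tt_ms -> tt_norm, vmax_norm (renormalized to the observed range),
# dir_per_ms -> dir_norm.
#' Build a normalized mechanical feature matrix from a manifest
#'
#' @param manifest Manifest data.frame.
#' @param features Character subset of `c("di","tt","vmax","dir")`.
#' @param train_ids Cell ids of the training split used to fit bounds;
#'   default all rows.
#' @param bounds Optional previously fitted bounds (list per feature).
#' @return List: `X` (cells x d matrix in \[0,1\]), `y` (0/1 integer labels),
#'   `cell_ids`, `bounds`, `classes`.
#' @export
feature_matrix <- function(manifest, features = c("di", "tt", "vmax"),
                           train_ids = manifest$cell_id, bounds = NULL) {
  features <- match.arg(features, c("di", "tt", "vmax", "dir"), several.ok = TRUE)
  raw <- list(di = manifest$di, tt = manifest$tt_ms,
              vmax = manifest$vmax_norm, dir = manifest$dir_per_ms)
  tr <- manifest$cell_id %in% train_ids
  if (!any(tr)) stop("no training rows to fit normalization bounds")
  if (is.null(bounds)) {
    bounds <- list()
    for (f in features) {
      bounds[[f]] <- if (f == "di") list(lo = 0, hi = 1) else fit_minmax(raw[[f]][tr])
    }
  }
  X <- sapply(features, function(f) {
    as.numeric(minmax_normalize(raw[[f]], bounds[[f]]))
  })
  X <- matrix(X, ncol = length(features),
              dimnames = list(NULL, features))
  classes <- sort(unique(manifest$class))
  if (length(classes) != 2) stop("feature_matrix supports exactly two classes")
  y <- as.integer(manifest$class == classes[2])
  list(X = X, y = y, cell_ids = manifest$cell_id, bounds = bounds,
       classes = classes)
}
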