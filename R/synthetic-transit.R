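#' Constriction channel geometry
#'
#' Describes the microfluidic squeezing channel: a straight channel of length
#' `channel_length` containing a centred constriction of length
#' `constriction_length` whose opening (`gap`) is smaller than a typical cell
#' diameter, so cells must deform to pass. Defaults follow the device the
#' framework targets: a 5.2 um top-to-bottom gap and 20 um depth.
#'
#' @param gap Constriction opening, um.
#' @param depth Channel depth (out-of-plane), um.
#' @param constriction_length Length of the narrow region along the flow
#'   axis, um. Not reported for the reference device; default 30 um.
#' @param channel_length Total simulated channel length, um.
#' @param flow_velocity Imposed far-field flow speed `u_flow`, um/ms.
#' @return An object of class `miml_geometry`.
#' @export
channel_geometry <- function(gap = 5.2, depth = 20, constriction_length = 30,
                             channel_length = 100, flow_velocity = 1.0) {
  if (gap <= 0 || constriction_length <= 0 || channel_length <= 0 ||
      depth <= 0 || flow_velocity <= 0)
    stop("geometry dimensions and flow velocity must be positive")
  if (constriction_length >= channel_length)
    stop("constriction_length must be smaller than channel_length")
  entry <- (channel_length - constriction_length) / 2
  structure(list(gap = gap, depth = depth,
                 constriction_length = constriction_length,
                 channel_length = channel_length,
                 flow_velocity = flow_velocity,
                 entry_x = entry, exit_x = entry + constriction_length),
            class = "miml_geometry")
}

#' Two-population configuration for the synthetic cell generator
#'
#' Each class is a population of cells with Gaussian diameter and stiffness
#' distributions (truncated at small positive values). `texture_overlap`
#' controls how visually distinguishable the two classes are: 1 means the
#' rendered image texture/intensity distributions are identical across
#' classes, 0 means fully distinct. Default diameters follow the measured
#' 14.2 +/- 4.4 um and 13.5 +/- 1.5 um populations of the target system.
#'
#' @param classes Character vector of two class names.
#' @param n Integer vector, cells per class.
#' @param diameter_mean,diameter_sd Per-class diameter distribution, um.
#' @param stiffness_mean,stiffness_sd Per-class stiffness distribution
#'   (dimensionless stretching-resistance analogue; softer = smaller).
#' @param texture_overlap Scalar in \[0,1\]; 1 = visually indistinguishable.
#' @param texture_mode Kind of visual class signal when overlap < 1; see
#'   [render_frames()].
#' @param shape_source `"trace"` renders each cell's own simulated shape;
#'   `"class_free"` renders shapes from a stiffness resampled from the pooled
#'   class mixture so that images carry no class information (images
#'   identical across classes in distribution).
#' @return An object of class `miml_population_config`.
#' @export
population_config <- function(classes = c("soft", "stiff"),
                              n = c(100L, 100L),
                              diameter_mean = c(14.2, 13.5),
                              diameter_sd = c(4.4, 1.5),
                              stiffness_mean = c(1, 10),
                              stiffness_sd = c(0.2, 2),
                              texture_overlap = 1,
                              texture_mode = c("granularity", "brightness"),
                              shape_source = c("trace", "class_free")) {
  shape_source <- match.arg(shape_source)
  texture_mode <- match.arg(texture_mode)
  k <- length(classes)
  if (k < 2) stop("need at least two classes")
  if (any(n < 1)) stop("per-class counts must be >= 1")
  if (any(diameter_sd < 0) || any(stiffness_sd < 0)) stop("sds must be >= 0")
  if (any(diameter_mean <= 0) || any(stiffness_mean <= 0))
    stop("diameter and stiffness means must be positive")
  if (texture_overlap < 0 || texture_overlap > 1)
    stop("texture_overlap must be in [0, 1]")
  stopifnot(length(n) == k, length(diameter_mean) == k, length(diameter_sd) == k,
            length(stiffness_mean) == k, length(stiffness_sd) == k)
  structure(list(classes = classes, n = as.integer(n),
                 diameter_mean = diameter_mean, diameter_sd = diameter_sd,
                 stiffness_mean = stiffness_mean, stiffness_sd = stiffness_sd,
                 texture_overlap = texture_overlap, texture_mode = texture_mode,
                 shape_source = shape_source),
            class = "miml_population_config")
}

rtrunc_norm <- function(n, mean, sd, lower) {
  x <- stats::rnorm(n, mean, sd)
  bad <- which(x <= lower)
  for (i in bad) {
    repeat {
      v <- stats::rnorm(1, mean, sd)
      if (v > lower) break
    }
    x[i] <- v
  }
  x
}

#' Sample a synthetic cell population
#'
#' Draws per-cell latent ground truth (class, diameter, stiffness, texture
#' seed) from the configured distributions. Deterministic given `seed`.
#' Diameters are truncated above 0.5 um.
#'
#' @param config A [population_config()].
#' @param seed Integer seed.
#' @return A data.frame of class specs: `cell_id`, `class`, `class_idx`
#'   (0-based), `diameter`, `stiffness`, `bending`, `texture_seed`.
#' @export
sample_population <- function(config, seed = 1L) {
  stopifnot(inherits(config, "miml_population_config"))
  set.seed(derive_seed(seed, "population"))
  rows <- list()
  for (i in seq_along(config$classes)) {
    n <- config$n[i]
    d <- rtrunc_norm(n, config$diameter_mean[i], config$diameter_sd[i], 0.5)
    s <- rtrunc_norm(n, config$stiffness_mean[i], config$stiffness_sd[i], 0.05)
    rows[[i]] <- data.frame(
      cell_id = sprintf("%s_%04d", config$classes[i], seq_len(n)),
      class = config$classes[i],
      class_idx = i - 1L,
      diameter = d,
      stiffness = s,
      bending = 0,
      texture_seed = sample.int(.Machine$integer.max, n),
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Simulate one cell's transit through the constriction
#'
#' Phenomenological mechanics standing in for a full fluid-structure solver:
#' inside the constriction the minor axis relaxes exponentially toward an
#' effective compressed gap `g_eff = gap + (D - gap) * s / (s + s0)` (soft
#' cells, small `s`, squeeze fully to the gap; rigid cells barely deform),
#' the major axis follows 2-D area conservation `a = D^2 / b`, and the
#' transit speed is the imposed flow reduced by a stiffness- and
#' confinement-dependent friction factor
#' `v = u_flow / (1 + kappa * s * (D - gap) / gap)`.
#' This reproduces the qualitative laws the method relies on: softer cells
#' show a larger deformation index, shorter transition time and higher peak
#' velocity. The trace continues briefly past the exit plane so the shape
#' recovery limb (needed for the deformation-index rate) is observable.
#'
#' @param cell One row of [sample_population()] output (or a list with
#'   `diameter` and `stiffness`).
#' @param geom A [channel_geometry()].
#' @param dt Time step, ms.
#' @param s0 Stiffness scale of the effective-gap law.
#' @param kappa Friction coefficient.
#' @param relax_rate Base relaxation rate (1/ms); per-cell rate is
#'   `relax_rate / stiffness`.
#' @param max_steps Cap on the trace length; very slow (stiff) transits are
#'   recorded on a coarsened time grid instead of overrunning this cap.
#' @return An object of class `miml_trace`: time grid, centroid position,
#'   major/minor axes, velocity, and entry/exit step indices.
#' @export
simulate_transit <- function(cell, geom, dt = 0.1, s0 = 5, kappa = 0.1,
                             relax_rate = 2, max_steps = 20000L) {
  stopifnot(inherits(geom, "miml_geometry"))
  if (dt <= 0) stop("dt must be positive")
  D <- cell$diameter
  s <- cell$stiffness
  if (D <= 0 || s <= 0) stop("diameter and stiffness must be positive")
  confined <- D > geom$gap
  g_eff <- if (confined) geom$gap + (D - geom$gap) * s / (s + s0) else D
  v_conf <- if (confined) geom$flow_velocity / (1 + kappa * s * (D - geom$gap) / geom$gap)
            else geom$flow_velocity
  rate <- relax_rate / s
  # duration estimate: lead-in + confined crossing + recovery tail (the tail
  # ends early once the minor axis is within 1% of recovered); very stiff
  # cells transit extremely slowly, so the grid is coarsened rather than
  # letting the step count grow unboundedly
  t_est <- geom$entry_x / geom$flow_velocity +
    geom$constriction_length / v_conf +
    min(log(100) / rate, 3 * geom$channel_length / geom$flow_velocity) +
    10 * dt
  nmax <- ceiling(t_est / dt) + 10L
  if (nmax > max_steps) {
    dt <- dt * ceiling(nmax / max_steps)
    nmax <- ceiling(t_est / dt) + 10L
  }

  x <- 0
  b <- D
  xs <- numeric(nmax); bs <- numeric(nmax); vs <- numeric(nmax)
  exited_at <- NA_integer_
  n <- nmax
  decay <- exp(-rate * dt)
  for (i in seq_len(nmax)) {
    inside <- x >= geom$entry_x && x < geom$exit_x
    v <- if (inside) v_conf else geom$flow_velocity
    target <- if (inside) g_eff else D
    b <- target + (b - target) * decay
    xs[i] <- x; bs[i] <- b; vs[i] <- v
    xnew <- x + v * dt
    # land exactly on the entry plane so a coarse grid cannot step across
    # the whole constriction in one fast pre-entry stride
    if (x < geom$entry_x && xnew > geom$entry_x) xnew <- geom$entry_x
    x <- xnew
    if (is.na(exited_at) && xs[i] >= geom$exit_x) exited_at <- i
    if (!is.na(exited_at)) {
      recovered <- abs(b - D) < 0.01 * max(D - geom$gap, 1e-6)
      if ((recovered && i >= exited_at + 2L) || x >= geom$channel_length) {
        n <- i
        break
      }
    }
  }
  xs <- xs[seq_len(n)]; bs <- bs[seq_len(n)]; vs <- vs[seq_len(n)]
  a <- D^2 / bs
  entry_index <- which(xs >= geom$entry_x)[1]
  exit_index <- which(xs >= geom$exit_x)[1]
  structure(list(times = (seq_len(n) - 1) * dt, dt = dt,
                 centroid_x = xs, a = a, b = bs, velocity = vs,
                 entry_index = entry_index,
                 exit_index = exit_index,
                 cell = as.list(cell[c("diameter", "stiffness")]),
                 geom = geom),
            class = "miml_trace")
}

#' Deformation-index series of a trace
#'
#' @param trace A `miml_trace`.
#' @return Numeric vector `(a - b) / (a + b)` per step.
#' @export
trace_di_series <- function(trace) {
  (trace$a - trace$b) / (trace$a + trace$b)
}

# Step at which the cell is maximally squeezed (max DI; ties -> first).
squeeze_step <- function(trace) which.max(trace_di_series(trace))
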