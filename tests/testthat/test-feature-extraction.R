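test_that("deformation index follows its closed form and is scale invariant", {
  expect_equal(compute_di(10, 10), 0)
  expect_equal(compute_di(12, 8), 0.2)
  expect_gt(compute_di(10, 1e-9), 1 - 1e-8)
  expect_equal(compute_di(8, 12), 0.2)  # swapped inputs
  expect_error(compute_di(0, 0), "positive")
  set.seed(11)
  for (i in 1:50) {
    a <- runif(1, 1, 50); b <- runif(1, 0.1, a); k <- runif(1, 0.01, 100)
    expect_equal(compute_di(k * a, k * b), compute_di(a, b), tolerance = 1e-12)
  }
})

test_that("transition time and vmax follow their index/normalization conventions", {
  tr <- fake_trace(centroid = seq(0, 49.5, by = 0.5) * 2, dt = 0.5,
                   entry = 10L, exit = 30L)
  expect_equal(compute_transition_time(tr), 10)
  tr_bad <- tr; tr_bad$exit_index <- NA_integer_
  expect_error(compute_transition_time(tr_bad), "incomplete transit")
  expect_error(compute_vmax(tr_bad), "incomplete transit")
  # constant centroid velocity 2 um/ms, u_flow 4 -> 0.5
  tr2 <- fake_trace(centroid = seq(0, 198, by = 2), dt = 1)
  expect_equal(compute_vmax(tr2, u_flow = 4), 0.5)
  expect_error(compute_vmax(tr2, u_flow = 0), "positive")
})

test_that("deformation-index rate averages absolute changes", {
  expect_equal(compute_dir(c(0, 0.2, 0.4, 0.2, 0), dt = 1), 0.2)
  expect_equal(compute_dir(rep(0.3, 10), dt = 1), 0)
  s <- c(0, 0.1, 0.3, 0.25, 0.05)
  expect_equal(compute_dir(s, dt = 0.5), 2 * compute_dir(s, dt = 1))
  expect_error(compute_dir(0.1, dt = 1), "length")
  expect_error(compute_dir(c(0.1, 0.2), dt = 0), "dt")
})

test_that("min-max normalization clips, reuses training bounds, flags constants", {
  expect_equal(as.numeric(minmax_normalize(c(2, 4, 6))), c(0, 0.5, 1))
  di <- c(0.1, 0.5, 0.9)
  expect_equal(as.numeric(minmax_normalize(di, list(lo = 0, hi = 1))), di)
  b <- fit_minmax(c(2, 4, 6))
  expect_equal(as.numeric(minmax_normalize(8, b)), 1)   # above hi -> clipped
  expect_equal(as.numeric(minmax_normalize(0, b)), 0)
  expect_warning(z <- minmax_normalize(rep(5, 4)), "constant")
  expect_equal(as.numeric(z), rep(0, 4))
})

test_that("segmentation thresholds, closes, and keeps the largest component", {
  expect_error(segment_cell(matrix(0.5, 16, 16)), "no cell detected")
  # single rendered ellipse: pixel count within 5% of analytic area
  sp <- image_spec()
  img <- cellmiml:::render_frame(30, 14, sp, 0.65, 0.05)
  m <- segment_cell(img)
  a_px <- 30 / sp$pixel_scale; b_px <- 14 / sp$pixel_scale
  expect_equal(sum(m$mask), pi * a_px * b_px / 4, tolerance = 0.05)
  # two blobs, one 4x larger: only the larger survives
  two <- matrix(0.05, 64, 64)
  two[10:13, 10:13] <- 0.9          # 16 px
  two[30:41, 30:41] <- 0.9          # 144 px
  m2 <- segment_cell(two)
  expect_gte(m2$component_count, 2)
  expect_false(m2$mask[11, 11])
  expect_true(m2$mask[35, 35])
})

test_that("moment-based ellipse fit recovers axes, ratios and rotations", {
  circ <- ellipse_mask(20, 20)
  e <- fit_ellipse(circ)
  expect_lt(abs(e$a / e$b - 1), 0.02)
  expect_equal(e$a, 20, tolerance = 0.04)
  # rasterized (anti-aliased) 30x10 ellipse, coverage-weighted moments
  cov <- cellmiml:::ellipse_coverage(30, 10, 64, 64)
  er <- fit_ellipse(cov > 0.5, weights = cov)
  expect_lt(abs(er$a / er$b - 3), 0.09)
  ell <- ellipse_mask(30, 10)
  e2 <- fit_ellipse(ell)
  expect_lt(abs(e2$a / e2$b - 3), 0.15)  # binary mask: quantization-limited
  rot <- ellipse_mask(30, 10, theta = pi / 4)
  e3 <- fit_ellipse(rot)
  expect_lt(abs(e3$a - e2$a) / e2$a, 0.01)
  expect_lt(abs(e3$b - e2$b) / e2$b, 0.015)
  # pixel_scale converts to physical units
  e4 <- fit_ellipse(ell, pixel_scale = 2)
  expect_equal(e4$a, 2 * e2$a)
  # thin line unresolvable
  thin <- matrix(FALSE, 32, 32); thin[16, 5:28] <- TRUE
  expect_error(fit_ellipse(thin), "thinner")
})

test_that("DI survives the render-segment-fit round trip", {
  sp <- image_spec()
  set.seed(23)
  for (i in 1:25) {
    a <- runif(1, 14, 80); b <- runif(1, 9, min(a, 30))
    img <- cellmiml:::render_frame(a, b, sp, 0.65, 0.05)
    di_hat <- di_from_image(img)
    expect_lt(abs(di_hat - compute_di(a, b)), 0.02)
  }
})

test_that("feature_matrix normalizes on the training split only", {
  man <- cached_dataset(mech_pop(25), seed = 21, tag = "ovl1")
  train_ids <- man$cell_id[1:30]
  fm <- feature_matrix(man, c("di", "tt", "vmax", "dir"), train_ids = train_ids)
  expect_true(all(fm$X >= 0 & fm$X <= 1))
  expect_equal(colnames(fm$X), c("di", "tt", "vmax", "dir"))
  tr_rows <- man$cell_id %in% train_ids
  expect_equal(fm$bounds$tt$lo, min(man$tt_ms[tr_rows]))
  expect_equal(fm$bounds$tt$hi, max(man$tt_ms[tr_rows]))
  expect_equal(fm$bounds$di, list(lo = 0, hi = 1))
  # reusing bounds reproduces the matrix
  fm2 <- feature_matrix(man, c("di", "tt", "vmax", "dir"), bounds = fm$bounds)
  expect_equal(fm2$X, fm$X)
})
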