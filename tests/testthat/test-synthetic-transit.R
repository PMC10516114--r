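test_that("population sampling validates config and is deterministic", {
  expect_error(population_config(n = c(0, 10)), "counts")
  expect_error(population_config(diameter_sd = c(-1, 1)), "sds")
  expect_error(population_config(texture_overlap = 1.5), "overlap")
  cfg <- mech_pop(20)
  p1 <- sample_population(cfg, seed = 7)
  p2 <- sample_population(cfg, seed = 7)
  expect_identical(p1, p2)
  expect_equal(as.numeric(table(p1$class)), c(20, 20))
  expect_true(all(p1$diameter > 0.5))
})

test_that("sample means recover configured distributions within 3 SE", {
  cfg <- population_config(n = c(100, 100), stiffness_mean = c(1, 10),
                           stiffness_sd = c(0.2, 2))
  pop <- sample_population(cfg, seed = 7)
  for (i in 1:2) {
    cl <- cfg$classes[i]
    s <- pop$stiffness[pop$class == cl]
    se <- cfg$stiffness_sd[i] / sqrt(100)
    expect_lt(abs(mean(s) - cfg$stiffness_mean[i]), 3 * se + 0.05)
    d <- pop$diameter[pop$class == cl]
    se_d <- cfg$diameter_sd[i] / sqrt(100)
    # slight upward bias from truncation at 0.5 um is tolerated
    expect_lt(abs(mean(d) - cfg$diameter_mean[i]), 3 * se_d + 0.1)
  }
})

test_that("transit mechanics follow the soft-fast/stiff-slow law", {
  geom <- tiny_geom()
  expect_error(simulate_transit(list(diameter = 10, stiffness = 1), geom, dt = 0),
               "dt")
  # undeformed small cell
  tr <- simulate_transit(list(diameter = 4, stiffness = 1), geom)
  expect_lt(max(trace_di_series(tr)), 0.05)
  expect_equal(compute_vmax(tr), 1, tolerance = 1e-9)
  # soft vs stiff, same diameter
  soft <- simulate_transit(list(diameter = 14.2, stiffness = 1), geom)
  stiff <- simulate_transit(list(diameter = 14.2, stiffness = 10), geom)
  expect_gt(max(trace_di_series(soft)), max(trace_di_series(stiff)))
  expect_lt(compute_transition_time(soft), compute_transition_time(stiff))
  expect_gt(compute_vmax(soft), compute_vmax(stiff))
  # trace invariants
  for (tr in list(soft, stiff)) {
    expect_true(all(tr$a >= tr$b - 1e-9))
    expect_true(all(tr$b > 0))
    expect_true(all(tr$velocity >= 0))
    expect_lt(tr$entry_index, tr$exit_index)
  }
})

test_that("rigid limit: DI vanishes and transit time is maximal on a stiffness grid", {
  geom <- tiny_geom()
  grid <- c(1, 10, 1e2, 1e4, 1e6)
  di <- tt <- numeric(length(grid))
  for (i in seq_along(grid)) {
    tr <- simulate_transit(list(diameter = 14.2, stiffness = grid[i]), geom)
    di[i] <- max(trace_di_series(tr))
    tt[i] <- compute_transition_time(tr)
  }
  expect_true(all(diff(di) < 0))
  expect_true(all(diff(tt) > 0))
  # closed-form effective-gap oracle: rigid limit leaves the cell unsqueezed
  g_eff <- 5.2 + (14.2 - 5.2) * grid / (grid + 5)
  expect_true(all(diff(g_eff) > 0))
  expect_lt(di[length(grid)], 0.01)
  expect_equal(which.max(tt), length(grid))
})

test_that("geometry limit: DI tends to zero as diameter approaches the gap", {
  geom <- tiny_geom()
  di <- vapply(c(5.25, 5.5, 6, 8), function(D) {
    max(trace_di_series(simulate_transit(list(diameter = D, stiffness = 1), geom)))
  }, 1.0)
  expect_true(all(diff(di) > 0))
  expect_lt(di[1], 0.02)
})

test_that("rendered frames are deterministic, round shapes stay round, area is conserved", {
  geom <- tiny_geom()
  cell <- list(diameter = 14, stiffness = 2, class_idx = 0L, texture_seed = 11L)
  tr <- simulate_transit(cell, geom)
  sp <- image_spec()
  f1 <- render_frames(tr, cell, sp, seed = 5)
  f2 <- render_frames(tr, cell, sp, seed = 5)
  expect_identical(f1$frames, f2$frames)
  expect_true(all(vapply(f1$frames, function(m) all(m >= 0 & m <= 1), TRUE)))
  # circle round trip on the entry frame (a == b there up to relaxation lag)
  e <- fit_ellipse(segment_cell(f1$frames[[1]]), sp$pixel_scale)
  expect_lt(e$a / e$b, 1.05)
  # rasterized area vs analytic pi*a*b/4 within 3%
  for (i in f1$frame_indices) {
    cov <- cellmiml:::ellipse_coverage(tr$a[i] / sp$pixel_scale,
                                       tr$b[i] / sp$pixel_scale,
                                       sp$height, sp$width)
    expect_equal(sum(cov),
                 pi * tr$a[i] * tr$b[i] / (4 * sp$pixel_scale^2),
                 tolerance = 0.03)
  }
  # oversized ellipse errors, naming the frame
  sp_small <- image_spec(height = 16, width = 16, pixel_scale = 0.5)
  expect_error(render_frames(tr, cell, sp_small, seed = 1), "frame")
})

test_that("make_dataset writes a complete, reproducible two-image-per-cell manifest", {
  pop <- mech_pop(10)
  d1 <- file.path(tempdir(), "mk1"); d2 <- file.path(tempdir(), "mk2")
  ds1 <- make_dataset(pop, out_dir = d1, seed = 9)
  ds2 <- make_dataset(pop, out_dir = d2, seed = 9)
  expect_equal(nrow(ds1$manifest), 20)
  expect_equal(sum(file.exists(file.path(d1, c(ds1$manifest$img_entry,
                                               ds1$manifest$img_squeezed)))), 40)
  expect_identical(ds1$manifest, ds2$manifest)
  expect_identical(readBin(file.path(d1, ds1$manifest$img_entry[1]), "raw", 1e5),
                   readBin(file.path(d2, ds2$manifest$img_entry[1]), "raw", 1e5))
  # manifest features equal recomputation from the cell's trace
  cells <- sample_population(pop, seed = 9)
  for (i in c(1, 15)) {
    tr <- simulate_transit(cells[i, ], channel_geometry())
    fe <- features_from_trace(tr)
    row <- ds1$manifest[ds1$manifest$cell_id == cells$cell_id[i], ]
    expect_equal(row$di, fe$di, tolerance = 1e-12)
    expect_equal(row$tt_ms, fe$tt_ms, tolerance = 1e-12)
    expect_equal(row$vmax_norm, fe$vmax_norm, tolerance = 1e-12)
    expect_equal(row$dir_per_ms, fe$dir_per_ms, tolerance = 1e-12)
  }
})

test_that("visual-overlap dial controls class distinguishability of textures", {
  # overlap 1: per-image mean intensities statistically indistinguishable
  m1 <- cached_dataset(mech_pop(25), seed = 21, tag = "ovl1")
  dir <- attr(m1, "dir")
  # intra-cell intensity sd: the class signal is texture granularity inside
  # the cell, so restrict the statistic to the segmented cell region
  img_stat <- function(man, col) {
    vapply(seq_len(nrow(man)), function(i) {
      img <- cellmiml:::read_gray_png(file.path(attr(man, "dir"), man[[col]][i]))
      stats::sd(img[segment_cell(img)$mask])
    }, 1.0)
  }
  v1 <- img_stat(m1, "img_squeezed")
  p_ovl1 <- stats::t.test(v1[m1$class == "soft"], v1[m1$class == "stiff"])$p.value
  expect_gt(p_ovl1, 0.01)
  # overlap 0: trivially distinguishable
  m0 <- cached_dataset(visual_pop(25), seed = 22, tag = "ovl0")
  v0 <- img_stat(m0, "img_squeezed")
  p_ovl0 <- stats::t.test(v0[m0$class == "soft"], v0[m0$class == "stiff"])$p.value
  expect_lt(p_ovl0, 1e-3)
})

test_that("stiffness monotonicity holds in the mean over small populations", {
  geom <- tiny_geom()
  set.seed(99)
  levels <- c(1, 2, 4, 8)
  mdi <- mtt <- mv <- numeric(length(levels))
  for (i in seq_along(levels)) {
    di <- tt <- vm <- numeric(15)
    for (j in 1:15) {
      D <- max(stats::rnorm(1, 14.2, 3), 6)
      tr <- simulate_transit(list(diameter = D, stiffness = levels[i]), geom)
      di[j] <- max(trace_di_series(tr))
      tt[j] <- compute_transition_time(tr)
      vm[j] <- compute_vmax(tr)
    }
    mdi[i] <- mean(di); mtt[i] <- mean(tt); mv[i] <- mean(vm)
  }
  expect_true(all(diff(mdi) < 0))
  expect_true(all(diff(mtt) > 0))
  expect_true(all(diff(mv) < 0))
})
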