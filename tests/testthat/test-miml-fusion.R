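small_fusion <- function(seed = 1L, d = 3L) {
  cfg <- small_encoder_cfg(head = "identity")
  build_fusion(cfg, fusion_cfg = fusion_config(n_cnn = embedding_width(cfg), d = d),
               seed = seed)
}

rand_imgs <- function(n, size = 32L, seed = 1) {
  set.seed(seed)
  lapply(seq_len(n), function(i) matrix(runif(size * size), size, size))
}

test_that("fused latent widths follow the architecture rules", {
  # reference scale: 512 image embedding + 16 mechanical latent = 528
  fc <- fusion_config()
  expect_equal(fc$n_cnn + fc$n_mlp, 528L)
  model <- small_fusion()
  expect_equal(model$fusion$layers[[1]]$d_in,
               embedding_width(model$encoder_cfg) + 16L)
  u <- extract_latent(model, rand_imgs(3), matrix(runif(9), 3))
  expect_equal(dim(u), c(3L, model$fusion_cfg$n_cnn + model$fusion_cfg$n_mlp))
  # mismatched n_cnn is a build error
  expect_error(build_fusion(small_encoder_cfg(head = "identity"),
                            fusion_cfg = fusion_config(n_cnn = 512L, d = 3L)),
               "embedding width")
})

test_that("forward yields normalized, deterministic predictions with shape checks", {
  model <- small_fusion(seed = 2)
  imgs <- rand_imgs(4, seed = 2)
  m <- matrix(runif(12), 4)
  p <- miml_predict_prob(model, imgs, m)
  expect_equal(dim(p), c(4L, 2L))
  expect_equal(rowSums(p), rep(1, 4), tolerance = 1e-6)
  p2 <- miml_predict_prob(model, imgs, m)
  expect_identical(p, p2)
  # duplicated example -> identical prediction
  p3 <- miml_predict_prob(model, imgs[c(1, 1)], m[c(1, 1), ])
  expect_identical(p3[1, ], p3[2, ])
  expect_error(miml_predict_prob(model, imgs, m[, 1:2]), "does not match d")
  expect_error(miml_predict_prob(model, imgs, {mm <- m; mm[2, 1] <- NA; mm}),
               "missing mechanical")
})

test_that("zeroing the mechanical branch removes sensitivity to m", {
  model <- small_fusion(seed = 3)
  for (i in seq_along(model$mech$layers)) {
    if (length(model$mech$layers[[i]]$params)) {
      model$mech$layers[[i]]$params$W[] <- 0
      model$mech$layers[[i]]$params$b[] <- 0
    }
  }
  imgs <- rand_imgs(2, seed = 3)
  m <- matrix(runif(6), 2)
  m2 <- m; m2[1, 2] <- m2[1, 2] + 0.1
  expect_equal(miml_predict_prob(model, imgs, m),
               miml_predict_prob(model, imgs, m2), tolerance = 1e-12)
})

test_that("one joint step reaches encoder, mechanical branch, and fusion head", {
  model <- small_fusion(seed = 4)
  imgs <- rand_imgs(4, seed = 4)
  train <- list(images = imgs, m = matrix(runif(12), 4), y = c(0L, 1L, 0L, 1L),
                cell_ids = paste0("a", 1:4))
  val <- list(images = rand_imgs(2, seed = 5), m = matrix(runif(6), 2),
              y = c(0L, 1L), cell_ids = paste0("b", 1:2))
  fit <- train_miml(model, train, val, epochs = 1, seed = 4, batch_size = 4)
  expect_false(identical(fit$model$encoder$net$layers[[1]]$params$W,
                         model$encoder$net$layers[[1]]$params$W))
  expect_false(identical(fit$model$mech$layers[[1]]$params$W,
                         model$mech$layers[[1]]$params$W))
  expect_false(identical(fit$model$fusion$layers[[1]]$params$W,
                         model$fusion$layers[[1]]$params$W))
  expect_error(train_miml(model, train,
                          list(images = imgs[1:2], m = train$m[1:2, ],
                               y = c(0L, 1L), cell_ids = c("a1", "zz")),
                          epochs = 1, seed = 1),
               "leakage")
})

test_that("epochs = 0 returns the initialized model", {
  model <- small_fusion(seed = 6)
  imgs <- rand_imgs(4, seed = 6)
  train <- list(images = imgs, m = matrix(runif(12), 4), y = c(0L, 1L, 0L, 1L),
                cell_ids = paste0("a", 1:4))
  val <- list(images = rand_imgs(2, seed = 7), m = matrix(runif(6), 2),
              y = c(0L, 1L), cell_ids = paste0("b", 1:2))
  fit <- train_miml(model, train, val, epochs = 0, seed = 6)
  expect_identical(cellmiml:::miml_params(fit$model), cellmiml:::miml_params(model))
  expect_equal(nrow(fit$history), 0)
})

test_that("checkpoints round-trip and reject mismatched architectures", {
  model <- small_fusion(seed = 8)
  path <- tempfile(fileext = ".rds")
  save_checkpoint(model, path,
                  norm_bounds = list(di = list(lo = 0, hi = 1)),
                  class_map = list(`0` = "soft", `1` = "stiff"))
  m2 <- load_checkpoint(path)
  imgs <- rand_imgs(2, seed = 8)
  mm <- matrix(runif(6), 2)
  expect_equal(miml_predict_prob(m2, imgs, mm),
               miml_predict_prob(model, imgs, mm), tolerance = 1e-12)
  expect_equal(m2$class_map[["1"]], "stiff")
  # corrupt: claim a different mechanical width
  ck <- readRDS(path)
  ck$fusion_cfg$d <- 4L
  saveRDS(ck, path)
  expect_error(load_checkpoint(path), "mismatch")
})

test_that("freeze policy all-but-head leaves both branches bit-identical", {
  model <- small_fusion(seed = 9)
  imgs <- rand_imgs(8, seed = 9)
  train <- list(images = imgs[1:6], m = matrix(runif(18), 6),
                y = rep(0:1, 3), cell_ids = paste0("a", 1:6))
  val <- list(images = imgs[7:8], m = matrix(runif(6), 2),
              y = c(0L, 1L), cell_ids = paste0("b", 1:2))
  ft <- fine_tune(model, train, val, epochs = 2, freeze = "all-but-head",
                  seed = 9)
  expect_identical(cellmiml:::nn_collect_params(ft$model$encoder$net),
                   cellmiml:::nn_collect_params(model$encoder$net))
  expect_identical(cellmiml:::nn_collect_params(ft$model$mech),
                   cellmiml:::nn_collect_params(model$mech))
  # the re-initialized head did train
  k <- length(model$fusion$layers)
  expect_false(identical(ft$model$fusion$layers[[k]]$params$W,
                         model$fusion$layers[[k]]$params$W))
  # frozen intermediate fusion layers unchanged
  expect_identical(ft$model$fusion$layers[[1]]$params$W,
                   model$fusion$layers[[1]]$params$W)
})
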