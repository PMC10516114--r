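test_that("confusion counts match hand counting and positive-class symmetry", {
  y <- c(rep(1, 4), rep(0, 6))
  c1 <- confusion(y, y)
  expect_equal(unlist(c1[c("tp", "tn", "fp", "fn")]),
               c(tp = 4, tn = 6, fp = 0, fn = 0))
  c2 <- confusion(y, rep(1, 10))
  expect_equal(unlist(c2[c("tp", "tn", "fp", "fn")]),
               c(tp = 4, tn = 0, fp = 6, fn = 0))
  pred <- c(1, 0, 1, 1, 0, 0, 1, 0, 0, 0)
  a <- confusion(y, pred, positive = 1)
  b <- confusion(y, pred, positive = 0)
  expect_equal(a$tp, b$tn); expect_equal(a$fp, b$fn)
  expect_error(confusion(y, pred[1:5]), "mismatch")
})

test_that("metrics match their closed forms, including degenerate counts", {
  m <- metrics(structure(list(tp = 3, fp = 1, fn = 1, tn = 5),
                         class = "miml_confusion"))
  expect_equal(m$accuracy, 0.8)
  expect_equal(m$precision, 0.75)
  expect_equal(m$recall, 0.75)
  expect_equal(m$f1, 0.75)
  # FP == FN implies precision == recall == f1
  m2 <- metrics(structure(list(tp = 7, fp = 2, fn = 2, tn = 1),
                          class = "miml_confusion"))
  expect_equal(m2$precision, m2$recall)
  expect_equal(m2$f1, m2$precision)
  expect_warning(m3 <- metrics(structure(list(tp = 0, fp = 0, fn = 3, tn = 5),
                                         class = "miml_confusion")),
                 "zero denominator")
  expect_equal(m3$precision, 0)
  expect_true(m3$degenerate)
})

test_that("metrics agree with brute-force counting on random prediction vectors", {
  set.seed(10)
  for (rep in 1:200) {
    n <- sample(5:50, 1)
    y <- rbinom(n, 1, runif(1, 0.2, 0.8))
    p <- rbinom(n, 1, runif(1, 0.2, 0.8))
    if (sum(y) == 0 || sum(y) == n) next
    cc <- confusion(y, p)
    mm <- suppressWarnings(metrics(cc))
    tp <- sum(y == 1 & p == 1); tn <- sum(y == 0 & p == 0)
    fp <- sum(y == 0 & p == 1); fn <- sum(y == 1 & p == 0)
    expect_equal(mm$accuracy, (tp + tn) / n, tolerance = 1e-12)
    if (tp + fp > 0) expect_equal(mm$precision, tp / (tp + fp), tolerance = 1e-12)
    if (tp + fn > 0) expect_equal(mm$recall, tp / (tp + fn), tolerance = 1e-12)
    # both printed forms of the F1 identity
    if (tp + fp > 0 && tp + fn > 0 && tp > 0) {
      P <- tp / (tp + fp); R <- tp / (tp + fn)
      expect_equal(mm$f1, 2 * R * P / (R + P), tolerance = 1e-12)
      expect_equal(mm$f1, 2 * tp / (2 * tp + fp + fn), tolerance = 1e-12)
    }
  }
})

test_that("AUC equals the Mann-Whitney rank statistic and handles ties", {
  expect_equal(roc_auc(c(0, 0, 1, 1), c(0.1, 0.2, 0.8, 0.9))$auc, 1.0)
  set.seed(4)
  for (rep in 1:50) {
    n <- sample(10:60, 1)
    y <- rbinom(n, 1, 0.5)
    if (sum(y) == 0 || sum(y) == n) next
    s <- round(rnorm(n), sample(0:1, 1))  # rounding induces ties
    auc <- roc_auc(y, s)$auc
    w <- stats::wilcox.test(s[y == 1], s[y == 0], exact = FALSE)$statistic
    expect_equal(auc, as.numeric(w) / (sum(y == 1) * sum(y == 0)),
                 tolerance = 1e-9)
  }
  expect_error(roc_auc(rep(1, 5), runif(5)), "both classes")
})

test_that("label-independent scores give chance AUC", {
  set.seed(6)
  y <- rbinom(2000, 1, 0.5)
  s <- rnorm(2000)
  expect_gt(roc_auc(y, s)$auc, 0.45)
  expect_lt(roc_auc(y, s)$auc, 0.55)
})

test_that("fold plans partition exactly, stratified within one cell", {
  ids <- sprintf("c%02d", 1:20)
  labs <- rep(c("a", "b"), each = 10)
  f <- make_folds(ids, labs, k = 5, seed = 1)
  expect_length(f, 5)
  expect_equal(sort(unlist(f)), sort(ids))
  expect_equal(lengths(f), rep(4L, 5))
  expect_error(make_folds(ids, labs, k = 21, seed = 1), "exceeds")
  # 60:40 ratio, per-fold within +/- 1 cell
  ids2 <- sprintf("d%02d", 1:50)
  labs2 <- rep(c("a", "b"), c(30, 20))
  f2 <- make_folds(ids2, labs2, k = 5, seed = 2)
  for (fold in f2) {
    na <- sum(fold %in% ids2[labs2 == "a"])
    expect_lte(abs(na - 6), 1)
  }
})

test_that("t-SNE embedding is deterministic and preserves strong separation", {
  set.seed(8)
  z <- rbind(matrix(rnorm(40 * 5), 40), matrix(rnorm(40 * 5, mean = 8), 40))
  e1 <- embed_2d(z, seed = 3)
  e2 <- embed_2d(z, seed = 3)
  expect_identical(e1, e2)
  expect_equal(dim(e1), c(80L, 2L))
  expect_gt(silhouette_score(e1, rep(c("a", "b"), each = 40)), 0.5)
  expect_error(embed_2d(z[1:3, ]), "at least 5")
  expect_error(embed_2d(z[1:8, ], perplexity = 30), "perplexity")
})

test_that("grad-cam returns a normalized heatmap aligned to the input", {
  enc <- build_encoder(small_encoder_cfg(), seed = 12)
  img <- matrix(runif(32 * 32), 32, 32)
  h <- grad_cam(enc, img, layer = "last")
  expect_equal(dim(h), dim(img))
  expect_true(all(is.finite(h)))
  expect_true(all(h >= 0 & h <= 1))
  h2 <- grad_cam(enc, img, layer = "penultimate", class = 1)
  expect_equal(dim(h2), dim(img))
  expect_error(grad_cam(enc, img, layer = "nope"), "available")
})
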