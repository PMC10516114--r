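# Engine correctness: analytic gradients vs central finite differences, and
# the optimizer/freezing contracts everything downstream relies on.

num_grad <- function(f, x, eps = 1e-5) {
  g <- x * 0
  for (i in seq_along(x)) {
    xp <- x; xp[i] <- xp[i] + eps
    xm <- x; xm[i] <- xm[i] - eps
    g[i] <- (f(xp) - f(xm)) / (2 * eps)
  }
  g
}

loss_of_net <- function(net, x, y) {
  fw <- cellmiml:::nn_forward(net, x, training = TRUE)
  cellmiml:::softmax_xent(fw$out, y)$loss
}

test_that("backprop matches finite differences through conv/bn/pool/gap/linear", {
  set.seed(42)
  layers <- list(
    cellmiml:::nn_conv("c1", 1L, 3L, 3L, 1L),
    cellmiml:::nn_bn("b1", 3L),
    cellmiml:::nn_relu("r1"),
    cellmiml:::nn_maxpool("p1", 3L, 2L, 1L),
    cellmiml:::nn_gap("g1"),
    cellmiml:::nn_linear("fc", 3L, 2L)
  )
  net <- list(layers = layers)
  x <- cellmiml:::fmap(matrix(runif(8 * 8 * 4), 1), 8L, 8L, 4L)
  y <- c(0L, 1L, 1L, 0L)
  fw <- cellmiml:::nn_forward(net, x, training = TRUE)
  lo <- cellmiml:::softmax_xent(fw$out, y)
  bw <- cellmiml:::nn_backward(net, fw$caches, lo$grad)
  for (li in c(1L, 2L, 6L)) {
    for (p in names(net$layers[[li]]$params)) {
      ana <- bw$grads[[li]][[p]]
      f <- function(v) {
        n2 <- net
        pn <- n2$layers[[li]]$params[[p]]
        pn[] <- v
        n2$layers[[li]]$params[[p]] <- pn
        loss_of_net(n2, x, y)
      }
      num <- num_grad(f, as.numeric(net$layers[[li]]$params[[p]]))
      expect_lt(max(abs(as.numeric(ana) - num)), 1e-5)
    }
  }
  # input gradient
  f_in <- function(v) {
    x2 <- x; x2$mat <- matrix(v, nrow = 1)
    loss_of_net(net, x2, y)
  }
  num_in <- num_grad(f_in, as.numeric(x$mat))
  expect_lt(max(abs(as.numeric(bw$gin$mat) - num_in)), 1e-5)
})

test_that("backprop matches finite differences through a projection resblock", {
  set.seed(7)
  layers <- list(
    cellmiml:::nn_resblock("rb", 2L, 4L, stride = 2L),
    cellmiml:::nn_gap("g"),
    cellmiml:::nn_linear("fc", 4L, 2L)
  )
  net <- list(layers = layers)
  x <- cellmiml:::fmap(matrix(runif(2 * 6 * 6 * 3), 2), 6L, 6L, 3L)
  y <- c(0L, 1L, 0L)
  fw <- cellmiml:::nn_forward(net, x, training = TRUE)
  lo <- cellmiml:::softmax_xent(fw$out, y)
  bw <- cellmiml:::nn_backward(net, fw$caches, lo$grad)
  for (sub in c("conv1", "bn2", "proj_conv")) {
    for (p in names(net$layers[[1]]$sub[[sub]]$params)) {
      ana <- bw$grads[[1]][[sub]][[p]]
      f <- function(v) {
        n2 <- net
        pn <- n2$layers[[1]]$sub[[sub]]$params[[p]]
        pn[] <- v
        n2$layers[[1]]$sub[[sub]]$params[[p]] <- pn
        loss_of_net(n2, x, y)
      }
      num <- num_grad(f, as.numeric(net$layers[[1]]$sub[[sub]]$params[[p]]))
      expect_lt(max(abs(as.numeric(ana) - num)), 1e-5)
    }
  }
})

test_that("adam updates are deterministic and respect frozen layers", {
  set.seed(1)
  net <- list(layers = list(cellmiml:::nn_linear("a", 3L, 4L),
                            cellmiml:::nn_relu("r"),
                            cellmiml:::nn_linear("b", 4L, 2L)))
  x <- matrix(runif(9), 3)
  y <- c(0L, 1L, 0L)
  step <- function(net, frozen_b = FALSE) {
    if (frozen_b) net$layers[[3]]$frozen <- TRUE
    opt <- cellmiml:::adam_init()
    fw <- cellmiml:::nn_forward(net, x, training = TRUE)
    lo <- cellmiml:::softmax_xent(fw$out, y)
    bw <- cellmiml:::nn_backward(net, fw$caches, lo$grad)
    cellmiml:::adam_step(net, bw$grads, opt)$net
  }
  n1 <- step(net); n2 <- step(net)
  expect_identical(n1$layers[[1]]$params$W, n2$layers[[1]]$params$W)
  expect_false(identical(n1$layers[[1]]$params$W, net$layers[[1]]$params$W))
  n3 <- step(net, frozen_b = TRUE)
  expect_identical(n3$layers[[3]]$params$W, net$layers[[3]]$params$W)
  expect_false(identical(n3$layers[[1]]$params$W, net$layers[[1]]$params$W))
})

test_that("softmax cross-entropy produces normalized probabilities", {
  set.seed(3)
  logits <- matrix(rnorm(10 * 4, sd = 5), 10)
  p <- cellmiml:::softmax_probs(logits)
  expect_equal(colSums(p), rep(1, 4), tolerance = 1e-12)
  expect_true(all(p >= 0))
})

test_that("feature MLP has the quoted layer sizes and parameter count", {
  net <- cellmiml:::build_feature_mlp_net(3L)
  expect_equal(cellmiml:::nn_count_params(net),
               3 * 32 + 32 + 32 * 16 + 16 + 16 * 2 + 2)
  dims <- lapply(net$layers, function(l) if (!is.null(l$params$W)) dim(l$params$W))
  expect_equal(Filter(Negate(is.null), dims),
               list(c(32L, 3L), c(16L, 32L), c(2L, 16L)))
})

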