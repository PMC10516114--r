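# Minimal backpropagation engine backing the feature MLP, the residual image
# encoder and the multimodal fusion network.
#
# Feature maps travel between layers as a list (fmap) holding a channels x
# (H*W*N) matrix `mat` plus spatial dims; vector activations are plain
# (features x N) matrices.  Convolution is im2col (C++) followed by BLAS GEMM.
# Networks are plain lists, so they copy, compare and serialize with base R.

fmap <- function(mat, h, w, n) list(mat = mat, h = h, w = w, n = n)

is_fmap <- function(x) is.list(x) && !is.null(x$mat)

get_mat <- function(x) if (is_fmap(x)) x$mat else x

set_mat <- function(x, m) {
  if (is_fmap(x)) {
    x$mat <- m
    x
  } else {
    m
  }
}

he_init <- function(nrow, ncol, fan_in) {
  matrix(stats::rnorm(nrow * ncol, sd = sqrt(2 / fan_in)), nrow, ncol)
}

## ---- layer constructors ----------------------------------------------------

nn_conv <- function(name, in_c, out_c, k, stride = 1L, pad = (k - 1L) %/% 2L) {
  list(type = "conv", name = name, in_c = in_c, out_c = out_c, k = k,
       stride = as.integer(stride), pad = as.integer(pad), frozen = FALSE,
       params = list(W = he_init(out_c, k * k * in_c, k * k * in_c),
                     b = numeric(out_c)))
}

nn_bn <- function(name, c) {
  list(type = "bn", name = name, c = c, eps = 1e-5, momentum = 0.3,
       frozen = FALSE,
       params = list(gamma = rep(1, c), beta = numeric(c)),
       state = list(mean = numeric(c), var = rep(1, c)))
}

nn_relu <- function(name) list(type = "relu", name = name, frozen = FALSE, params = list())

nn_maxpool <- function(name, k = 3L, stride = 2L, pad = 1L) {
  list(type = "maxpool", name = name, k = as.integer(k),
       stride = as.integer(stride), pad = as.integer(pad),
       frozen = FALSE, params = list())
}

nn_gap <- function(name) list(type = "gap", name = name, frozen = FALSE, params = list())

nn_linear <- function(name, d_in, d_out) {
  list(type = "linear", name = name, d_in = d_in, d_out = d_out, frozen = FALSE,
       params = list(W = he_init(d_out, d_in, d_in), b = numeric(d_out)))
}

# Residual block: conv-bn-relu-conv-bn plus identity (or 1x1 projection when
# stride or width changes), then ReLU on the sum.
nn_resblock <- function(name, in_c, out_c, stride = 1L, k = 3L) {
  proj <- (stride != 1L || in_c != out_c)
  sub <- list(
    conv1 = nn_conv(paste0(name, ".conv1"), in_c, out_c, k, stride),
    bn1   = nn_bn(paste0(name, ".bn1"), out_c),
    conv2 = nn_conv(paste0(name, ".conv2"), out_c, out_c, k, 1L),
    bn2   = nn_bn(paste0(name, ".bn2"), out_c)
  )
  if (proj) {
    sub$proj_conv <- nn_conv(paste0(name, ".proj"), in_c, out_c, 1L, stride, 0L)
    sub$proj_bn <- nn_bn(paste0(name, ".proj_bn"), out_c)
  }
  list(type = "resblock", name = name, proj = proj, frozen = FALSE,
       params = list(), sub = sub)
}

## ---- forward ---------------------------------------------------------------

conv_out_dim <- function(d, k, stride, pad) (d + 2L * pad - k) %/% stride + 1L

layer_forward <- function(layer, x, training = FALSE) {
  switch(layer$type,
    conv = {
      stopifnot(is_fmap(x))
      if (nrow(x$mat) != layer$in_c)
        stop("channel mismatch in ", layer$name, ": got ", nrow(x$mat),
             ", expected ", layer$in_c)
      oh <- conv_out_dim(x$h, layer$k, layer$stride, layer$pad)
      ow <- conv_out_dim(x$w, layer$k, layer$stride, layer$pad)
      if (oh < 1L || ow < 1L)
        stop("input ", x$h, "x", x$w, " too small for layer ", layer$name)
      cols <- cpp_im2col(x$mat, x$h, x$w, nrow(x$mat), x$n,
                         layer$k, layer$stride, layer$pad)
      out <- layer$params$W %*% cols + layer$params$b
      list(out = fmap(out, oh, ow, x$n),
           cache = list(cols = cols, h = x$h, w = x$w, n = x$n),
           layer = layer)
    },
    bn = {
      m <- get_mat(x)
      # fine-tuning on tiny batches keeps the pretrained statistics frozen
      training <- training && !isTRUE(layer$freeze_stats)
      if (training) {
        mu <- rowMeans(m)
        xc <- m - mu
        v <- rowMeans(xc * xc)
        layer$state$mean <- (1 - layer$momentum) * layer$state$mean + layer$momentum * mu
        layer$state$var <- (1 - layer$momentum) * layer$state$var + layer$momentum * v
      } else {
        mu <- layer$state$mean
        v <- layer$state$var
        xc <- m - mu
      }
      inv_sd <- 1 / sqrt(v + layer$eps)
      xhat <- xc * inv_sd
      out <- layer$params$gamma * xhat + layer$params$beta
      list(out = set_mat(x, out),
           cache = list(xhat = xhat, xc = xc, inv_sd = inv_sd, training = training),
           layer = layer)
    },
    relu = {
      m <- get_mat(x)
      out <- m * (m > 0)
      list(out = set_mat(x, out), cache = list(mask = m > 0), layer = layer)
    },
    maxpool = {
      stopifnot(is_fmap(x))
      r <- cpp_maxpool(x$mat, x$h, x$w, nrow(x$mat), x$n,
                       layer$k, layer$stride, layer$pad)
      oh <- conv_out_dim(x$h, layer$k, layer$stride, layer$pad)
      ow <- conv_out_dim(x$w, layer$k, layer$stride, layer$pad)
      list(out = fmap(r$out, oh, ow, x$n),
           cache = list(argmax = r$argmax, h = x$h, w = x$w, n = x$n),
           layer = layer)
    },
    gap = {
      stopifnot(is_fmap(x))
      s <- x$h * x$w
      arr <- array(x$mat, c(nrow(x$mat), s, x$n))
      out <- colMeans(aperm(arr, c(2, 1, 3)), dims = 1)
      if (is.null(dim(out))) out <- matrix(out, nrow = nrow(x$mat))
      list(out = out, cache = list(h = x$h, w = x$w, n = x$n), layer = layer)
    },
    linear = {
      m <- get_mat(x)
      out <- layer$params$W %*% m + layer$params$b
      list(out = out, cache = list(x = m), layer = layer)
    },
    resblock = layer_forward_resblock(layer, x, training),
    stop("unknown layer type ", layer$type)
  )
}

layer_forward_resblock <- function(layer, x, training) {
  s <- layer$sub
  f1 <- layer_forward(s$conv1, x, training); s$conv1 <- f1$layer
  f2 <- layer_forward(s$bn1, f1$out, training); s$bn1 <- f2$layer
  m2 <- f2$out
  relu_mask <- get_mat(m2) > 0
  m2 <- set_mat(m2, get_mat(m2) * relu_mask)
  f3 <- layer_forward(s$conv2, m2, training); s$conv2 <- f3$layer
  f4 <- layer_forward(s$bn2, f3$out, training); s$bn2 <- f4$layer
  if (layer$proj) {
    p1 <- layer_forward(s$proj_conv, x, training); s$proj_conv <- p1$layer
    p2 <- layer_forward(s$proj_bn, p1$out, training); s$proj_bn <- p2$layer
    short <- p2$out
    proj_cache <- list(c = p1$cache, b = p2$cache)
  } else {
    short <- x
    proj_cache <- NULL
  }
  stopifnot(all(dim(get_mat(f4$out)) == dim(get_mat(short))))
  sum_mat <- get_mat(f4$out) + get_mat(short)
  out_mask <- sum_mat > 0
  out <- set_mat(f4$out, sum_mat * out_mask)
  layer$sub <- s
  list(out = out,
       cache = list(c1 = f1$cache, b1 = f2$cache, relu1 = relu_mask,
                    c2 = f3$cache, b2 = f4$cache, proj = proj_cache,
                    out_mask = out_mask),
       layer = layer)
}

nn_forward <- function(net, x, training = FALSE, record = FALSE) {
  caches <- vector("list", length(net$layers))
  outs <- if (record) vector("list", length(net$layers)) else NULL
  for (i in seq_along(net$layers)) {
    l <- net$layers[[i]]
    f <- if (l$type == "resblock") layer_forward_resblock(l, x, training)
         else layer_forward(l, x, training)
    x <- f$out
    caches[[i]] <- f$cache
    if (record) outs[[i]] <- x
    net$layers[[i]] <- f$layer  # BN running stats
  }
  list(out = x, caches = caches, net = net, outs = outs)
}

## ---- backward --------------------------------------------------------------

layer_backward <- function(layer, cache, gout) {
  switch(layer$type,
    conv = {
      g <- get_mat(gout)
      gW <- g %*% t(cache$cols)
      gb <- rowSums(g)
      dcols <- crossprod(layer$params$W, g)
      gin <- cpp_col2im(dcols, cache$h, cache$w, layer$in_c, cache$n,
                        layer$k, layer$stride, layer$pad)
      list(gin = fmap(gin, cache$h, cache$w, cache$n),
           grads = list(W = gW, b = gb))
    },
    bn = {
      g <- get_mat(gout)
      M <- ncol(g)
      dgamma <- rowSums(g * cache$xhat)
      dbeta <- rowSums(g)
      if (cache$training) {
        dxhat <- g * layer$params$gamma
        t1 <- dxhat
        t2 <- rowMeans(dxhat)
        t3 <- cache$xhat * rowMeans(dxhat * cache$xhat)
        gin <- layer$params$gamma * cache$inv_sd * (t1 - t2 - t3)
      } else {
        gin <- g * layer$params$gamma * cache$inv_sd
      }
      list(gin = set_mat(gout, gin), grads = list(gamma = dgamma, beta = dbeta))
    },
    relu = {
      g <- get_mat(gout)
      list(gin = set_mat(gout, g * cache$mask), grads = list())
    },
    maxpool = {
      g <- get_mat(gout)
      gin <- cpp_maxpool_bwd(g, cache$argmax, cache$h, cache$w, nrow(g), cache$n)
      list(gin = fmap(gin, cache$h, cache$w, cache$n), grads = list())
    },
    gap = {
      s <- cache$h * cache$w
      g <- get_mat(gout) / s  # (C x N)
      idx <- rep(seq_len(cache$n), each = s)
      gin <- g[, idx, drop = FALSE]
      list(gin = fmap(gin, cache$h, cache$w, cache$n), grads = list())
    },
    linear = {
      g <- get_mat(gout)
      gW <- g %*% t(cache$x)
      gb <- rowSums(g)
      gin <- crossprod(layer$params$W, g)
      list(gin = gin, grads = list(W = gW, b = gb))
    },
    stop("unknown layer type ", layer$type)
  )
}

layer_backward_resblock <- function(layer, cache, gout) {
  s <- layer$sub
  g <- get_mat(gout) * cache$out_mask
  gsum <- set_mat(gout, g)
  # main path
  b2 <- layer_backward(s$bn2, cache$b2, gsum)
  c2 <- layer_backward(s$conv2, cache$c2, b2$gin)
  gr1 <- set_mat(c2$gin, get_mat(c2$gin) * cache$relu1)
  b1 <- layer_backward(s$bn1, cache$b1, gr1)
  c1 <- layer_backward(s$conv1, cache$c1, b1$gin)
  gin_main <- c1$gin
  grads <- list(conv1 = c1$grads, bn1 = b1$grads, conv2 = c2$grads, bn2 = b2$grads)
  if (layer$proj) {
    pb <- layer_backward(s$proj_bn, cache$proj$b, gsum)
    pc <- layer_backward(s$proj_conv, cache$proj$c, pb$gin)
    grads$proj_conv <- pc$grads
    grads$proj_bn <- pb$grads
    gin <- set_mat(gin_main, get_mat(gin_main) + get_mat(pc$gin))
  } else {
    gin <- set_mat(gin_main, get_mat(gin_main) + get_mat(gsum))
  }
  list(gin = gin, grads = grads)
}

# Backward through layers `from` (default all) down to layer index `to`.
# Returns per-layer grads and the gradient w.r.t. the output of layer `to - 1`
# (or the input when to == 1).
nn_backward <- function(net, caches, gout, to = 1L) {
  n <- length(net$layers)
  grads <- vector("list", n)
  for (i in seq(n, to)) {
    l <- net$layers[[i]]
    b <- if (l$type == "resblock") layer_backward_resblock(l, caches[[i]], gout)
         else layer_backward(l, caches[[i]], gout)
    grads[[i]] <- b$grads
    gout <- b$gin
  }
  list(grads = grads, gin = gout)
}

## ---- optimizer -------------------------------------------------------------

adam_init <- function(lr = 1e-3, beta1 = 0.9, beta2 = 0.999, eps = 1e-8,
                      weight_decay = 0) {
  list(lr = lr, beta1 = beta1, beta2 = beta2, eps = eps,
       weight_decay = weight_decay, t = 0L, m = list(), v = list())
}

.adam_update_params <- function(params, grads, opt, key) {
  for (p in names(params)) {
    k <- paste0(key, ".", p)
    g <- grads[[p]]
    if (is.null(opt$m[[k]])) {
      opt$m[[k]] <- g * 0
      opt$v[[k]] <- g * 0
    }
    opt$m[[k]] <- opt$beta1 * opt$m[[k]] + (1 - opt$beta1) * g
    opt$v[[k]] <- opt$beta2 * opt$v[[k]] + (1 - opt$beta2) * g * g
    mhat <- opt$m[[k]] / (1 - opt$beta1^opt$t)
    vhat <- opt$v[[k]] / (1 - opt$beta2^opt$t)
    params[[p]] <- params[[p]] - opt$lr * mhat / (sqrt(vhat) + opt$eps)
    if (opt$weight_decay > 0 && p == "W")  # decoupled decay, weights only
      params[[p]] <- params[[p]] * (1 - opt$lr * opt$weight_decay)
  }
  list(params = params, opt = opt)
}

adam_step <- function(net, grads, opt) {
  opt$t <- opt$t + 1L
  for (i in seq_along(net$layers)) {
    l <- net$layers[[i]]
    if (isTRUE(l$frozen)) next
    if (l$type == "resblock") {
      for (s in names(l$sub)) {
        if (isTRUE(l$sub[[s]]$frozen)) next
        gr <- grads[[i]][[s]]
        if (is.null(gr) || !length(gr)) next
        u <- .adam_update_params(l$sub[[s]]$params, gr, opt, l$sub[[s]]$name)
        l$sub[[s]]$params <- u$params
        opt <- u$opt
      }
    } else if (length(l$params)) {
      gr <- grads[[i]]
      if (!is.null(gr) && length(gr)) {
        u <- .adam_update_params(l$params, gr, opt, l$name)
        l$params <- u$params
        opt <- u$opt
      }
    }
    net$layers[[i]] <- l
  }
  list(net = net, opt = opt)
}

## ---- loss ------------------------------------------------------------------

# logits: (K x N); y: integer class in 0..K-1.
softmax_xent <- function(logits, y) {
  K <- nrow(logits)
  N <- ncol(logits)
  z <- logits - matrix(apply(logits, 2, max), K, N, byrow = TRUE)
  e <- exp(z)
  p <- e / matrix(colSums(e), K, N, byrow = TRUE)
  idx <- cbind(y + 1L, seq_len(N))
  loss <- -mean(log(pmax(p[idx], 1e-12)))
  grad <- p
  grad[idx] <- grad[idx] - 1
  grad <- grad / N
  list(loss = loss, probs = p, grad = grad)
}

softmax_probs <- function(logits) {
  K <- nrow(logits)
  N <- ncol(logits)
  z <- logits - matrix(apply(logits, 2, max), K, N, byrow = TRUE)
  e <- exp(z)
  e / matrix(colSums(e), K, N, byrow = TRUE)
}

## ---- parameter utilities ---------------------------------------------------

nn_collect_params <- function(net) {
  out <- list()
  for (l in net$layers) {
    if (l$type == "resblock") {
      for (s in l$sub) if (length(s$params)) out[[s$name]] <- s$params
    } else if (length(l$params)) {
      out[[l$name]] <- l$params
    }
  }
  out
}

nn_collect_states <- function(net) {
  out <- list()
  for (l in net$layers) {
    if (l$type == "resblock") {
      for (s in l$sub) if (!is.null(s$state)) out[[s$name]] <- s$state
    } else if (!is.null(l$state)) {
      out[[l$name]] <- l$state
    }
  }
  out
}

nn_restore <- function(net, params, states = NULL) {
  for (i in seq_along(net$layers)) {
    l <- net$layers[[i]]
    if (l$type == "resblock") {
      for (s in names(l$sub)) {
        nm <- l$sub[[s]]$name
        if (!is.null(params[[nm]])) {
          stopifnot(all(mapply(function(a, b) identical(dim(a), dim(b)) && length(a) == length(b),
                               l$sub[[s]]$params, params[[nm]])))
          l$sub[[s]]$params <- params[[nm]]
        }
        if (!is.null(states) && !is.null(states[[nm]])) l$sub[[s]]$state <- states[[nm]]
      }
    } else {
      if (!is.null(params[[l$name]])) l$params <- params[[l$name]]
      if (!is.null(states) && !is.null(states[[l$name]])) l$state <- states[[l$name]]
    }
    net$layers[[i]] <- l
  }
  net
}

nn_count_params <- function(net) {
  sum(vapply(unlist(nn_collect_params(net), recursive = FALSE), length, 1L))
}

nn_set_bn_freeze <- function(net, flag) {
  for (i in seq_along(net$layers)) {
    l <- net$layers[[i]]
    if (l$type == "bn") l$freeze_stats <- flag
    if (l$type == "resblock") {
      for (s in names(l$sub)) {
        if (l$sub[[s]]$type == "bn") l$sub[[s]]$freeze_stats <- flag
      }
    }
    net$layers[[i]] <- l
  }
  net
}

nn_set_frozen <- function(net, frozen, layers = NULL) {
  for (i in seq_along(net$layers)) {
    if (!is.null(layers) && !(net$layers[[i]]$name %in% layers)) next
    net$layers[[i]]$frozen <- frozen
    if (net$layers[[i]]$type == "resblock") {
      for (s in names(net$layers[[i]]$sub)) net$layers[[i]]$sub[[s]]$frozen <- frozen
    }
  }
  net
}

# Deterministic substream seed derived from a run seed and a label.
derive_seed <- function(seed, name) {
  h <- sum(utf8ToInt(name) * seq_along(utf8ToInt(name)))
  as.integer((as.numeric(seed) * 2654435L + h * 97L) %% 2147483647)
}
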