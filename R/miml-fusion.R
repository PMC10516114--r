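#' Fusion head configuration
#'
#' Widths of the multimodal fusion network: the image embedding `z1` (width
#' `n_cnn`) and the mechanical latent `z2` (width `n_mlp`) are concatenated
#' into `u` and passed through Linear-BatchNorm-ReLU to `h2_dim`, again to
#' `h3_dim`, then Linear-Softmax to `n_classes`.
#'
#' @param n_cnn Image-embedding width (must match the encoder).
#' @param n_mlp Mechanical-latent width.
#' @param h2_dim,h3_dim Intermediate fusion widths.
#' @param n_classes Number of classes.
#' @param d Mechanical feature dimensionality (3, or 4 with the deformation
#'   rate).
#' @return Object of class `miml_fusion_config`.
#' @export
fusion_config <- function(n_cnn = 512L, n_mlp = 16L, h2_dim = 64L,
                          h3_dim = 16L, n_classes = 2L, d = 3L) {
  stopifnot(n_classes >= 2, d >= 1)
  structure(list(n_cnn = as.integer(n_cnn), n_mlp = as.integer(n_mlp),
                 h2_dim = as.integer(h2_dim), h3_dim = as.integer(h3_dim),
                 n_classes = as.integer(n_classes), d = as.integer(d)),
            class = "miml_fusion_config")
}

#' Build the multimodal image-mechanics model
#'
#' Image branch: the residual encoder with its terminal fully connected
#' layer replaced by an identity mapping, so `z1` is the global-average-pool
#' embedding. Mechanical branch: a feed-forward net on the normalized
#' feature vector `m` (hidden sizes `mech_hidden`, last width = `n_mlp`).
#' Fusion head per the architecture above.
#'
#' @param encoder_cfg An [encoder_config()] (head forced to identity).
#' @param mech_hidden Hidden widths of the mechanical branch.
#' @param fusion_cfg A [fusion_config()]; `n_cnn` must equal the encoder
#'   embedding width.
#' @param seed Integer seed for initialization.
#' @return Object of class `miml_model`.
#' @export
build_fusion <- function(encoder_cfg, mech_hidden = c(32L, 16L),
                         fusion_cfg = NULL, seed = 1L) {
  stopifnot(inherits(encoder_cfg, "miml_encoder_config"))
  encoder_cfg$head <- "identity"
  emb <- embedding_width(encoder_cfg)
  if (is.null(fusion_cfg))
    fusion_cfg <- fusion_config(n_cnn = emb,
                                n_mlp = mech_hidden[length(mech_hidden)])
  stopifnot(inherits(fusion_cfg, "miml_fusion_config"))
  if (fusion_cfg$n_cnn != emb)
    stop("fusion_cfg$n_cnn (", fusion_cfg$n_cnn,
         ") does not match encoder embedding width (", emb, ")")
  if (fusion_cfg$n_mlp != mech_hidden[length(mech_hidden)])
    stop("fusion_cfg$n_mlp must equal the last mechanical hidden width")
  encoder <- build_encoder(encoder_cfg, seed = seed)
  set.seed(derive_seed(seed, "mech_init"))
  mech_layers <- list()
  d_in <- fusion_cfg$d
  for (i in seq_along(mech_hidden)) {
    mech_layers[[length(mech_layers) + 1L]] <-
      nn_linear(sprintf("mech_fc%d", i), d_in, mech_hidden[i])
    mech_layers[[length(mech_layers) + 1L]] <- nn_relu(sprintf("mech_relu%d", i))
    d_in <- mech_hidden[i]
  }
  set.seed(derive_seed(seed, "fusion_init"))
  u_dim <- fusion_cfg$n_cnn + fusion_cfg$n_mlp
  fusion_layers <- list(
    nn_linear("fuse_fc1", u_dim, fusion_cfg$h2_dim),
    nn_bn("fuse_bn1", fusion_cfg$h2_dim),
    nn_relu("fuse_relu1"),
    nn_linear("fuse_fc2", fusion_cfg$h2_dim, fusion_cfg$h3_dim),
    nn_bn("fuse_bn2", fusion_cfg$h3_dim),
    nn_relu("fuse_relu2"),
    nn_linear("fuse_fc3", fusion_cfg$h3_dim, fusion_cfg$n_classes)
  )
  structure(list(encoder = encoder,
                 mech = list(layers = mech_layers),
                 fusion = list(layers = fusion_layers),
                 encoder_cfg = encoder_cfg, fusion_cfg = fusion_cfg,
                 mech_hidden = as.integer(mech_hidden),
                 norm_bounds = NULL, class_map = NULL),
            class = "miml_model")
}

# Full forward pass. images: list/array; m: N x d matrix.
# Returns probs (N x K), u (u_dim x N), plus caches when training.
miml_forward <- function(model, images, m, training = FALSE) {
  x <- images_to_fmap(images, model$encoder_cfg$in_channels)
  n <- x$n
  m <- as.matrix(m)
  if (nrow(m) != n) stop("mechanical features: expected ", n, " rows, got ", nrow(m))
  if (ncol(m) != model$fusion_cfg$d)
    stop("mechanical feature width ", ncol(m), " does not match d = ",
         model$fusion_cfg$d)
  if (anyNA(m)) stop("missing mechanical features for example(s) ",
                     paste(which(rowSums(is.na(m)) > 0), collapse = ", "))
  fe <- nn_forward(model$encoder$net, x, training)
  z1 <- fe$out                       # (n_cnn x N)
  fm <- nn_forward(model$mech, t(m), training)
  z2 <- fm$out                       # (n_mlp x N)
  u <- rbind(z1, z2)                 # fixed order: image latent then mech
  ff <- nn_forward(model$fusion, u, training)
  model$encoder$net <- fe$net
  model$mech <- fm$net
  model$fusion <- ff$net
  list(logits = ff$out, probs = softmax_probs(ff$out), u = u, model = model,
       caches = list(enc = fe$caches, mech = fm$caches, fus = ff$caches))
}

miml_backward_step <- function(model, fw, grad_logits, opt) {
  bw_f <- nn_backward(model$fusion, fw$caches$fus, grad_logits)
  gu <- bw_f$gin
  n_cnn <- model$fusion_cfg$n_cnn
  g_z1 <- gu[seq_len(n_cnn), , drop = FALSE]
  g_z2 <- gu[-seq_len(n_cnn), , drop = FALSE]
  bw_e <- nn_backward(model$encoder$net, fw$caches$enc, g_z1)
  bw_m <- nn_backward(model$mech, fw$caches$mech, g_z2)
  big <- list(layers = c(model$encoder$net$layers, model$mech$layers,
                         model$fusion$layers))
  grads <- c(bw_e$grads, bw_m$grads, bw_f$grads)
  st <- adam_step(big, grads, opt)
  ne <- length(model$encoder$net$layers)
  nm <- length(model$mech$layers)
  model$encoder$net$layers <- st$net$layers[seq_len(ne)]
  model$mech$layers <- st$net$layers[ne + seq_len(nm)]
  model$fusion$layers <- st$net$layers[(ne + nm + 1):length(st$net$layers)]
  list(model = model, opt = st$opt)
}

miml_params <- function(model) {
  list(enc = nn_collect_params(model$encoder$net),
       mech = nn_collect_params(model$mech),
       fus = nn_collect_params(model$fusion))
}

miml_states <- function(model) {
  list(enc = nn_collect_states(model$encoder$net),
       mech = nn_collect_states(model$mech),
       fus = nn_collect_states(model$fusion))
}

miml_restore <- function(model, params, states = NULL) {
  model$encoder$net <- nn_restore(model$encoder$net, params$enc, states$enc)
  model$mech <- nn_restore(model$mech, params$mech, states$mech)
  model$fusion <- nn_restore(model$fusion, params$fus, states$fus)
  model
}

#' Predict class probabilities with a fused model
#'
#' @param model A trained `miml_model`.
#' @param images List of H x W matrices (or H x W x N array).
#' @param m N x d matrix of normalized mechanical features.
#' @param batch_size Evaluation batch size.
#' @return N x n_classes probability matrix (rows sum to 1).
#' @export
miml_predict_prob <- function(model, images, m, batch_size = 64L) {
  n <- if (is.list(images)) length(images) else dim(images)[3]
  probs <- NULL
  for (start in seq(1L, n, by = batch_size)) {
    idx <- start:min(start + batch_size - 1L, n)
    sub <- if (is.list(images)) images[idx] else images[, , idx, drop = FALSE]
    fw <- miml_forward(model, sub, m[idx, , drop = FALSE], training = FALSE)
    probs <- rbind(probs, t(fw$probs))
  }
  probs
}

#' Train the multimodal model end to end
#'
#' Both branches and the fusion head are optimised jointly with Adam on
#' cross-entropy. Splits must be disjoint by cell id; normalization bounds
#' must have been fitted on the training split only. The best-validation
#' epoch's parameters are retained.
#'
#' @param model A `miml_model` from [build_fusion()].
#' @param train,val Lists with `images`, `m` (N x d, normalized), `y`
#'   (integer 0/1), `cell_ids`.
#' @param epochs Training epochs.
#' @param seed Integer seed.
#' @param batch_size Minibatch size.
#' @param lr Adam learning rate.
#' @return List: `model`, `history`, `best_epoch`.
#' @export
train_miml <- function(model, train, val, epochs = 15L, seed = 1L,
                       batch_size = 32L, lr = 1e-3, weight_decay = 0) {
  stopifnot(inherits(model, "miml_model"))
  if (length(intersect(unique(train$cell_ids), unique(val$cell_ids))) > 0)
    stop("leakage: cell_ids overlap between train and val splits")
  opt <- adam_init(lr = lr, weight_decay = weight_decay)
  n <- length(train$images)
  hist <- data.frame(epoch = integer(), train_acc = double(), val_acc = double())
  best <- list(acc = -Inf, params = miml_params(model),
               states = miml_states(model), epoch = 0L)
  set.seed(derive_seed(seed, "train_miml"))
  if (epochs >= 1L) for (ep in seq_len(epochs)) {
    perm <- sample.int(n)
    correct <- 0L; seen <- 0L
    for (start in seq(1L, n, by = batch_size)) {
      idx <- perm[start:min(start + batch_size - 1L, n)]
      if (length(idx) < 2L) next
      fw <- miml_forward(model, train$images[idx],
                         train$m[idx, , drop = FALSE], training = TRUE)
      model <- fw$model
      lo <- softmax_xent(fw$logits, train$y[idx])
      correct <- correct + sum(max.col(t(lo$probs)) - 1L == train$y[idx])
      seen <- seen + length(idx)
      st <- miml_backward_step(model, fw, lo$grad, opt)
      model <- st$model; opt <- st$opt
    }
    # train accuracy accumulated over the epoch's minibatches
    tr_acc <- correct / seen
    va_acc <- mean(max.col(miml_predict_prob(model, val$images, val$m)) - 1L == val$y)
    hist <- rbind(hist, data.frame(epoch = ep, train_acc = tr_acc, val_acc = va_acc))
    if (va_acc > best$acc) {
      best <- list(acc = va_acc, params = miml_params(model),
                   states = miml_states(model), epoch = ep)
    }
  }
  model <- miml_restore(model, best$params, best$states)
  list(model = model, history = hist, best_epoch = best$epoch)
}

#' Fused latent vectors
#'
#' Returns the concatenated latent `u = [z1; z2]` per example (image latent
#' first; the order is fixed and serialized with checkpoints). 2-D reduction
#' for plotting is delegated to [embed_2d()].
#'
#' @inheritParams miml_predict_prob
#' @return N x (n_cnn + n_mlp) matrix.
#' @export
extract_latent <- function(model, images, m, batch_size = 64L) {
  n <- if (is.list(images)) length(images) else dim(images)[3]
  out <- NULL
  for (start in seq(1L, n, by = batch_size)) {
    idx <- start:min(start + batch_size - 1L, n)
    sub <- if (is.list(images)) images[idx] else images[, , idx, drop = FALSE]
    fw <- miml_forward(model, sub, m[idx, , drop = FALSE], training = FALSE)
    out <- rbind(out, t(fw$u))
  }
  out
}

#' Fine-tune a pretrained model on a small related task
#'
#' Re-initializes only the final classification layer and continues training
#' under a freeze policy: `"none"` (all weights trainable), `"encoder"`
#' (image branch frozen), or `"all-but-head"` (only the re-initialized final
#' layer trains).
#'
#' @param model A pretrained `miml_model` (e.g. from [load_checkpoint()]).
#' @param train,val Target-task splits as in [train_miml()].
#' @param epochs Fine-tuning epochs (default 30).
#' @param freeze Freeze policy.
#' @param seed Integer seed.
#' @param lr Adam learning rate.
#' @param batch_size Minibatch size; smaller than the from-scratch default
#'   so a tiny fine-tuning set still yields several updates per epoch.
#' @param weight_decay Decoupled L2 decay on weight matrices during
#'   fine-tuning; regularizes the re-initialized head against the very small
#'   sample.
#' @return List: `model`, `history`, `best_epoch`.
#' @export
fine_tune <- function(model, train, val, epochs = 30L,
                      freeze = c("none", "encoder", "all-but-head"),
                      seed = 1L, lr = 1e-3, batch_size = 8L,
                      weight_decay = 0.05) {
  freeze <- match.arg(freeze)
  stopifnot(inherits(model, "miml_model"))
  set.seed(derive_seed(seed, "finetune_head"))
  k <- length(model$fusion$layers)
  head <- model$fusion$layers[[k]]
  model$fusion$layers[[k]] <- nn_linear(head$name, head$d_in, head$d_out)
  # batch-norm statistics stay at their pretrained values: the fine-tuning
  # batches are far too small to re-estimate them stably
  model$encoder$net <- nn_set_bn_freeze(model$encoder$net, TRUE)
  model$mech <- nn_set_bn_freeze(model$mech, TRUE)
  model$fusion <- nn_set_bn_freeze(model$fusion, TRUE)
  if (freeze == "encoder") {
    model$encoder$net <- nn_set_frozen(model$encoder$net, TRUE)
  } else if (freeze == "all-but-head") {
    model$encoder$net <- nn_set_frozen(model$encoder$net, TRUE)
    model$mech <- nn_set_frozen(model$mech, TRUE)
    model$fusion <- nn_set_frozen(model$fusion, TRUE)
    model$fusion$layers[[k]]$frozen <- FALSE
  }
  out <- train_miml(model, train, val, epochs = epochs, seed = seed, lr = lr,
                    batch_size = batch_size, weight_decay = weight_decay)
  out$model$encoder$net <- nn_set_frozen(out$model$encoder$net, FALSE)
  out$model$mech <- nn_set_frozen(out$model$mech, FALSE)
  out$model$fusion <- nn_set_frozen(out$model$fusion, FALSE)
  out$model$encoder$net <- nn_set_bn_freeze(out$model$encoder$net, FALSE)
  out$model$mech <- nn_set_bn_freeze(out$model$mech, FALSE)
  out$model$fusion <- nn_set_bn_freeze(out$model$fusion, FALSE)
  out
}

## ---- checkpoints ------------------------------------------------------------

#' Save a model checkpoint
#'
#' Single-file archive embedding the architecture configs, weights, batch
#' norm statistics, normalization bounds and class map, with a versioned
#' schema field.
#'
#' @param model A `miml_model` or `miml_encoder`.
#' @param path Output file path.
#' @param norm_bounds Normalization bounds fitted on the training split.
#' @param class_map Named list mapping class index (0/1) to class name.
#' @return Invisibly, `path`.
#' @export
save_checkpoint <- function(model, path, norm_bounds = NULL, class_map = NULL) {
  ck <- if (inherits(model, "miml_model")) {
    list(schema = 1L, kind = "miml",
         encoder_cfg = model$encoder_cfg, fusion_cfg = model$fusion_cfg,
         mech_hidden = model$mech_hidden,
         params = miml_params(model), states = miml_states(model),
         norm_bounds = norm_bounds %||% model$norm_bounds,
         class_map = class_map %||% model$class_map,
         latent_order = c("z1_image", "z2_mech"))
  } else if (inherits(model, "miml_encoder")) {
    list(schema = 1L, kind = "cnn", encoder_cfg = model$config,
         n_classes = model$n_classes,
         params = nn_collect_params(model$net),
         states = nn_collect_states(model$net),
         norm_bounds = norm_bounds, class_map = class_map)
  } else stop("unsupported model class")
  saveRDS(ck, path)
  invisible(path)
}

#' Load a model checkpoint
#'
#' Rebuilds the architecture from the stored configs and restores weights.
#' A shape mismatch (e.g. loading into a different architecture) raises an
#' error listing the differing parameter shapes.
#'
#' @param path Checkpoint file from [save_checkpoint()].
#' @return A `miml_model` or `miml_encoder`.
#' @export
load_checkpoint <- function(path) {
  ck <- readRDS(path)
  if (is.null(ck$schema)) stop("not a recognised checkpoint file")
  if (ck$kind == "miml") {
    model <- build_fusion(ck$encoder_cfg, mech_hidden = ck$mech_hidden,
                          fusion_cfg = ck$fusion_cfg, seed = 1L)
    check_param_shapes(miml_params(model), ck$params)
    model <- miml_restore(model, ck$params, ck$states)
    model$norm_bounds <- ck$norm_bounds
    model$class_map <- ck$class_map
    model
  } else {
    enc <- build_encoder(ck$encoder_cfg, n_classes = ck$n_classes, seed = 1L)
    check_param_shapes(list(x = nn_collect_params(enc$net)), list(x = ck$params))
    enc$net <- nn_restore(enc$net, ck$params, ck$states)
    enc
  }
}

check_param_shapes <- function(built, stored) {
  bad <- character()
  for (grp in names(built)) {
    for (lay in names(built[[grp]])) {
      for (p in names(built[[grp]][[lay]])) {
        a <- built[[grp]][[lay]][[p]]
        b <- stored[[grp]][[lay]][[p]]
        if (is.null(b) || length(a) != length(b) ||
            !identical(dim(a), dim(b)))
          bad <- c(bad, sprintf("%s/%s/%s: built %s vs stored %s",
                                grp, lay, p,
                                paste(dim(a) %||% length(a), collapse = "x"),
                                paste(dim(b) %||% length(b), collapse = "x")))
      }
    }
  }
  if (length(bad))
    stop("checkpoint architecture mismatch:\n  ", paste(bad, collapse = "\n  "))
  invisible(TRUE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
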