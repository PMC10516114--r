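#' Residual encoder configuration
#'
#' The encoder is a residual CNN: a 7x7 stride-2 stem convolution with batch
#' normalization, ReLU and 3x3 stride-2 max pooling, followed by `stages`
#' stages of residual blocks. Filters start at `base_filters` and double each
#' stage; stages 2..4 downsample with stride 2 in their first block, where a
#' 1x1 projection convolution matches the shortcut dimensions. A global
#' average pool yields the embedding (width `base_filters * 2^(stages-1)`),
#' optionally followed by a fully connected classifier head.
#'
#' @param in_channels Image channels (grayscale default).
#' @param base_filters Filters in stage 1 (64 for the reference
#'   architecture; smaller values give a desk-scale encoder).
#' @param stages Number of stages.
#' @param blocks_per_stage Residual blocks per stage.
#' @param input_size Expected square input size in pixels (build-time shape
#'   check).
#' @param head `"classifier"` or `"identity"` (embedding output).
#' @return Object of class `miml_encoder_config`.
#' @export
encoder_config <- function(in_channels = 1L, base_filters = 64L, stages = 4L,
                           blocks_per_stage = 2L, input_size = 64L,
                           head = c("classifier", "identity")) {
  head <- match.arg(head)
  stopifnot(base_filters >= 1, stages >= 1, blocks_per_stage >= 1)
  structure(list(in_channels = as.integer(in_channels),
                 base_filters = as.integer(base_filters),
                 stages = as.integer(stages),
                 blocks_per_stage = as.integer(blocks_per_stage),
                 input_size = as.integer(input_size), head = head),
            class = "miml_encoder_config")
}

#' Embedding width implied by an encoder configuration
#' @param config A [encoder_config()].
#' @return Integer embedding width (`base_filters * 2^(stages-1)`).
#' @export
embedding_width <- function(config) {
  as.integer(config$base_filters * 2^(config$stages - 1L))
}

#' Build the residual image encoder
#'
#' @param config A [encoder_config()].
#' @param n_classes Classes for the classifier head (ignored for identity).
#' @param seed Integer seed for weight initialization.
#' @return Object of class `miml_encoder`: the layer list plus metadata.
#' @export
build_encoder <- function(config, n_classes = 2L, seed = 1L) {
  stopifnot(inherits(config, "miml_encoder_config"))
  # shape audit: stem conv + pool + (stages-1) downsamples, each stride 2
  size <- config$input_size
  reductions <- 2L + (config$stages - 1L)
  if (size < 2L^reductions)
    stop("input ", size, "x", size, " too small to survive ", reductions,
         " stride-2 reductions (needs at least ", 2L^reductions, " px)")
  set.seed(derive_seed(seed, "encoder_init"))
  layers <- list(
    nn_conv("stem_conv", config$in_channels, config$base_filters, 7L, 2L, 3L),
    nn_bn("stem_bn", config$base_filters),
    nn_relu("stem_relu"),
    nn_maxpool("stem_pool", 3L, 2L, 1L)
  )
  in_c <- config$base_filters
  for (st in seq_len(config$stages)) {
    out_c <- config$base_filters * 2L^(st - 1L)
    for (bl in seq_len(config$blocks_per_stage)) {
      stride <- if (st > 1L && bl == 1L) 2L else 1L
      layers[[length(layers) + 1L]] <-
        nn_resblock(sprintf("stage%d_block%d", st, bl), in_c, out_c, stride)
      in_c <- out_c
    }
  }
  layers[[length(layers) + 1L]] <- nn_gap("gap")
  if (config$head == "classifier")
    layers[[length(layers) + 1L]] <-
      nn_linear("fc", embedding_width(config), n_classes)
  structure(list(net = list(layers = layers), config = config,
                 n_classes = as.integer(n_classes)),
            class = "miml_encoder")
}

# Images (list of H x W matrices, or H x W x N array) -> fmap with C channels.
images_to_fmap <- function(images, channels = 1L) {
  if (is.list(images)) {
    h <- nrow(images[[1]]); w <- ncol(images[[1]])
    if (!all(vapply(images, function(m) nrow(m) == h && ncol(m) == w, TRUE)))
      stop("all frames in a batch must share the same size")
    arr <- array(unlist(images, use.names = FALSE), c(h, w, length(images)))
  } else {
    arr <- images
    if (length(dim(arr)) == 2) dim(arr) <- c(dim(arr), 1L)
    h <- dim(arr)[1]; w <- dim(arr)[2]
  }
  if (channels != 1L) stop("only single-channel images are supported here")
  fmap(matrix(as.numeric(arr), nrow = 1L), h, w, dim(arr)[3])
}

#' Encode images into embeddings
#'
#' @param encoder A `miml_encoder` built with `head = "identity"` (for a
#'   classifier-head encoder the penultimate activations are returned, which
#'   are identical by construction).
#' @param images List of H x W matrices or an H x W x N array.
#' @return N x embedding_width matrix, rows in batch order.
#' @export
encode <- function(encoder, images) {
  stopifnot(inherits(encoder, "miml_encoder"))
  x <- images_to_fmap(images, encoder$config$in_channels)
  net <- encoder$net
  if (encoder$config$head == "classifier") {
    # stop before the fc head: embeddings are the GAP output
    net$layers <- net$layers[seq_len(length(net$layers) - 1L)]
  }
  out <- nn_forward(net, x, training = FALSE)$out
  t(out)
}

#' Class probabilities from the image-only classifier
#'
#' Eval-mode forward pass in batches.
#'
#' @param encoder A `miml_encoder` with classifier head.
#' @param images List of H x W matrices or an H x W x N array.
#' @param batch_size Evaluation batch size.
#' @return N x n_classes probability matrix.
#' @export
encoder_predict_prob <- function(encoder, images, batch_size = 64L) {
  stopifnot(encoder$config$head == "classifier")
  n <- if (is.list(images)) length(images) else dim(images)[3]
  probs <- NULL
  for (start in seq(1L, n, by = batch_size)) {
    idx <- start:min(start + batch_size - 1L, n)
    sub <- if (is.list(images)) images[idx] else images[, , idx, drop = FALSE]
    x <- images_to_fmap(sub)
    logits <- nn_forward(encoder$net, x, training = FALSE)$out
    probs <- rbind(probs, t(softmax_probs(logits)))
  }
  probs
}

# Shared epoch loop for image-based models. `batch_fn(idx, training)` returns
# list(loss-ready forward); here specialised for the plain image classifier.
#' Train the image-only classifier
#'
#' Trains encoder + classifier head with Adam on cross-entropy, recording
#' train/validation accuracy per epoch and retaining the parameters of the
#' best-validation epoch. Splits must be disjoint by cell id.
#'
#' @param encoder A `miml_encoder` with classifier head.
#' @param train,val Lists with `images` (list of H x W matrices), `y`
#'   (integer 0/1), `cell_ids`.
#' @param epochs Training epochs (the reference protocol stabilises by 40;
#'   desk-scale runs use fewer).
#' @param seed Integer seed.
#' @param batch_size Minibatch size.
#' @param lr Adam learning rate.
#' @return List: `model` (best-validation encoder), `history` (data.frame
#'   epoch/train_acc/val_acc), `best_epoch`.
#' @export
train_image_classifier <- function(encoder, train, val, epochs = 40L,
                                   seed = 1L, batch_size = 32L, lr = 1e-3) {
  stopifnot(inherits(encoder, "miml_encoder"),
            encoder$config$head == "classifier")
  if (length(intersect(unique(train$cell_ids), unique(val$cell_ids))) > 0)
    stop("leakage: cell_ids overlap between train and val splits")
  net <- encoder$net
  opt <- adam_init(lr = lr)
  n <- length(train$images)
  hist <- data.frame(epoch = integer(), train_acc = double(), val_acc = double())
  best <- list(acc = -Inf, params = nn_collect_params(net),
               states = nn_collect_states(net), epoch = 0L)
  set.seed(derive_seed(seed, "train_cnn"))
  if (epochs >= 1L) for (ep in seq_len(epochs)) {
    perm <- sample.int(n)
    correct <- 0L; seen <- 0L
    for (start in seq(1L, n, by = batch_size)) {
      idx <- perm[start:min(start + batch_size - 1L, n)]
      if (length(idx) < 2L) next  # batch norm needs >= 2 samples
      x <- images_to_fmap(train$images[idx])
      fw <- nn_forward(net, x, training = TRUE)
      net <- fw$net
      lo <- softmax_xent(fw$out, train$y[idx])
      correct <- correct + sum(max.col(t(lo$probs)) - 1L == train$y[idx])
      seen <- seen + length(idx)
      bw <- nn_backward(net, fw$caches, lo$grad)
      st <- adam_step(net, bw$grads, opt)
      net <- st$net; opt <- st$opt
    }
    # train accuracy accumulated over the epoch's minibatches
    tr_acc <- correct / seen
    enc_ep <- encoder; enc_ep$net <- net
    va_acc <- mean(max.col(encoder_predict_prob(enc_ep, val$images)) - 1L == val$y)
    hist <- rbind(hist, data.frame(epoch = ep, train_acc = tr_acc, val_acc = va_acc))
    if (va_acc > best$acc) {
      best <- list(acc = va_acc, params = nn_collect_params(net),
                   states = nn_collect_states(net), epoch = ep)
    }
  }
  net <- nn_restore(net, best$params, best$states)
  encoder$net <- net
  list(model = encoder, history = hist, best_epoch = best$epoch)
}
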