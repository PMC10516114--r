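# Classical classifiers for the mechanical-feature comparison. The decision
# tree, random forest, KNN and RBF-kernel SVM are implemented in-package
# (no suitable backends in the supported dependency set); logistic
# regression uses glmnet ridge; the feed-forward network uses the in-package
# engine. Hyperparameters follow conventional defaults and are recorded on
# the fitted object.

#' Tabular model specification
#'
#' @param kind One of `"lr"`, `"svm"`, `"dt"`, `"rf"`, `"knn"`, `"mlp"`.
#' @param seed Integer seed (recorded in all outputs).
#' @param k Neighbour count for KNN (separate formal so that
#'   `tabular_spec("knn", k = 1)` does not partially match `kind`).
#' @param ... Hyperparameter overrides (e.g. `C`, `n_trees`, `max_depth`,
#'   `epochs`).
#' @return Object of class `miml_tabular_spec`.
#' @export
tabular_spec <- function(kind = c("lr", "svm", "dt", "rf", "knn", "mlp"),
                         seed = 1L, k = NULL, ...) {
  kind <- match.arg(kind)
  extra <- list(...)
  if (!is.null(k)) extra$k <- k
  hyper <- utils::modifyList(switch(kind,
    lr = list(C = 1),
    svm = list(C = 1, gamma = NULL, sweeps = 40L),
    dt = list(max_depth = Inf, min_n = 2L),
    rf = list(n_trees = 100L, max_depth = Inf, min_n = 2L),
    knn = list(k = 5L),
    mlp = list(hidden = c(32L, 16L), epochs = 200L, lr = 1e-3,
               patience = 40L, batch_size = 32L)
  ), extra)
  structure(list(kind = kind, hyper = hyper, seed = as.integer(seed)),
            class = "miml_tabular_spec")
}

## ---- CART -------------------------------------------------------------------

gini_best_split <- function(x, y) {
  ord <- order(x)
  xs <- x[ord]; ys <- y[ord]
  n <- length(ys)
  cum1 <- cumsum(ys)
  tot1 <- cum1[n]
  i <- seq_len(n - 1L)
  valid <- xs[i] < xs[i + 1L]
  if (!any(valid)) return(NULL)
  nl <- i; nr <- n - i
  p1l <- cum1[i] / nl; p1r <- (tot1 - cum1[i]) / nr
  gl <- 2 * p1l * (1 - p1l); gr <- 2 * p1r * (1 - p1r)
  score <- (nl * gl + nr * gr) / n
  score[!valid] <- Inf
  bi <- which.min(score)
  list(threshold = (xs[bi] + xs[bi + 1L]) / 2, score = score[bi])
}

fit_tree_node <- function(X, y, depth, max_depth, min_n, mtry) {
  n <- length(y)
  p1 <- mean(y)
  if (n < min_n || depth >= max_depth || p1 == 0 || p1 == 1)
    return(list(leaf = TRUE, prob = p1, n = n))
  feats <- if (mtry < ncol(X)) sort(sample.int(ncol(X), mtry)) else seq_len(ncol(X))
  best <- NULL
  for (j in feats) {
    sp <- gini_best_split(X[, j], y)
    if (!is.null(sp) && (is.null(best) || sp$score < best$score - 1e-12))
      best <- list(feature = j, threshold = sp$threshold, score = sp$score)
  }
  if (is.null(best)) return(list(leaf = TRUE, prob = p1, n = n))
  go <- X[, best$feature] <= best$threshold
  if (!any(go) || all(go)) return(list(leaf = TRUE, prob = p1, n = n))
  list(leaf = FALSE, feature = best$feature, threshold = best$threshold,
       left = fit_tree_node(X[go, , drop = FALSE], y[go], depth + 1L,
                            max_depth, min_n, mtry),
       right = fit_tree_node(X[!go, , drop = FALSE], y[!go], depth + 1L,
                             max_depth, min_n, mtry))
}

predict_tree <- function(node, X) {
  n <- nrow(X)
  out <- numeric(n)
  rec <- function(node, idx) {
    if (!length(idx)) return()
    if (node$leaf) {
      out[idx] <<- node$prob
      return()
    }
    go <- X[idx, node$feature] <= node$threshold
    rec(node$left, idx[go])
    rec(node$right, idx[!go])
  }
  rec(node, seq_len(n))
  out
}

## ---- RBF-kernel SVM (Pegasos) ----------------------------------------------

rbf_kernel <- function(A, B, gamma) {
  an <- rowSums(A^2); bn <- rowSums(B^2)
  d2 <- outer(an, bn, "+") - 2 * A %*% t(B)
  exp(-gamma * pmax(d2, 0))
}

fit_svm_pegasos <- function(X, y01, C, gamma, sweeps, seed) {
  n <- nrow(X)
  y <- ifelse(y01 == 1, 1, -1)
  if (is.null(gamma)) {
    v <- mean(apply(X, 2, stats::var))
    gamma <- 1 / (ncol(X) * max(v, 1e-8))   # sklearn-style 'scale'
  }
  lambda <- 1 / (n * C)
  K <- rbf_kernel(X, X, gamma)
  alpha <- numeric(n)
  set.seed(derive_seed(seed, "svm"))
  Tt <- sweeps * n
  order_all <- sample.int(n, Tt, replace = TRUE)
  for (t in seq_len(Tt)) {
    i <- order_all[t]
    f <- sum(alpha * y * K[, i]) / (lambda * t)
    if (y[i] * f < 1) alpha[i] <- alpha[i] + 1
  }
  decision <- as.numeric((K %*% (alpha * y)) / (lambda * Tt))
  # Platt scaling on training decisions for probability output
  platt <- suppressWarnings(stats::glm(y01 ~ decision, family = stats::binomial()))
  list(alpha = alpha, y = y, X = X, gamma = gamma, lambda = lambda, T = Tt,
       platt = stats::coef(platt))
}

predict_svm <- function(fit, X) {
  K <- rbf_kernel(fit$X, X, fit$gamma)
  dec <- as.numeric(crossprod(K, fit$alpha * fit$y) / (fit$lambda * fit$T))
  eta <- fit$platt[1] + fit$platt[2] * dec
  list(decision = dec, prob = 1 / (1 + exp(-eta)))
}

## ---- fitting front end ------------------------------------------------------

#' Fit a tabular classifier on mechanical features
#'
#' @param spec A [tabular_spec()].
#' @param data List with `X` (numeric matrix in \[0,1\]) and `y` (integer 0/1
#'   labels), e.g. from [feature_matrix()].
#' @return Object of class `miml_tabular_model` supporting
#'   [predict.miml_tabular_model()] for classes and probabilities.
#' @export
fit_classifier <- function(spec, data) {
  stopifnot(inherits(spec, "miml_tabular_spec"))
  X <- as.matrix(data$X); y <- as.integer(data$y)
  if (anyNA(X) || anyNA(y)) stop("feature matrix must not contain missing values")
  if (length(unique(y)) < 2) stop("single-class input: need both classes to fit")
  if (min(table(y)) < 2) stop("need at least 2 rows per class")
  h <- spec$hyper
  fit <- switch(spec$kind,
    lr = {
      if (ncol(X) >= 2) {
        glmnet::glmnet(X, y, family = "binomial", alpha = 0,
                       lambda = 1 / (nrow(X) * h$C), standardize = FALSE)
      } else {
        df <- data.frame(y = y, x1 = X[, 1])
        suppressWarnings(stats::glm(y ~ ., data = df, family = stats::binomial()))
      }
    },
    svm = fit_svm_pegasos(X, y, h$C, h$gamma, h$sweeps, spec$seed),
    dt = {
      set.seed(derive_seed(spec$seed, "dt"))
      fit_tree_node(X, y, 0L, h$max_depth, h$min_n, ncol(X))
    },
    rf = {
      set.seed(derive_seed(spec$seed, "rf"))
      mtry <- max(1L, floor(sqrt(ncol(X))))
      lapply(seq_len(h$n_trees), function(b) {
        idx <- sample.int(nrow(X), replace = TRUE)
        fit_tree_node(X[idx, , drop = FALSE], y[idx], 0L,
                      h$max_depth, h$min_n, mtry)
      })
    },
    knn = list(X = X, y = y, k = h$k),
    mlp = fit_feature_mlp(data, seed = spec$seed, hidden = h$hidden,
                          epochs = h$epochs, lr = h$lr,
                          patience = h$patience, batch_size = h$batch_size)
  )
  structure(list(kind = spec$kind, spec = spec, fit = fit, d = ncol(X)),
            class = "miml_tabular_model")
}

#' Predict method for tabular classifiers
#'
#' @param object A `miml_tabular_model`.
#' @param newdata Numeric feature matrix.
#' @param type `"class"` (0/1) or `"prob"` (probability of class 1).
#' @param ... Unused.
#' @export
predict.miml_tabular_model <- function(object, newdata, type = c("class", "prob"), ...) {
  type <- match.arg(type)
  X <- as.matrix(newdata)
  p <- switch(object$kind,
    lr = {
      if (inherits(object$fit, "glmnet")) {
        as.numeric(stats::predict(object$fit, X, type = "response"))
      } else {
        as.numeric(stats::predict(object$fit,
                                  data.frame(x1 = X[, 1]), type = "response"))
      }
    },
    svm = predict_svm(object$fit, X)$prob,
    dt = predict_tree(object$fit, X),
    rf = {
      preds <- vapply(object$fit, function(tree) predict_tree(tree, X),
                      numeric(nrow(X)))
      rowMeans(matrix(preds, nrow = nrow(X)))
    },
    knn = {
      f <- object$fit
      d2 <- outer(rowSums(X^2), rowSums(f$X^2), "+") - 2 * X %*% t(f$X)
      apply(d2, 1, function(dr) {
        nn <- order(dr)[seq_len(f$k)]  # stable order: lowest index on ties
        mean(f$y[nn])
      })
    },
    mlp = predict_feature_mlp(object$fit, X)
  )
  if (type == "prob") p else as.integer(p > 0.5)
}

## ---- feature MLP ------------------------------------------------------------

#' Fit the feed-forward network on mechanical features
#'
#' Architecture d -> 32 -> 16 -> 2 with ReLU hidden activations and a 2-way
#' softmax output (706 trainable parameters for d = 3). Trained with Adam on
#' cross-entropy, early-stopping on a validation plateau.
#'
#' @param data List with `X` (n x d matrix) and `y` (0/1).
#' @param seed Integer seed.
#' @param hidden Hidden-layer widths.
#' @param epochs Maximum epochs.
#' @param lr Learning rate.
#' @param patience Early-stop patience (epochs without val improvement).
#' @param batch_size Minibatch size.
#' @return Object of class `miml_feature_mlp`.
#' @export
fit_feature_mlp <- function(data, seed = 1L, hidden = c(32L, 16L),
                            epochs = 200L, lr = 1e-3, patience = 20L,
                            batch_size = 32L) {
  X <- as.matrix(data$X); y <- as.integer(data$y)
  d <- ncol(X)
  if (d == 0) stop("feature matrix has no columns")
  net <- build_feature_mlp_net(d, hidden, n_classes = 2L, seed = seed)
  set.seed(derive_seed(seed, "mlp_train"))
  n <- nrow(X)
  # stratified 15% validation split for early stopping
  val_idx <- unlist(lapply(split(seq_len(n), y), function(ix) {
    k <- max(1L, round(0.15 * length(ix)))
    sample(ix, k)
  }))
  tr_idx <- setdiff(seq_len(n), val_idx)
  if (!length(tr_idx)) tr_idx <- seq_len(n)
  opt <- adam_init(lr = lr)
  best <- list(loss = Inf, params = nn_collect_params(net),
               states = nn_collect_states(net), since = 0L)
  for (ep in seq_len(epochs)) {
    perm <- sample(tr_idx)
    for (start in seq(1L, length(perm), by = batch_size)) {
      idx <- perm[start:min(start + batch_size - 1L, length(perm))]
      fw <- nn_forward(net, t(X[idx, , drop = FALSE]), training = TRUE)
      net <- fw$net
      lo <- softmax_xent(fw$out, y[idx])
      bw <- nn_backward(net, fw$caches, lo$grad)
      st <- adam_step(net, bw$grads, opt)
      net <- st$net; opt <- st$opt
    }
    # early stop on validation-loss plateau (less noisy than accuracy at
    # desk-scale validation sizes)
    fv <- nn_forward(net, t(X[val_idx, , drop = FALSE]))
    vl <- softmax_xent(fv$out, y[val_idx])$loss
    if (vl < best$loss - 1e-5) {
      best <- list(loss = vl, params = nn_collect_params(net),
                   states = nn_collect_states(net), since = 0L)
    } else {
      best$since <- best$since + 1L
      if (best$since >= patience) break
    }
  }
  net <- nn_restore(net, best$params, best$states)
  structure(list(net = net, d = d, hidden = hidden, seed = seed),
            class = "miml_feature_mlp")
}

build_feature_mlp_net <- function(d, hidden = c(32L, 16L), n_classes = 2L,
                                  seed = 1L) {
  set.seed(derive_seed(seed, "mlp_init"))
  layers <- list()
  d_in <- d
  for (i in seq_along(hidden)) {
    layers[[length(layers) + 1L]] <- nn_linear(sprintf("mlp_fc%d", i), d_in, hidden[i])
    layers[[length(layers) + 1L]] <- nn_relu(sprintf("mlp_relu%d", i))
    d_in <- hidden[i]
  }
  layers[[length(layers) + 1L]] <- nn_linear("mlp_out", d_in, n_classes)
  list(layers = layers)
}

predict_feature_mlp <- function(fit, X) {
  p <- softmax_probs(nn_forward(fit$net, t(as.matrix(X)))$out)
  p[2, ]
}

## ---- model comparison --------------------------------------------------------

#' Cross-validated comparison of tabular classifiers
#'
#' Runs every model kind on every requested feature subset using one shared
#' grouped fold plan (no per-model re-splitting) and reports mean and sd of
#' fold accuracies, mirroring the pairwise-feature comparison design.
#'
#' @param fm A [feature_matrix()] result (one row per cell).
#' @param folds A `miml_folds` plan over `fm$cell_ids`.
#' @param kinds Model kinds to include.
#' @param feature_sets List of character vectors naming columns of `fm$X`;
#'   default: all pairs of available features.
#' @param seed Integer seed.
#' @return data.frame: model, features, mean_acc, sd_acc, plus per-fold
#'   accuracies in the `"fold_acc"` attribute.
#' @export
compare_models <- function(fm, folds, kinds = c("lr", "svm", "dt", "rf", "knn", "mlp"),
                           feature_sets = NULL, seed = 1L) {
  stopifnot(inherits(folds, "miml_folds"))
  cols <- colnames(fm$X)
  if (is.null(feature_sets)) {
    feature_sets <- if (length(cols) >= 2) utils::combn(cols, 2, simplify = FALSE)
                    else list(cols)
  }
  all_ids <- unlist(folds)
  if (!setequal(all_ids, fm$cell_ids)) stop("fold plan does not cover all rows")
  rows <- list()
  fold_acc <- list()
  for (kind in kinds) {
    for (fs in feature_sets) {
      accs <- vapply(seq_along(folds), function(f) {
        test_ids <- folds[[f]]
        tr <- !(fm$cell_ids %in% test_ids)
        dat <- list(X = fm$X[tr, fs, drop = FALSE], y = fm$y[tr])
        mod <- fit_classifier(tabular_spec(kind, seed = seed), dat)
        pred <- predict(mod, fm$X[!tr, fs, drop = FALSE], type = "class")
        mean(pred == fm$y[!tr])
      }, 1.0)
      key <- paste(kind, paste(fs, collapse = "+"), sep = ":")
      fold_acc[[key]] <- accs
      rows[[key]] <- data.frame(model = kind,
                                features = paste(fs, collapse = "+"),
                                mean_acc = mean(accs), sd_acc = stats::sd(accs),
                                stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "fold_acc") <- fold_acc
  out
}
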