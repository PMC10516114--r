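MANIFEST_COLS <- c("cell_id", "class", "di", "tt_ms", "vmax_norm",
                   "dir_per_ms", "img_entry", "img_squeezed")

#' Read a dataset manifest
#'
#' @param path Manifest CSV path. Image paths are resolved relative to the
#'   manifest's directory.
#' @param check_images Verify that every referenced image file exists.
#' @return Manifest data.frame (unknown columns preserved) with attribute
#'   `"dir"`.
#' @export
read_manifest <- function(path, check_images = TRUE) {
  if (!file.exists(path)) stop("manifest not found: ", path)
  m <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(MANIFEST_COLS, names(m))
  if (length(missing))
    stop("manifest missing column(s): ", paste(missing, collapse = ", "))
  dir <- dirname(path)
  if (check_images) {
    for (col in c("img_entry", "img_squeezed")) {
      ok <- file.exists(file.path(dir, m[[col]]))
      if (!all(ok))
        stop("missing image file(s) for cell_id(s): ",
             paste(utils::head(m$cell_id[!ok], 5), collapse = ", "))
    }
  }
  attr(m, "dir") <- dir
  m
}

#' Write a dataset manifest
#'
#' Required columns are written first in the canonical order; unknown
#' columns are preserved after them. UTF-8, header row, '.' decimal.
#'
#' @param rows Manifest data.frame.
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_manifest <- function(rows, path) {
  missing <- setdiff(MANIFEST_COLS, names(rows))
  if (length(missing))
    stop("manifest missing column(s): ", paste(missing, collapse = ", "))
  extra <- setdiff(names(rows), MANIFEST_COLS)
  rows <- rows[, c(MANIFEST_COLS, extra), drop = FALSE]
  ok <- tryCatch({
    utils::write.csv(rows, path, row.names = FALSE, fileEncoding = "UTF-8")
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) stop("failed to write manifest ", path, ": ",
                        conditionMessage(ok))
  invisible(path)
}

#' Grouped, stratified train/val/test split
#'
#' 4:1 split into train+val and test, stratified by class and grouped by
#' cell id; validation is the first fold of a k-fold plan inside the 80%.
#'
#' @param manifest Manifest data.frame (one row per cell).
#' @param seed Integer seed.
#' @param test_frac Test fraction (default 0.2).
#' @param k Folds inside the train+val portion.
#' @return List of cell-id vectors: `train`, `val`, `test`, `trainval`, and
#'   the `folds` plan over the train+val cells.
#' @export
split_dataset <- function(manifest, seed = 1L, test_frac = 0.2, k = 5L) {
  ids <- manifest$cell_id
  if (anyDuplicated(ids)) stop("manifest must have one row per cell")
  labels <- manifest$class
  tab <- table(labels)
  if (any(tab < k)) stop("class with fewer than k cells: ",
                         paste(names(tab)[tab < k], collapse = ", "))
  set.seed(derive_seed(seed, "split"))
  test <- character()
  for (cl in names(tab)) {
    cls_ids <- sample(ids[labels == cl])
    n_test <- round(test_frac * length(cls_ids))
    test <- c(test, cls_ids[seq_len(n_test)])
  }
  trainval <- setdiff(ids, test)
  tv_labels <- labels[match(trainval, ids)]
  folds <- make_folds(trainval, tv_labels, k = k, seed = seed)
  val <- folds[[1]]
  train <- setdiff(trainval, val)
  list(train = train, val = val, test = test, trainval = trainval,
       folds = folds)
}

#' Load per-image training examples from a manifest
#'
#' Each of the two per-cell frames becomes its own example sharing the
#' cell's mechanical feature vector and label; splits must therefore always
#' be made at the cell level.
#'
#' @param manifest Manifest data.frame.
#' @param cell_ids Cells to load.
#' @param features Mechanical feature subset.
#' @param bounds Normalization bounds (fit them on the training split).
#' @param which_images `"both"`, `"entry"`, or `"squeezed"`.
#' @param dir Image directory; defaults to the manifest's `"dir"` attribute.
#' @return List: `images`, `m`, `y`, `cell_ids` (per image), `classes`.
#' @export
load_examples <- function(manifest, cell_ids, features = c("di", "tt", "vmax"),
                          bounds = NULL, which_images = "both", dir = NULL) {
  dir <- dir %||% attr(manifest, "dir") %||% "."
  fm <- feature_matrix(manifest, features, train_ids = cell_ids, bounds = bounds)
  sel <- manifest$cell_id %in% cell_ids
  rows <- which(sel)
  cols <- switch(which_images, both = c("img_entry", "img_squeezed"),
                 entry = "img_entry", squeezed = "img_squeezed",
                 stop("unknown which_images"))
  images <- list(); m <- NULL; y <- integer(); cid <- character()
  for (i in rows) {
    for (col in cols) {
      images[[length(images) + 1L]] <- read_gray_png(file.path(dir, manifest[[col]][i]))
      m <- rbind(m, fm$X[i, , drop = FALSE])
      y <- c(y, fm$y[i])
      cid <- c(cid, manifest$cell_id[i])
    }
  }
  list(images = images, m = m, y = y, cell_ids = cid,
       classes = fm$classes, bounds = fm$bounds)
}

#' Per-image and per-cell evaluation of probabilistic predictions
#'
#' Cell-level predictions average the per-image probabilities of each cell.
#'
#' @param y Integer 0/1 labels per image.
#' @param probs N x 2 probability matrix.
#' @param cell_ids Cell id per image.
#' @return List with `per_image` and `per_cell` metric lists (accuracy,
#'   precision, recall, f1, auc).
#' @export
evaluate_predictions <- function(y, probs, cell_ids) {
  score <- probs[, 2]
  eval_one <- function(yy, ss) {
    pred <- as.integer(ss > 0.5)
    mm <- suppressWarnings(metrics(confusion(yy, pred)))
    auc <- if (length(unique(yy)) == 2) roc_auc(yy, ss)$auc else NA_real_
    list(accuracy = mm$accuracy, precision = mm$precision,
         recall = mm$recall, f1 = mm$f1, auc = auc)
  }
  cell_score <- tapply(score, cell_ids, mean)
  cell_y <- tapply(y, cell_ids, function(v) v[1])
  list(per_image = eval_one(y, score),
       per_cell = eval_one(as.integer(cell_y), as.numeric(cell_score)))
}

#' Experiment configuration
#'
#' Bundles every knob of an end-to-end run. One global `seed` is fanned out
#' to named substreams (population, splits, initialization, shuffling), so
#' stages can be re-run in isolation.
#'
#' @param seed Global seed.
#' @param population A [population_config()].
#' @param geometry A [channel_geometry()].
#' @param images An [image_spec()].
#' @param features Mechanical feature subset.
#' @param encoder An [encoder_config()].
#' @param epochs Training epochs for neural recipes.
#' @param folds Cross-validation folds.
#' @param test_frac Held-out test fraction.
#' @param out_dir Working directory for generated data (tempdir default).
#' @return Object of class `miml_run_config`.
#' @export
run_config <- function(seed = 1L, population = population_config(),
                       geometry = channel_geometry(), images = image_spec(),
                       features = c("di", "tt", "vmax"),
                       encoder = encoder_config(base_filters = 8L,
                                                blocks_per_stage = 1L),
                       epochs = 10L, folds = 5L, test_frac = 0.2,
                       out_dir = NULL) {
  structure(list(seed = as.integer(seed), population = population,
                 geometry = geometry, images = images, features = features,
                 encoder = encoder, epochs = as.integer(epochs),
                 folds = as.integer(folds), test_frac = test_frac,
                 out_dir = out_dir %||% file.path(tempdir(), "cellmiml_run")),
            class = "miml_run_config")
}

#' Run an end-to-end experiment recipe
#'
#' Generates (or reuses) a synthetic dataset, splits it grouped and
#' stratified, runs the requested model over the cross-validation folds and
#' the held-out test set, and returns a reproducible report.
#' `"miml+dir"` differs from `"miml"` only by the 4th mechanical feature.
#'
#' @param recipe One of `"tabular"`, `"cnn"`, `"miml"`, `"miml+dir"`.
#' @param config A [run_config()].
#' @param manifest Optional pre-built manifest (skips simulation).
#' @return Object of class `miml_report`: per-fold metrics data.frame,
#'   mean/sd summaries, and the config snapshot.
#' @export
run_experiment <- function(recipe = c("tabular", "cnn", "miml", "miml+dir"),
                           config = run_config(), manifest = NULL) {
  recipe <- match.arg(recipe)
  stage <- "simulate"
  res <- tryCatch({
    if (is.null(manifest)) {
      ds <- make_dataset(config$population, config$geometry, config$images,
                         out_dir = config$out_dir, seed = config$seed)
      manifest <- read_manifest(ds$manifest_path)
    }
    stage <- "split"
    sp <- split_dataset(manifest, seed = config$seed,
                        test_frac = config$test_frac, k = config$folds)
    features <- if (recipe == "miml+dir") c(config$features, "dir") else config$features
    features <- unique(features)
    stage <- "train"
    per_fold <- list()
    for (f in seq_along(sp$folds)) {
      val_ids <- sp$folds[[f]]
      train_ids <- setdiff(sp$trainval, val_ids)
      fold_res <- run_fold(recipe, manifest, train_ids, val_ids, sp$test,
                           features, config, fold = f)
      per_fold[[f]] <- fold_res
    }
    stage <- "report"
    df <- do.call(rbind, per_fold)
    summ <- stats::aggregate(accuracy ~ split, df, function(v) c(mean = mean(v), sd = stats::sd(v)))
    structure(list(recipe = recipe, per_fold = df, summary = summ,
                   config = config, seed = config$seed,
                   package_version = as.character(utils::packageVersion("cellmiml"))),
              class = "miml_report")
  }, error = function(e) {
    stop("experiment stage '", stage, "' failed [recipe ", recipe, ", seed ",
         config$seed, "]: ", conditionMessage(e), call. = FALSE)
  })
  res
}

run_fold <- function(recipe, manifest, train_ids, val_ids, test_ids,
                     features, config, fold) {
  if (recipe == "tabular") {
    fm_train <- feature_matrix(manifest[manifest$cell_id %in% c(train_ids, val_ids, test_ids), ],
                               features, train_ids = train_ids)
    tr <- fm_train$cell_ids %in% train_ids
    va <- fm_train$cell_ids %in% val_ids
    te <- fm_train$cell_ids %in% test_ids
    mod <- fit_classifier(tabular_spec("mlp", seed = config$seed),
                          list(X = fm_train$X[tr, , drop = FALSE], y = fm_train$y[tr]))
    out <- lapply(list(train = tr, val = va, test = te), function(ix) {
      p <- predict(mod, fm_train$X[ix, , drop = FALSE], type = "prob")
      ev <- evaluate_predictions(fm_train$y[ix], cbind(1 - p, p),
                                 fm_train$cell_ids[ix])
      ev$per_cell
    })
  } else {
    tr <- load_examples(manifest, train_ids, features)
    va <- load_examples(manifest, val_ids, features, bounds = tr$bounds)
    te <- load_examples(manifest, test_ids, features, bounds = tr$bounds)
    enc_cfg <- config$encoder
    enc_cfg$input_size <- config$images$height
    if (recipe == "cnn") {
      enc_cfg$head <- "classifier"
      enc <- build_encoder(enc_cfg, n_classes = 2L,
                           seed = derive_seed(config$seed, paste0("fold", fold)))
      fit <- train_image_classifier(enc, tr, va, epochs = config$epochs,
                                    seed = derive_seed(config$seed, paste0("cnnf", fold)))
      pred <- function(split) encoder_predict_prob(fit$model, split$images)
    } else {
      fcfg <- fusion_config(n_cnn = embedding_width(enc_cfg),
                            d = length(features))
      model <- build_fusion(enc_cfg, fusion_cfg = fcfg,
                            seed = derive_seed(config$seed, paste0("fold", fold)))
      fit <- train_miml(model, tr, va, epochs = config$epochs,
                        seed = derive_seed(config$seed, paste0("mimlf", fold)))
      pred <- function(split) miml_predict_prob(fit$model, split$images, split$m)
    }
    out <- lapply(list(train = tr, val = va, test = te), function(split) {
      ev <- evaluate_predictions(split$y, pred(split), split$cell_ids)
      ev$per_cell
    })
  }
  do.call(rbind, lapply(names(out), function(s) {
    data.frame(fold = fold, split = s, accuracy = out[[s]]$accuracy,
               precision = out[[s]]$precision, recall = out[[s]]$recall,
               f1 = out[[s]]$f1, auc = out[[s]]$auc, stringsAsFactors = FALSE)
  }))
}
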