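#' Confusion counts for binary predictions
#'
#' @param y_true,y_pred Vectors of equal length with values in \{0,1\} (or
#'   two-level factors/characters).
#' @param positive The value counted as positive; default `1`.
#' @return Object of class `miml_confusion`: `tp`, `tn`, `fp`, `fn`.
#' @export
confusion <- function(y_true, y_pred, positive = 1) {
  if (length(y_true) != length(y_pred)) stop("y_true and y_pred length mismatch")
  t_pos <- y_true == positive
  p_pos <- y_pred == positive
  structure(list(tp = sum(t_pos & p_pos), tn = sum(!t_pos & !p_pos),
                 fp = sum(!t_pos & p_pos), fn = sum(t_pos & !p_pos),
                 positive = positive),
            class = "miml_confusion")
}

#' Classification metrics from confusion counts
#'
#' Accuracy `(TP+TN)/total`, precision `TP/(TP+FP)`, recall `TP/(TP+FN)` and
#' F1 `2TP/(2TP+FP+FN)`. A zero denominator yields 0 with the `degenerate`
#' flag set and a warning.
#'
#' @param counts A `miml_confusion`.
#' @return Object of class `miml_metrics` with fields `accuracy`,
#'   `precision`, `recall`, `f1`, `degenerate`.
#' @export
metrics <- function(counts) {
  stopifnot(inherits(counts, "miml_confusion"))
  total <- counts$tp + counts$tn + counts$fp + counts$fn
  if (total == 0) stop("empty confusion counts")
  safe_div <- function(num, den) if (den == 0) NA_real_ else num / den
  precision <- safe_div(counts$tp, counts$tp + counts$fp)
  recall <- safe_div(counts$tp, counts$tp + counts$fn)
  f1 <- safe_div(2 * counts$tp, 2 * counts$tp + counts$fp + counts$fn)
  degenerate <- anyNA(c(precision, recall, f1))
  if (degenerate) {
    warning("zero denominator in precision/recall/F1; reporting 0")
    precision <- if (is.na(precision)) 0 else precision
    recall <- if (is.na(recall)) 0 else recall
    f1 <- if (is.na(f1)) 0 else f1
  }
  structure(list(accuracy = (counts$tp + counts$tn) / total,
                 precision = precision, recall = recall, f1 = f1,
                 degenerate = degenerate),
            class = "miml_metrics")
}

#' ROC curve and AUC
#'
#' Thresholds sweep the unique scores (ties grouped); AUC by the trapezoid
#' rule, equivalent to the Mann-Whitney rank statistic.
#'
#' @param y_true Binary labels (positive = 1 unless `positive` given).
#' @param scores Real-valued scores, larger = more positive.
#' @param positive Positive label value.
#' @return List: `fpr`, `tpr` (curve points), `auc`.
#' @export
roc_auc <- function(y_true, scores, positive = 1) {
  if (length(y_true) != length(scores)) stop("length mismatch")
  pos <- y_true == positive
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0) stop("both classes must be present")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; p <- pos[ord]
  # group tied scores
  grp <- cumsum(!duplicated(s))
  tp <- cumsum(p); fp <- cumsum(!p)
  last <- !duplicated(grp, fromLast = TRUE)
  tpr <- c(0, tp[last] / n1)
  fpr <- c(0, fp[last] / n0)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  list(fpr = fpr, tpr = tpr, auc = auc)
}

#' Grouped, stratified k-fold plan over cells
#'
#' Folds partition cell ids exactly, are stratified by class (per-fold class
#' counts within one cell of the global ratio) and never split a cell's
#' images across folds (grouping is at the cell level by construction).
#'
#' @param cell_ids Unique cell identifiers.
#' @param labels Class label per cell id.
#' @param k Number of folds.
#' @param seed Integer seed.
#' @return Object of class `miml_folds`: list of `k` character vectors.
#' @export
make_folds <- function(cell_ids, labels, k = 5L, seed = 1L) {
  if (anyDuplicated(cell_ids)) stop("cell_ids must be unique at the cell level")
  if (length(cell_ids) != length(labels)) stop("length mismatch")
  if (k > length(cell_ids)) stop("k exceeds number of cells")
  tab <- table(labels)
  if (any(tab < k)) stop("every class needs at least k cells")
  set.seed(derive_seed(seed, "folds"))
  folds <- vector("list", k)
  for (cl in names(tab)) {
    ids <- cell_ids[labels == cl]
    ids <- sample(ids)
    assign_fold <- rep(seq_len(k), length.out = length(ids))
    for (f in seq_len(k)) folds[[f]] <- c(folds[[f]], ids[assign_fold == f])
  }
  structure(folds, class = "miml_folds")
}

#' 2-D embedding of latent vectors (t-SNE)
#'
#' @param latents Numeric matrix, rows = examples.
#' @param seed Integer seed (layout is deterministic given seed).
#' @param perplexity t-SNE perplexity; default adapts to the row count.
#' @return n x 2 coordinate matrix.
#' @export
embed_2d <- function(latents, seed = 1L, perplexity = NULL) {
  latents <- as.matrix(latents)
  n <- nrow(latents)
  if (n < 5) stop("need at least 5 rows to embed")
  if (is.null(perplexity)) perplexity <- max(2, min(30, floor((n - 1) / 3)))
  if (floor((n - 1) / 3) < perplexity)
    stop("too few rows for perplexity ", perplexity,
         "; need at least ", 3 * perplexity + 1,
         " rows (or lower the perplexity)")
  set.seed(derive_seed(seed, "tsne"))
  fit <- Rtsne::Rtsne(latents, dims = 2, perplexity = perplexity,
                      check_duplicates = FALSE, pca = n > 50, verbose = FALSE)
  fit$Y
}

#' Mean silhouette width of a binary labelling
#'
#' Small helper used by the latent-space diagnostics; Euclidean distances.
#'
#' @param x Numeric matrix, rows = points.
#' @param labels Two-level grouping vector.
#' @return Mean silhouette width in \[-1, 1\].
#' @export
silhouette_score <- function(x, labels) {
  x <- as.matrix(x)
  d <- as.matrix(stats::dist(x))
  labs <- unique(labels)
  if (length(labs) < 2) stop("need two groups")
  s <- numeric(nrow(x))
  for (i in seq_len(nrow(x))) {
    own <- labels == labels[i]
    a <- if (sum(own) > 1) sum(d[i, own]) / (sum(own) - 1) else 0
    b <- min(vapply(labs[labs != labels[i]],
                    function(l) mean(d[i, labels == l]), 1.0))
    s[i] <- if (max(a, b) > 0) (b - a) / max(a, b) else 0
  }
  mean(s)
}
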