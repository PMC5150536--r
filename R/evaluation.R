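# Jackknife (leave-one-out) and stratified k-fold evaluation, reporting
# sensitivity, specificity, accuracy and the Matthews correlation coefficient
# recomputed from explicit confusion counts.

#' Matthews correlation coefficient from confusion counts
#'
#' `(tp*tn - fp*fn) / sqrt((tp+fp)(tp+fn)(tn+fp)(tn+fn))`, defined as 0 when
#' any denominator factor is 0.
#'
#' @param tp,tn,fp,fn Non-negative confusion counts.
#' @return A value in \[-1, 1\].
#' @examples
#' compute_mcc(10, 10, 0, 0)
#' @export
compute_mcc <- function(tp, tn, fp, fn) {
  if (any(c(tp, tn, fp, fn) < 0)) abort("confusion counts must be non-negative")
  # doubles avoid integer overflow in the products
  tp <- as.numeric(tp); tn <- as.numeric(tn)
  fp <- as.numeric(fp); fn <- as.numeric(fn)
  d <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  if (d == 0) return(0)
  (tp * tn - fp * fn) / sqrt(d)
}

#' Evaluation metrics from confusion counts
#'
#' Sensitivity `Sn = tp/(tp+fn)`, specificity `Sp = tn/(tn+fp)`, accuracy
#' `Acc = (tp+tn)/total`, and [compute_mcc()]. Sn and Sp error out when the
#' corresponding class is absent rather than silently reporting 0.
#'
#' @param tp,tn,fp,fn Non-negative confusion counts.
#' @return An `eval_metrics` object (list with the four counts and `sn`,
#'   `sp`, `acc`, `mcc`).
#' @examples
#' eval_metrics(534, 1232, 252, 208)
#' @export
eval_metrics <- function(tp, tn, fp, fn) {
  if (any(c(tp, tn, fp, fn) < 0)) abort("confusion counts must be non-negative")
  if (tp + fn == 0) abort("no positive samples: Sn undefined")
  if (tn + fp == 0) abort("no negative samples: Sp undefined")
  structure(
    list(
      tp = tp, tn = tn, fp = fp, fn = fn,
      sn = tp / (tp + fn),
      sp = tn / (tn + fp),
      acc = (tp + tn) / (tp + tn + fp + fn),
      mcc = compute_mcc(tp, tn, fp, fn)
    ),
    class = "eval_metrics"
  )
}

#' @export
print.eval_metrics <- function(x, ...) {
  cat(sprintf(
    "<eval_metrics> Sn %.2f%%  Sp %.2f%%  Acc %.2f%%  MCC %.2f  (tp %d, tn %d, fp %d, fn %d)\n",
    100 * x$sn, 100 * x$sp, 100 * x$acc, x$mcc, x$tp, x$tn, x$fp, x$fn
  ))
  invisible(x)
}

# confusion counts for binary factors with levels c("negative", "positive")
confusion_metrics <- function(truth, pred) {
  eval_metrics(
    tp = sum(truth == "positive" & pred == "positive"),
    tn = sum(truth == "negative" & pred == "negative"),
    fp = sum(truth == "negative" & pred == "positive"),
    fn = sum(truth == "positive" & pred == "negative")
  )
}

# fold assignment: k = n gives singleton folds (leave-one-out); otherwise
# stratified within class under the given seed
fold_ids <- function(y, k, seed = NULL) {
  n <- length(y)
  if (k < 2L) abort("k must be at least 2")
  if (k > n) abort("k cannot exceed the number of samples")
  if (k == n) return(seq_len(n))
  folds <- integer(n)
  if (!is.null(seed)) {
    old <- get0(".Random.seed", envir = globalenv())
    on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
    set.seed(seed)
  }
  for (cl in levels(y)) {
    idx <- which(y == cl)
    folds[idx] <- sample(rep_len(seq_len(k), length(idx)))
  }
  folds
}

# core CV engine over a fixed feature matrix: one prediction per row
cv_predict_matrix <- function(X, y, config, folds) {
  pred <- factor(rep(NA_character_, length(y)), levels = levels(y))
  for (f in unique(folds)) {
    test <- folds == f
    fit <- train_svm(X[!test, , drop = FALSE], y[!test], config)
    pred[test] <- predict_svm(fit, X[test, , drop = FALSE])$label
  }
  pred
}

#' Leave-one-out evaluation of an SVM on a fixed feature matrix
#'
#' Every sample is predicted by a model trained on all remaining samples.
#' This is the evaluator the wrapper feature-selection scans use.
#'
#' @param features Feature tibble (from [encode_dataset()]) or numeric
#'   matrix.
#' @param y Binary factor with levels `c("negative", "positive")`.
#' @param config An [svm_config()].
#' @return An `eval_metrics` object.
#' @export
jackknife_matrix <- function(features, y, config = svm_config()) {
  X <- feature_matrix(features)
  y <- as_binary_factor(y)
  check_two_classes(y)
  pred <- cv_predict_matrix(X, y, config, seq_along(y))
  confusion_metrics(y, pred)
}

as_binary_factor <- function(y) {
  if (is.factor(y) && identical(levels(y), c("negative", "positive"))) return(y)
  y <- as.character(y)
  if (!all(y %in% c("negative", "positive"))) {
    abort("labels must be 'positive'/'negative' (see layer_view())")
  }
  factor(y, levels = c("negative", "positive"))
}

check_two_classes <- function(y) {
  if (any(table(y) < 2L)) {
    abort("each class needs at least 2 samples for evaluation")
  }
}

#' Jackknife (leave-one-out) evaluation of the full pipeline on sequences
#'
#' Encodes a binary sequence dataset and evaluates an RBF-SVM by
#' leave-one-out. In `"leakage_free"` mode (default) the bi-profile Bayes
#' frequencies are refit in every fold with the held-out sequence excluded;
#' in `"paper_literal"` mode they are fit once on the complete dataset, the
#' convention under which published jackknife figures for this method family
#' are computed.
#'
#' @param data Dataset tibble; either already binary (labels
#'   `positive`/`negative` or a `y` column) or three-class, in which case
#'   `layer` selects the view.
#' @param layer `"I"` or `"II"`, used when `data` is three-class.
#' @param families Feature families to encode.
#' @param features Optional character vector of feature names to restrict to
#'   (a selection result's `selected`, say).
#' @param config An [svm_config()].
#' @param mode `"leakage_free"` or `"paper_literal"`.
#' @param alpha BPB smoothing pseudocount.
#' @param fold_hook Optional `function(held_out_id, train_ids)` called once
#'   per fold; used to instrument leakage checks.
#' @return An `eval_metrics` object.
#' @export
jackknife <- function(data, layer = "I", families = c("BPB", "NC", "PseNC"),
                      features = NULL, config = svm_config(),
                      mode = c("leakage_free", "paper_literal"),
                      alpha = 0, fold_hook = NULL) {
  mode <- match.arg(mode)
  d <- if ("y" %in% names(data)) data else layer_view(data, layer)
  kfold(d, layer = layer, families = families, features = features,
        config = config, k = nrow(d), seed = NULL, mode = mode,
        alpha = alpha, fold_hook = fold_hook)
}

#' Stratified k-fold evaluation of the full pipeline on sequences
#'
#' Same contract as [jackknife()] but with `k` stratified folds drawn under
#' `seed`. With `k` equal to the dataset size the folds are singletons and
#' the result is exactly the jackknife, prediction by prediction.
#'
#' @inheritParams jackknife
#' @param k Number of folds (2 to `nrow(data)`).
#' @param seed Integer seed for the stratified split (ignored when `k = n`).
#' @return An `eval_metrics` object.
#' @export
kfold <- function(data, k, seed = 1L, layer = "I",
                  families = c("BPB", "NC", "PseNC"), features = NULL,
                  config = svm_config(),
                  mode = c("leakage_free", "paper_literal"),
                  alpha = 0, fold_hook = NULL) {
  mode <- match.arg(mode)
  d <- if ("y" %in% names(data)) data else layer_view(data, layer)
  y <- as_binary_factor(d$y)
  check_two_classes(y)
  folds <- fold_ids(y, k, seed)

  if (mode == "paper_literal") {
    bpb <- if ("BPB" %in% families) {
      fit_bpb(d[y == "positive", ], d[y == "negative", ], alpha = alpha)
    }
    X <- feature_matrix(encode_dataset(d, bpb, families))
    if (!is.null(features)) X <- X[, features, drop = FALSE]
    pred <- factor(rep(NA_character_, length(y)), levels = levels(y))
    for (f in unique(folds)) {
      test <- folds == f
      if (!is.null(fold_hook)) fold_hook(d$id[test], d$id[!test])
      fit <- train_svm(X[!test, , drop = FALSE], y[!test], config)
      pred[test] <- predict_svm(fit, X[test, , drop = FALSE])$label
    }
    return(confusion_metrics(y, pred))
  }

  # leakage-free: refit BPB on the training part of every fold
  static <- static_blocks(d, families)
  pred <- factor(rep(NA_character_, length(y)), levels = levels(y))
  for (f in unique(folds)) {
    test <- folds == f
    if (!is.null(fold_hook)) fold_hook(d$id[test], d$id[!test])
    Xb <- fold_features(d, y, test, families, static, alpha)
    if (!is.null(features)) Xb <- Xb[, features, drop = FALSE]
    fit <- train_svm(Xb[!test, , drop = FALSE], y[!test], config)
    pred[test] <- predict_svm(fit, Xb[test, , drop = FALSE])$label
  }
  confusion_metrics(y, pred)
}

# NC / PseNC do not depend on the training partition; encode once
static_blocks <- function(d, families) {
  blocks <- list()
  if ("NC" %in% families) blocks$NC <- encode_nc(d)
  if ("PseNC" %in% families) blocks$PseNC <- encode_psenc(d)
  blocks
}

fold_features <- function(d, y, test, families, static, alpha) {
  blocks <- list()
  if ("BPB" %in% families) {
    train <- d[!test, ]
    ytr <- y[!test]
    bpb <- fit_bpb(train[ytr == "positive", ], train[ytr == "negative", ],
                   alpha = alpha)
    blocks$BPB <- encode_bpb(bpb, d)
  }
  do.call(cbind, unname(c(blocks, static[intersect(names(static), families)])))
}
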