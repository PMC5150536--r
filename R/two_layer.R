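# The two-layer cascade: layer I decides enhancer vs non-enhancer; only
# sequences called enhancers are passed to layer II, which decides strong vs
# weak. Each layer carries its own bi-profile Bayes model, feature subset and
# SVM operating point.

#' Train the two-layer enhancer predictor
#'
#' Trains layer I (enhancer vs non-enhancer) on the full three-class dataset
#' and layer II (strong vs weak) on the enhancers only. Feature subsets may
#' be supplied directly (e.g. a [run_full_selection()] result's `selected`)
#' or found by running the selection schedule per layer.
#'
#' @param data Three-class dataset tibble (labels `strong_enhancer`,
#'   `weak_enhancer`, `non_enhancer`).
#' @param config1,config2 [svm_config()] per layer; defaults are the
#'   published operating points ([layer_svm_defaults()]).
#' @param features1,features2 Optional character vectors of feature names
#'   per layer; `NULL` uses all 2n + 4 + 64 features.
#' @param selection Optional [selection_config()]; when given, the full
#'   wrapper schedule is run per layer and overrides `features1`/`features2`.
#' @param alpha BPB smoothing pseudocount.
#' @return A `two_layer_model` with elements `layer1` and `layer2`, each a
#'   list of the fitted `bpb`, `features`, `svm` and config, plus the
#'   selection results when selection was run.
#' @export
train_two_layer <- function(data,
                            config1 = layer_svm_defaults("I"),
                            config2 = layer_svm_defaults("II"),
                            features1 = NULL, features2 = NULL,
                            selection = NULL, alpha = 0) {
  sel1 <- sel2 <- NULL
  if (!is.null(selection)) {
    sel1 <- run_full_selection(data, "I",
                               stamp_svm(selection, config1))
    sel2 <- run_full_selection(data, "II",
                               stamp_svm(selection, config2))
    features1 <- sel1$selected
    features2 <- sel2$selected
  }
  layer1 <- fit_layer(data, "I", config1, features1, alpha)
  layer2 <- fit_layer(data, "II", config2, features2, alpha)
  layer1$selection <- sel1
  layer2$selection <- sel2
  structure(list(layer1 = layer1, layer2 = layer2, n = attr(data, "n")),
            class = "two_layer_model")
}

stamp_svm <- function(selection, svm) {
  selection$svm <- svm
  selection
}

fit_layer <- function(data, layer, config, features, alpha) {
  d <- layer_view(data, layer)
  y <- as_binary_factor(d$y)
  bpb <- fit_bpb(d[y == "positive", ], d[y == "negative", ], alpha = alpha)
  X <- feature_matrix(encode_dataset(d, bpb))
  if (!is.null(features)) X <- X[, features, drop = FALSE]
  list(bpb = bpb, features = colnames(X), svm = train_svm(X, y, config),
       config = config)
}

#' @export
print.two_layer_model <- function(x, ...) {
  cat(sprintf(
    "<two_layer_model> layer I: %d features (C=%g, gamma=%g); layer II: %d features (C=%g, gamma=%g)\n",
    length(x$layer1$features), x$layer1$config$C, x$layer1$config$gamma,
    length(x$layer2$features), x$layer2$config$C, x$layer2$config$gamma
  ))
  invisible(x)
}

#' Predict enhancer class and strength for new sequences
#'
#' Applies the cascade: sequences called negative by layer I are
#' `non_enhancer` (layer II is not consulted and its score is `NA`);
#' sequences called positive are passed to layer II, which labels them
#' `strong_enhancer` or `weak_enhancer`.
#'
#' @param object A `two_layer_model`.
#' @param newdata Dataset tibble (columns `id`, `seq`) or character vector of
#'   sequences, all length-compatible with the model.
#' @param ... Unused.
#' @return A tibble with one row per input sequence: `id`, `layer1_label`
#'   (`enhancer`/`non_enhancer`), `layer1_score`, `layer2_label`
#'   (`strong`/`weak`/`NA`), `layer2_score`, and the final 3-way `label`.
#' @export
predict.two_layer_model <- function(object, newdata, ...) {
  d <- if (is.character(newdata)) {
    tibble(id = paste0("seq", seq_along(newdata)), seq = toupper(newdata))
  } else {
    dplyr::mutate(as_tibble(newdata)[c("id", "seq")], seq = toupper(.data$seq))
  }
  if (nrow(d) == 0L) {
    return(tibble(id = character(), layer1_label = character(),
                  layer1_score = numeric(), layer2_label = character(),
                  layer2_score = numeric(), label = character()))
  }
  X1 <- layer_features(d, object$layer1)
  p1 <- predict_svm(object$layer1$svm, X1)
  is_enh <- p1$label == "positive"

  layer2_label <- rep(NA_character_, nrow(d))
  layer2_score <- rep(NA_real_, nrow(d))
  if (any(is_enh)) {
    X2 <- layer_features(d[is_enh, ], object$layer2)
    p2 <- predict_svm(object$layer2$svm, X2)
    layer2_label[is_enh] <- ifelse(p2$label == "positive", "strong", "weak")
    layer2_score[is_enh] <- p2$score
  }

  tibble(
    id = d$id,
    layer1_label = ifelse(is_enh, "enhancer", "non_enhancer"),
    layer1_score = p1$score,
    layer2_label = layer2_label,
    layer2_score = layer2_score,
    label = dplyr::case_when(
      !is_enh ~ "non_enhancer",
      layer2_label == "strong" ~ "strong_enhancer",
      TRUE ~ "weak_enhancer"
    )
  )
}

layer_features <- function(d, layer) {
  fams <- unique(feature_family(layer$features))
  X <- feature_matrix(encode_dataset(d, layer$bpb, fams))
  X[, layer$features, drop = FALSE]
}
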