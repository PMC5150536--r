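# broom-style tidiers for the package's fitted objects.

#' Tidy a bi-profile Bayes model
#'
#' @param x A `bpb_model`.
#' @param ... Unused.
#' @return Long tibble: `class` (positive/negative), `base`, `position`,
#'   `freq`.
#' @export
tidy.bpb_model <- function(x, ...) {
  long <- function(m, cls) {
    tibble(
      class = cls,
      base = rep(BASES, times = ncol(m)),
      position = rep(seq_len(ncol(m)), each = 4L),
      freq = as.vector(m)
    )
  }
  dplyr::bind_rows(long(x$pos_freq, "positive"), long(x$neg_freq, "negative"))
}

#' @export
glance.bpb_model <- function(x, ...) {
  tibble(n = x$n, alpha = x$alpha)
}

#' Tidy an F-score ranking
#'
#' @param x An `fscore_ranking`.
#' @param ... Unused.
#' @return The ranking as a plain tibble (feature, fscore, rank, class
#'   means).
#' @export
tidy.fscore_ranking <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "fscore_ranking")
  as_tibble(out)
}

#' @export
glance.fscore_ranking <- function(x, ...) {
  tibble(n_features = nrow(x), n_pos = attr(x, "n_pos"),
         n_neg = attr(x, "n_neg"),
         max_fscore = max(x$fscore[is.finite(x$fscore)]))
}

#' Tidy a selection result
#'
#' @param x A `selection_result`.
#' @param ... Unused.
#' @return The scan trajectory: one row per evaluated grid point with
#'   `stage`, `param` (threshold, dimension or trial index), `n_features`,
#'   `acc`, `sn`, `sp`, `mcc`, `valid`.
#' @export
tidy.selection_result <- function(x, ...) {
  x$trajectory
}

#' @export
glance.selection_result <- function(x, ...) {
  fams <- table(factor(feature_family(x$selected),
                       levels = c("BPB", "NC", "PseNC")))
  tibble(n_selected = length(x$selected),
         n_bpb = as.integer(fams[["BPB"]]),
         n_nc = as.integer(fams[["NC"]]),
         n_psenc = as.integer(fams[["PseNC"]]),
         best_acc = x$best_acc)
}

#' Tidy evaluation metrics
#'
#' @param x An `eval_metrics`.
#' @param ... Unused.
#' @return Two-column tibble `metric`/`value` over tp, tn, fp, fn, sn, sp,
#'   acc, mcc.
#' @export
tidy.eval_metrics <- function(x, ...) {
  tibble(metric = names(unclass(x)),
         value = as.numeric(unlist(unclass(x))))
}

#' @export
glance.eval_metrics <- function(x, ...) {
  as_tibble(unclass(x))
}

#' One-row summary of a two-layer model
#'
#' @param x A `two_layer_model`.
#' @param ... Unused.
#' @return Tibble with per-layer feature counts and SVM parameters.
#' @export
glance.two_layer_model <- function(x, ...) {
  tibble(
    layer = c("I", "II"),
    n_features = c(length(x$layer1$features), length(x$layer2$features)),
    C = c(x$layer1$config$C, x$layer2$config$C),
    gamma = c(x$layer1$config$gamma, x$layer2$config$gamma)
  )
}

#' Table-style metrics report
#'
#' Formats one or more named `eval_metrics` as the conventional
#' Sn(%) / Sp(%) / Acc(%) / MCC table, percentages to two decimals.
#'
#' @param ... Named `eval_metrics` objects.
#' @return A tibble with columns `model`, `Sn`, `Sp`, `Acc`, `MCC`.
#' @export
metrics_table <- function(...) {
  ms <- list(...)
  if (length(ms) == 1L && is.list(ms[[1]]) && !inherits(ms[[1]], "eval_metrics")) {
    ms <- ms[[1]]
  }
  dplyr::bind_rows(purrr::imap(ms, function(m, nm) {
    tibble(model = nm, Sn = round(100 * m$sn, 2), Sp = round(100 * m$sp, 2),
           Acc = round(100 * m$acc, 2), MCC = round(m$mcc, 2))
  }))
}
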