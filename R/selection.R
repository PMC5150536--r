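# Two-step wrapper feature selection driven by jackknife accuracy:
#   1. coarse scan over F-score thresholds (keep features with F >= w),
#   2. fine scan over the number of top-ranked dimensions,
# then cross-family combination: a greedy add-one pass over NC and a
# coarse + fine scan over PseNC, each stage accepted only if it improves the
# running accuracy. Accuracy is the selection criterion throughout; Sn, Sp
# and MCC are logged but never drive a decision.

#' Evaluator factories for wrapper selection
#'
#' An evaluator is a `function(features, y)` returning an `eval_metrics`;
#' the scans call it on candidate feature subsets. `jackknife_evaluator()`
#' (the published protocol) evaluates by leave-one-out;
#' `kfold_evaluator()` is a cheaper stratified k-fold alternative for large
#' datasets.
#'
#' @param config An [svm_config()].
#' @param k,seed Folds and split seed for the k-fold variant.
#' @return A function `(features, y) -> eval_metrics`.
#' @export
jackknife_evaluator <- function(config = svm_config()) {
  force(config)
  function(features, y) jackknife_matrix(features, y, config)
}

#' @rdname jackknife_evaluator
#' @export
kfold_evaluator <- function(k = 5L, config = svm_config(), seed = 1L) {
  force(config); force(k); force(seed)
  function(features, y) {
    X <- feature_matrix(features)
    y <- as_binary_factor(y)
    folds <- fold_ids(y, k, seed)
    confusion_metrics(y, cv_predict_matrix(X, y, config, folds))
  }
}

# memoized evaluation of a feature subset (cache shared across scan stages)
evaluate_set <- function(X, y, feats, evaluator, cache) {
  key <- paste(sort(feats), collapse = "\r")
  if (!is.null(cache[[key]])) return(cache[[key]])
  m <- evaluator(X[, feats, drop = FALSE], y)
  cache[[key]] <- m
  m
}

metrics_to_row <- function(m) {
  tibble(acc = m$acc, sn = m$sn, sp = m$sp, mcc = m$mcc)
}

new_selection_result <- function(selected, trajectory, best) {
  structure(
    list(selected = selected, trajectory = trajectory,
         best_acc = best$acc, best_metrics = best),
    class = "selection_result"
  )
}

#' @export
print.selection_result <- function(x, ...) {
  fams <- table(factor(feature_family(x$selected),
                       levels = c("BPB", "NC", "PseNC")))
  cat(sprintf(
    "<selection_result> %d features (%s), best Acc %.2f%% over %d scan points\n",
    length(x$selected),
    paste(sprintf("%s(%d)", names(fams), fams), collapse = " + "),
    100 * x$best_acc, nrow(x$trajectory)
  ))
  invisible(x)
}

#' Coarse F-score-threshold scan
#'
#' For each threshold `w` on the grid, evaluates the classifier on `base`
#' plus all ranked features with F-score >= `w`, and returns the best subset
#' by accuracy. Ties resolve to the larger threshold (fewer features).
#' Thresholds retaining no feature are recorded as invalid and skipped.
#'
#' @param features Feature tibble or matrix holding at least the ranked and
#'   base features.
#' @param y Binary labels.
#' @param ranking An [fscore()] ranking of the candidate features.
#' @param evaluator See [jackknife_evaluator()].
#' @param w_start,w_end,step Threshold grid `seq(w_start, w_end, step)`;
#'   `w_end = NULL` uses the largest finite F-score.
#' @param base Feature names always included (default none).
#' @param stage Stage tag recorded in the trajectory.
#' @param cache Internal memoization environment.
#' @return A `selection_result`: `selected` (base plus the winning subset,
#'   in rank order), the scan `trajectory` (threshold, n_features, Acc, Sn,
#'   Sp, MCC), and `best_acc`.
#' @export
coarse_threshold_scan <- function(features, y, ranking,
                                  evaluator = jackknife_evaluator(),
                                  w_start = 0, w_end = NULL, step = 0.001,
                                  base = character(), stage = "coarse",
                                  cache = new.env(parent = emptyenv())) {
  if (step <= 0) abort("step must be positive")
  X <- feature_matrix(features)
  w_end <- w_end %||% max(ranking$fscore[is.finite(ranking$fscore)])
  grid <- seq(w_start, w_end, by = step)
  rows <- vector("list", length(grid))
  best <- NULL; best_w <- NA_real_; best_set <- NULL
  for (i in seq_along(grid)) {
    w <- grid[i]
    set <- ranking$feature[ranking$fscore >= w]
    if (length(set) == 0L) {
      rows[[i]] <- tibble(stage = stage, param = w, n_features = 0L,
                          acc = NA_real_, sn = NA_real_, sp = NA_real_,
                          mcc = NA_real_, valid = FALSE)
      next
    }
    m <- evaluate_set(X, y, c(base, set), evaluator, cache)
    rows[[i]] <- dplyr::bind_cols(
      tibble(stage = stage, param = w, n_features = length(base) + length(set)),
      metrics_to_row(m), tibble(valid = TRUE)
    )
    # ties resolve to the larger threshold, i.e. fewer features
    if (is.null(best) || m$acc >= best$acc) {
      best <- m; best_w <- w; best_set <- set
    }
  }
  if (is.null(best)) abort("no threshold on the grid retained any feature")
  new_selection_result(c(base, best_set), dplyr::bind_rows(rows), best)
}

#' Fine dimension scan over the top-d ranked features
#'
#' Evaluates `base` plus the top `d` features of the ranking for each `d` on
#' the grid and returns the best by accuracy; ties resolve to the smaller
#' `d` (fewer features).
#'
#' @inheritParams coarse_threshold_scan
#' @param d_min,d_max,step Dimension grid `seq(d_min, d_max, step)`.
#' @return A `selection_result` (see [coarse_threshold_scan()]).
#' @export
fine_dimension_scan <- function(features, y, ranking,
                                evaluator = jackknife_evaluator(),
                                d_min = 1L, d_max = nrow(ranking), step = 2L,
                                base = character(), stage = "fine",
                                cache = new.env(parent = emptyenv())) {
  if (step < 1L) abort("step must be at least 1")
  if (d_min < 1L || d_min > d_max) abort("need 1 <= d_min <= d_max")
  if (d_max > nrow(ranking)) abort("d_max exceeds the number of ranked features")
  X <- feature_matrix(features)
  grid <- seq(as.integer(d_min), as.integer(d_max), by = as.integer(step))
  rows <- vector("list", length(grid))
  best <- NULL; best_set <- NULL
  for (i in seq_along(grid)) {
    d <- grid[i]
    set <- ranking$feature[seq_len(d)]
    m <- evaluate_set(X, y, c(base, set), evaluator, cache)
    rows[[i]] <- dplyr::bind_cols(
      tibble(stage = stage, param = as.numeric(d),
             n_features = length(base) + d),
      metrics_to_row(m), tibble(valid = TRUE)
    )
    # strict improvement only: ties resolve to the smaller d
    if (is.null(best) || m$acc > best$acc) {
      best <- m; best_set <- set
    }
  }
  new_selection_result(c(base, best_set), dplyr::bind_rows(rows), best)
}

#' Greedy add-one combination step
#'
#' Tries candidate features in descending F-score order; each candidate is
#' kept iff adding it improves the running accuracy (strictly, under the
#' default `accept = "strict"`; `"gte"` also keeps ties). Stops after
#' `k_max` trials or when candidates are exhausted.
#'
#' @inheritParams coarse_threshold_scan
#' @param ranking Ranking of the candidate features (must be disjoint from
#'   `base`).
#' @param k_max Maximum number of candidates tried.
#' @param base_metrics Optional `eval_metrics` of `base` (re-evaluated when
#'   missing).
#' @param accept `"strict"` (default) or `"gte"`.
#' @return A `selection_result`; its trajectory records one row per trial
#'   with `param` = trial index and `kept` in the `valid` column.
#' @export
greedy_add <- function(features, y, base, ranking,
                       evaluator = jackknife_evaluator(), k_max = 4L,
                       base_metrics = NULL, accept = c("strict", "gte"),
                       stage = "greedy", cache = new.env(parent = emptyenv())) {
  accept <- match.arg(accept)
  X <- feature_matrix(features)
  candidates <- setdiff(ranking$feature, base)
  if (is.null(base_metrics)) {
    base_metrics <- evaluate_set(X, y, base, evaluator, cache)
  }
  current <- base
  best <- base_metrics
  rows <- list()
  for (cand in head(candidates, k_max)) {
    m <- evaluate_set(X, y, c(current, cand), evaluator, cache)
    keep <- if (accept == "strict") m$acc > best$acc else m$acc >= best$acc
    rows[[length(rows) + 1L]] <- dplyr::bind_cols(
      tibble(stage = stage, param = as.numeric(length(rows) + 1L),
             n_features = length(current) + 1L),
      metrics_to_row(m), tibble(valid = keep)
    )
    if (keep) {
      current <- c(current, cand)
      best <- m
    }
  }
  new_selection_result(current, dplyr::bind_rows(rows), best)
}

#' Wrapper-selection schedule configuration
#'
#' Defaults follow the published schedule: a coarse BPB threshold scan at
#' step 0.001 over the full F-score range, a fine BPB dimension scan at step
#' 2 spanning +/-10 dimensions around the coarse optimum, a greedy add-one
#' pass over the 4 NC features, then a PseNC coarse threshold scan at step
#' 0.01 and fine dimension scan at step 2 (span +/-10). On large inputs the
#' default jackknife evaluator is the dominant cost; coarser grids or
#' [kfold_evaluator()] scale it down.
#'
#' @param svm [svm_config()] used by the evaluator.
#' @param evaluator `"jackknife"`, `"kfold"`, or a
#'   `function(features, y) -> eval_metrics`.
#' @param bpb_w_start,bpb_w_end,bpb_w_step Coarse BPB threshold grid
#'   (`bpb_w_end = NULL`: max finite F-score).
#' @param bpb_fine_step,bpb_fine_span Fine BPB dimension grid: the coarse
#'   optimum +/- `bpb_fine_span`, step `bpb_fine_step`.
#' @param nc_k_max Maximum NC candidates tried by the greedy pass.
#' @param psenc_w_start,psenc_w_end,psenc_w_step PseNC coarse grid.
#' @param psenc_fine_step,psenc_fine_span PseNC fine grid.
#' @param accept `"strict"` or `"gte"` accept rule for combination stages.
#' @param alpha BPB smoothing pseudocount.
#' @param kfold_k,seed Folds/seed when `evaluator = "kfold"`.
#' @param stages Which stages to run, in order; disable all for no selection.
#' @return A `selection_config` list.
#' @export
selection_config <- function(svm = svm_config(), evaluator = "jackknife",
                             bpb_w_start = 0, bpb_w_end = NULL,
                             bpb_w_step = 0.001,
                             bpb_fine_step = 2L, bpb_fine_span = 10L,
                             nc_k_max = 4L,
                             psenc_w_start = 0, psenc_w_end = NULL,
                             psenc_w_step = 0.01,
                             psenc_fine_step = 2L, psenc_fine_span = 10L,
                             accept = c("strict", "gte"), alpha = 0,
                             kfold_k = 5L, seed = 1L,
                             stages = c("bpb_coarse", "bpb_fine", "nc_greedy",
                                        "psenc_coarse", "psenc_fine")) {
  structure(
    list(svm = svm, evaluator = evaluator,
         bpb_w_start = bpb_w_start, bpb_w_end = bpb_w_end,
         bpb_w_step = bpb_w_step, bpb_fine_step = bpb_fine_step,
         bpb_fine_span = bpb_fine_span, nc_k_max = nc_k_max,
         psenc_w_start = psenc_w_start, psenc_w_end = psenc_w_end,
         psenc_w_step = psenc_w_step, psenc_fine_step = psenc_fine_step,
         psenc_fine_span = psenc_fine_span,
         accept = match.arg(accept), alpha = alpha,
         kfold_k = kfold_k, seed = seed, stages = stages),
    class = "selection_config"
  )
}

resolve_evaluator <- function(config) {
  ev <- config$evaluator
  if (is.function(ev)) return(ev)
  switch(ev,
    jackknife = jackknife_evaluator(config$svm),
    kfold = kfold_evaluator(config$kfold_k, config$svm, config$seed),
    abort("evaluator must be 'jackknife', 'kfold', or a function")
  )
}

#' Run the full feature-selection schedule for one layer
#'
#' Fits the bi-profile Bayes model on the layer's classes, encodes all three
#' feature families, and executes the wrapper schedule: BPB coarse threshold
#' scan, BPB fine dimension scan, NC greedy add-one, PseNC coarse threshold
#' scan, PseNC fine dimension scan. Every combination stage is accepted only
#' if it improves the running accuracy, so the final accuracy is
#' non-decreasing across stages.
#'
#' @param data Dataset tibble (three-class, or binary with a `y` column).
#' @param layer `"I"` or `"II"`.
#' @param config A [selection_config()].
#' @return A `selection_result` whose `trajectory` concatenates all stage
#'   scans and which additionally carries `stage_summary` (tibble: stage,
#'   n_features, acc after that stage) and the fitted `bpb` model.
#' @export
run_full_selection <- function(data, layer = "I", config = selection_config()) {
  d <- if ("y" %in% names(data)) data else layer_view(data, layer)
  y <- as_binary_factor(d$y)
  check_two_classes(y)
  bpb <- fit_bpb(d[y == "positive", ], d[y == "negative", ],
                 alpha = config$alpha)
  feats <- encode_dataset(d, bpb)
  X <- feature_matrix(feats)
  evaluator <- resolve_evaluator(config)
  cache <- new.env(parent = emptyenv())
  fam <- feature_family(colnames(X))

  stages <- config$stages
  traj <- list()
  summary_rows <- list()
  note_stage <- function(name, res) {
    traj[[length(traj) + 1L]] <<- res$trajectory
    summary_rows[[length(summary_rows) + 1L]] <<-
      tibble(stage = name, n_features = length(res$selected),
             acc = res$best_acc)
  }

  if (length(stages) == 0L) {
    all_feats <- colnames(X)
    m <- evaluate_set(X, y, all_feats, evaluator, cache)
    res <- new_selection_result(
      all_feats,
      dplyr::bind_cols(tibble(stage = "none", param = NA_real_,
                              n_features = length(all_feats)),
                       metrics_to_row(m), tibble(valid = TRUE)),
      m
    )
    res$stage_summary <- tibble(stage = "none",
                                n_features = length(all_feats), acc = m$acc)
    res$bpb <- bpb
    return(res)
  }

  rank_bpb <- fscore(X[, fam == "BPB", drop = FALSE], y)
  current <- NULL

  if ("bpb_coarse" %in% stages) {
    current <- coarse_threshold_scan(
      X, y, rank_bpb, evaluator,
      w_start = config$bpb_w_start, w_end = config$bpb_w_end,
      step = config$bpb_w_step, stage = "bpb_coarse", cache = cache
    )
    note_stage("bpb_coarse", current)
  } else {
    feats0 <- rank_bpb$feature
    m0 <- evaluate_set(X, y, feats0, evaluator, cache)
    current <- new_selection_result(feats0, tibble(), m0)
  }

  if ("bpb_fine" %in% stages) {
    d_star <- length(current$selected)
    fine <- fine_dimension_scan(
      X, y, rank_bpb, evaluator,
      d_min = max(1L, d_star - config$bpb_fine_span),
      d_max = min(nrow(rank_bpb), d_star + config$bpb_fine_span),
      step = config$bpb_fine_step, stage = "bpb_fine", cache = cache
    )
    # the fine grid may not contain the coarse optimum itself; only accept
    # an improvement so accuracy never regresses between stages
    if (fine$best_acc >= current$best_acc) current <- fine
    note_stage("bpb_fine", current)
  }

  if ("nc_greedy" %in% stages) {
    rank_nc <- fscore(X[, fam == "NC", drop = FALSE], y)
    current <- greedy_add(
      X, y, current$selected, rank_nc, evaluator,
      k_max = config$nc_k_max, base_metrics = current$best_metrics,
      accept = config$accept, stage = "nc_greedy", cache = cache
    )
    note_stage("nc_greedy", current)
  }

  rank_pse <- fscore(X[, fam == "PseNC", drop = FALSE], y)

  if ("psenc_coarse" %in% stages) {
    scan <- coarse_threshold_scan(
      X, y, rank_pse, evaluator,
      w_start = config$psenc_w_start, w_end = config$psenc_w_end,
      step = config$psenc_w_step, base = current$selected,
      stage = "psenc_coarse", cache = cache
    )
    ok <- if (config$accept == "strict") scan$best_acc > current$best_acc
          else scan$best_acc >= current$best_acc
    if (ok) current <- scan else current$trajectory <- scan$trajectory
    note_stage("psenc_coarse", current)
  }

  if ("psenc_fine" %in% stages) {
    base_noPse <- current$selected[feature_family(current$selected) != "PseNC"]
    k_star <- length(current$selected) - length(base_noPse)
    d_max <- min(nrow(rank_pse), k_star + config$psenc_fine_span)
    d_min <- max(1L, k_star - config$psenc_fine_span)
    if (d_max >= 1L) {
      scan <- fine_dimension_scan(
        X, y, rank_pse, evaluator,
        d_min = d_min, d_max = d_max, step = config$psenc_fine_step,
        base = base_noPse, stage = "psenc_fine", cache = cache
      )
      ok <- if (config$accept == "strict") scan$best_acc > current$best_acc
            else scan$best_acc >= current$best_acc
      if (ok) current <- scan else current$trajectory <- scan$trajectory
      note_stage("psenc_fine", current)
    }
  }

  # order the final set BPB, NC, PseNC with stable intra-family rank order
  sel <- current$selected
  sel <- sel[order(match(feature_family(sel), c("BPB", "NC", "PseNC")))]
  out <- new_selection_result(sel, dplyr::bind_rows(traj),
                              current$best_metrics)
  out$stage_summary <- dplyr::bind_rows(summary_rows)
  out$bpb <- bpb
  out
}
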