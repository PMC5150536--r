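# A small planted-signal binary dataset shared by the selection tests.
# The kfold evaluator keeps the wrapper scans cheap here; the jackknife-driven
# schedule is exercised end to end in test-acceptance.R.
sel_data <- local({
  spec <- generator_spec(
    n = 40, class_sizes = c(positive = 50, negative = 50),
    # boosting each base at two positions keeps the boosts composition-neutral,
    # so the only mononucleotide signal is the planted C shift
    positional_signal = tibble::tibble(class = "positive", position = 1:8,
                                       base = rep(c("A", "C", "G", "T"), 2),
                                       boost = 0.45),
    composition_shift = list(positive = c(A = -0.02, C = 0.06, G = -0.02,
                                          T = -0.02)),
    trimer_signal = NULL, seed = 101
  )
  d <- generate_dataset(spec)
  v <- layer_view(d, "I")
  bpb <- fit_bpb(v[v$y == "positive", ], v[v$y == "negative", ])
  X <- enhancr:::feature_matrix(encode_dataset(v, bpb))
  list(d = d, v = v, X = X, y = v$y,
       ev = kfold_evaluator(k = 5, config = svm_config(C = 1, gamma = "scale"),
                            seed = 1))
})

test_that("coarse threshold scan keeps everything at 0 and skips empty grids", {
  fam <- enhancr:::feature_family(colnames(sel_data$X))
  rk <- fscore(sel_data$X[, fam == "BPB"], sel_data$y)
  wmax <- max(rk$fscore[is.finite(rk$fscore)])
  res <- coarse_threshold_scan(sel_data$X, sel_data$y, rk, sel_data$ev,
                               w_start = 0, w_end = wmax * 1.5,
                               step = wmax * 0.3)
  traj <- tidy(res)
  expect_equal(traj$n_features[traj$param == 0], nrow(rk))  # threshold 0: all
  expect_true(any(!traj$valid))            # grid points above max are skipped
  expect_true(all(is.na(traj$acc[!traj$valid])))
  expect_equal(res$best_acc, max(traj$acc, na.rm = TRUE))
  # ties resolve toward the larger threshold (fewer features)
  best_rows <- traj[traj$valid & traj$acc == res$best_acc, ]
  expect_equal(length(res$selected),
               min(best_rows$n_features))
  expect_error(
    coarse_threshold_scan(sel_data$X, sel_data$y, rk, sel_data$ev,
                          w_start = wmax * 2, w_end = wmax * 3, step = wmax),
    "retained"
  )
})

test_that("fine dimension scan brackets the grid and degenerates correctly", {
  fam <- enhancr:::feature_family(colnames(sel_data$X))
  rk <- fscore(sel_data$X[, fam == "BPB"], sel_data$y)
  all_d <- nrow(rk)
  res <- fine_dimension_scan(sel_data$X, sel_data$y, rk, sel_data$ev,
                             d_min = all_d, d_max = all_d)
  expect_setequal(res$selected, rk$feature)  # no selection
  top1 <- fine_dimension_scan(sel_data$X, sel_data$y, rk, sel_data$ev,
                              d_min = 1, d_max = 1)
  expect_equal(top1$selected, rk$feature[1])
  expect_error(fine_dimension_scan(sel_data$X, sel_data$y, rk, sel_data$ev,
                                   d_min = 1, d_max = all_d + 1), "exceeds")
  # on strongly separable data the scanned optimum is at least as good as
  # using every ranked feature
  scan <- fine_dimension_scan(sel_data$X, sel_data$y, rk, sel_data$ev,
                              d_min = 10, d_max = all_d, step = 14)
  expect_gte(scan$best_acc,
             tidy(scan)$acc[tidy(scan)$param == all_d])
})

test_that("greedy add-one keeps only strict improvements", {
  fam <- enhancr:::feature_family(colnames(sel_data$X))
  base <- fscore(sel_data$X[, fam == "BPB"], sel_data$y)$feature[1:10]
  # with a fixed kernel width, a constant candidate column leaves the RBF
  # kernel (and hence the accuracy) exactly unchanged
  ev_fixed <- kfold_evaluator(k = 5, config = svm_config(C = 1, gamma = 0.5),
                              seed = 1)
  Xc <- cbind(sel_data$X[, base], dead = rep(0.5, nrow(sel_data$X)))
  rk_dead <- fscore(Xc[, "dead", drop = FALSE], sel_data$y)
  res <- greedy_add(Xc, sel_data$y, base, rk_dead, ev_fixed)
  expect_equal(res$selected, base)            # rejected: no information added
  expect_false(any(tidy(res)$valid))
  # k_max = 0 returns the base untouched without trying anything
  rk_nc <- fscore(sel_data$X[, fam == "NC"], sel_data$y)
  res0 <- greedy_add(sel_data$X, sel_data$y, base, rk_nc, sel_data$ev,
                     k_max = 0)
  expect_equal(res0$selected, base)
  expect_equal(nrow(tidy(res0)), 0L)
})

test_that("the full schedule is monotone, deterministic, and finds planted NC signal", {
  cfg <- selection_config(
    svm = svm_config(C = 1, gamma = "scale"),
    evaluator = "kfold", kfold_k = 5, seed = 1,
    bpb_w_step = 0.05, psenc_w_step = 0.05,
    bpb_fine_span = 4, psenc_fine_span = 4
  )
  res <- run_full_selection(sel_data$d, "I", cfg)
  ss <- res$stage_summary
  # accuracy never regresses across accepted stages
  expect_true(all(diff(ss$acc) >= -1e-12))
  expect_equal(res$best_acc, max(ss$acc))
  expect_equal(res$best_acc, ss$acc[nrow(ss)])
  # planted C-composition shift: NC_C is the top-ranked NC candidate
  fam <- enhancr:::feature_family(colnames(sel_data$X))
  rk_nc <- fscore(sel_data$X[, fam == "NC"], sel_data$y)
  expect_equal(rk_nc$feature[1], "NC_C")
  # determinism: identical rerun
  res2 <- run_full_selection(sel_data$d, "I", cfg)
  expect_identical(res$selected, res2$selected)
  expect_identical(res$best_acc, res2$best_acc)
  expect_identical(tidy(res), tidy(res2))
  # the final set only contains known feature names
  expect_true(all(enhancr:::feature_family(res$selected) %in%
                    c("BPB", "NC", "PseNC")))
})

test_that("disabling all scans returns the full unselected feature set", {
  cfg <- selection_config(svm = svm_config(C = 1, gamma = "scale"),
                          evaluator = "kfold", kfold_k = 5,
                          stages = character(0))
  res <- run_full_selection(sel_data$d, "I", cfg)
  expect_equal(length(res$selected), ncol(sel_data$X))
  expect_equal(res$stage_summary$stage, "none")
})

test_that("selection results tidy and glance coherently", {
  fam <- enhancr:::feature_family(colnames(sel_data$X))
  rk <- fscore(sel_data$X[, fam == "BPB"], sel_data$y)
  res <- fine_dimension_scan(sel_data$X, sel_data$y, rk, sel_data$ev,
                             d_min = 2, d_max = 10, step = 4)
  g <- glance(res)
  expect_equal(g$n_selected, length(res$selected))
  expect_equal(g$best_acc, res$best_acc)
  expect_equal(g$n_bpb + g$n_nc + g$n_psenc, g$n_selected)
  expect_s3_class(autoplot(res), "ggplot")
  expect_s3_class(autoplot(rk), "ggplot")
})
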