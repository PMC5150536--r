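test_that("generation is reproducible and byte-identical for a fixed seed", {
  spec <- generator_spec(n = 50, class_sizes = c(strong_enhancer = 10,
                                                 weak_enhancer = 10,
                                                 non_enhancer = 20),
                         seed = 11)
  d1 <- generate_dataset(spec)
  d2 <- generate_dataset(spec)
  expect_identical(d1$seq, d2$seq)
  f1 <- withr::local_tempfile(fileext = ".fa")
  f2 <- withr::local_tempfile(fileext = ".fa")
  write_fasta(d1, f1); write_fasta(d2, f2)
  expect_identical(readLines(f1), readLines(f2))
  # and a different seed gives different sequences
  d3 <- generate_dataset(generator_spec(n = 50,
                                        class_sizes = spec$class_sizes,
                                        seed = 12))
  expect_false(identical(d1$seq, d3$seq))
})

test_that("generator specifications validate their inputs", {
  expect_error(generator_spec(n = 2), "at least 3")
  expect_error(generator_spec(effect_size = 2), "effect_size")
  expect_error(generator_spec(class_sizes = c(10, 10)), "named")
  expect_error(generator_spec(
    n = 10,
    positional_signal = tibble::tibble(class = "enhancer", position = 50,
                                       base = "G", boost = 0.3)
  ), "exceed")
  expect_error(generator_spec(background = c(A = 1, C = 1, G = 0, T = 0)),
               "probability")
})

test_that("truth reports name exactly the planted features", {
  comp_only <- generator_spec(
    n = 30, class_sizes = c(positive = 5, negative = 5),
    positional_signal = NULL, trimer_signal = NULL,
    composition_shift = list(positive = c(A = -0.02, C = 0.06, G = -0.02,
                                          T = -0.02)),
    seed = 1
  )
  tr <- truth_report(comp_only)
  direct <- tr[!tr$indirect, ]
  expect_setequal(direct$feature, c("NC_A", "NC_C", "NC_G", "NC_T"))
  expect_true(all(tr$family[tr$indirect] == "PseNC"))
  # a G boost at position 17 names both BPB features for that position
  pos17 <- generator_spec(
    n = 30, class_sizes = c(positive = 5, negative = 5),
    positional_signal = tibble::tibble(class = "positive", position = 17,
                                       base = "G", boost = 0.3),
    composition_shift = NULL, trimer_signal = NULL, seed = 1
  )
  expect_setequal(truth_report(pos17)$feature,
                  c("BPB_pos_17", "BPB_neg_17"))
  # no signal at all -> empty manifest
  null_spec <- generator_spec(n = 30, class_sizes = c(positive = 5,
                                                      negative = 5),
                              positional_signal = NULL,
                              composition_shift = NULL, trimer_signal = NULL,
                              seed = 1)
  expect_equal(nrow(truth_report(null_spec)), 0L)
  expect_equal(nrow(truth_report(generator_spec(n = 50, effect_size = 0))), 0L)
})

test_that("null F-score calibration: ~5% of features exceed the permuted 95th percentile", {
  spec <- generator_spec(n = 500, class_sizes = c(positive = 100,
                                                  negative = 100),
                         positional_signal = NULL, composition_shift = NULL,
                         trimer_signal = NULL, effect_size = 0, seed = 53)
  d <- generate_dataset(spec)
  v <- layer_view(d, "I")
  score_bpb <- function(y) {
    bpb <- fit_bpb(v[y == "positive", ], v[y == "negative", ])
    r <- fscore(encode_bpb(bpb, v), y)   # 1000 BPB features
    r$fscore
  }
  f_true <- score_bpb(v$y)
  set.seed(54)
  y_perm <- factor(sample(as.character(v$y)),
                   levels = c("negative", "positive"))
  f_ref <- score_bpb(y_perm)
  frac <- mean(f_true > stats::quantile(f_ref, 0.95))
  expect_gte(frac, 0.02)
  expect_lte(frac, 0.08)
})

test_that("planted F-score signal grows with effect size", {
  mean_planted_f <- function(effect, seed) {
    spec <- generator_spec(
      n = 60, class_sizes = c(positive = 100, negative = 100),
      positional_signal = tibble::tibble(class = "positive",
                                         position = seq(5, 50, by = 5),
                                         base = "G", boost = 0.4),
      composition_shift = NULL, trimer_signal = NULL,
      effect_size = effect, seed = seed
    )
    d <- generate_dataset(spec)
    v <- layer_view(d, "I")
    bpb <- fit_bpb(v[v$y == "positive", ], v[v$y == "negative", ])
    r <- fscore(encode_bpb(bpb, v), v$y)
    planted <- c(paste0("BPB_pos_", seq(5, 50, by = 5)),
                 paste0("BPB_neg_", seq(5, 50, by = 5)))
    mean(r$fscore[r$feature %in% planted])
  }
  for (seed in c(61, 62, 63)) {
    f <- vapply(c(0, 0.5, 1), mean_planted_f, numeric(1), seed = seed)
    expect_true(all(diff(f) > 0))
  }
})

test_that("a +0.06 C shift lifts NC_C above the other NC features", {
  spec <- generator_spec(
    n = 100, class_sizes = c(positive = 200, negative = 200),
    positional_signal = NULL, trimer_signal = NULL,
    composition_shift = default_composition_shift(0.06),
    seed = 67
  )
  # default shift targets enhancer classes; relabel for a binary run
  spec$composition_shift <- list(positive = spec$composition_shift$enhancer)
  d <- generate_dataset(spec)
  v <- layer_view(d, "I")
  r <- fscore(encode_nc(v), v$y)
  f <- setNames(r$fscore, r$feature)
  expect_gt(f[["NC_C"]], stats::median(f[c("NC_A", "NC_T", "NC_G")]))
  expect_equal(r$feature[1], "NC_C")
})

test_that("trimer enrichment raises the planted trinucleotide frequencies", {
  base_spec <- generator_spec(
    n = 100, class_sizes = c(positive = 100, negative = 100),
    positional_signal = NULL, composition_shift = NULL,
    trimer_signal = tibble::tibble(class = "positive",
                                   trimer = c("ATA", "GGC"), multiplier = 2),
    seed = 71
  )
  d <- generate_dataset(base_spec)
  v <- layer_view(d, "I")
  P <- encode_psenc(v)
  pos_mean <- colMeans(P[v$y == "positive", c("PseNC_ATA", "PseNC_GGC")])
  neg_mean <- colMeans(P[v$y == "negative", c("PseNC_ATA", "PseNC_GGC")])
  # doubled expectation, within sampling tolerance
  expect_true(all(pos_mean / neg_mean > 1.5))
})

test_that("exported synthetic datasets carry manifest and truth files", {
  spec <- generator_spec(n = 40, class_sizes = c(strong_enhancer = 5,
                                                 weak_enhancer = 5,
                                                 non_enhancer = 10),
                         seed = 73)
  d <- generate_dataset(spec)
  dir <- withr::local_tempdir()
  export_synthetic(d, dir)
  expect_true(file.exists(file.path(dir, "manifest.tsv")))
  expect_true(file.exists(file.path(dir, "truth.tsv")))
  back <- read_dataset_manifest(file.path(dir, "manifest.tsv"))
  expect_equal(nrow(back), 20L)
  truth <- read.delim(file.path(dir, "truth.tsv"))
  expect_true(all(c("family", "feature", "layer", "effect", "indirect") %in%
                    names(truth)))
})
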