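test_that("BPB fitting reproduces hand-counted frequencies", {
  m <- fit_bpb(c("ACG", "ACG", "ATG"), c("TTT", "TTT"))
  expect_equal(unname(m$pos_freq[, 2]), c(0, 2 / 3, 0, 1 / 3))  # A C G T
  expect_equal(unname(m$neg_freq[, 1]), c(0, 0, 0, 1))
  # singleton / identical-class columns are indicator vectors
  one <- fit_bpb("ACG", c("TTT", "GGG"))
  expect_true(all(apply(one$pos_freq, 2, max) == 1))
  same <- fit_bpb(c("ACG", "ACG"), "TTT")
  expect_equal(unname(same$pos_freq["C", 2]), 1)
  expect_error(fit_bpb(character(0), "TTT"), "non-empty")
  expect_error(fit_bpb(c("ACG", "ACGT"), "TTT"), "length")
})

test_that("BPB encoding looks up per-position class frequencies", {
  m <- fit_bpb(c("ACG", "ACG", "ATG"), c("TTT", "TTT"))
  v <- encode_bpb(m, "ACG")
  expect_equal(unname(v[1, ]), c(1, 2 / 3, 1, 0, 0, 0))
  expect_error(encode_bpb(m, "ACGT"), "length")
  # n = 200 input gives a 400-dimensional vector
  set.seed(21)
  big <- fit_bpb(rand_seqs(5, 200), rand_seqs(5, 200))
  expect_equal(ncol(encode_bpb(big, rand_seqs(1, 200))), 400L)
  # a positive training sequence always has positive first-half entries
  pos <- rand_seqs(4, 30)
  mm <- fit_bpb(pos, rand_seqs(4, 30))
  expect_true(all(encode_bpb(mm, pos[1])[1, 1:30] > 0))
})

test_that("NC and PseNC match their closed-form examples and normalise", {
  expect_equal(unname(encode_nc("AAAA")[1, ]), c(1, 0, 0, 0))
  expect_equal(unname(encode_nc("ACGT")[1, ]), rep(0.25, 4))
  p <- encode_psenc("AAAA")
  expect_equal(unname(p[1, "PseNC_AAA"]), 1)
  expect_equal(sum(p), 1)
  p2 <- encode_psenc("ACGTA")
  expect_equal(
    unname(p2[1, c("PseNC_ACG", "PseNC_CGT", "PseNC_GTA")]),
    rep(1 / 3, 3),
    ignore_attr = TRUE
  )
  expect_equal(ncol(p2), 64L)
  set.seed(5)
  s <- rand_seqs(10, 37)
  expect_equal(unname(rowSums(encode_nc(s))), rep(1, 10))
  expect_equal(unname(rowSums(encode_psenc(s))), rep(1, 10))
  expect_error(encode_psenc("AC"), "at least 3")
  expect_error(encode_nc(""), "empty")
})

test_that("encoders agree with naive character-scanning references", {
  set.seed(7)
  for (rep in 1:5) {
    n <- sample(4:12, 1)
    pos <- rand_seqs(sample(2:6, 1), n)
    neg <- rand_seqs(sample(2:6, 1), n)
    ref <- ref_fit_bpb(pos, neg)
    m <- fit_bpb(pos, neg)
    expect_equal(unname(m$pos_freq), unname(ref$pos), tolerance = 1e-10)
    expect_equal(unname(m$neg_freq), unname(ref$neg), tolerance = 1e-10)
    probe <- rand_seqs(3, n)
    expect_equal(unname(encode_bpb(m, probe)[2, ]),
                 ref_encode_bpb(ref, probe[2]), tolerance = 1e-10)
    expect_equal(unname(encode_nc(probe)[1, ]), unname(ref_nc(probe[1])),
                 tolerance = 1e-10)
    expect_equal(unname(encode_psenc(probe)[3, ]),
                 unname(ref_psenc(probe[3])), tolerance = 1e-10)
  }
})

test_that("fitted BPB frequency columns are stochastic within 1e-12", {
  set.seed(9)
  m <- fit_bpb(rand_seqs(25, 40), rand_seqs(30, 40))
  expect_equal(colSums(m$pos_freq), rep(1, 40), tolerance = 1e-12)
  expect_equal(colSums(m$neg_freq), rep(1, 40), tolerance = 1e-12)
  expect_true(all(m$pos_freq >= 0 & m$pos_freq <= 1))
  sm <- fit_bpb(rand_seqs(5, 10), rand_seqs(5, 10), alpha = 1)
  expect_equal(colSums(sm$pos_freq), rep(1, 10), tolerance = 1e-12)
  expect_true(all(sm$pos_freq > 0))  # smoothing removes exact zeros
})

test_that("dataset encoding concatenates families with stable names", {
  set.seed(13)
  d <- validate_dataset(tibble::tibble(
    id = sprintf("s%d", 1:6), seq = rand_seqs(6, 200),
    label = rep(c("positive", "negative"), 3)
  ))
  bpb <- fit_bpb(d$seq[d$label == "positive"], d$seq[d$label == "negative"])
  F <- encode_dataset(d, bpb)
  expect_equal(ncol(F) - 1L, 400L + 4L + 64L)  # 468 features + sample_id
  expect_equal(F$sample_id, d$id)
  expect_false(anyDuplicated(names(F)) > 0)
  fam <- feature_family(setdiff(names(F), "sample_id"))
  expect_equal(unname(table(fam)[c("BPB", "NC", "PseNC")]), c(400L, 4L, 64L),
               ignore_attr = TRUE)
  nc_only <- encode_dataset(d, families = "NC")
  expect_equal(names(nc_only), c("sample_id", "NC_A", "NC_T", "NC_G", "NC_C"))
  expect_error(encode_dataset(d, families = character(0)), "at least one")
  expect_error(encode_dataset(d, bpb = NULL, families = "BPB"), "bpb_model")
})

test_that("permuting dataset order permutes feature rows identically", {
  set.seed(17)
  d <- validate_dataset(tibble::tibble(
    id = sprintf("s%d", 1:8), seq = rand_seqs(8, 25),
    label = rep(c("positive", "negative"), 4)
  ))
  bpb <- fit_bpb(d$seq[d$label == "positive"], d$seq[d$label == "negative"])
  F1 <- encode_dataset(d, bpb)
  perm <- sample(nrow(d))
  F2 <- encode_dataset(d[perm, ], bpb)
  expect_equal(F2, F1[perm, ], ignore_attr = TRUE)
})

test_that("BPB and feature tables survive a TSV round-trip", {
  set.seed(19)
  d <- validate_dataset(tibble::tibble(
    id = c("x", "y"), seq = rand_seqs(2, 12),
    label = c("positive", "negative")
  ))
  m <- fit_bpb(rand_seqs(4, 12), rand_seqs(4, 12))
  tf <- withr::local_tempfile(fileext = ".tsv")
  write_bpb(m, tf)
  back <- read_bpb(tf)
  expect_equal(back$pos_freq, m$pos_freq, tolerance = 1e-12)
  expect_equal(back$neg_freq, m$neg_freq, tolerance = 1e-12)
  F <- encode_dataset(d, m)
  tf2 <- withr::local_tempfile(fileext = ".tsv")
  write_features(F, tf2)
  expect_equal(read_features(tf2), F, tolerance = 1e-12)
})
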