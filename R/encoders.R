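# Sequence encoders: bi-profile Bayes (2n features), mononucleotide
# composition (4), trinucleotide / pseudo-nucleotide composition (64).
#
# All three families are frequencies, so every feature lies in [0, 1] and no
# rescaling is needed before the SVM.

#' Fit a bi-profile Bayes model
#'
#' Estimates, separately for the positive and the negative training class,
#' the per-position nucleotide frequencies of fixed-length sequences. The
#' resulting model encodes any length-`n` sequence as a 2n-vector of
#' posterior probabilities: positions 1..n are the frequencies of the
#' sequence's observed bases in the positive class, positions n+1..2n the
#' frequencies in the negative class.
#'
#' @param positives,negatives Character vectors of sequences, or dataset
#'   tibbles with a `seq` column. Both classes must be non-empty and all
#'   sequences of length `n`.
#' @param n Sequence length; inferred from the data when `NULL`.
#' @param alpha Additive (Laplace) smoothing pseudocount per base, default 0
#'   (raw frequencies). With `alpha > 0` column `j` of each frequency matrix
#'   is `(counts + alpha) / (m_j + 4 alpha)`.
#' @return A `bpb_model`: list with `n`, `pos_freq` and `neg_freq` (4 x n
#'   matrices, rows A/C/G/T, columns summing to 1 when no positions are
#'   masked), and `alpha`.
#' @examples
#' fit_bpb(c("ACG", "ACG", "ATG"), c("TTT", "TTT"))
#' @export
fit_bpb <- function(positives, negatives, n = NULL, alpha = 0) {
  pos <- if (is.data.frame(positives)) positives$seq else positives
  neg <- if (is.data.frame(negatives)) negatives$seq else negatives
  if (length(pos) == 0L || length(neg) == 0L) {
    abort("both classes must be non-empty to fit a bi-profile Bayes model")
  }
  n <- n %||% nchar(pos[1])
  if (any(nchar(c(pos, neg)) != n)) {
    abort(sprintf("all sequences must have length %d to fit BPB", n))
  }
  structure(
    list(
      n = as.integer(n),
      pos_freq = position_freqs(seq_matrix(pos), n, alpha),
      neg_freq = position_freqs(seq_matrix(neg), n, alpha),
      alpha = alpha
    ),
    class = "bpb_model"
  )
}

# 4 x n frequency matrix from an integer sequence matrix; masked (NA)
# positions contribute nothing and shrink that column's denominator
position_freqs <- function(S, n, alpha = 0) {
  counts <- vapply(seq_len(n), function(j) tabulate(S[, j], nbins = 4L),
                   integer(4))
  denom <- colSums(counts) + 4 * alpha
  denom[denom == 0] <- NA_real_  # column entirely masked
  f <- sweep(counts + alpha, 2, denom, "/")
  f[is.na(f)] <- 0.25
  dimnames(f) <- list(BASES, NULL)
  f
}

#' @export
print.bpb_model <- function(x, ...) {
  cat(sprintf("<bpb_model> n = %d, alpha = %g\n", x$n, x$alpha))
  invisible(x)
}

#' Encode sequences with a fitted bi-profile Bayes model
#'
#' @param model A `bpb_model` from [fit_bpb()].
#' @param seqs Character vector of sequences (or dataset tibble), each of
#'   length `model$n`. Masked (non-ACGT) positions look up the uniform value
#'   0.25.
#' @return A numeric matrix, one row per sequence, with 2n columns named
#'   `BPB_pos_1..n`, `BPB_neg_1..n`; all entries in \[0, 1\].
#' @export
encode_bpb <- function(model, seqs) {
  stopifnot(inherits(model, "bpb_model"))
  s <- if (is.data.frame(seqs)) seqs$seq else seqs
  if (any(nchar(s) != model$n)) {
    abort(sprintf("sequences must have length %d to be BPB-encoded", model$n))
  }
  S <- seq_matrix(s)
  out <- cbind(bpb_lookup(S, model$pos_freq), bpb_lookup(S, model$neg_freq))
  colnames(out) <- c(paste0("BPB_pos_", seq_len(model$n)),
                     paste0("BPB_neg_", seq_len(model$n)))
  rownames(out) <- if (is.data.frame(seqs)) seqs$id else NULL
  out
}

bpb_lookup <- function(S, freq) {
  m <- nrow(S); n <- ncol(S)
  idx <- cbind(as.vector(S), rep(seq_len(n), each = m))
  v <- freq[idx]
  v[is.na(v)] <- 0.25  # masked base
  matrix(v, m, n)
}

#' Mononucleotide composition
#'
#' Normalised single-base frequencies in the fixed order (A, T, G, C).
#' Masked positions are excluded from both numerator and denominator.
#'
#' @param seqs Character vector of sequences or a dataset tibble.
#' @return Numeric matrix, one row per sequence, columns
#'   `NC_A, NC_T, NC_G, NC_C`; each row sums to 1.
#' @examples
#' encode_nc("ACGT")
#' @export
encode_nc <- function(seqs) {
  s <- if (is.data.frame(seqs)) seqs$seq else seqs
  if (any(nchar(s) == 0L)) abort("cannot encode an empty sequence")
  S <- seq_matrix(s)
  counts <- t(apply(S, 1, tabulate, nbins = 4L))  # A C G T
  valid <- rowSums(counts)
  if (any(valid == 0L)) abort("sequence with no unambiguous bases")
  out <- (counts / valid)[, match(NC_ORDER, BASES), drop = FALSE]
  colnames(out) <- paste0("NC_", NC_ORDER)
  rownames(out) <- if (is.data.frame(seqs)) seqs$id else NULL
  out
}

#' Trinucleotide (pseudo-nucleotide) composition
#'
#' Frequencies of the 64 overlapping trinucleotides, lexicographic
#' (AAA, AAC, ..., TTT): counts over the n-2 sliding windows divided by the
#' number of unambiguous windows. Windows containing a masked base are
#' skipped.
#'
#' @param seqs Character vector of sequences (length >= 3) or a dataset
#'   tibble.
#' @return Numeric matrix, one row per sequence, 64 columns named
#'   `PseNC_AAA`, ...; each row sums to 1.
#' @examples
#' encode_psenc("ACGTA")
#' @export
encode_psenc <- function(seqs) {
  s <- if (is.data.frame(seqs)) seqs$seq else seqs
  if (any(nchar(s) < 3L)) {
    abort("sequences must be at least 3 bp for trinucleotide composition")
  }
  S <- seq_matrix(s)
  n <- ncol(S)
  w <- seq_len(n - 2L)
  # trimer code in 1..64 per window; NA where any base is masked
  code <- 16L * (S[, w, drop = FALSE] - 1L) +
    4L * (S[, w + 1L, drop = FALSE] - 1L) +
    S[, w + 2L, drop = FALSE]
  out <- t(apply(code, 1, function(r) {
    r <- r[!is.na(r)]
    if (length(r) == 0L) abort("sequence with no unambiguous trinucleotide window")
    tabulate(r, nbins = 64L) / length(r)
  }))
  colnames(out) <- paste0("PseNC_", TRIMERS)
  rownames(out) <- if (is.data.frame(seqs)) seqs$id else NULL
  out
}

#' Encode a dataset into a feature tibble
#'
#' Concatenates the requested feature families in the fixed order BPB, NC,
#' PseNC. Row order follows the dataset; feature names are stable and encode
#' family and origin (`BPB_pos_17`, `NC_C`, `PseNC_ATA`).
#'
#' @param data Dataset tibble (columns `id`, `seq`, ...).
#' @param bpb A fitted `bpb_model`; required iff `"BPB"` is requested.
#' @param families Subset of `c("BPB", "NC", "PseNC")`.
#' @return A tibble with `sample_id` as its first column and one numeric
#'   column per feature (2n + 4 + 64 = 468 for all families at n = 200).
#' @export
encode_dataset <- function(data, bpb = NULL,
                           families = c("BPB", "NC", "PseNC")) {
  if (length(families) == 0L) abort("at least one feature family is required")
  families <- match.arg(families, several.ok = TRUE)
  blocks <- list()
  if ("BPB" %in% families) {
    if (is.null(bpb)) abort("BPB features require a fitted bpb_model")
    blocks$BPB <- encode_bpb(bpb, data)
  }
  if ("NC" %in% families) blocks$NC <- encode_nc(data)
  if ("PseNC" %in% families) blocks$PseNC <- encode_psenc(data)
  X <- do.call(cbind, unname(blocks))
  dplyr::bind_cols(tibble(sample_id = data$id), as_tibble(X))
}

#' Family of each feature name
#'
#' @param features Character vector of feature names.
#' @return Character vector among `"BPB"`, `"NC"`, `"PseNC"`.
#' @export
feature_family <- function(features) {
  fam <- dplyr::case_when(
    grepl("^BPB_(pos|neg)_\\d+$", features) ~ "BPB",
    grepl("^NC_[ATGC]$", features) ~ "NC",
    grepl("^PseNC_[ACGT]{3}$", features) ~ "PseNC",
    TRUE ~ NA_character_
  )
  if (anyNA(fam)) {
    abort(paste0("unrecognised feature name(s): ",
                 paste(features[is.na(fam)], collapse = ", ")))
  }
  fam
}

# feature tibble -> plain numeric matrix (sample_id column dropped)
feature_matrix <- function(features) {
  if (is.matrix(features)) return(features)
  ids <- features$sample_id
  X <- as.matrix(features[setdiff(names(features), "sample_id")])
  rownames(X) <- ids
  X
}

# serialization ---------------------------------------------------------------

#' Write/read a bi-profile Bayes model as TSV
#'
#' Human-inspectable format: long table with columns `class`
#' (positive/negative), `base`, `position`, `freq`.
#'
#' @param model A `bpb_model`.
#' @param path TSV path.
#' @return `path` (write) or a `bpb_model` (read).
#' @export
write_bpb <- function(model, path) {
  write.table(tidy(model), path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_bpb
#' @export
read_bpb <- function(path) {
  d <- read.delim(path, stringsAsFactors = FALSE)
  n <- max(d$position)
  grab <- function(cls) {
    dd <- d[d$class == cls, ]
    m <- matrix(0, 4, n, dimnames = list(BASES, NULL))
    m[cbind(match(dd$base, BASES), dd$position)] <- dd$freq
    m
  }
  structure(
    list(n = as.integer(n), pos_freq = grab("positive"),
         neg_freq = grab("negative"), alpha = NA_real_),
    class = "bpb_model"
  )
}

#' Write/read a feature tibble as TSV
#'
#' @param features Feature tibble from [encode_dataset()].
#' @param path TSV path.
#' @return `path` (write) or the feature tibble (read).
#' @export
write_features <- function(features, path) {
  write.table(features, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_features
#' @export
read_features <- function(path) {
  as_tibble(read.delim(path, stringsAsFactors = FALSE, check.names = FALSE))
}
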