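# Naive character-scanning reference implementations, written independently
# of the package internals, used as oracles for the encoders and the F-score.

ref_fit_bpb <- function(pos, neg) {
  n <- nchar(pos[1])
  count_class <- function(seqs) {
    m <- matrix(0, 4, n, dimnames = list(c("A", "C", "G", "T"), NULL))
    for (s in seqs) {
      for (j in seq_len(n)) {
        b <- substr(s, j, j)
        if (b %in% rownames(m)) m[b, j] <- m[b, j] + 1
      }
    }
    denom <- colSums(m)
    sweep(m, 2, ifelse(denom == 0, 1, denom), "/")
  }
  list(pos = count_class(pos), neg = count_class(neg))
}

ref_encode_bpb <- function(ref, s) {
  n <- nchar(s)
  v <- numeric(2 * n)
  for (j in seq_len(n)) {
    b <- substr(s, j, j)
    v[j] <- if (b %in% rownames(ref$pos)) ref$pos[b, j] else 0.25
    v[n + j] <- if (b %in% rownames(ref$neg)) ref$neg[b, j] else 0.25
  }
  v
}

ref_nc <- function(s) {
  chars <- strsplit(s, "")[[1]]
  chars <- chars[chars %in% c("A", "C", "G", "T")]
  counts <- vapply(c("A", "T", "G", "C"), function(b) sum(chars == b),
                   numeric(1))
  counts / length(chars)
}

ref_psenc <- function(s) {
  bases <- c("A", "C", "G", "T")
  trimers <- character(0)
  for (b1 in bases) for (b2 in bases) for (b3 in bases) {
    trimers <- c(trimers, paste0(b1, b2, b3))
  }
  n <- nchar(s)
  counts <- setNames(numeric(64), trimers)
  valid <- 0
  for (j in seq_len(n - 2)) {
    w <- substr(s, j, j + 2)
    if (w %in% trimers) {
      counts[w] <- counts[w] + 1
      valid <- valid + 1
    }
  }
  counts / valid
}

# direct transcription of the F-score formula, one feature at a time
ref_fscore <- function(X, y) {
  pos <- X[y == "positive", , drop = FALSE]
  neg <- X[y == "negative", , drop = FALSE]
  np <- nrow(pos); nn <- nrow(neg)
  out <- numeric(ncol(X))
  for (i in seq_len(ncol(X))) {
    xb <- mean(X[, i]); xp <- mean(pos[, i]); xn <- mean(neg[, i])
    num <- (xp - xb)^2 + (xn - xb)^2
    den <- sum((pos[, i] - xp)^2) / (np - 1) + sum((neg[, i] - xn)^2) / (nn - 1)
    out[i] <- if (den > 0) num / den else if (num > 0) Inf else 0
  }
  setNames(out, colnames(X))
}

rand_seqs <- function(k, n, alphabet = c("A", "C", "G", "T")) {
  vapply(seq_len(k), function(i) {
    paste(sample(alphabet, n, replace = TRUE), collapse = "")
  }, character(1))
}

# small well-separated 2-D point clouds for SVM tests
toy_clouds <- function(m = 20, gap = 4, seed = 42) {
  set.seed(seed)
  X <- rbind(matrix(rnorm(2 * m), m), matrix(rnorm(2 * m, gap), m))
  colnames(X) <- c("f1", "f2")
  y <- factor(rep(c("negative", "positive"), each = m),
              levels = c("negative", "positive"))
  list(X = X, y = y)
}
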