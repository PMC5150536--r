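# Per-feature F-score: squared separation of the class means from the
# overall mean over the pooled within-class sample variances,
#
#   F(i) = [ (mean_pos - mean)^2 + (mean_neg - mean)^2 ] /
#          [ var_pos + var_neg ]
#
# where var_pos / var_neg are the usual (n-1)-denominator sample variances of
# feature i inside each class. A greater F-score means a greater difference
# between the two classes relative to their scatter.

#' Rank features by F-score
#'
#' @param features Feature tibble (from [encode_dataset()]) or numeric
#'   matrix.
#' @param y Binary labels (factor with levels `c("negative", "positive")`, or
#'   coercible character).
#' @return An `fscore_ranking`: a tibble with one row per feature, columns
#'   `feature`, `fscore`, `rank` (1 = highest), `mean_all`, `mean_pos`,
#'   `mean_neg`, sorted by descending F-score with ties broken by original
#'   column index. Attributes `n_pos` / `n_neg` carry the class sizes.
#'   Constant features (zero numerator and denominator) score 0; features
#'   constant within each class but different between classes score `Inf`
#'   and rank first.
#' @examples
#' X <- cbind(sig = c(2, 4, 0, 2), noise = c(1, 2, 1, 2))
#' fscore(X, c("positive", "positive", "negative", "negative"))
#' @export
fscore <- function(features, y) {
  X <- feature_matrix(features)
  y <- as_binary_factor(y)
  n_pos <- sum(y == "positive")
  n_neg <- sum(y == "negative")
  if (n_pos < 2L || n_neg < 2L) {
    abort("each class needs at least 2 samples for a finite F-score denominator")
  }
  Xp <- X[y == "positive", , drop = FALSE]
  Xn <- X[y == "negative", , drop = FALSE]
  mean_all <- colMeans(X)
  mean_pos <- colMeans(Xp)
  mean_neg <- colMeans(Xn)
  num <- (mean_pos - mean_all)^2 + (mean_neg - mean_all)^2
  den <- apply(Xp, 2, var) + apply(Xn, 2, var)
  f <- ifelse(den > 0, num / den, ifelse(num > 0, Inf, 0))

  ord <- order(-f, seq_along(f))  # ties by original column index
  out <- tibble(
    feature = colnames(X),
    fscore = unname(f),
    mean_all = unname(mean_all),
    mean_pos = unname(mean_pos),
    mean_neg = unname(mean_neg)
  )[ord, ]
  out$rank <- seq_len(nrow(out))
  attr(out, "n_pos") <- n_pos
  attr(out, "n_neg") <- n_neg
  class(out) <- c("fscore_ranking", class(out))
  out
}
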