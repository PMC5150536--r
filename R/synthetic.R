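# Synthetic benchmark generator: labelled fixed-length A/C/G/T fragments with
# three controllable, independently plantable signal kinds --
#   * positional base biases (what the bi-profile Bayes encoding detects),
#   * per-class mononucleotide composition shifts (what NC detects),
#   * trinucleotide enrichment (what PseNC detects),
# all scaled by a global effect size. At effect 0 every class is an
# exchangeable draw from the background, which keeps null calibration
# analytic.

#' Specification for a synthetic enhancer benchmark
#'
#' The defaults emulate the published benchmark's shape: 742 strong
#' enhancers, 742 weak enhancers and 1484 non-enhancers of 200 bp, a
#' C-composition enrichment in enhancers, an enhancer-vs-background
#' positional signal at 10 positions (layer-I signal), an independent
#' strong-vs-weak positional contrast at 10 other positions (layer-II
#' signal), and enrichment of trinucleotides reported informative for this
#' task (ATA, TAT, GGC for layer I; CAG, AGG for layer II).
#'
#' @param n Fragment length in bp (default 200).
#' @param class_sizes Named integer vector of per-class counts. Classes
#'   `strong_enhancer`/`weak_enhancer`/`non_enhancer` give the two-layer
#'   benchmark; any two names give a generic binary dataset.
#' @param positional_signal Tibble with columns `class`, `position`, `base`,
#'   `boost`: at `position`, the emission probability of `base` is raised by
#'   `effect_size * boost` (then renormalised) for the matching class.
#'   `class = "enhancer"` targets both enhancer classes. `NULL` disables.
#' @param composition_shift Named list: class (or `"enhancer"`) to a
#'   length-4 named vector of probability deltas over A/C/G/T summing to 0,
#'   applied (scaled by effect) to the background composition.
#' @param trimer_signal Tibble with columns `class`, `trimer`, `multiplier`:
#'   the expected count of `trimer` is raised toward `multiplier` times its
#'   background expectation by overwrite-insertion. `NULL` disables.
#' @param effect_size Global scalar in \[0, 1\] multiplying all signals; 0
#'   makes all classes exchangeable background draws.
#' @param background Base composition of the background (named, sums to 1).
#' @param seed Integer seed; generation is fully reproducible.
#' @return A `generator_spec` list.
#' @export
generator_spec <- function(n = 200L,
                           class_sizes = c(strong_enhancer = 742L,
                                           weak_enhancer = 742L,
                                           non_enhancer = 1484L),
                           positional_signal = default_positional_signal(n),
                           composition_shift = default_composition_shift(),
                           trimer_signal = default_trimer_signal(),
                           effect_size = 1,
                           background = c(A = 0.25, C = 0.25,
                                          G = 0.25, T = 0.25),
                           seed = 1L) {
  if (n < 3L) abort("n must be at least 3")
  if (is.null(names(class_sizes)) || any(class_sizes < 1L)) {
    abort("class_sizes must be a named vector of positive counts")
  }
  if (effect_size < 0 || effect_size > 1) abort("effect_size must be in [0, 1]")
  background <- background[BASES]
  if (abs(sum(background) - 1) > 1e-8 || any(background < 0)) {
    abort("background must be a probability vector over A/C/G/T")
  }
  if (!is.null(positional_signal)) {
    stopifnot(all(c("class", "position", "base", "boost") %in%
                    names(positional_signal)))
    if (any(positional_signal$position > n)) {
      abort("positional_signal positions exceed n")
    }
    if (any(positional_signal$boost < 0)) abort("boosts must be non-negative")
  }
  structure(
    list(n = as.integer(n), class_sizes = class_sizes,
         positional_signal = positional_signal,
         composition_shift = composition_shift,
         trimer_signal = trimer_signal,
         effect_size = effect_size, background = background,
         seed = as.integer(seed)),
    class = "generator_spec"
  )
}

#' @rdname generator_spec
#' @export
default_positional_signal <- function(n = 200L) {
  # layer-I signal in the first half of the fragment, layer-II in the second,
  # scaled with n so the defaults work at any fragment length >= 40
  pos1 <- unique(pmax(1L, as.integer(round(seq(0.05, 0.45, length.out = 10) * n))))
  pos2 <- unique(pmin(n, as.integer(round(seq(0.52, 0.95, length.out = 10) * n))))
  dplyr::bind_rows(
    tibble(class = "enhancer", position = pos1,
           base = rep_len(c("G", "A"), length(pos1)), boost = 0.35),
    tibble(class = "strong_enhancer", position = pos2,
           base = rep_len(c("T", "C"), length(pos2)), boost = 0.35)
  )
}

#' @rdname generator_spec
#' @export
default_composition_shift <- function(delta = 0.06) {
  list(enhancer = c(A = -delta / 3, C = delta, G = -delta / 3, T = -delta / 3))
}

#' @rdname generator_spec
#' @export
default_trimer_signal <- function() {
  dplyr::bind_rows(
    tibble(class = "enhancer", trimer = c("ATA", "TAT", "GGC"),
           multiplier = 2),
    tibble(class = "strong_enhancer", trimer = c("CAG", "AGG"),
           multiplier = 2)
  )
}

# classes a signal row tagged `cls` applies to
signal_classes <- function(cls, all_classes) {
  if (cls == "enhancer") {
    intersect(c("strong_enhancer", "weak_enhancer"), all_classes)
  } else {
    intersect(cls, all_classes)
  }
}

# per-class base composition after the (effect-scaled) shift
class_composition <- function(spec, cls) {
  p <- spec$background
  for (tag in names(spec$composition_shift %||% list())) {
    if (cls %in% signal_classes(tag, cls)) {
      delta <- spec$composition_shift[[tag]][BASES]
      delta[is.na(delta)] <- 0
      p <- p + spec$effect_size * delta
    }
  }
  if (any(p < 0)) p <- pmax(p, 1e-6)
  p / sum(p)
}

#' Generate a synthetic labelled sequence dataset
#'
#' Draws each class i.i.d. from its (shifted) base composition, resamples the
#' boosted positions from their boosted per-position distributions, and
#' plants extra trinucleotide occurrences by overwrite-insertion with a
#' Poisson count calibrated so the expected enrichment matches the requested
#' multiplier. Fully reproducible from `spec$seed`.
#'
#' @param spec A [generator_spec()].
#' @return A validated dataset ([validate_dataset()]) with the planted-signal
#'   manifest ([truth_report()]) in attribute `"truth"`.
#' @export
generate_dataset <- function(spec) {
  stopifnot(inherits(spec, "generator_spec"))
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(spec$seed)

  n <- spec$n
  e <- spec$effect_size
  out <- vector("list", length(spec$class_sizes))
  all_classes <- names(spec$class_sizes)

  for (ci in seq_along(spec$class_sizes)) {
    cls <- all_classes[ci]
    m <- spec$class_sizes[[ci]]
    p <- class_composition(spec, cls)
    S <- matrix(sample.int(4L, m * n, replace = TRUE, prob = p), m, n)

    boosted <- integer(0)
    ps <- spec$positional_signal
    if (!is.null(ps) && nrow(ps) > 0) {
      hit <- vapply(ps$class, function(tag) cls %in% signal_classes(tag, cls),
                    logical(1))
      for (r in which(hit)) {
        q <- p
        b <- match(ps$base[r], BASES)
        q[b] <- q[b] + e * ps$boost[r]
        q <- q / sum(q)
        j <- ps$position[r]
        S[, j] <- sample.int(4L, m, replace = TRUE, prob = q)
        boosted <- c(boosted, j)
      }
    }

    ts <- spec$trimer_signal
    if (!is.null(ts) && nrow(ts) > 0 && e > 0) {
      hit <- vapply(ts$class, function(tag) cls %in% signal_classes(tag, cls),
                    logical(1))
      # candidate start positions whose 3-bp window avoids boosted positions
      starts <- setdiff(seq_len(n - 2L),
                        unique(c(boosted, boosted - 1L, boosted - 2L)))
      for (r in which(hit)) {
        codes <- match(strsplit(ts$trimer[r], "")[[1]], BASES)
        expect0 <- (n - 2L) * prod(p[codes])
        extra <- (ts$multiplier[r] - 1) * e * expect0
        if (extra <= 0) next
        k <- stats::rpois(m, extra)
        for (i in which(k > 0)) {
          at <- sample(starts, min(k[i], length(starts)))
          for (a in at) S[i, a:(a + 2L)] <- codes
        }
      }
    }

    seqs <- apply(S, 1, function(r) paste(BASES[r], collapse = ""))
    out[[ci]] <- tibble(
      id = sprintf("%s_%04d", cls, seq_len(m)),
      seq = seqs, label = cls
    )
  }

  d <- validate_dataset(dplyr::bind_rows(out), n = n)
  attr(d, "truth") <- truth_report(spec)
  d
}

#' Manifest of planted signals
#'
#' Machine-readable list of the features a generated dataset plants signal
#' in, for recovery scoring: each row names a feature, its family, the layer
#' whose contrast it informs (`"I"` for enhancer-vs-non, `"II"` for
#' strong-vs-weak), the planted effect, and whether the feature is only
#' indirectly affected (trinucleotides perturbed by a composition shift).
#'
#' @param spec A [generator_spec()].
#' @return A tibble with columns `family`, `feature`, `layer`, `effect`,
#'   `indirect`.
#' @export
truth_report <- function(spec) {
  rows <- list()
  layer_of <- function(cls) {
    if (cls %in% c("enhancer", "non_enhancer")) "I"
    else if (cls %in% c("strong_enhancer", "weak_enhancer")) "II"
    else "I"
  }
  ps <- spec$positional_signal
  if (!is.null(ps) && nrow(ps) > 0) {
    rows$pos <- tibble(
      family = "BPB",
      feature = c(paste0("BPB_pos_", ps$position),
                  paste0("BPB_neg_", ps$position)),
      layer = rep(vapply(ps$class, layer_of, character(1)), 2),
      effect = rep(spec$effect_size * ps$boost, 2),
      indirect = FALSE
    )
  }
  cs <- spec$composition_shift
  for (tag in names(cs %||% list())) {
    delta <- cs[[tag]]
    nz <- names(delta)[delta != 0]
    rows[[paste0("nc_", tag)]] <- tibble(
      family = "NC", feature = paste0("NC_", nz), layer = layer_of(tag),
      effect = spec$effect_size * unname(delta[nz]), indirect = FALSE
    )
    # every trinucleotide containing a shifted base moves too
    induced <- TRIMERS[vapply(TRIMERS, function(t) {
      any(strsplit(t, "")[[1]] %in% nz)
    }, logical(1))]
    rows[[paste0("nc_ind_", tag)]] <- tibble(
      family = "PseNC", feature = paste0("PseNC_", induced),
      layer = layer_of(tag), effect = NA_real_, indirect = TRUE
    )
  }
  ts <- spec$trimer_signal
  if (!is.null(ts) && nrow(ts) > 0) {
    rows$tri <- tibble(
      family = "PseNC", feature = paste0("PseNC_", ts$trimer),
      layer = vapply(ts$class, layer_of, character(1)),
      effect = spec$effect_size * (ts$multiplier - 1), indirect = FALSE
    )
  }
  res <- dplyr::bind_rows(rows)
  if (nrow(res) == 0L) {
    return(tibble(family = character(), feature = character(),
                  layer = character(), effect = numeric(),
                  indirect = logical()))
  }
  if (spec$effect_size == 0) res <- res[0, ]
  res
}

#' Write a generated dataset plus its manifest and truth file
#'
#' Writes one FASTA per class, a `manifest.tsv` (path, label) and, when the
#' dataset carries one, the planted-signal manifest as `truth.tsv`.
#'
#' @param data Dataset from [generate_dataset()].
#' @param dir Output directory.
#' @return The manifest path, invisibly.
#' @export
export_synthetic <- function(data, dir) {
  manifest <- export_dataset(data, dir)
  truth <- attr(data, "truth")
  if (!is.null(truth)) {
    write.table(truth, file.path(dir, "truth.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  invisible(manifest)
}
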