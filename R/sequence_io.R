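# Reading, validating and writing fixed-length labelled DNA fragments.
#
# A dataset is an ordinary tibble with columns `id`, `seq`, `label`; after
# validate_dataset() it carries class "enh_dataset" and attributes `n`
# (fragment length) and `ambiguity` (the policy applied). Labels are attached
# from per-class FASTA files or a manifest, never parsed out of headers.

ENHANCER_LABELS <- c("strong_enhancer", "weak_enhancer", "non_enhancer")

#' Read labelled DNA fragments from a FASTA file
#'
#' Reads every entry of a (optionally gzipped) FASTA file, uppercases the
#' sequence, and attaches one class label to all entries. Entry order is
#' preserved.
#'
#' @param path Path to a FASTA file.
#' @param label Class label attached to every record, e.g.
#'   `"strong_enhancer"`, `"weak_enhancer"`, `"non_enhancer"`, or
#'   `"positive"`/`"negative"` for a generic binary task.
#' @return A tibble with columns `id`, `seq`, `label`.
#' @examples
#' tf <- tempfile(fileext = ".fa")
#' writeLines(c(">s1", "ACGTACGT", ">s2", "TTTTACGT"), tf)
#' read_fasta(tf, label = "non_enhancer")
#' @export
read_fasta <- function(path, label) {
  if (!file.exists(path)) {
    abort(paste0("FASTA file not found: ", path))
  }
  set <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) {
      abort(paste0("malformed FASTA in '", path, "': ", conditionMessage(e)))
    }
  )
  if (length(set) == 0L) {
    abort(paste0("empty FASTA file: ", path))
  }
  tibble(
    id = sub("\\s.*$", "", names(set)),
    seq = unname(toupper(as.character(set))),
    label = as.character(label)
  )
}

#' Write a dataset to FASTA
#'
#' Inverse of [read_fasta()]: writes `id` as the header and `seq` as the
#' sequence, preserving row order. Labels are not written into headers; use
#' one file per class (see [export_dataset()]).
#'
#' @param data Tibble with columns `id` and `seq`.
#' @param path Output path (`.gz` suffix compresses).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(data, path) {
  stopifnot(all(c("id", "seq") %in% names(data)))
  set <- Biostrings::BStringSet(setNames(data$seq, data$id))
  Biostrings::writeXStringSet(set, path,
                              compress = grepl("\\.gz$", path))
  invisible(path)
}

#' Read a dataset from a manifest of per-class FASTA files
#'
#' The manifest is a TSV with columns `path` and `label`; relative paths are
#' resolved against the manifest's own directory.
#'
#' @param manifest Path to the manifest TSV.
#' @return A tibble with columns `id`, `seq`, `label`, rows in manifest order.
#' @export
read_dataset_manifest <- function(manifest) {
  m <- read.delim(manifest, stringsAsFactors = FALSE)
  if (!all(c("path", "label") %in% names(m))) {
    abort("manifest must have columns 'path' and 'label'")
  }
  base <- dirname(manifest)
  paths <- ifelse(file.exists(m$path), m$path, file.path(base, m$path))
  dplyr::bind_rows(purrr::map2(paths, m$label, read_fasta))
}

#' Validate a dataset of fixed-length fragments
#'
#' Checks that every sequence has the common length `n` and contains only
#' A/C/G/T. Ambiguous symbols (N, IUPAC codes, ...) are rejected by default;
#' under `ambiguity = "mask"` they are retained but excluded from every
#' downstream count (BPB lookups at masked positions return 0.25, NC and
#' PseNC denominators shrink accordingly).
#'
#' @param data Tibble with columns `id`, `seq`, `label`.
#' @param n Expected fragment length in bp; `NULL` infers it from the first
#'   record (all records must still agree).
#' @param ambiguity `"reject"` (default) or `"mask"`.
#' @return The validated dataset: a tibble of class `enh_dataset` carrying
#'   attributes `n` and `ambiguity`.
#' @examples
#' d <- tibble::tibble(id = c("a", "b"),
#'                     seq = c("ACGTACGT", "GGGGCCCC"),
#'                     label = c("positive", "negative"))
#' validate_dataset(d)
#' @export
validate_dataset <- function(data, n = NULL, ambiguity = c("reject", "mask")) {
  ambiguity <- match.arg(ambiguity)
  stopifnot(all(c("id", "seq", "label") %in% names(data)))
  if (nrow(data) == 0L) abort("dataset has no records")

  data <- dplyr::mutate(data, seq = toupper(.data$seq))
  lens <- nchar(data$seq)
  n <- n %||% lens[1]
  if (any(lens != n)) {
    bad <- data$id[lens != n][1]
    abort(sprintf(
      "all sequences must have length %d; '%s' has length %d",
      n, bad, nchar(data$seq[data$id == bad][1])
    ))
  }

  if (ambiguity == "reject") {
    dirty <- grepl("[^ACGT]", data$seq)
    if (any(dirty)) {
      i <- which(dirty)[1]
      pos <- regexpr("[^ACGT]", data$seq[i])
      abort(sprintf(
        "non-ACGT symbol '%s' in record '%s' at position %d (use ambiguity = \"mask\" to keep such records)",
        substr(data$seq[i], pos, pos), data$id[i], pos
      ))
    }
  }

  out <- as_tibble(data[c("id", "seq", "label")])
  class(out) <- c("enh_dataset", class(out))
  attr(out, "n") <- as.integer(n)
  attr(out, "ambiguity") <- ambiguity
  out
}

#' @export
print.enh_dataset <- function(x, ...) {
  cat(sprintf("<enh_dataset> %d fragments of %d bp (ambiguity: %s)\n",
              nrow(x), attr(x, "n"), attr(x, "ambiguity")))
  print(class_counts(x))
  invisible(x)
}

#' Per-class record counts
#'
#' @param data A dataset tibble with a `label` column.
#' @return A tibble with columns `label` and `n`.
#' @export
class_counts <- function(data) {
  dplyr::count(as_tibble(data)[c("label")], .data$label, name = "n")
}

#' Binary view of a three-class enhancer dataset
#'
#' Layer I ("enhancer") labels strong and weak enhancers positive and
#' non-enhancers negative. Layer II ("strength") keeps only enhancers and
#' labels strong positive, weak negative.
#'
#' @param data Dataset with labels among
#'   `strong_enhancer`/`weak_enhancer`/`non_enhancer`, or already binary with
#'   labels `positive`/`negative` (returned unchanged with `y` added).
#' @param layer `"I"` (enhancer vs non-enhancer) or `"II"` (strong vs weak).
#' @return The (possibly filtered) dataset with an added factor column `y`
#'   with levels `c("negative", "positive")`.
#' @export
layer_view <- function(data, layer = c("I", "II")) {
  layer <- match.arg(layer)
  labs <- unique(data$label)
  if (all(labs %in% c("positive", "negative"))) {
    data$y <- factor(data$label, levels = c("negative", "positive"))
    return(data)
  }
  if (!all(labs %in% ENHANCER_LABELS)) {
    abort(paste0("unknown labels: ",
                 paste(setdiff(labs, ENHANCER_LABELS), collapse = ", ")))
  }
  if (layer == "I") {
    data$y <- factor(
      ifelse(data$label == "non_enhancer", "negative", "positive"),
      levels = c("negative", "positive")
    )
    data
  } else {
    keep <- data$label != "non_enhancer"
    out <- data[keep, , drop = FALSE]
    out$y <- factor(
      ifelse(out$label == "strong_enhancer", "positive", "negative"),
      levels = c("negative", "positive")
    )
    out
  }
}

#' Export a dataset as per-class FASTA files plus a manifest
#'
#' @param data Validated dataset.
#' @param dir Output directory (created if needed).
#' @return Path of the written manifest TSV, invisibly.
#' @export
export_dataset <- function(data, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  labs <- unique(data$label)
  paths <- file.path(dir, paste0(labs, ".fasta"))
  for (i in seq_along(labs)) {
    write_fasta(data[data$label == labs[i], ], paths[i])
  }
  manifest <- file.path(dir, "manifest.tsv")
  write.table(
    data.frame(path = basename(paths), label = labs),
    manifest, sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(manifest)
}

# integer coding -------------------------------------------------------------

# sequences -> m x n integer matrix, A/C/G/T -> 1..4, anything else -> NA
seq_matrix <- function(seqs) {
  n <- nchar(seqs[1])
  m <- matrix(
    match(unlist(strsplit(seqs, "", fixed = TRUE)), BASES),
    nrow = length(seqs), ncol = n, byrow = TRUE
  )
  m
}
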