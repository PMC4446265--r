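# Performance evaluation: auROC, train/test splitting, and validation of
# group predictions against external TF peak sets.

#' Area under the ROC curve
#'
#' `P(score_pos > score_neg) + 0.5 P(tie)`, computed from midranks in
#' `O(n log n)`.
#'
#' @param scores numeric decision values.
#' @param labels +1/-1 (or any two-level coding where positives are
#'   `> 0`).
#' @return auROC in `[0, 1]`.
#' @export
auroc <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  pos <- labels > 0
  n1 <- sum(pos)
  n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0) stop("both classes must be present")
  r <- rank(scores)          # midranks handle ties
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Split top-ranked peaks evenly into training and test sets
#'
#' Takes the `n` strongest peaks by score and splits them into two
#' disjoint halves at random (seeded).  When fewer than `n` peaks are
#' available all peaks are used, with a warning; an odd count puts the
#' extra peak in the training half.
#'
#' @param peaks a `peaks` data frame with a `score` column.
#' @param n number of top peaks to use (default 2000).
#' @param seed integer seed for the split.
#' @return list with `train` and `test`, each a `peaks` data frame.
#' @export
train_test_split <- function(peaks, n = 2000, seed = 1) {
  if (nrow(peaks) < n) {
    warning("only ", nrow(peaks), " peaks available (requested ", n,
            "); using all")
    n <- nrow(peaks)
  }
  top <- peaks[order(-peaks$score)[seq_len(n)], , drop = FALSE]
  idx <- .with_seed(seed, sample(n))
  n_train <- ceiling(n / 2)
  list(train = top[sort(idx[seq_len(n_train)]), , drop = FALSE],
       test = top[sort(idx[-seq_len(n_train)]), , drop = FALSE])
}

#' Validate group predictions against external TF peak sets
#'
#' Labels each training window positive when it overlaps an external
#' TF's peak set (by at least `min_overlap` bases) and computes the
#' auROC of the group's activations against those labels, for every
#' external set; the ranked table answers whether the TF predicted for
#' the group is supported by its ChIP-seq data.
#'
#' @param activations named per-example activations of a group (names =
#'   example ids, which must match `windows$id`).
#' @param windows `labeled_seqs` rows with genomic origins for the same
#'   examples.
#' @param external named list: TF name -> BED path or data frame with
#'   `chrom`, `start`, `end`.
#' @param min_overlap minimum overlap in bases (default 1).
#' @return data frame with `tf`, `auroc`, `n_overlap`, `rank`, sorted by
#'   decreasing auROC.  External sets with zero overlap are skipped with
#'   a warning.
#' @export
validate_group <- function(activations, windows, external,
                           min_overlap = 1) {
  windows <- as_labeled_seqs(windows)
  windows <- windows[!is.na(windows$chrom), , drop = FALSE]
  act <- activations[windows$id]
  if (anyNA(act)) stop("activations missing for some windows")
  q <- GenomicRanges::GRanges(
    windows$chrom,
    IRanges::IRanges(start = windows$start + 1, end = windows$end))

  rows <- list()
  for (tf in names(external)) {
    ext <- external[[tf]]
    if (is.character(ext)) ext <- read_peaks(ext, "bed6")
    s <- GenomicRanges::GRanges(
      ext$chrom, IRanges::IRanges(start = ext$start + 1, end = ext$end))
    # peak sets routinely cover different chromosome subsets
    ov <- suppressWarnings(
      GenomicRanges::countOverlaps(q, s, minoverlap = min_overlap))
    lab <- ifelse(ov > 0, 1, -1)
    if (!any(lab > 0)) {
      warning("no overlap with ", tf, "; skipped")
      next
    }
    if (!any(lab < 0)) {
      warning("all windows overlap ", tf, "; skipped")
      next
    }
    rows[[tf]] <- data.frame(tf = tf, auroc = auroc(act, lab),
                             n_overlap = sum(lab > 0))
  }
  if (!length(rows)) {
    return(data.frame(tf = character(0), auroc = numeric(0),
                      n_overlap = integer(0), rank = integer(0)))
  }
  out <- do.call(rbind, rows)
  out <- out[order(-out$auroc), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}
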