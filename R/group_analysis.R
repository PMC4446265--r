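# Group-level interpretation of a fitted model: class association,
# empirical-null significance calls, hit localization and motif export.

#' Per-group activations and class association
#'
#' The activation of group `g` on example `i` is `w_g . x_{i,g}`, the
#' group's contribution to the decision value.  The loss-form score
#' `score(g, i) = log(1 + exp(-y_i w_g . x_{i,g}))` is summed within each
#' class to give the positive and negative class scores.  Class
#' association defaults to the sign of the mean-activation difference
#' between classes (`method = "activation"`); `method = "score"` instead
#' associates the group with the class whose summed loss-form score is
#' larger.  Note the two conventions can disagree: a group that fits the
#' positive class well makes the positive-class loss small, so the
#' loss-form maximum points at the class the group does not explain.
#'
#' @param fit an `sgl_fit`.
#' @param M a `feature_matrix` over the same feature space.
#' @param g group id.
#' @param method class-association rule (default `"activation"`).
#' @return list with `group`, `class` (+1, -1, or NA for an all-zero
#'   group), `class_score_pos`, `class_score_neg`, and `activations`.
#' @export
class_scores <- function(fit, M, g, method = c("activation", "score")) {
  method <- match.arg(method)
  A <- fit$assignment
  if (g < 1 || g > A$G) stop("no such group: ", g)
  idx <- which(A$group_of == g)
  act <- as.numeric(M$counts[, idx, drop = FALSE] %*% fit$w[idx])
  y <- M$labels
  score_i <- .log1pexp_neg(y * act)
  sp <- sum(score_i[y > 0])
  sn <- sum(score_i[y < 0])

  cls <- if (all(fit$w[idx] == 0)) {
    NA_integer_
  } else if (method == "activation") {
    d <- mean(act[y > 0]) - mean(act[y < 0])
    if (d >= 0) 1L else -1L
  } else {
    if (sp >= sn) 1L else -1L
  }
  list(group = g, class = cls, class_score_pos = sp,
       class_score_neg = sn,
       activations = stats::setNames(act, M$ids))
}

#' Call examples significantly explained by a group
#'
#' For a positive-class group the activations of the negative examples
#' form the empirical null; each positive example gets
#' `p = (1 + #{null >= activation}) / (1 + N_null)` (the +1 correction
#' avoids zero p-values), Benjamini-Hochberg is applied within the
#' group's class, and examples with `q <= fdr` are called significant.
#' For a negative-class group the roles of the classes (and the tail
#' direction) are mirrored.
#'
#' @param activations named per-example activations of the group.
#' @param labels +1/-1 per example.
#' @param class the group's associated class (+1 or -1).
#' @param fdr false discovery rate threshold (default 0.05).
#' @return data frame (one row per member-class example) with
#'   `id`, `activation`, `p`, `q`, `significant`.
#' @export
call_significant <- function(activations, labels, class, fdr = 0.05) {
  stopifnot(class %in% c(-1, 1))
  member <- labels == class
  null <- labels == -class
  if (!any(null)) stop("empty empirical null class")
  a_m <- activations[member]
  a_0 <- activations[null]
  exceed <- if (class > 0) {
    vapply(a_m, function(a) sum(a_0 >= a), numeric(1))
  } else {
    vapply(a_m, function(a) sum(a_0 <= a), numeric(1))
  }
  p <- (1 + exceed) / (1 + length(a_0))
  q <- stats::p.adjust(p, method = "BH")
  out <- data.frame(id = names(activations)[member], activation = a_m,
                    p = p, q = q, significant = q <= fdr,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Group report across all groups of a fit
#'
#' Runs [class_scores()] and [call_significant()] for every group and
#' tabulates class association, class scores, the number of significant
#' examples and motif-finding eligibility (at least `min_examples`
#' significant examples).
#'
#' @inheritParams class_scores
#' @param fdr false discovery rate threshold (default 0.05).
#' @param min_examples minimum significant examples for a group to be
#'   eligible for motif finding (default 25).
#' @return An object of class `group_report`: list with `table` (one row
#'   per group) and `details` (per-group significance data frames).
#' @export
group_report <- function(fit, M, fdr = 0.05, min_examples = 25,
                         method = c("activation", "score")) {
  method <- match.arg(method)
  A <- fit$assignment
  rows <- vector("list", A$G)
  details <- vector("list", A$G)
  for (g in seq_len(A$G)) {
    cs <- class_scores(fit, M, g, method)
    n_sig <- 0L
    if (!is.na(cs$class)) {
      sig <- call_significant(cs$activations, M$labels, cs$class, fdr)
      details[[g]] <- sig
      n_sig <- sum(sig$significant)
    }
    rows[[g]] <- data.frame(
      group = g, size = A$sizes[g],
      nonzero = sum(fit$w[A$group_of == g] != 0),
      class = ifelse(is.na(cs$class), "none",
                     ifelse(cs$class > 0, "+1", "-1")),
      class_score_pos = cs$class_score_pos,
      class_score_neg = cs$class_score_neg,
      n_significant = n_sig,
      eligible_for_motif = n_sig >= min_examples)
  }
  structure(list(table = do.call(rbind, rows), details = details,
                 fdr = fdr, min_examples = min_examples),
            class = "group_report")
}

#' @export
print.group_report <- function(x, ...) {
  print(x$table)
  invisible(x)
}

# per-position group score profile for one encoded sequence:
# at each start position, the sum of weights of group patterns matching
# there (either orientation); NA-free, 0 where nothing matches
.position_scores <- function(seq, fit, g, space) {
  A <- fit$assignment
  wg <- ifelse(A$group_of == g, fit$w, 0)
  codes <- .window_codes(.encode_seq(seq), space$k)
  cols <- .geom_columns(codes, space)
  sc <- matrix(0, nrow(cols), ncol(cols))
  ok <- !is.na(cols)
  sc[ok] <- wg[cols[ok]]
  list(total = rowSums(sc), per_geom = sc, cols = cols)
}

#' Localize the binding hit of a group within each sequence
#'
#' Scores every start position of each sequence by the summed weight of
#' the group's patterns matching there (in either orientation), and
#' reports the maximum-scoring position (leftmost on ties) together with
#' the orientation of the strongest matching pattern (forward preferred
#' on ties) and a 50-base window centered on the matched k-mer, clipped
#' to the sequence bounds.
#'
#' @param fit an `sgl_fit`.
#' @param M the `feature_matrix` the fit was trained on (supplies the
#'   feature space).
#' @param seqs `labeled_seqs` rows for the examples to localize
#'   (typically the significant members of the group).
#' @param g group id.
#' @param q_values optional named q-values to attach to the hits.
#' @param window_bases total hit-window width (default 50).
#' @return data frame of class `hit_calls`: `example_id`, `group`,
#'   `position` (0-based k-mer start), `strand`, `win_start`, `win_end`
#'   (0-based half-open, within the sequence), `activation`, `q`.
#'   Examples where no group pattern matches are skipped with a warning.
#' @export
locate_hits <- function(fit, M, seqs, g, q_values = NULL,
                        window_bases = 50) {
  seqs <- as_labeled_seqs(seqs)
  space <- M$space
  k <- space$k
  half <- window_bases / 2
  rows <- list()
  skipped <- 0L
  for (i in seq_len(nrow(seqs))) {
    ps <- .position_scores(seqs$seq[i], fit, g, space)
    # candidate positions: at least one group pattern with nonzero
    # weight matches there
    matched <- rowSums(abs(ps$per_geom)) > 0
    if (!any(matched)) {
      skipped <- skipped + 1L
      next
    }
    cand <- which(matched)
    pos <- cand[which.max(ps$total[cand])]  # leftmost maximum
    # strongest matching pattern at that position decides the strand
    contrib <- ps$per_geom[pos, ]
    best_geom <- which.max(abs(contrib))   # first (exact) wins ties
    col <- ps$cols[pos, best_geom]
    pat <- space$patterns[col]
    r <- space$geometries$r[best_geom]
    s <- space$geometries$s[best_geom]
    win <- substr(seqs$seq[i], pos, pos + k - 1)
    if (r > 0) {
      substr(win, s, s + r - 1) <- strrep(".", r)
    }
    strand <- if (win == pat) "+" else "-"

    center <- (pos - 1) + floor(k / 2)
    L <- nchar(seqs$seq[i])
    w_start <- max(0, center - half)
    w_end <- min(L, center + half)
    rows[[length(rows) + 1]] <- data.frame(
      example_id = seqs$id[i], group = g, position = pos - 1L,
      strand = strand, win_start = w_start, win_end = w_end,
      activation = sum(ps$total),
      q = if (!is.null(q_values)) unname(q_values[seqs$id[i]]) else NA_real_,
      stringsAsFactors = FALSE)
  }
  if (skipped > 0) {
    warning(skipped, " example(s) skipped: no group pattern matches")
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(example_id = character(0), group = integer(0),
               position = integer(0), strand = character(0),
               win_start = numeric(0), win_end = numeric(0),
               activation = numeric(0), q = numeric(0))
  class(out) <- c("hit_calls", "data.frame")
  out
}

#' Export hit windows as FASTA and BED for motif finding
#'
#' One FASTA record per hit, named `example|group|position` (with a
#' `|len=` tag appended when the window was clipped below the full
#' width); when genomic origins are known a BED6 file in genome
#' coordinates is written alongside.  These files are the hand-off to
#' any external motif discovery tool.
#'
#' @param hits a `hit_calls` data frame from [locate_hits()].
#' @param seqs the `labeled_seqs` the hits refer to.
#' @param fasta_path output FASTA path.
#' @param bed_path optional output BED path.
#' @param window_bases nominal window width used to flag clipping
#'   (default 50).
#' @return Invisible list of written paths.
#' @export
export_hit_windows <- function(hits, seqs, fasta_path, bed_path = NULL,
                               window_bases = 50) {
  seqs <- as_labeled_seqs(seqs)
  ridx <- match(hits$example_id, seqs$id)
  if (anyNA(ridx)) stop("hit references unknown example")
  sub <- substr(seqs$seq[ridx], hits$win_start + 1, hits$win_end)
  nm <- paste(hits$example_id, hits$group, hits$position, sep = "|")
  short <- nchar(sub) < window_bases
  nm[short] <- paste0(nm[short], "|len=", nchar(sub)[short])
  x <- Biostrings::DNAStringSet(sub)
  names(x) <- nm
  Biostrings::writeXStringSet(x, fasta_path)
  paths <- list(fasta = fasta_path)
  known <- !is.na(seqs$chrom[ridx])
  if (!is.null(bed_path) && any(known)) {
    df <- data.frame(
      seqs$chrom[ridx][known],
      format(seqs$start[ridx][known] + hits$win_start[known],
             scientific = FALSE, trim = TRUE),
      format(seqs$start[ridx][known] + hits$win_end[known],
             scientific = FALSE, trim = TRUE),
      nm[known], 0, ifelse(hits$strand[known] == "-", "-", "+"))
    utils::write.table(df, bed_path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    paths$bed <- bed_path
  }
  invisible(paths)
}

#' Position frequency matrix from a group's hits
#'
#' Aligns the matched k-mer occurrences at their start, reverse
#' complements reverse-orientation matches so all instances are in a
#' common orientation, and tabulates base frequencies per column.
#'
#' @param hits a `hit_calls` data frame.
#' @param seqs the `labeled_seqs` the hits refer to.
#' @param k k-mer length of the feature space.
#' @param min_examples minimum number of hits required (default 25).
#' @return A 4 x k integer matrix with rows A, C, G, T; every column
#'   sums to the number of hits.
#' @export
build_group_pfm <- function(hits, seqs, k, min_examples = 25) {
  if (nrow(hits) < min_examples) {
    stop("need at least ", min_examples, " hits to build a PFM, got ",
         nrow(hits))
  }
  seqs <- as_labeled_seqs(seqs)
  ridx <- match(hits$example_id, seqs$id)
  kmer <- substr(seqs$seq[ridx], hits$position + 1, hits$position + k)
  rev <- hits$strand == "-"
  kmer[rev] <- revcomp(kmer[rev])
  mat <- matrix(0L, 4, k, dimnames = list(c("A", "C", "G", "T"), NULL))
  chars <- do.call(rbind, strsplit(kmer, "", fixed = TRUE))
  for (j in seq_len(k)) {
    tab <- table(factor(chars[, j], levels = c("A", "C", "G", "T")))
    mat[, j] <- as.integer(tab)
  }
  mat
}

#' Write PFMs in MEME minimal motif format
#'
#' @param pfms named list of 4 x k PFMs (counts or probabilities).
#' @param path output path.
#' @param background background base frequencies (default uniform).
#' @return `path`, invisibly.
#' @export
write_meme <- function(pfms, path, background = rep(0.25, 4)) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("MEME version 4", "", "ALPHABET= ACGT", "",
               "strands: + -", "",
               "Background letter frequencies",
               paste("A", background[1], "C", background[2],
                     "G", background[3], "T", background[4]), ""), con)
  for (nm in names(pfms)) {
    pfm <- pfms[[nm]]
    n <- sum(pfm[, 1])
    pr <- sweep(pfm, 2, colSums(pfm), "/")
    writeLines(c(paste("MOTIF", nm),
                 paste0("letter-probability matrix: alength= 4 w= ",
                        ncol(pfm), " nsites= ", n)), con)
    writeLines(apply(t(pr), 1, function(r)
      paste(sprintf("%.6f", r), collapse = " ")), con)
    writeLines("", con)
  }
  invisible(path)
}
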