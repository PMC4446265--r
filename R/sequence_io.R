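#' Labeled sequence sets
#'
#' The container passed between window extraction, feature counting and
#' hit localization: one row per fixed-width sequence with a class label
#' (+1 for peak windows, -1 for flank/background windows), an optional
#' task identifier for multitask training, and the genomic origin of the
#' window when it is known.
#'
#' @param id unique sequence identifiers.
#' @param seq sequence strings over A/C/G/T/N (stored uppercase).
#' @param label +1 or -1 per sequence.
#' @param task optional task identifier (NA when single-task).
#' @param chrom,start,end optional genomic origin (0-based half-open).
#' @return A data frame of class `labeled_seqs`.
#' @export
labeled_seqs <- function(id, seq, label, task = NA,
                         chrom = NA, start = NA, end = NA) {
  if (anyDuplicated(id)) {
    stop("duplicate sequence id: ", id[duplicated(id)][1])
  }
  if (!all(label %in% c(-1, 1))) stop("labels must be +1 or -1")
  n <- length(id)
  out <- data.frame(id = as.character(id), seq = toupper(seq),
                    label = as.integer(label),
                    task = rep_len(task, n), chrom = rep_len(chrom, n),
                    start = rep_len(start, n), end = rep_len(end, n),
                    stringsAsFactors = FALSE)
  class(out) <- c("labeled_seqs", "data.frame")
  out
}

#' @rdname labeled_seqs
#' @param x a data frame with at least `id`, `seq`, `label` columns.
#' @export
as_labeled_seqs <- function(x) {
  if (inherits(x, "labeled_seqs")) return(x)
  stopifnot(all(c("id", "seq", "label") %in% names(x)))
  labeled_seqs(x$id, x$seq, x$label,
               task = if ("task" %in% names(x)) x$task else NA,
               chrom = if ("chrom" %in% names(x)) x$chrom else NA,
               start = if ("start" %in% names(x)) x$start else NA,
               end = if ("end" %in% names(x)) x$end else NA)
}

#' Read peak calls from BED6 or ENCODE narrowPeak files
#'
#' Coordinates are 0-based half-open throughout.  For narrowPeak input the
#' summit is `start + offset` where the offset is column 10; an offset of
#' -1 (unknown summit, common in ENCODE releases) and all BED6 records
#' fall back to the interval midpoint `floor((start + end) / 2)`.
#' Records whose resolved summit lies outside the interval are rejected
#' with a warning; malformed lines abort with their line number.
#'
#' @param path peak file path.
#' @param dialect `"bed6"` or `"narrowPeak"`.
#' @return A data frame of class `peaks` with columns `chrom`, `start`,
#'   `end`, `name`, `score`, `strand`, `summit`, in file order.
#' @export
read_peaks <- function(path, dialect = c("bed6", "narrowPeak")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("peak file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  min_fields <- if (dialect == "narrowPeak") 10L else 3L

  fields <- strsplit(lines, "[ \t]+")
  nf <- lengths(fields)
  bad <- which(nf < min_fields)
  if (length(bad)) {
    stop("malformed ", dialect, " line ", bad[1], ": expected >= ",
         min_fields, " fields, got ", nf[bad[1]])
  }
  get <- function(i, default) {
    vapply(fields, function(f) if (length(f) >= i) f[i] else default,
           character(1))
  }
  chrom <- get(1, NA_character_)
  start <- suppressWarnings(as.numeric(get(2, NA_character_)))
  end <- suppressWarnings(as.numeric(get(3, NA_character_)))
  bad <- which(is.na(start) | is.na(end) | end <= start | start < 0)
  if (length(bad)) {
    stop("malformed ", dialect, " line ", bad[1],
         ": invalid coordinates")
  }
  name <- get(4, ".")
  score <- suppressWarnings(as.numeric(get(5, "0")))
  strand <- get(6, ".")
  strand[!strand %in% c("+", "-", ".")] <- "."

  if (dialect == "narrowPeak") {
    offset <- suppressWarnings(as.numeric(get(10, "-1")))
    summit <- ifelse(offset >= 0, start + offset,
                     floor((start + end) / 2))
  } else {
    summit <- floor((start + end) / 2)
  }

  ok <- summit >= start & summit < end
  if (any(!ok)) {
    warning(sum(!ok), " record(s) rejected: summit outside interval")
  }
  out <- data.frame(chrom = chrom, start = start, end = end, name = name,
                    score = score, strand = strand, summit = summit,
                    stringsAsFactors = FALSE)[ok, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("peaks", "data.frame")
  out
}

#' Extract peak and flank windows as labeled sequences
#'
#' The positive example for each peak is a `width`-long window centered on
#' the summit, `[summit - floor(width/2), summit + ceiling(width/2))`.
#' The negative example is a window of the same width centered `flank_gap`
#' bases upstream (lower coordinate) of the summit, which at the defaults
#' (150 bp window, 300 bp gap) leaves a 150 bp gap between the two
#' windows.  Pairs whose windows run past the chromosome bounds are
#' dropped together; sequences with more than `max_n_frac` ambiguous
#' bases are dropped individually.  All sequences are uppercased.
#'
#' @param peaks a `peaks` data frame from [read_peaks()].
#' @param genome a `Biostrings::DNAStringSet`, or a FASTA path.
#' @param width window width in bases (default 150).
#' @param flank_gap distance from summit to flank-window center
#'   (default 300).
#' @param max_n_frac maximum tolerated fraction of N per window
#'   (default 0.1).
#' @return A `labeled_seqs` data frame of positives followed by their
#'   flanks, with genomic origins attached.  Drop counts are reported via
#'   warnings.
#' @export
extract_windows <- function(peaks, genome, width = 150, flank_gap = 300,
                            max_n_frac = 0.1) {
  if (is.character(genome)) genome <- Biostrings::readDNAStringSet(genome)
  names(genome) <- sub("\\s.*$", "", names(genome))
  missing_chr <- setdiff(unique(peaks$chrom), names(genome))
  if (length(missing_chr)) {
    stop("chromosome(s) missing from genome: ",
         paste(missing_chr, collapse = ", "))
  }

  half_lo <- floor(width / 2)
  half_hi <- ceiling(width / 2)
  pos_start <- peaks$summit - half_lo
  pos_end <- peaks$summit + half_hi
  neg_start <- pos_start - flank_gap
  neg_end <- pos_end - flank_gap

  chrlen <- Biostrings::width(genome)[match(peaks$chrom, names(genome))]
  in_bounds <- pos_start >= 0 & pos_end <= chrlen &
    neg_start >= 0 & neg_end <= chrlen
  if (any(!in_bounds)) {
    warning(sum(!in_bounds),
            " peak/flank pair(s) dropped at chromosome bounds")
  }
  idx <- which(in_bounds)
  if (!length(idx)) {
    return(labeled_seqs(character(0), character(0), integer(0)))
  }

  fetch <- function(starts, ends) {
    toupper(as.character(Biostrings::subseq(
      genome[peaks$chrom[idx]], start = starts + 1, end = ends)))
  }
  pos_seq <- fetch(pos_start[idx], pos_end[idx])
  neg_seq <- fetch(neg_start[idx], neg_end[idx])

  mk_id <- function(tag) {
    paste0(peaks$chrom[idx], ":", peaks$summit[idx], ":", tag, ":",
           seq_along(idx))
  }
  out <- labeled_seqs(
    id = c(mk_id("peak"), mk_id("flank")),
    seq = c(pos_seq, neg_seq),
    label = rep(c(1L, -1L), each = length(idx)),
    chrom = rep(peaks$chrom[idx], 2),
    start = c(pos_start[idx], neg_start[idx]),
    end = c(pos_end[idx], neg_end[idx]))

  n_frac <- 1 - nchar(gsub("[^ACGT]", "", out$seq)) / nchar(out$seq)
  if (any(n_frac > max_n_frac)) {
    warning(sum(n_frac > max_n_frac),
            " window(s) dropped: ambiguous-base fraction above ",
            max_n_frac)
    out <- out[n_frac <= max_n_frac, , drop = FALSE]
  }
  rownames(out) <- NULL
  out
}

#' Write and read labeled sequences as FASTA
#'
#' Labels (and tasks, when present) are encoded in the FASTA headers as
#' `id|label=+1|task=...` so a written set round-trips exactly through
#' [read_labeled_fasta()].
#'
#' @param seqs a `labeled_seqs` data frame.
#' @param path output FASTA path.
#' @return `path`, invisibly.
#' @export
write_sequences <- function(seqs, path) {
  seqs <- as_labeled_seqs(seqs)
  if (nrow(seqs) == 0) {
    Biostrings::writeXStringSet(Biostrings::DNAStringSet(), path)
    return(invisible(path))
  }
  headers <- paste0(seqs$id, "|label=", ifelse(seqs$label > 0, "+1", "-1"))
  has_task <- !is.na(seqs$task)
  headers[has_task] <- paste0(headers[has_task], "|task=",
                              seqs$task[has_task])
  x <- Biostrings::DNAStringSet(seqs$seq)
  names(x) <- headers
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' @rdname write_sequences
#' @export
read_labeled_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  if (length(x) == 0) return(labeled_seqs(character(0), character(0), integer(0)))
  parts <- strsplit(names(x), "|", fixed = TRUE)
  label_tag <- vapply(parts, function(p) {
    hit <- grep("^label=", p, value = TRUE)
    if (length(hit) != 1) NA_character_ else sub("^label=", "", hit)
  }, character(1))
  if (anyNA(label_tag)) {
    stop("FASTA header without label tag: ",
         names(x)[which(is.na(label_tag))[1]])
  }
  task_tag <- vapply(parts, function(p) {
    hit <- grep("^task=", p, value = TRUE)
    if (length(hit)) sub("^task=", "", hit[1]) else NA_character_
  }, character(1))
  labeled_seqs(id = vapply(parts, `[`, character(1), 1),
               seq = as.character(x),
               label = as.integer(label_tag),
               task = task_tag)
}

#' Write sequence windows as BED6
#'
#' Emits the genomic origins of a labeled sequence set (peak windows as
#' `+1`-scored records, flanks as `-1`).  Sequences without a known origin
#' are skipped.
#'
#' @param seqs a `labeled_seqs` data frame with origin columns.
#' @param path output BED path.
#' @return `path`, invisibly.
#' @export
write_windows_bed <- function(seqs, path) {
  seqs <- as_labeled_seqs(seqs)
  keep <- !is.na(seqs$chrom)
  df <- data.frame(seqs$chrom[keep],
                   format(seqs$start[keep], scientific = FALSE, trim = TRUE),
                   format(seqs$end[keep], scientific = FALSE, trim = TRUE),
                   seqs$id[keep], seqs$label[keep], ".")
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
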