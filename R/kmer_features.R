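#' Enumerate the wildcard k-mer feature space
#'
#' Builds the dictionary of sequence features used throughout the model:
#' every exact k-mer over A/C/G/T plus every k-mer carrying exactly one
#' interior run of 1..`max_run` consecutive wildcard positions (written
#' `.`, matching any base).  A pattern and its reverse complement describe
#' the same double-stranded signal and are collapsed to a single feature,
#' keeping the lexicographically smaller member (`.` sorts before the
#' bases) as the canonical name.
#'
#' Wildcard runs never touch the first or last position: a pattern with a
#' terminal wildcard is equivalent to a shorter k-mer and would only
#' duplicate information already in the space.
#'
#' @param k k-mer length (default 8).
#' @param max_run maximum wildcard run length, `0 <= max_run <= k - 2`
#'   (default 2).
#' @return An object of class `kmer_space`: a list with `k`, `max_run`,
#'   `patterns` (ordered canonical patterns), `palindromic` (logical),
#'   and internal lookup tables used by [count_features()].
#' @export
#' @examples
#' sp <- kmer_feature_space(k = 2, max_run = 0)
#' sp$patterns  # 10 canonical dimers
kmer_feature_space <- function(k = 8, max_run = 2) {
  if (k < 2) stop("k must be >= 2")
  if (max_run < 0 || max_run > k - 2) {
    stop("max_run must be in [0, k - 2]: a run of length ", max_run,
         " would touch the first or last position of a ", k, "-mer")
  }

  # geometries: r = wildcard run length (0 = exact), s = 1-based run start
  geoms <- data.frame(r = 0L, s = NA_integer_)
  for (r in seq_len(max_run)) {
    starts <- seq.int(2L, k - r)
    geoms <- rbind(geoms, data.frame(r = r, s = starts))
  }

  bases <- c("A", "C", "G", "T")
  decode <- function(codes, m) {
    # codes (0-based) -> matrix of m base characters, most significant first
    out <- matrix("", length(codes), m)
    for (j in seq_len(m)) {
      out[, j] <- bases[(codes %/% 4^(m - j)) %% 4 + 1]
    }
    out
  }

  geom_strings <- vector("list", nrow(geoms))
  for (gi in seq_len(nrow(geoms))) {
    r <- geoms$r[gi]; s <- geoms$s[gi]
    m <- k - r
    chars <- decode(seq.int(0, 4^m - 1), m)
    if (r == 0L) {
      pats <- do.call(paste0, as.data.frame(chars, stringsAsFactors = FALSE))
    } else {
      left <- chars[, seq_len(s - 1), drop = FALSE]
      right <- chars[, s:m, drop = FALSE]
      pats <- do.call(paste0, c(
        as.data.frame(left, stringsAsFactors = FALSE),
        list(strrep(".", r)),
        as.data.frame(right, stringsAsFactors = FALSE)))
    }
    geom_strings[[gi]] <- pats
  }

  all_pats <- unlist(geom_strings, use.names = FALSE)
  rc <- revcomp(all_pats)
  fwd_rank <- .pattern_rank(all_pats)
  rc_rank <- .pattern_rank(rc)
  canon <- ifelse(fwd_rank <= rc_rank, all_pats, rc)

  keep <- !duplicated(canon)
  patterns <- canon[keep]
  palindromic <- (all_pats == rc)[keep]

  # per-geometry map: reduced code (0-based) -> canonical column index
  col_of <- match(canon, patterns)
  maps <- vector("list", nrow(geoms))
  offset <- 0L
  for (gi in seq_len(nrow(geoms))) {
    n_g <- length(geom_strings[[gi]])
    maps[[gi]] <- col_of[offset + seq_len(n_g)]
    offset <- offset + n_g
  }

  structure(
    list(k = as.integer(k), max_run = as.integer(max_run),
         patterns = patterns, palindromic = palindromic,
         geometries = geoms, maps = maps),
    class = "kmer_space")
}

#' @export
print.kmer_space <- function(x, ...) {
  cat("wildcard k-mer feature space: k =", x$k,
      ", max wildcard run =", x$max_run, "\n")
  cat(length(x$patterns), "canonical features (reverse complements collapsed)\n")
  invisible(x)
}

# rolling k-mer codes for one encoded sequence; NA where a window holds
# any non-ACGT base
.window_codes <- function(enc, k) {
  L <- length(enc)
  if (L < k) stop("sequence shorter than k")
  codes <- numeric(L - k + 1)
  for (j in seq_len(k)) {
    codes <- codes * 4 + enc[j:(L - k + j)]
  }
  codes
}

# map window codes to canonical column indices for every geometry;
# returns an integer matrix (positions x geometries), NA where no match
.geom_columns <- function(codes, space) {
  k <- space$k
  gs <- space$geometries
  out <- matrix(NA_integer_, length(codes), nrow(gs))
  for (gi in seq_len(nrow(gs))) {
    r <- gs$r[gi]; s <- gs$s[gi]
    if (r == 0L) {
      reduced <- codes
    } else {
      hi <- codes %/% 4^(k - s + 1)
      lo <- codes %% 4^(k - s - r + 1)
      reduced <- hi * 4^(k - s - r + 1) + lo
    }
    out[, gi] <- space$maps[[gi]][reduced + 1]
  }
  out
}

#' Count wildcard k-mer features in labeled sequences
#'
#' For every sequence and every canonical pattern, counts the positions at
#' which the pattern or its reverse complement matches the forward strand.
#' Occurrences may overlap; palindromic patterns are counted once per
#' position; a wildcard position matches any of A/C/G/T; windows
#' containing N (or any other character) match no pattern at all.
#'
#' @param seqs a `labeled_seqs` object (see [labeled_seqs()]) or any data
#'   frame with columns `id`, `seq`, `label` and optionally `task`.
#' @param space a `kmer_space` from [kmer_feature_space()].
#' @return An object of class `feature_matrix`: list with `counts` (sparse
#'   examples x features matrix), `ids`, `labels` (+1/-1), `tasks`, and
#'   the `space`.
#' @export
count_features <- function(seqs, space) {
  stopifnot(inherits(space, "kmer_space"))
  seqs <- as_labeled_seqs(seqs)
  n <- nrow(seqs)
  k <- space$k
  widths <- nchar(seqs$seq)
  if (any(widths < k)) {
    stop("sequence(s) shorter than k = ", k, ": ",
         paste(utils::head(seqs$id[widths < k], 3), collapse = ", "))
  }

  trip_i <- vector("list", n)
  trip_j <- vector("list", n)
  for (i in seq_len(n)) {
    codes <- .window_codes(.encode_seq(seqs$seq[i]), k)
    cols <- .geom_columns(codes, space)
    j <- cols[!is.na(cols)]
    trip_i[[i]] <- rep.int(i, length(j))
    trip_j[[i]] <- j
  }
  counts <- Matrix::sparseMatrix(
    i = unlist(trip_i), j = unlist(trip_j), x = 1,
    dims = c(n, length(space$patterns)),
    dimnames = list(seqs$id, NULL))

  structure(
    list(counts = counts, ids = seqs$id, labels = seqs$label,
         tasks = if ("task" %in% names(seqs)) seqs$task else rep(NA, n),
         space = space),
    class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat("feature matrix:", nrow(x$counts), "examples x",
      ncol(x$counts), "features\n")
  cat("  labels: ", sum(x$labels > 0), " positive / ",
      sum(x$labels < 0), " negative\n", sep = "")
  invisible(x)
}

# subset a kmer_space to a set of column indices, keeping lookup tables
# consistent (dropped columns map to NA and are ignored when counting)
.subset_space <- function(space, idx) {
  trans <- rep(NA_integer_, length(space$patterns))
  trans[idx] <- seq_along(idx)
  space$patterns <- space$patterns[idx]
  space$palindromic <- space$palindromic[idx]
  space$maps <- lapply(space$maps, function(m) trans[m])
  space
}

#' Select the most discriminative features
#'
#' Ranks features by a scale-free two-class separation score,
#' `|mean(pos) - mean(neg)| / (pooled sd + 1e-8)`, and keeps the `n_top`
#' best.  Ties are broken by dictionary order of the pattern, so the
#' selection is fully deterministic.
#'
#' @param M a `feature_matrix` with both classes present.
#' @param n_top number of features to keep (default 5000; capped at the
#'   number of available features).
#' @return A reduced `feature_matrix` whose `space` is the corresponding
#'   subset of the input space, with example order preserved.
#' @export
select_features <- function(M, n_top = 5000) {
  stopifnot(inherits(M, "feature_matrix"))
  if (n_top <= 0) stop("n_top must be positive")
  y <- M$labels
  if (!any(y > 0) || !any(y < 0)) stop("both classes must be present")

  score <- .discriminative_score(M$counts, y)
  ord <- order(-score, .pattern_rank(M$space$patterns))
  keep <- sort(ord[seq_len(min(n_top, length(score)))])

  M$counts <- M$counts[, keep, drop = FALSE]
  M$space <- .subset_space(M$space, keep)
  M
}

# |mean difference| / pooled sd, computed column-wise on a sparse matrix
.discriminative_score <- function(X, y, eps = 1e-8) {
  pos <- which(y > 0); neg <- which(y < 0)
  n1 <- length(pos); n2 <- length(neg)
  m1 <- Matrix::colMeans(X[pos, , drop = FALSE])
  m2 <- Matrix::colMeans(X[neg, , drop = FALSE])
  ss1 <- Matrix::colSums(X[pos, , drop = FALSE]^2) - n1 * m1^2
  ss2 <- Matrix::colSums(X[neg, , drop = FALSE]^2) - n2 * m2^2
  sd_pool <- sqrt(pmax(ss1 + ss2, 0) / max(n1 + n2 - 2, 1))
  abs(m1 - m2) / (sd_pool + eps)
}
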