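# Independent reference implementations ("oracles") used to check the
# package's algorithms.  These deliberately use different algorithms /
# code paths from the implementation under test.

# ---- generic convex minimizer (scipy SLSQP on an exact smooth
# reformulation); problems is a list of lists, see inst/oracles/ ----
slsqp_oracle <- function(problems) {
  script <- system.file("oracles", "sgl_slsqp.py", package = "peakgl")
  stopifnot(nzchar(script))
  infile <- tempfile(fileext = ".json")
  jsonlite::write_json(problems, infile, auto_unbox = TRUE, digits = NA)
  out <- system2("python", script, stdout = TRUE, stdin = infile)
  jsonlite::fromJSON(paste(out, collapse = ""), simplifyVector = FALSE)
}

# ---- O(n^2) pairwise auROC ----
brute_auroc <- function(scores, labels) {
  pos <- scores[labels > 0]
  neg <- scores[labels < 0]
  total <- 0
  for (a in pos) for (b in neg) {
    total <- total + (a > b) + 0.5 * (a == b)
  }
  total / (length(pos) * length(neg))
}

# ---- brute-force Benjamini-Hochberg step-up: largest i with
# p_(i) <= i/n * alpha; reject all p <= that threshold ----
bh_reject <- function(p, alpha) {
  n <- length(p)
  ps <- sort(p)
  k <- 0
  for (i in seq_len(n)) {
    if (ps[i] <= i / n * alpha) k <- i
  }
  if (k == 0) rep(FALSE, n) else p <= ps[k]
}

# ---- exhaustive enumerate-canonicalize-dedupe feature space oracle ----
oracle_revcomp <- function(x) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", "." = ".")
  vapply(strsplit(x, ""), function(ch)
    paste(rev(unname(comp[ch])), collapse = ""), character(1))
}

oracle_enumerate <- function(k, max_run) {
  bases <- c("A", "C", "G", "T")
  exact <- apply(do.call(expand.grid,
                         rev(rep(list(bases), k))), 1, function(r)
    paste(rev(r), collapse = ""))
  pats <- exact
  if (max_run > 0) {
    for (r in seq_len(max_run)) {
      for (s in 2:(k - r)) {
        core <- apply(do.call(expand.grid,
                              rev(rep(list(bases), k - r))), 1, function(x)
          paste(rev(x), collapse = ""))
        pats <- c(pats, paste0(substr(core, 1, s - 1), strrep(".", r),
                               substr(core, s, k - r)))
      }
    }
  }
  # canonicalize: keep smaller of pattern / revcomp under . < A < C < G < T
  ord_val <- function(x) {
    chartr(".ACGT", "01234", x)
  }
  rc <- oracle_revcomp(pats)
  canon <- ifelse(ord_val(pats) <= ord_val(rc), pats, rc)
  sort(unique(canon))
}

# ---- regex-scan occurrence count of one pattern (both orientations,
# overlaps allowed, palindromes counted once) ----
oracle_pattern_count <- function(seq, pattern) {
  rc <- oracle_revcomp(pattern)
  scan <- function(pat) {
    # "." must not match N: restrict wildcard to ACGT
    re <- gsub(".", "[ACGT]", pat, fixed = TRUE)
    m <- gregexpr(paste0("(?=", re, ")"), seq, perl = TRUE)[[1]]
    if (m[1] == -1) integer(0) else as.integer(m)
  }
  if (pattern == rc) length(scan(pattern))
  else length(unique(c(scan(pattern), scan(rc))))
}

# ---- naive agglomerative clustering (average linkage) on a distance
# matrix; returns cluster memberships at G clusters ----
oracle_average_linkage <- function(D, G) {
  n <- nrow(D)
  clusters <- as.list(seq_len(n))
  while (length(clusters) > G) {
    best <- c(NA, NA)
    best_d <- Inf
    for (a in seq_len(length(clusters) - 1)) {
      for (b in (a + 1):length(clusters)) {
        d <- mean(D[clusters[[a]], clusters[[b]]])
        if (d < best_d) {
          best_d <- d
          best <- c(a, b)
        }
      }
    }
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
  }
  member <- integer(n)
  for (i in seq_along(clusters)) member[clusters[[i]]] <- i
  member
}

# same-partition check up to label permutation
same_partition <- function(a, b) {
  length(unique(a)) == length(unique(b)) &&
    !is.unsorted(tapply(b, a, function(x) length(unique(x)))) &&
    all(tapply(b, a, function(x) length(unique(x))) == 1) &&
    all(tapply(a, b, function(x) length(unique(x))) == 1)
}

# ---- dinucleotide count vector of a sequence ----
dinuc_counts <- function(seq) {
  ch <- strsplit(seq, "")[[1]]
  if (length(ch) < 2) return(table(character(0)))
  table(paste0(ch[-length(ch)], ch[-1]))
}

# ---- direct log-loss summation ----
oracle_logloss <- function(X, y, w) {
  sum(vapply(seq_along(y), function(i)
    log(1 + exp(-y[i] * sum(X[i, ] * w))), numeric(1)))
}
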