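# Programmatic fixtures shared across test files.

# write a tiny two-chromosome genome FASTA; returns its path
toy_genome <- function(seed = 42, len1 = 4000, len2 = 2500) {
  path <- tempfile(fileext = ".fa")
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  s1 <- paste(sample(c("A", "C", "G", "T"), len1, TRUE), collapse = "")
  s2 <- paste(sample(c("A", "C", "G", "T"), len2, TRUE), collapse = "")
  if (!is.null(old)) assign(".Random.seed", old, globalenv())
  writeLines(c(">chr1", s1, ">chr2", s2), path)
  path
}

# write peak lines to a temp file; returns its path
write_peak_file <- function(lines) {
  path <- tempfile(fileext = ".bed")
  writeLines(lines, path)
  path
}

# position probability matrix with one dominant base per position
noisy_ppm <- function(consensus, p = 0.9) {
  ch <- strsplit(consensus, "")[[1]]
  m <- matrix((1 - p) / 3, length(ch), 4,
              dimnames = list(NULL, c("A", "C", "G", "T")))
  m[cbind(seq_along(ch), match(ch, c("A", "C", "G", "T")))] <- p
  m
}

# canonical form of a k-mer under reverse-complement collapsing
canonical_kmer <- function(x) {
  rc <- oracle_revcomp(x)
  ifelse(chartr(".ACGT", "01234", x) <= chartr(".ACGT", "01234", rc), x, rc)
}

# small random two-class feature-matrix-like object for solver tests
random_problem <- function(seed, n = 60, p = 30, G = 5) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  X <- matrix(rpois(n * p, lambda = 1), n, p)
  beta <- rnorm(p, sd = 0.5) * rbinom(p, 1, 0.3)
  pr <- as.numeric(1 / (1 + exp(-(X %*% beta - mean(X %*% beta)))))
  y <- ifelse(runif(n) < pr, 1, -1)
  if (!any(y > 0)) y[1] <- 1
  if (!any(y < 0)) y[1] <- -1
  grp <- sort(rep_len(seq_len(G), p))
  if (!is.null(old)) assign(".Random.seed", old, globalenv())
  M <- structure(list(
    counts = X, labels = y, ids = paste0("ex", seq_len(n)),
    tasks = rep(NA, n),
    space = list(patterns = paste0("f", seq_len(p)))),
    class = "feature_matrix")
  A <- peakgl:::.as_group_assignment(stats::setNames(grp, paste0("f", seq_len(p))))
  list(M = M, A = A, X = X, y = y)
}

# scalar count of one canonical pattern in one example
count_of <- function(M, pattern, row = 1) {
  unname(M$counts[row, match(pattern, M$space$patterns)])
}
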