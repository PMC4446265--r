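# Internal sequence utilities shared across modules.

# byte lookup: A/a=0, C/c=1, G/g=2, T/t=3, everything else NA
.base_lut <- local({
  lut <- rep(NA_integer_, 256)
  for (b in c("A", "C", "G", "T")) {
    code <- match(b, c("A", "C", "G", "T")) - 1L
    lut[as.integer(charToRaw(b)) + 1L] <- code
    lut[as.integer(charToRaw(tolower(b))) + 1L] <- code
  }
  lut
})

# encode one sequence string as integers 0..3 (NA for N or anything else)
.encode_seq <- function(seq) {
  .base_lut[as.integer(charToRaw(seq)) + 1L]
}

#' Reverse complement of DNA strings and wildcard patterns
#'
#' Complements A/C/G/T (case preserved) and leaves the wildcard character
#' `.` unchanged, then reverses the string, so it is valid both for plain
#' sequences and for wildcard k-mer patterns.
#'
#' @param x character vector of DNA strings, possibly containing `.`.
#' @return character vector of reverse complements.
#' @export
#' @examples
#' revcomp(c("ACGT", "AA.T"))
revcomp <- function(x) {
  stringi::stri_reverse(chartr("ACGTacgt.", "TGCAtgca.", x))
}

# Locale-independent lexicographic order value for equal-length patterns
# over the alphabet . < A < C < G < T.  Encodes each string as a base-5
# number; exact for nchar <= 22 in double precision.
.pattern_rank <- function(x) {
  if (length(x) == 0) return(numeric(0))
  n <- nchar(x[1])
  stopifnot(n <= 22, all(nchar(x) == n))
  enc <- chartr(".ACGT", "01234", x)
  digits <- matrix(as.integer(charToRaw(paste(enc, collapse = ""))) - 48L,
                   nrow = n)
  as.numeric(5^(n - seq_len(n)) %*% digits)
}

# stable checksum of a text/binary file for run manifests
.file_checksum <- function(path) unname(tools::md5sum(path))
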