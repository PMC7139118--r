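# DNA sequence primitives shared across modules.

#' Reverse complement
#'
#' Reverse complement over the alphabet `{A,C,G,T,N}` (case preserved,
#' `N <-> N`). Vectorised over a character vector of sequences.
#'
#' @param seq Character vector of DNA sequences.
#' @return Character vector of reverse complements.
#' @examples
#' revcomp("AAAC")  # "GTTT"
#' @export
revcomp <- function(seq) {
  if (!is.character(seq)) stop("seq must be character", call. = FALSE)
  bad <- grepl("[^ACGTNacgtn]", seq)
  if (any(bad)) {
    stop("sequence contains characters outside A/C/G/T/N: ",
         substr(seq[bad][1L], 1L, 40L), call. = FALSE)
  }
  comp <- chartr("ACGTacgt", "TGCAtgca", seq)
  vapply(comp, function(s) {
    paste(rev(strsplit(s, "", fixed = TRUE)[[1L]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# Complement of single bases (upper case), as a character vector op.
comp_base <- function(b) chartr("ACGTN", "TGCAN", b)

# Watson-Crick pairing predicate on single upper-case bases; optional G:U
# (here G:T at the DNA level) wobble.
wc_pair <- function(a, b, allow_wobble = FALSE) {
  ok <- (a == "A" & b == "T") | (a == "T" & b == "A") |
    (a == "C" & b == "G") | (a == "G" & b == "C")
  if (allow_wobble) {
    ok <- ok | (a == "G" & b == "T") | (a == "T" & b == "G")
  }
  ok
}

# Uniform random DNA string of length n (uses the current RNG stream).
random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Split a sequence into a character vector of single bases.
seq_chars <- function(s) strsplit(s, "", fixed = TRUE)[[1L]]
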