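#' Reverse-complement DNA sequences
#'
#' Vectorised Watson-Crick reverse complement over the alphabet `{A,C,G,T,N}`
#' (`N` maps to `N`). Assembly treats read orientation as unknown, so both a
#' read and its reverse complement are considered everywhere reads are matched.
#'
#' @param seq Character vector of uppercase DNA sequences.
#' @return Character vector of the same length.
#' @examples
#' revcomp(c("GATTACA", "ACGT"))
#' @export
revcomp <- function(seq) {
  if (length(seq) == 0) return(character())
  bad <- grepl("[^ACGTN]", seq)
  if (any(bad)) {
    abort(sprintf("non-DNA character in sequence(s): %s",
                  paste(utils::head(which(bad), 3), collapse = ", ")))
  }
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(seq)))
}

# Hamming distance between two equal-length strings.
hamming <- function(a, b) {
  sum(utf8ToInt(a) != utf8ToInt(b))
}

# Deterministic RNG scope: runs `expr` under `seed` and restores the caller's
# RNG state afterwards, so library calls never perturb user randomness.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

rand_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
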