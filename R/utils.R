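# Internal helpers shared across modules.

BASES <- c("A", "C", "G", "T")
PURINES <- c("A", "G")

# Codon -> amino acid lookup (standard nuclear code), taken from Biostrings.
genetic_code <- function() Biostrings::GENETIC_CODE

#' @noRd
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(seed)
  force(code)
}

check_dna <- function(x, what = "sequence") {
  if (length(x) != 1L || !is.character(x)) {
    stop(what, " must be a single character string", call. = FALSE)
  }
  if (nchar(x) > 0L && grepl("[^ACGT]", x)) {
    stop(what, " contains characters outside A/C/G/T", call. = FALSE)
  }
  invisible(x)
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

#' Hamming distance between two equal-length strings
#' @noRd
hamming <- function(a, b) {
  if (nchar(a) != nchar(b)) stop("hamming distance requires equal lengths")
  sum(utf8ToInt(a) != utf8ToInt(b))
}

# Translate a nucleotide string codon-by-codon; trailing partial codon dropped.
# Returns a character vector of amino acids ('*' for stop), not stopping at
# the first stop so that downstream code can locate premature termination.
translate_nt <- function(nt) {
  n <- nchar(nt) %/% 3L
  if (n == 0L) return(character(0))
  starts <- seq.int(1L, by = 3L, length.out = n)
  codons <- substring(nt, starts, starts + 2L)
  aa <- unname(genetic_code()[codons])
  if (anyNA(aa)) stop("untranslatable codon encountered")
  aa
}

# All positions (1-based) where `motif` occurs in `seq` (overlaps included).
find_motif <- function(seq, motif) {
  k <- nchar(motif)
  n <- nchar(seq)
  if (n < k) return(integer(0))
  starts <- seq_len(n - k + 1L)
  starts[substring(seq, starts, starts + k - 1L) == motif]
}

# Minimum pairwise Hamming distance among equal-length distinct strings.
# Returns Inf when no two distinct strings share a length.
min_pairwise_hamming <- function(seqs) {
  seqs <- unique(seqs)
  best <- Inf
  for (len in unique(nchar(seqs))) {
    grp <- seqs[nchar(seqs) == len]
    if (length(grp) < 2L) next
    m <- matrix(unlist(lapply(grp, utf8ToInt), use.names = FALSE),
                nrow = len)
    for (i in seq_len(ncol(m) - 1L)) {
      d <- colSums(m[, (i + 1L):ncol(m), drop = FALSE] != m[, i])
      best <- min(best, min(d))
      if (best == 1) return(1)
    }
  }
  best
}
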