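# Small sequence helpers shared across modules.

COMP <- c(A = "T", C = "G", G = "C", T = "A", N = "N",
          a = "t", c = "g", g = "c", t = "a", n = "n")

#' Reverse complement of DNA strings
#'
#' Vectorised over its input; only A/C/G/T/N are accepted.
#'
#' @param x character vector of DNA strings.
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  if (length(x) == 0L) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# DNA -> RNA transliteration (T->U), uppercasing on the way.
dna_to_rna <- function(x) chartr("Tt", "Uu", toupper(x))

rna_to_dna <- function(x) chartr("Uu", "Tt", toupper(x))

# 0-based half-open substring of a 1-based R string.
seq_slice <- function(seq, start, end) substr(seq, start + 1L, end)

`%||%` <- function(a, b) if (is.null(a)) b else a

# Deterministic local RNG scope: runs expr under a seed and restores the
# caller's RNG state afterwards.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
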