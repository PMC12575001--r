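# Internal helpers shared across modules.

#' @importFrom stats rnorm runif setNames cor sd
#' @importFrom utils write.table read.table head tail
NULL

# Row-wise numerically stable softmax.
softmax_rows <- function(z) {
  z <- z - apply(z, 1L, max)
  e <- exp(z)
  e / rowSums(e)
}

#' Normalize a nucleotide string
#'
#' Uppercases, maps U to T, and replaces every non-ACGT character (IUPAC
#' ambiguity codes included) with N.
#'
#' @param x A character scalar.
#' @return Normalized character scalar over the alphabet A/C/G/T/N.
#' @export
normalize_seq <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  x <- chartr("u", "t", x)
  x <- toupper(x)
  gsub("[^ACGT]", "N", x)
}

# Reverse complement over A/C/G/T/N (N maps to N).
revcomp <- function(x) {
  x <- normalize_seq(x)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

# Deterministic local RNG scope: evaluates expr with the given seed and
# restores the caller's RNG state afterwards.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

# Write a data.frame as headerless TSV (used for BED and truth tables).
write_tsv_plain <- function(df, path, col.names = FALSE) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = col.names)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
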