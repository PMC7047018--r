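#' Truncated percentage
#'
#' Report `100 * num / den` truncated (not rounded) to one decimal place,
#' the convention used throughout for printed percentages.
#'
#' @param num Numerator (numeric).
#' @param den Denominator (numeric, > 0).
#' @param digits Decimal places kept after truncation (default 1).
#' @return Numeric vector of truncated percentages.
#' @examples
#' pct_trunc(291, 684) # 42.5
#' pct_trunc(28, 684)  # 4.0
#' @export
pct_trunc <- function(num, den, digits = 1) {
  stopifnot(all(den > 0))
  f <- 10^digits
  trunc(100 * num / den * f) / f
}

STOP_CODONS <- c("TAA", "TAG", "TGA")

## Split a DNA string into consecutive codons starting at `offset` (0-based);
## trailing bases not filling a codon are dropped.
codon_split <- function(seq, offset = 0L) {
  n <- nchar(seq)
  if (n - offset < 3L) return(character(0))
  starts <- seq.int(offset + 1L, n - 2L, by = 3L)
  substring(seq, starts, starts + 2L)
}

reverse_complement <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

## Derive a 32-bit substream seed from a master seed and an index so that
## adding genes never reshuffles earlier genes.
substream_seed <- function(seed, index) {
  as.integer((as.numeric(seed) * 2654435761 + as.numeric(index) * 40503) %%
    2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
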