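#' Vertebrate mitochondrial genetic code
#'
#' Codon-to-amino-acid lookup for the vertebrate mitochondrial code
#' (NCBI translation table 2). It differs from the standard code in four
#' codons: AGA and AGG are stops, ATA encodes Met and TGA encodes Trp.
#' Stops are written `"*"`.
#'
#' @return Named character vector of length 64; names are codons in
#'   `A`/`C`/`G`/`T` letters, values single-letter amino acids.
#' @examples
#' mt_code()[["ATA"]]  # "M"
#' mt_code()[["AGA"]]  # "*"
#' @export
mt_code <- function() .mt_code

# Built once at load: amino acids listed in TCAG order over
# (pos1 slowest, pos3 fastest), the conventional 64-codon listing.
.mt_code <- local({
  aas <- strsplit(
    "FFLLSSSSYY**CCWWLLLLPPPPHHQQRRRRIIMMTTTTNNKKSS**VVVVAAAADDEEGGGG",
    "")[[1]]
  b <- c("T", "C", "A", "G")
  codons <- as.vector(vapply(b, function(p1)
    vapply(b, function(p2) paste0(p1, p2, b), character(4)), matrix("", 4, 4)))
  stats::setNames(aas, codons)
})

#' Translate codons under the vertebrate mitochondrial code
#'
#' @param codons Character vector of 3-letter codons (case-insensitive).
#'   Codons containing characters outside `A/C/G/T` translate to `NA`.
#' @return Character vector of single-letter amino acids (`"*"` = stop).
#' @examples
#' translate_mt(c("GGA", "GGG", "ATA", "TGA"))
#' @export
translate_mt <- function(codons) {
  out <- unname(.mt_code[toupper(codons)])
  out
}

#' Reverse complement of nucleotide sequences
#'
#' Gaps (`-`) and `N` are preserved; input may be a character vector of
#' single bases or of longer strings.
#'
#' @param x Character vector.
#' @return Reverse-complemented sequences, same shape as `x`.
#' @export
revcomp <- function(x) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N", `-` = "-",
            a = "t", c = "g", g = "c", t = "a", n = "n")
  one <- function(s) {
    ch <- rev(strsplit(s, "")[[1]])
    mapped <- comp[ch]
    mapped[is.na(mapped)] <- "N"
    paste(mapped, collapse = "")
  }
  vapply(x, one, character(1), USE.NAMES = FALSE)
}

# complement of single bases, vectorised (used on per-base vectors)
complement_base <- function(b) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N", `-` = "-")
  out <- comp[b]
  out[is.na(out)] <- "N"
  unname(out)
}

is_stop_mt <- function(codons) {
  aa <- translate_mt(codons)
  !is.na(aa) & aa == "*"
}
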