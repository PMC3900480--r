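#' @useDynLib mirflow, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats pnbinom rbinom rgamma rmultinom rnbinom rpois runif
#'   sd setNames
#' @importFrom utils read.table write.table head
NULL

# Internal coordinate convention: 0-based half-open on the forward strand.
# All user-facing positions in returned tables are 1-based inclusive.

#' Normalize a nucleotide string to the DNA alphabet
#'
#' Sequences are normalized to upper-case DNA (U becomes T) at ingest; one
#' canonical alphabet keeps all matching arithmetic simple.  Rendering as RNA
#' happens only in reports.
#'
#' @param x character vector of nucleotide sequences.
#' @return character vector over A,C,G,T,N.
#' @export
norm_dna <- function(x) {
  x <- chartr("u", "t", tolower(x))
  toupper(x)
}

#' Render a DNA-alphabet sequence as RNA
#' @param x character vector.
#' @return character vector with T replaced by U.
#' @export
as_rna <- function(x) chartr("Tt", "Uu", toupper(x))

#' Reverse complement
#' @param x character vector of DNA sequences.
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  vapply(x, function(s) {
    intToUtf8(rev(utf8ToInt(chartr("ACGTN", "TGCAN", norm_dna(s)))))
  }, character(1), USE.NAMES = FALSE)
}

# round half away from zero, the convention used for all reported percentages
round_half_up <- function(x, digits = 2) {
  f <- 10^digits
  sign(x) * floor(abs(x) * f + 0.5) / f
}

`%||%` <- function(a, b) if (is.null(a)) b else a

validate_alphabet <- function(seq, what = "sequence", allow_n = TRUE) {
  pat <- if (allow_n) "^[ACGTUNacgtun]+$" else "^[ACGTUacgtu]+$"
  bad <- which(!grepl(pat, seq))
  if (length(bad))
    stop(sprintf("%s %d contains characters outside the nucleotide alphabet",
                 what, bad[1]), call. = FALSE)
  invisible(TRUE)
}
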