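# Read cleaning along the published discard taxonomy: base-quality screen,
# then per-read categorization with fixed precedence
#   3'-adapter-null -> insert-null -> 5'-adapter contaminant ->
#   shorter-than-18-nt -> polyA -> retained,
# 18-30 nt inserts retained and collapsed to unique reads.

#' Base-quality screen
#'
#' A read fails when more than `fmax` of its bases are below Phred `qmin`
#' (Sanger +33 encoding) or it contains more than `nmax` N calls.  The
#' thresholds are conventional small-RNA defaults and are configurable.
#'
#' @param seqs character vector of read sequences.
#' @param quals character vector of quality strings (same lengths).
#' @param qmin minimum acceptable Phred score (default 20).
#' @param fmax maximal tolerated fraction of low-quality bases (default 0.5).
#' @param nmax maximal tolerated number of N bases (default 1).
#' @return logical vector, `TRUE` = pass.
#' @export
quality_screen <- function(seqs, quals, qmin = 20, fmax = 0.5, nmax = 1) {
  stopifnot(length(seqs) == length(quals))
  if (!length(seqs)) return(logical(0))
  low_frac <- vapply(quals, function(q) {
    ph <- utf8ToInt(q) - 33L
    mean(ph < qmin)
  }, numeric(1), USE.NAMES = FALSE)
  n_n <- nchar(seqs) - nchar(gsub("N", "", seqs, fixed = TRUE))
  low_frac <= fmax & n_n <= nmax
}

#' Categorize reads and trim the 3' adapter
#'
#' The 3' adapter is located by an exact match of its first `match_len`
#' bases anywhere in the read, with one fallback pass allowing a single
#' mismatch.  Each read lands in exactly one category; retained reads return
#' the insert (sequence 5' of the adapter match) of 18-30 nt.
#'
#' @param seqs character vector of (quality-passed) read sequences.
#' @param adapter3,adapter5 adapter sequences.
#' @param match_len adapter prefix length used for matching (default 12).
#' @param min_len,max_len retained insert length window (default 18-30).
#' @param polyA_frac insert A-fraction at or above which the insert is
#'   classed polyA (default 0.8).
#' @return data.frame with columns `category` (factor over the taxonomy) and
#'   `insert` (`NA` for discarded reads).
#' @export
classify_and_trim <- function(seqs, adapter3, adapter5, match_len = 12L,
                              min_len = 18L, max_len = 30L,
                              polyA_frac = 0.8) {
  if (nchar(adapter3) < match_len || nchar(adapter5) < match_len)
    stop("adapter shorter than match_len")
  a3 <- substr(norm_dna(adapter3), 1, match_len)
  a5 <- substr(norm_dna(adapter5), 1, match_len)
  seqs <- norm_dna(seqs)
  n <- length(seqs)
  cats <- c("retained", "adaptor3_null", "insert_null",
            "adaptor5_contaminant", "shorter_than_18nt", "polyA")
  category <- character(n)
  insert <- rep(NA_character_, n)
  if (!n)
    return(data.frame(category = factor(character(0), levels = cats),
                      insert = character(0), stringsAsFactors = FALSE))

  pos <- regexpr(a3, seqs, fixed = TRUE)
  miss <- which(pos < 0)
  if (length(miss)) {
    # fallback: one mismatch allowed
    m1 <- Biostrings::vmatchPattern(a3,
                                    Biostrings::DNAStringSet(seqs[miss]),
                                    max.mismatch = 1)
    first <- vapply(m1, function(r)
      if (length(r)) min(IRanges::start(r)) else -1L, integer(1))
    pos[miss] <- first
  }
  no_ad <- pos < 0
  category[no_ad] <- "adaptor3_null"
  at0 <- !no_ad & pos == 1
  category[at0] <- "insert_null"
  todo <- which(!no_ad & !at0)
  ins <- substr(seqs[todo], 1, pos[todo] - 1)
  is_a5 <- startsWith(ins, a5)
  short <- !is_a5 & (nchar(ins) < min_len | nchar(ins) > max_len)
  a_frac <- (nchar(ins) - nchar(gsub("A", "", ins, fixed = TRUE))) / nchar(ins)
  polya <- !is_a5 & !short & a_frac >= polyA_frac
  keep <- !is_a5 & !short & !polya
  category[todo[is_a5]] <- "adaptor5_contaminant"
  category[todo[short]] <- "shorter_than_18nt"
  category[todo[polya]] <- "polyA"
  category[todo[keep]] <- "retained"
  insert[todo[keep]] <- ins[keep]
  data.frame(category = factor(category, levels = cats), insert = insert,
             stringsAsFactors = FALSE)
}

#' Collapse retained inserts to unique reads
#'
#' @param inserts character vector of retained inserts (18-30 nt).
#' @return list with `uniques` (data.frame `seq`, `count`, sorted by
#'   descending count then lexicographic) and `histogram` (named integer
#'   vector keyed 18..30).
#' @export
collapse_reads <- function(inserts) {
  inserts <- inserts[!is.na(inserts)]
  lens <- nchar(inserts)
  stopifnot(!length(lens) || (min(lens) >= 18 && max(lens) <= 30))
  hist <- setNames(integer(13), as.character(18:30))
  tab <- table(factor(lens, levels = 18:30))
  hist[names(tab)] <- as.integer(tab)
  if (!length(inserts)) {
    return(list(uniques = data.frame(seq = character(0), count = integer(0),
                                     stringsAsFactors = FALSE),
                histogram = hist))
  }
  cnt <- table(inserts)
  uq <- data.frame(seq = names(cnt), count = as.integer(cnt),
                   stringsAsFactors = FALSE)
  uq <- uq[order(-uq$count, uq$seq), , drop = FALSE]
  rownames(uq) <- NULL
  list(uniques = uq, histogram = hist)
}

#' Filter accounting summary
#'
#' Reproduces the published summary layout: the high-quality read count is
#' the 100% base, each discard category is reported as count and percentage
#' of it (half-up, 2 decimals), and the retained ("high quality reads") row
#' is the identity `high_quality - sum(discards)`.
#'
#' @param high_quality number of reads passing the base-quality screen.
#' @param discards named numeric vector of per-category discard counts
#'   (categories `adaptor3_null`, `insert_null`, `adaptor5_contaminant`,
#'   `shorter_than_18nt`, `polyA`).
#' @param total_reads optional raw read count before the quality screen.
#' @return data.frame with columns `type`, `count`, `pct`.
#' @export
filter_summary <- function(high_quality, discards, total_reads = NA) {
  stopifnot(all(discards >= 0), high_quality >= sum(discards))
  retained <- high_quality - sum(discards)
  rows <- data.frame(
    type = c("total_reads", "high_quality", names(discards),
             "high_quality_reads"),
    count = c(total_reads, high_quality, unname(discards), retained),
    stringsAsFactors = FALSE)
  rows$pct <- round_half_up(rows$count / high_quality * 100, 2)
  rows$pct[rows$type == "total_reads"] <- NA
  rows
}

#' Preprocess one library
#'
#' Quality screen, categorize/trim, collapse; the one-stop entry for the
#' cleaning stage.
#'
#' @param reads data.frame with columns `seq` and `qual` (e.g. from
#'   [read_fastq()]).
#' @param adapter3,adapter5 adapter sequences.
#' @param ... passed to [classify_and_trim()] and [quality_screen()].
#' @return list with `summary` ([filter_summary()] layout), `uniques`,
#'   `histogram`, `inserts` (retained insert multiset), `categories`.
#' @export
preprocess_library <- function(reads, adapter3, adapter5, ...) {
  dots <- list(...)
  qargs <- dots[names(dots) %in% c("qmin", "fmax", "nmax")]
  cargs <- dots[names(dots) %in% c("match_len", "min_len", "max_len",
                                   "polyA_frac")]
  pass <- do.call(quality_screen, c(list(reads$seq, reads$qual), qargs))
  hq <- reads$seq[pass]
  cl <- do.call(classify_and_trim,
                c(list(hq, adapter3 = adapter3, adapter5 = adapter5), cargs))
  disc <- table(cl$category)
  disc <- disc[setdiff(names(disc), "retained")]
  coll <- collapse_reads(cl$insert)
  list(summary = filter_summary(length(hq),
                                setNames(as.numeric(disc), names(disc)),
                                total_reads = nrow(reads)),
       uniques = coll$uniques, histogram = coll$histogram,
       inserts = cl$insert[!is.na(cl$insert)], categories = cl$category)
}
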