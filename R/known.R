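# Known-miRNA identification: mismatch-tolerant assignment of unique reads
# to reference matures, family collapsing to the highest-expressed member,
# hairpin verification of each identified mature, and positional
# nucleotide-bias profiling.

#' Assign unique reads to reference mature miRNAs
#'
#' A read is assigned to the mature with the fewest mismatches (ungapped,
#' full length of the shorter sequence, at most `max_mismatch`); ties go to
#' the lexicographically first reference name.
#'
#' @param uniques data.frame `seq`, `count`.
#' @param mature named character vector of reference mature sequences.
#' @param max_mismatch mismatch tolerance (default 2).
#' @return `uniques` with columns `mirna` (`NA` when unassigned) and
#'   `mismatches`.
#' @export
match_known <- function(uniques, mature, max_mismatch = 2L) {
  stopifnot(!is.null(names(mature)))
  nm <- sort(names(mature))
  out <- uniques
  if (!nrow(uniques)) {
    out$mirna <- character(0); out$mismatches <- integer(0)
    return(out)
  }
  bm <- best_hamming_match_cpp(norm_dna(uniques$seq), norm_dna(mature[nm]),
                               max_mismatch)
  mirna <- rep(NA_character_, nrow(uniques))
  mirna[bm$ref > 0] <- nm[bm$ref[bm$ref > 0]]
  out$mirna <- mirna
  out$mismatches <- bm$mismatches
  out
}

#' Per-miRNA expression profile across libraries
#'
#' @param assignments named list (one [match_known()] result per library).
#' @return integer matrix miRNA x library of summed read counts.
#' @export
profile_expression <- function(assignments) {
  all_mir <- sort(unique(unlist(lapply(assignments, function(a)
    a$mirna[!is.na(a$mirna)]))))
  m <- matrix(0L, length(all_mir), length(assignments),
              dimnames = list(all_mir, names(assignments)))
  for (L in names(assignments)) {
    a <- assignments[[L]]
    a <- a[!is.na(a$mirna), , drop = FALSE]
    if (!nrow(a)) next
    s <- tapply(a$count, a$mirna, sum)
    m[names(s), L] <- as.integer(s)
  }
  m
}

#' miRNA family from a miRBase-style name
#'
#' Strips the species prefix, the arm suffix (-5p/-3p), a trailing paralog
#' number, and trailing paralog letters after the core number:
#' `xdu-let-7f-5p` -> `let-7`, `miR-133a` -> `miR-133`.
#'
#' @param names character vector of miRNA names.
#' @param pattern optional replacement regex list; the default implements
#'   the rule above.
#' @return character vector of family names.
#' @export
mirna_family <- function(names, pattern = NULL) {
  x <- sub("^[a-z]{2,4}-(?=(miR|mir|let)-)", "", names, perl = TRUE)
  x <- sub("-[35]p$", "", x)
  x <- sub("^((miR|mir|let)-\\d+[a-z]*)-\\d+$", "\\1", x)
  x <- sub("^((miR|mir|let)-\\d+)[a-z]+$", "\\1", x)
  if (any(!nzchar(x))) stop("empty family name derived")
  x
}

#' Collapse miRNA families to their highest-expressed member
#'
#' For each family the member with the largest summed count across libraries
#' becomes the representative (ties: lexicographically smaller name).
#'
#' @param profile miRNA x library count matrix ([profile_expression()]).
#' @param families optional named family labels; derived from row names via
#'   [mirna_family()] when missing.
#' @return data.frame `family`, `representative`, `total_count`, `n_members`.
#' @export
collapse_families <- function(profile, families = NULL) {
  if (is.null(families)) families <- mirna_family(rownames(profile))
  tot <- rowSums(profile)
  ord <- order(families, -tot, rownames(profile))
  df <- data.frame(name = rownames(profile)[ord], family = families[ord],
                   total = tot[ord], stringsAsFactors = FALSE)
  first <- !duplicated(df$family)
  data.frame(family = df$family[first], representative = df$name[first],
             total_count = df$total[first],
             n_members = as.integer(table(df$family)[df$family[first]]),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Verify that a mature miRNA sits in one arm of a folded hairpin
#'
#' The precursor (or genomic flank) is folded with [fold_mfe()]; the check
#' passes when at least `min_paired_frac` of the mature's bases are paired
#' within one arm of a stem-loop (shared with the novel-miRNA criteria).
#'
#' @param mature mature sequence.
#' @param precursor precursor or flank sequence containing it.
#' @param min_paired_frac minimal paired fraction of mature bases (0.75).
#' @param max_mismatch tolerance when locating the mature in the precursor.
#' @return `TRUE`, `FALSE`, or `NA` when the mature cannot be located
#'   ("unverifiable").
#' @export
verify_hairpin <- function(mature, precursor, min_paired_frac = 0.75,
                           max_mismatch = 2L) {
  mature <- norm_dna(mature); precursor <- norm_dna(precursor)
  p <- regexpr(mature, precursor, fixed = TRUE)[1]
  if (p < 0 && max_mismatch > 0) {
    m <- Biostrings::matchPattern(mature, Biostrings::DNAString(precursor),
                                  max.mismatch = max_mismatch)
    if (length(m)) p <- min(IRanges::start(m))
  }
  if (p < 0) return(NA)
  h <- fold_mfe(precursor)
  mature_arm_check(h$pairs, p, p + nchar(mature) - 1L,
                   min_paired_frac = min_paired_frac)
}

#' Positional nucleotide bias of identified matures
#'
#' Base frequencies per position (from the 5' end, position 1), computed
#' over unique identified mature sequences (unweighted by default), plus the
#' 3'-terminal base distribution.
#'
#' @param seqs character vector of identified mature sequences.
#' @param weights optional per-sequence weights (e.g. read counts) for the
#'   count-weighted variant.
#' @return list of class `mirna_bias`: `freq` (position x base matrix over
#'   A,C,G,U; rows sum to 1 over sequences long enough to cover the
#'   position), `terminal` (3'-end base frequencies), and spotlights
#'   `pos1`, `pos9`.
#' @export
nucleotide_bias <- function(seqs, weights = NULL) {
  if (!length(seqs)) stop("nucleotide_bias needs a nonempty sequence set")
  seqs <- as_rna(norm_dna(seqs))
  if (is.null(weights)) weights <- rep(1, length(seqs))
  stopifnot(length(weights) == length(seqs), all(weights > 0))
  maxlen <- max(nchar(seqs))
  bases <- c("A", "C", "G", "U")
  freq <- matrix(0, maxlen, 4, dimnames = list(seq_len(maxlen), bases))
  ch <- strsplit(seqs, "")
  for (p in seq_len(maxlen)) {
    cover <- which(nchar(seqs) >= p)
    b <- vapply(ch[cover], `[`, character(1), p)
    w <- tapply(weights[cover], factor(b, levels = bases), sum, default = 0)
    freq[p, ] <- w / sum(w)
  }
  term <- vapply(ch, function(x) x[length(x)], character(1))
  tw <- tapply(weights, factor(term, levels = bases), sum, default = 0)
  structure(list(freq = freq, terminal = tw / sum(tw),
                 pos1 = freq[1, ],
                 pos9 = if (maxlen >= 9) freq[9, ] else NULL),
            class = "mirna_bias")
}

#' @export
print.mirna_bias <- function(x, ...) {
  cat("Positional nucleotide bias over", nrow(x$freq), "positions\n")
  cat(sprintf("  position 1: U = %.1f%%\n", 100 * x$pos1[["U"]]))
  if (!is.null(x$pos9))
    cat(sprintf("  position 9: U = %.1f%%\n", 100 * x$pos9[["U"]]))
  cat(sprintf("  3' terminal: U = %.1f%%\n", 100 * x$terminal[["U"]]))
  invisible(x)
}

#' Identify known miRNAs across libraries
#'
#' Runs assignment, expression profiling, family collapsing and hairpin
#' verification in one pass.
#'
#' @param uniques_by_lib named list of per-library `uniques` data.frames.
#' @param mature named character vector of reference matures.
#' @param precursors optional data.frame `mature`, `seq` giving a precursor
#'   per mature for hairpin verification; matures without a verifiable
#'   hairpin are excluded from the identified set.
#' @param max_mismatch mismatch tolerance (default 2).
#' @return list: `profile` (identified miRNA x library counts), `families`,
#'   `assignments`, `hairpin_ok` (named logical/NA per assigned mature),
#'   `bias` (per-library [nucleotide_bias()] of identified matures).
#' @export
identify_known <- function(uniques_by_lib, mature, precursors = NULL,
                           max_mismatch = 2L) {
  assignments <- lapply(uniques_by_lib, match_known, mature = mature,
                        max_mismatch = max_mismatch)
  profile <- profile_expression(assignments)
  hairpin_ok <- setNames(rep(NA, nrow(profile)), rownames(profile))
  if (!is.null(precursors)) {
    for (nm in rownames(profile)) {
      i <- match(nm, precursors$mature)
      hairpin_ok[nm] <- if (is.na(i)) NA
        else verify_hairpin(mature[[nm]], precursors$seq[i])
    }
    keep <- !is.na(hairpin_ok) & hairpin_ok
    profile <- profile[keep, , drop = FALSE]
  }
  families <- collapse_families(profile)
  bias <- lapply(colnames(profile), function(L) {
    idf <- rownames(profile)[profile[, L] > 0]
    if (!length(idf)) return(NULL)
    nucleotide_bias(unname(mature[idf]))
  })
  names(bias) <- colnames(profile)
  list(profile = profile, families = families, assignments = assignments,
       hairpin_ok = hairpin_ok, bias = bias)
}
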