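# Hierarchical small-RNA class annotation.  Class precedence (fixed,
# documented, configurable):
#   miRNA > rRNA > tRNA > snRNA > snoRNA > scRNA > repeat > exon_sense >
#   exon_antisense > intron_sense > intron_antisense > unannotated
# miRNA matching tolerates up to 2 mismatches; the other sequence classes
# require exact substring matches; genomic-context classes come from the
# best exact genome hit intersected with the annotation tracks.

ANNOT_CLASSES <- c("miRNA", "rRNA", "tRNA", "snRNA", "snoRNA", "scRNA",
                   "repeat", "exon_sense", "exon_antisense", "intron_sense",
                   "intron_antisense", "unannotated")

#' Ungapped mismatch-tolerant mapping of a query against references
#'
#' Finds all ungapped alignments of the full query on both strands of every
#' reference with at most `max_mismatch` substitutions, via
#' `Biostrings::matchPattern`.
#'
#' @param query a single sequence (>= 18 nt).
#' @param references named character vector of reference sequences.
#' @param max_mismatch 0, 1 or 2.
#' @return data.frame `ref`, `pos` (1-based start on the forward strand),
#'   `strand`, `mismatches`, sorted by (mismatches, ref, pos).
#' @export
map_ungapped <- function(query, references, max_mismatch = 0L) {
  if (!length(references)) stop("empty reference set")
  stopifnot(max_mismatch %in% 0:2, nchar(query) >= 18)
  query <- norm_dna(query)
  if (is.null(names(references)))
    names(references) <- sprintf("ref%d", seq_along(references))
  pat_f <- Biostrings::DNAString(query)
  pat_r <- Biostrings::reverseComplement(pat_f)
  out <- list()
  for (nm in names(references)) {
    subj <- Biostrings::DNAString(norm_dna(references[[nm]]))
    for (std in c("+", "-")) {
      pat <- if (std == "+") pat_f else pat_r
      m <- Biostrings::matchPattern(pat, subj, max.mismatch = max_mismatch)
      if (!length(m)) next
      st <- IRanges::start(m)
      mm <- Biostrings::neditStartingAt(pat, subj, starting.at = st)
      out[[length(out) + 1]] <- data.frame(
        ref = nm, pos = st, strand = std, mismatches = mm,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(ref = character(0), pos = integer(0),
                      strand = character(0), mismatches = integer(0),
                      stringsAsFactors = FALSE))
  hits <- do.call(rbind, out)
  hits <- hits[hits$mismatches <= max_mismatch, , drop = FALSE]
  hits <- hits[order(hits$mismatches, hits$ref, hits$pos), , drop = FALSE]
  rownames(hits) <- NULL
  hits
}

# exact substring membership of reads in a set of reference sequences
# (sense strand); returns the first matching reference name or NA
match_class_exact <- function(reads, refs) {
  if (!length(refs)) return(rep(NA_character_, length(reads)))
  hay <- paste(norm_dna(unlist(refs)), collapse = "X")
  starts <- cumsum(c(1, nchar(refs) + 1))[seq_along(refs)]
  hit <- vapply(norm_dna(reads), function(r) {
    p <- regexpr(r, hay, fixed = TRUE)[1]
    if (p < 0) NA_integer_ else p
  }, integer(1), USE.NAMES = FALSE)
  idx <- findInterval(hit, starts)
  ifelse(is.na(hit), NA_character_, names(refs)[idx])
}

# context of a 0-based half-open interval against the tracks, given hit strand
interval_context <- function(start0, end0, strand, tracks) {
  ov <- tracks$start < end0 & tracks$end > start0
  if (!any(ov)) return("unannotated")
  kinds <- tracks$name[ov]
  if ("repeat" %in% kinds) return("repeat")
  if ("exon" %in% kinds)
    return(if (strand == "+") "exon_sense" else "exon_antisense")
  if ("intron" %in% kinds)
    return(if (strand == "+") "intron_sense" else "intron_antisense")
  "unannotated"
}

#' Annotate unique reads by the class hierarchy
#'
#' @param uniques data.frame `seq`, `count` (one library's collapsed reads).
#' @param refs named list of reference sets: `miRNA` (named character vector
#'   of matures), and any of `rRNA`, `tRNA`, `snRNA`, `snoRNA`, `scRNA`.
#' @param genome single genome sequence (or `NULL` to skip genomic context).
#' @param tracks BED-like track data.frame ([read_tracks()]); 0-based
#'   half-open.
#' @param max_mm_mirna mismatch tolerance of the miRNA class (default 2).
#' @return data.frame: `seq`, `count`, `class`, `matched_ref`,
#'   `genome_hits`, `hit_start` (0-based), `hit_strand`.
#' @export
annotate_hierarchy <- function(uniques, refs, genome = NULL, tracks = NULL,
                               max_mm_mirna = 2L) {
  n <- nrow(uniques)
  cls <- rep("unannotated", n)
  matched <- rep(NA_character_, n)
  ghits <- rep(0L, n)
  hstart <- rep(NA_integer_, n)
  hstrand <- rep(NA_character_, n)
  if (!n)
    return(cbind(uniques, data.frame(class = character(0),
                                     matched_ref = character(0),
                                     genome_hits = integer(0),
                                     hit_start = integer(0),
                                     hit_strand = character(0))))

  # miRNA first (precedence): <=2 mismatches, ungapped, shorter-in-longer
  if (!is.null(refs$miRNA) && length(refs$miRNA)) {
    mt <- sort(names(refs$miRNA))
    bm <- best_hamming_match_cpp(norm_dna(uniques$seq),
                                 norm_dna(refs$miRNA[mt]), max_mm_mirna)
    hit <- bm$ref > 0
    cls[hit] <- "miRNA"
    matched[hit] <- mt[bm$ref[hit]]
  }
  # other sequence classes, exact
  for (cl in c("rRNA", "tRNA", "snRNA", "snoRNA", "scRNA")) {
    open <- which(cls == "unannotated")
    if (!length(open) || is.null(refs[[cl]]) || !length(refs[[cl]])) next
    hm <- match_class_exact(uniques$seq[open], refs[[cl]])
    got <- !is.na(hm)
    cls[open[got]] <- cl
    matched[open[got]] <- hm[got]
  }
  # genome hits and genomic context for the remainder
  open <- which(cls == "unannotated")
  if (length(open) && !is.null(genome)) {
    for (i in open) {
      hits <- map_ungapped(uniques$seq[i], c(genome = genome),
                           max_mismatch = 0L)
      ghits[i] <- nrow(hits)
      if (!nrow(hits)) next
      best <- hits[1, ]
      hstart[i] <- best$pos - 1L
      hstrand[i] <- best$strand
      if (!is.null(tracks))
        cls[i] <- interval_context(best$pos - 1L,
                                   best$pos - 1L + nchar(uniques$seq[i]),
                                   best$strand, tracks)
    }
  }
  out <- uniques
  out$class <- factor(cls, levels = ANNOT_CLASSES)
  out$matched_ref <- matched
  out$genome_hits <- ghits
  out$hit_start <- hstart
  out$hit_strand <- hstrand
  out
}

#' Class tallies on unique and count-weighted bases
#'
#' @param records an [annotate_hierarchy()] result.
#' @return data.frame: `class`, `unique_count`, `total_count`, `unique_pct`,
#'   `total_pct` (percentages of the library totals, half-up 2 decimals).
#' @export
class_tally <- function(records) {
  uq <- tapply(rep(1L, nrow(records)), records$class, sum, default = 0L)
  tot <- tapply(records$count, records$class, sum, default = 0L)
  data.frame(class = ANNOT_CLASSES,
             unique_count = as.integer(uq[ANNOT_CLASSES]),
             total_count = as.integer(tot[ANNOT_CLASSES]),
             unique_pct = tabulate_percentages(as.numeric(uq[ANNOT_CLASSES]),
                                               sum(uq)),
             total_pct = tabulate_percentages(as.numeric(tot[ANNOT_CLASSES]),
                                              sum(tot)),
             stringsAsFactors = FALSE)
}

#' Percentages of a library total
#'
#' @param counts numeric vector of class counts.
#' @param total library total (> 0).
#' @return percentages, rounded half-up to 2 decimals.
#' @export
tabulate_percentages <- function(counts, total) {
  if (is.na(total) || total <= 0) stop("library total must be positive")
  round_half_up(counts / total * 100, 2)
}
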