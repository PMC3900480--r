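# Novel-miRNA calling: fold the +/-150 nt genomic flank of each candidate
# read and apply the stem-loop criteria -- intron/antisense-exon context,
# mature within one arm of a hairpin, 2-nt 3' overhang geometry, no large
# internal loops or bulges in the duplex, precursor free energy <= -18
# kcal/mol, <= 10 genome hits, and 20-22 nt mature length.

#' Default thresholds of the novel-miRNA criteria
#'
#' @param flank flank width in nt on each side (150).
#' @param energy_max maximal precursor free energy in kcal/mol (-18,
#'   inclusive).
#' @param max_loop maximal unpaired run (nt) tolerated inside the
#'   mature/star duplex (5).
#' @param max_star_gap maximal separation in nt between the mature and its
#'   star along the sequence (the terminal-loop span, 35); a real hairpin
#'   precursor is compact, and without this bound a long-range imperfect
#'   stem in a random flank can mimic one arm.
#' @param hit_cap maximal number of exact genome hits (10).
#' @param len_range inclusive mature length window (20-22).
#' @param min_reads minimal per-library read support (5).
#' @param min_paired_frac minimal paired fraction of mature bases (0.75).
#' @return named list of thresholds.
#' @export
novel_params <- function(flank = 150L, energy_max = -18, max_loop = 5L,
                         hit_cap = 10L, len_range = c(20L, 22L),
                         min_reads = 5L, min_paired_frac = 0.75,
                         max_star_gap = 35L) {
  list(flank = flank, energy_max = energy_max, max_loop = max_loop,
       hit_cap = hit_cap, len_range = len_range, min_reads = min_reads,
       min_paired_frac = min_paired_frac, max_star_gap = max_star_gap)
}

#' Extract the genomic flank around a read locus
#'
#' @param genome genome sequence.
#' @param start0,end0 0-based half-open read locus on the forward strand.
#' @param strand `"+"` or `"-"`; for `"-"` the reverse complement is
#'   returned so the mature always reads 5' to 3' within the flank.
#' @param flank flank width (150 nt each side), clipped at contig ends.
#' @return list `seq`, `mature_start`/`mature_end` (1-based within the
#'   flank), `flank_start0` (genomic 0-based origin of the flank).
#' @export
extract_flanks <- function(genome, start0, end0, strand = "+", flank = 150L) {
  glen <- nchar(genome)
  if (start0 < 0 || end0 > glen || start0 >= end0)
    stop("locus outside genome")
  lo <- max(0L, start0 - flank)
  hi <- min(glen, end0 + flank)
  seq <- substring(genome, lo + 1L, hi)
  ms <- start0 - lo + 1L
  me <- end0 - lo
  if (strand == "-") {
    seq <- revcomp(seq)
    w <- end0 - start0
    ms <- hi - end0 + 1L
    me <- ms + w - 1L
  }
  list(seq = seq, mature_start = ms, mature_end = me, flank_start0 = lo)
}

#' Evaluate a hairpin candidate against the seven criteria
#'
#' @param read_seq candidate mature sequence.
#' @param flankinfo an [extract_flanks()] result.
#' @param context genomic context class of the read's best hit (one of the
#'   annotation classes).
#' @param genome_hits number of exact genome hits of the read.
#' @param params [novel_params()].
#' @return list: `criteria` (named logical, seven entries), `verdict`,
#'   `hairpin` (folded flank), `precursor_energy`, `star` (1-based star
#'   coordinates within the flank or `NULL`).
#' @export
evaluate_candidate <- function(read_seq, flankinfo, context, genome_hits,
                               params = novel_params()) {
  ms <- flankinfo$mature_start; me <- flankinfo$mature_end
  crit <- c(in_intron_or_antisense_exon = FALSE,
            folds_hairpin_mature_in_arm = FALSE,
            has_2nt_3prime_overhang = FALSE,
            no_large_loops = FALSE,
            energy_le_minus18 = FALSE,
            genome_hits_le_10 = FALSE,
            length_20_22 = FALSE)
  crit[["in_intron_or_antisense_exon"]] <-
    context %in% c("intron_sense", "intron_antisense", "exon_antisense")
  crit[["genome_hits_le_10"]] <- genome_hits >= 1 && genome_hits <= params$hit_cap
  w <- nchar(read_seq)
  crit[["length_20_22"]] <- w >= params$len_range[1] && w <= params$len_range[2]

  h <- fold_mfe(flankinfo$seq)
  arm_ok <- mature_arm_check(h$pairs, ms, me, params$min_paired_frac)
  if (arm_ok) {
    # hairpin compactness: the star must sit within max_star_gap of the
    # mature, otherwise this is long-range pairing, not a precursor stem
    st0 <- star_coords(h$pairs, ms, me)
    gap <- if (is.null(st0)) Inf
           else if (st0[1] > me) st0[1] - me - 1 else ms - st0[2] - 1
    arm_ok <- gap <= params$max_star_gap
  }
  crit[["folds_hairpin_mature_in_arm"]] <- arm_ok
  star <- NULL
  prec_energy <- NA_real_
  if (crit[["folds_hairpin_mature_in_arm"]]) {
    star <- star_coords(h$pairs, ms, me)
    # a Dicer duplex has sharp ends: besides the 2-nt 3' overhangs, the star
    # must mirror the mature's paired span (net bulge asymmetry <= 2 nt)
    sym_ok <- FALSE
    if (!is.null(star)) {
      idx <- ms:me
      paired <- idx[!is.na(h$pairs[idx])]
      i1 <- min(paired); i2 <- max(paired)
      asym <- abs(abs(h$pairs[i1] - h$pairs[i2]) - (i2 - i1))
      sym_ok <- asym <= 2
    }
    crit[["has_2nt_3prime_overhang"]] <- !is.null(star) && sym_ok &&
      star[1] >= 1 && star[2] <= nchar(flankinfo$seq) &&
      (star[1] > me || star[2] < ms)
    if (!is.null(star)) {
      lo <- min(ms, star[1]); hi <- max(me, star[2])
      star_lo <- max(1L, star[1])
      star_hi <- min(star[2], nchar(flankinfo$seq))
      crit[["no_large_loops"]] <-
        max_unpaired_run(h$pairs, ms, me) <= params$max_loop &&
        max_unpaired_run(h$pairs, star_lo, star_hi) <= params$max_loop
      # energy of the local precursor (the mature/star stem-loop), refolded
      prec <- substring(flankinfo$seq, max(1L, lo - 2L),
                        min(nchar(flankinfo$seq), hi + 2L))
      prec_energy <- fold_mfe(prec)$energy
      crit[["energy_le_minus18"]] <- prec_energy <= params$energy_max
    }
  }
  list(criteria = crit, verdict = all(crit), hairpin = h,
       precursor_energy = prec_energy, star = star)
}

#' Call novel miRNA candidates from annotated unique reads
#'
#' Takes per-library annotation records, pools reads that were not assigned
#' to a known small-RNA sequence class, applies the cheap gates (per-library
#' read support, genome hit cap, length, genomic context), folds the
#' surviving loci and applies the structural criteria, merges candidates by
#' locus identity, and names them `novel-mir-<k>` in descending total-count
#' order (ties by locus coordinate).
#'
#' @param records_by_lib named list of [annotate_hierarchy()] results.
#' @param genome genome sequence.
#' @param tracks annotation tracks.
#' @param params [novel_params()].
#' @return list: `novel` (data.frame `name`, `seq`, one count column per
#'   library, `start0`, `strand`, `energy`), `evaluations` (per evaluated
#'   read: criteria flags and verdict), `structures` (dot-bracket strings of
#'   called candidates).
#' @export
call_novel <- function(records_by_lib, genome, tracks,
                       params = novel_params()) {
  libs <- names(records_by_lib)
  pool <- list()
  for (L in libs) {
    r <- records_by_lib[[L]]
    keep <- r$class %in% c("exon_antisense", "intron_sense",
                           "intron_antisense", "unannotated")
    r <- r[keep, , drop = FALSE]
    if (nrow(r)) {
      r$library <- L
      pool[[L]] <- r[, c("seq", "count", "class", "genome_hits",
                         "hit_start", "hit_strand", "library")]
    }
  }
  empty <- data.frame(name = character(0), seq = character(0))
  if (!length(pool))
    return(list(novel = empty, evaluations = NULL, structures = character(0)))
  pool <- do.call(rbind, pool)

  # group reads by locus (best-hit start/strand): 3'-trimmed variants of one
  # mature share the locus and their support pools; unmapped reads keep
  # their sequence as the key (they fail the context gate anyway)
  pool$locus <- ifelse(is.na(pool$hit_start), paste0("seq:", pool$seq),
                       paste(pool$hit_start, pool$hit_strand))
  loci <- unique(pool$locus)
  cnt <- matrix(0L, length(loci), length(libs), dimnames = list(loci, libs))
  for (i in seq_len(nrow(pool)))
    cnt[pool$locus[i], pool$library[i]] <-
      cnt[pool$locus[i], pool$library[i]] + pool$count[i]
  # locus representative: the highest-count (then longest) member sequence
  meta_rows <- lapply(loci, function(lc) {
    sub <- pool[pool$locus == lc, , drop = FALSE]
    per_seq <- tapply(sub$count, sub$seq, sum)
    best <- names(per_seq)[order(-per_seq, -nchar(names(per_seq)))][1]
    sub[match(best, sub$seq), , drop = FALSE]
  })
  meta <- do.call(rbind, meta_rows)

  support_ok <- apply(cnt, 1, max) >= params$min_reads
  evals <- list()
  for (i in which(support_ok)) {
    s <- meta$seq[i]
    ctx <- as.character(meta$class[i])
    gh <- meta$genome_hits[i]
    w <- nchar(s)
    cheap_ok <- ctx %in% c("intron_sense", "intron_antisense",
                           "exon_antisense") &&
      gh >= 1 && gh <= params$hit_cap &&
      w >= params$len_range[1] && w <= params$len_range[2]
    if (!cheap_ok) next
    fl <- extract_flanks(genome, meta$hit_start[i], meta$hit_start[i] + w,
                         strand = meta$hit_strand[i], flank = params$flank)
    ev <- evaluate_candidate(s, fl, ctx, gh, params)
    evals[[s]] <- c(ev, list(seq = s, locus = loci[i],
                             start0 = meta$hit_start[i],
                             strand = meta$hit_strand[i]))
  }
  if (!length(evals))
    return(list(novel = empty, evaluations = evals, structures = character(0)))

  called <- Filter(function(e) isTRUE(e$verdict), evals)
  if (!length(called))
    return(list(novel = empty, evaluations = evals, structures = character(0)))
  tot <- vapply(called, function(e) sum(cnt[e$locus, ]), numeric(1))
  ord <- order(-tot, vapply(called, `[[`, numeric(1), "start0"))
  called <- called[ord]
  novel <- data.frame(
    name = sprintf("novel-mir-%d", seq_along(called)),
    seq = vapply(called, `[[`, character(1), "seq"),
    stringsAsFactors = FALSE, row.names = NULL)
  novel <- cbind(novel, cnt[vapply(called, `[[`, character(1), "locus"), ,
                            drop = FALSE])
  rownames(novel) <- NULL
  novel$start0 <- vapply(called, `[[`, numeric(1), "start0")
  novel$strand <- vapply(called, `[[`, character(1), "strand")
  novel$energy <- vapply(called, `[[`, numeric(1), "precursor_energy")
  structures <- setNames(vapply(called, function(e) e$hairpin$structure,
                                character(1)), novel$name)
  list(novel = novel, evaluations = evals, structures = structures)
}
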