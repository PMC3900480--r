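# Synthetic-data generator: a miniature genome with planted miRNA hairpin
# loci, decoy ncRNA classes, transcripts with planted target sites, and
# three stage-libraries (E13/E19/E27-like) of adaptered reads with planted
# abundances, fold changes and the five contaminant classes of the read
# filter taxonomy.  Everything is deterministic for a fixed seed and the
# returned ground truth drives every downstream recovery test.

#' Simulation configuration
#'
#' Defaults emulate the study design the pipeline targets: three pooled
#' stage libraries of single-end adaptered reads with 18-30 nt inserts,
#' contaminant rates matching the published per-category discard fractions,
#' miRNA-dominated class composition, first-base U bias of 0.85 on planted
#' matures, and modest negative-binomial overdispersion.
#'
#' @param seed integer seed; all generator randomness derives from it.
#' @param genome_length genome size in nt.
#' @param n_known_mirna number of planted known matures (reference-listed).
#' @param n_novel_mirna number of planted novel hairpin loci (intronic).
#' @param n_decoy named counts of decoy ncRNA reference sequences per class.
#' @param n_decoy_loci number of non-miRNA genomic loci that emit
#'   unassigned degradation-like reads (candidate-caller negatives).
#' @param n_transcripts number of transcript sequences for target scanning.
#' @param library_sizes named integer vector of reads per library.
#' @param read_length raw read length in nt.
#' @param adapter3,adapter5 adapter sequences (Illumina small-RNA style).
#' @param contamination_rates per-category probabilities for the discard
#'   classes among high-quality reads.
#' @param quality_fail_rate fraction of raw reads failing the base-quality
#'   screen.
#' @param error_rate per-base uniform substitution sequencing-error rate.
#' @param isomir_rate probability that a clean miRNA read is a 3'-trimmed
#'   isomiR (1-2 nt).
#' @param first_base_u_prob probability that a planted mature starts with U.
#' @param dispersion negative-binomial-style overdispersion of planted
#'   counts (0 degenerates to multinomial/Poisson sampling).
#' @param abundance_shape gamma shape of the Dirichlet abundance prior;
#'   larger values keep every planted species detectably expressed.
#' @param min_mirna_reads optional floor on the drawn per-library count of
#'   every planted miRNA/novel species (0 disables); the excess is taken
#'   from the most abundant species so library sizes are conserved.
#' @param class_fractions expected read fractions per small-RNA class.
#' @param fold_change_spec optional data.frame (`name`, `library`, `log2fc`)
#'   of planted per-library log2 fold changes relative to baseline
#'   abundance; `NULL` plants the default pattern (a third of known matures
#'   shifted by +/-1..3 between stages).
#' @return a `sim_config` list, validated.
#' @export
sim_config <- function(seed = 1L,
                       genome_length = 60000L,
                       n_known_mirna = 25L,
                       n_novel_mirna = 8L,
                       n_decoy = c(rRNA = 8L, tRNA = 8L, snRNA = 4L,
                                   snoRNA = 4L, scRNA = 3L),
                       n_decoy_loci = 12L,
                       n_transcripts = 30L,
                       library_sizes = c(E13 = 20000L, E19 = 20000L, E27 = 20000L),
                       read_length = 44L,
                       adapter3 = "TGGAATTCTCGGGTGCCAAGG",
                       adapter5 = "GTTCAGAGTTCTACAGTCCGACGATC",
                       contamination_rates = c(adaptor3_null = 0.000134,
                                               insert_null = 0.000177,
                                               adaptor5_contaminant = 0.00469,
                                               shorter_than_18nt = 0.00946,
                                               polyA = 0.000015),
                       quality_fail_rate = 0.0059,
                       error_rate = 0.001,
                       isomir_rate = 0.2,
                       first_base_u_prob = 0.85,
                       dispersion = 0.05,
                       abundance_shape = 2,
                       min_mirna_reads = 0L,
                       class_fractions = c(miRNA = 0.62, rRNA = 0.16,
                                           tRNA = 0.025, snRNA = 0.004,
                                           snoRNA = 0.002, scRNA = 0.004,
                                           novel = 0.015, other = 0.17),
                       fold_change_spec = NULL) {
  cfg <- as.list(environment())
  stopifnot(all(cfg$contamination_rates >= 0),
            sum(cfg$contamination_rates) <= 1,
            all(cfg$library_sizes >= 1),
            cfg$dispersion >= 0,
            abs(sum(cfg$class_fractions) - 1) < 1e-8,
            nchar(cfg$adapter3) >= 12)
  cfg$class_fractions <- cfg$class_fractions / sum(cfg$class_fractions)
  class(cfg) <- "sim_config"
  cfg
}

random_seq <- function(n, gc = 0.5) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

#' Sample planted mature miRNA sequences
#'
#' Matures are 20-22 nt with a biased first base (U with probability
#' `first_base_u_prob`) and moderately GC-rich interiors so designed stems
#' are stable.
#'
#' @param n number of matures.
#' @param first_base_u_prob probability of U at position 1.
#' @param len_range inclusive length range.
#' @param gc interior GC content.
#' @return character vector of DNA-alphabet sequences.
#' @export
simulate_matures <- function(n, first_base_u_prob = 0.85,
                             len_range = c(20L, 22L), gc = 0.6) {
  vapply(seq_len(n), function(i) {
    len <- sample(len_range[1]:len_range[2], 1)
    first <- if (runif(1) < first_base_u_prob) "T"
             else sample(c("A", "C", "G"), 1)
    paste0(first, random_seq(len - 1, gc = gc))
  }, character(1))
}

# Design a hairpin precursor with the mature in the 5' arm: a GC-rich
# reverse-complement-palindromic stem (mature plus a few extra pairs) closed
# by a short loop.  Re-checked against the folding backend at generation
# time; redesigned on the rare failure.
design_precursor <- function(mature, stem_ext = 4L, loop_range = c(4L, 8L),
                             energy_max = -18) {
  for (try in 1:25) {
    ext5 <- random_seq(stem_ext, gc = 0.7)
    loop <- random_seq(sample(loop_range[1]:loop_range[2], 1), gc = 0.3)
    stem <- paste0(ext5, mature)
    prec <- paste0(stem, loop, revcomp(stem))
    h <- fold_mfe(prec)
    mstart <- stem_ext + 1L
    mend <- stem_ext + nchar(mature)
    if (h$energy <= energy_max &&
        mature_arm_check(h$pairs, mstart, mend)) {
      return(list(seq = prec, mature_start = mstart, mature_end = mend,
                  energy = h$energy))
    }
  }
  stop("could not design a stable hairpin precursor for mature ", mature)
}

mirbase_style_names <- function(n) {
  # families with occasional paralog letters and arm suffixes, so family
  # collapsing has real work to do
  fams <- 100 + seq_len(n) * 7
  out <- character(0)
  fi <- 1
  while (length(out) < n) {
    fam <- fams[fi]; fi <- fi + 1
    k <- min(sample(1:3, 1, prob = c(0.6, 0.3, 0.1)), n - length(out))
    if (k == 1) {
      out <- c(out, sprintf("xdu-miR-%d-5p", fam))
    } else {
      letters_k <- letters[seq_len(k)]
      arms <- sample(c("-5p", "-3p"), k, replace = TRUE)
      out <- c(out, sprintf("xdu-miR-%d%s%s", fam, letters_k, arms))
    }
  }
  out[seq_len(n)]
}

#' Generate the synthetic genome, loci and reference sets
#'
#' Builds a block-structured genome (exon, intron, repeat and intergenic
#' blocks on the forward strand), plants novel-miRNA hairpin precursors
#' inside introns and decoy degradation loci in exon/intron blocks, designs
#' hairpin precursors for the known matures, draws decoy ncRNA references
#' per class, and embeds target sites for the novel matures in a transcript
#' set.  Deterministic for a fixed seed.
#'
#' @param config a [sim_config()].
#' @return list of class `sim_genome` with elements `genome` (single
#'   sequence), `tracks` (BED-like data.frame, 0-based half-open),
#'   `known` (data.frame name/seq/family), `known_precursors`,
#'   `novel` (data.frame with locus coordinates), `decoys` (per-class
#'   sequence list), `decoy_loci`, `transcripts`, `planted_sites`.
#' @export
simulate_genome <- function(config = sim_config()) {
  set.seed(config$seed)
  glen <- config$genome_length

  # block-structured annotation on one contig
  blocks <- list(); pos <- 0L
  types <- c("exon", "intron", "repeat", "intergenic")
  while (pos < glen) {
    ty <- sample(types, 1, prob = c(0.3, 0.4, 0.1, 0.2))
    len <- switch(ty,
                  exon = sample(400:800, 1), intron = sample(600:1200, 1),
                  "repeat" = sample(150:300, 1), intergenic = sample(300:600, 1))
    len <- min(len, glen - pos)
    blocks[[length(blocks) + 1]] <- data.frame(
      chrom = "chr1", start = pos, end = pos + len, name = ty, strand = "+",
      stringsAsFactors = FALSE)
    pos <- pos + len
  }
  tracks <- do.call(rbind, blocks)
  genome_chars <- strsplit(random_seq(glen, gc = 0.45), "")[[1]]

  # known matures with miRBase-style names and designed precursors
  known_names <- sort(mirbase_style_names(config$n_known_mirna))
  known_seq <- simulate_matures(config$n_known_mirna,
                                config$first_base_u_prob)
  known <- data.frame(name = known_names, seq = known_seq,
                      family = mirna_family(known_names),
                      stringsAsFactors = FALSE)
  kprec <- lapply(known$seq, design_precursor)
  known_precursors <- data.frame(
    name = sub("-[35]p$", "", known$name),
    mature = known$name,
    seq = vapply(kprec, `[[`, character(1), "seq"),
    mature_start = vapply(kprec, `[[`, integer(1), "mature_start"),
    mature_end = vapply(kprec, `[[`, integer(1), "mature_end"),
    energy = vapply(kprec, `[[`, numeric(1), "energy"),
    stringsAsFactors = FALSE)

  # plant novel precursors inside introns (criterion: intron or antisense
  # exon context); record mature genomic coordinates (0-based half-open)
  introns <- tracks[tracks$name == "intron", , drop = FALSE]
  introns <- introns[order(-(introns$end - introns$start)), , drop = FALSE]
  if (nrow(introns) < 1 && config$n_novel_mirna > 0)
    stop("genome too small to host intronic loci")
  novel <- NULL
  used <- IRanges::IRanges()
  place_in <- function(block_df, width) {
    for (try in 1:200) {
      b <- block_df[sample(nrow(block_df), 1), ]
      if (b$end - b$start <= width + 2) next
      s <- b$start + sample.int(b$end - b$start - width, 1)
      cand <- IRanges::IRanges(s + 1, s + width)
      if (length(used) && any(IRanges::overlapsAny(cand, used))) next
      used <<- c(used, cand)
      return(s)
    }
    stop("could not place a locus without overlap after bounded retries")
  }
  if (config$n_novel_mirna > 0) {
    nov_mature <- simulate_matures(config$n_novel_mirna,
                                   config$first_base_u_prob)
    rows <- lapply(seq_len(config$n_novel_mirna), function(i) {
      pr <- design_precursor(nov_mature[i])
      s <- place_in(introns, nchar(pr$seq))
      genome_chars[(s + 1):(s + nchar(pr$seq))] <<- strsplit(pr$seq, "")[[1]]
      data.frame(name = sprintf("planted-novel-%d", i), seq = nov_mature[i],
                 prec_seq = pr$seq,
                 prec_start = s, prec_end = s + nchar(pr$seq),
                 start = s + pr$mature_start - 1L,
                 end = s + pr$mature_end, strand = "+",
                 energy = pr$energy, stringsAsFactors = FALSE)
    })
    novel <- do.call(rbind, rows)
  }

  # decoy degradation loci: reads from exon (sense) and intron blocks that
  # must not be called as novel miRNAs.  They are true negatives by
  # construction: a candidate locus whose local fold already looks
  # hairpin-like (most of the window paired into one nearby arm) is
  # re-sampled, mirroring the positive-side guarantee that every planted
  # precursor verifies as a hairpin.
  exons <- tracks[tracks$name == "exon", , drop = FALSE]
  genome <- paste(genome_chars, collapse = "")
  hairpin_like <- function(start0, end0) {
    fl <- extract_flanks(genome, start0, end0, "+", flank = 90L)
    h <- fold_mfe(fl$seq)
    if (!mature_arm_check(h$pairs, fl$mature_start, fl$mature_end,
                          min_paired_frac = 0.6, end_slack = 4))
      return(FALSE)
    st <- star_coords(h$pairs, fl$mature_start, fl$mature_end)
    !is.null(st)
  }
  decoy_loci <- NULL
  if (config$n_decoy_loci > 0) {
    rows <- lapply(seq_len(config$n_decoy_loci), function(i) {
      in_exon <- (i %% 2 == 0)
      for (try in 1:40) {
        width <- sample(20:22, 1)
        s <- place_in(if (in_exon) exons else introns, width)
        if (!hairpin_like(s, s + width)) break
      }
      data.frame(name = sprintf("decoy-locus-%d", i),
                 start = s, end = s + width, strand = "+",
                 context = if (in_exon) "exon" else "intron",
                 stringsAsFactors = FALSE)
    })
    decoy_loci <- do.call(rbind, rows)
  }
  if (!is.null(decoy_loci))
    decoy_loci$seq <- substring(genome, decoy_loci$start + 1, decoy_loci$end)

  # decoy ncRNA reference sets per class
  decoy_len <- c(rRNA = 1200L, tRNA = 76L, snRNA = 150L, snoRNA = 110L,
                 scRNA = 300L)
  decoys <- lapply(names(config$n_decoy), function(cl) {
    n <- config$n_decoy[[cl]]
    if (n == 0) return(character(0))
    setNames(vapply(seq_len(n), function(i) random_seq(decoy_len[[cl]]),
                    character(1)),
             sprintf("%s-%d", cl, seq_len(n)))
  })
  names(decoys) <- names(config$n_decoy)

  # transcripts with planted seed-match sites for the novel matures
  transcripts <- NULL; planted_sites <- NULL
  if (config$n_transcripts > 0) {
    tx <- vapply(seq_len(config$n_transcripts),
                 function(i) random_seq(sample(300:600, 1)), character(1))
    names(tx) <- sprintf("tx-%d", seq_len(config$n_transcripts))
    sites <- list()
    if (!is.null(novel)) {
      for (i in seq_len(nrow(novel))) {
        n_sites <- sample(1:3, 1)
        for (k in seq_len(n_sites)) {
          j <- sample(length(tx), 1)
          site <- revcomp(substr(novel$seq[i], 1, 9))
          pos <- sample.int(nchar(tx[j]) - 9, 1)
          substr(tx[j], pos, pos + 8) <- site
          sites[[length(sites) + 1]] <- data.frame(
            mirna = novel$name[i], transcript = names(tx)[j],
            start = pos, end = pos + 8L, stringsAsFactors = FALSE)
        }
      }
      planted_sites <- unique(do.call(rbind, sites))
    }
    transcripts <- data.frame(id = names(tx), seq = unname(tx),
                              stringsAsFactors = FALSE)
  }

  structure(list(genome = genome, tracks = tracks, known = known,
                 known_precursors = known_precursors, novel = novel,
                 decoys = decoys, decoy_loci = decoy_loci,
                 transcripts = transcripts, planted_sites = planted_sites,
                 config = config),
            class = "sim_genome")
}

# default planted differential-expression pattern: a third of known matures
# shifted between stages by +/- 1..3 log2 units, stage pattern chosen per
# miRNA (peak at E19, dip at E19, or monotone increase)
default_fold_changes <- function(known_names) {
  n_de <- max(1L, floor(length(known_names) / 3))
  de <- sort(sample(known_names, n_de))
  rows <- lapply(de, function(nm) {
    mag <- sample(1:3, 1)
    pat <- sample(c("peakE19", "dipE19", "up"), 1)
    l2 <- switch(pat,
                 peakE19 = c(E13 = -mag, E19 = 0, E27 = -mag),
                 dipE19 = c(E13 = mag, E19 = 0, E27 = mag),
                 up = c(E13 = -mag, E19 = 0, E27 = mag))
    data.frame(name = nm, library = names(l2), log2fc = unname(l2),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Simulate the three stage libraries
#'
#' Clean reads are planted species (known matures, novel matures, decoy
#' ncRNA fragments, decoy-locus fragments) with per-library abundances drawn
#' from a Dirichlet prior scaled by the planted fold changes, counts drawn
#' by gamma-perturbed multinomial sampling (negative-binomial-like
#' overdispersion, exact library-size conservation), then rendered as insert
#' + 3' adapter reads with optional 3'-trimmed isomiRs and uniform
#' substitution errors.  Contaminant reads for the five discard classes and
#' low-quality reads are injected at the configured rates.
#'
#' @param sim a [simulate_genome()] result.
#' @param config the same [sim_config()] (defaults to the one in `sim`).
#' @return list of class `sim_libraries`: `reads` (per-library data.frame
#'   id/seq/qual), `expected` (species x library count matrix of drawn clean
#'   counts), `contaminants` (category x library counts, including
#'   `quality_fail`), `species` (data.frame name/seq/class), `abundance`
#'   (expected per-library relative abundances among clean reads).
#' @export
simulate_libraries <- function(sim, config = sim$config) {
  set.seed(config$seed + 1L)
  libs <- names(config$library_sizes)

  # species table
  sp <- list()
  sp[[1]] <- data.frame(name = sim$known$name, seq = sim$known$seq,
                        class = "miRNA", stringsAsFactors = FALSE)
  if (!is.null(sim$novel))
    sp[[2]] <- data.frame(name = sim$novel$name, seq = sim$novel$seq,
                          class = "novel", stringsAsFactors = FALSE)
  frag_from <- function(seqs, class, n_frag) {
    if (!length(seqs) || n_frag == 0) return(NULL)
    rows <- lapply(seq_len(n_frag), function(i) {
      src <- seqs[[sample(length(seqs), 1)]]
      w <- sample(18:30, 1)
      s <- sample.int(nchar(src) - w + 1, 1)
      data.frame(name = sprintf("%s-frag-%d", class, i),
                 seq = substr(src, s, s + w - 1), class = class,
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  }
  for (cl in names(sim$decoys))
    sp[[length(sp) + 1]] <- frag_from(sim$decoys[[cl]], cl,
                                      n_frag = 3 * max(1, length(sim$decoys[[cl]])))
  if (!is.null(sim$decoy_loci))
    sp[[length(sp) + 1]] <- data.frame(name = sim$decoy_loci$name,
                                       seq = sim$decoy_loci$seq,
                                       class = "other", stringsAsFactors = FALSE)
  species <- do.call(rbind, sp)
  species <- species[!duplicated(species$seq), , drop = FALSE]
  rownames(species) <- NULL

  # baseline within-class abundances: Dirichlet
  base_w <- rgamma(nrow(species), shape = config$abundance_shape,
                   rate = 1) + 1e-6
  cf <- config$class_fractions
  cls <- species$class
  cls_key <- ifelse(cls %in% names(cf), cls, "other")
  w0 <- numeric(nrow(species))
  for (k in unique(cls_key)) {
    i <- which(cls_key == k)
    w0[i] <- cf[[k]] * base_w[i] / sum(base_w[i])
  }

  fc <- config$fold_change_spec
  if (is.null(fc)) fc <- default_fold_changes(sim$known$name)

  abundance <- matrix(0, nrow(species), length(libs),
                      dimnames = list(species$name, libs))
  for (L in libs) {
    w <- w0
    if (!is.null(fc) && nrow(fc)) {
      sel <- fc[fc$library == L, , drop = FALSE]
      m <- match(sel$name, species$name)
      ok <- !is.na(m)
      w[m[ok]] <- w[m[ok]] * 2^sel$log2fc[ok]
    }
    abundance[, L] <- w / sum(w)
  }

  expected <- matrix(0L, nrow(species), length(libs),
                     dimnames = list(species$name, libs))
  contam_cat <- c(names(config$contamination_rates), "quality_fail")
  contaminants <- matrix(0L, length(contam_cat), length(libs),
                         dimnames = list(contam_cat, libs))
  reads <- list()

  a3 <- norm_dna(config$adapter3)
  a5 <- norm_dna(config$adapter5)
  rl <- config$read_length
  finish_read <- function(insert) {
    r <- paste0(insert, a3)
    if (nchar(r) < rl) r <- paste0(r, strrep("A", rl - nchar(r)))
    substr(r, 1, rl)
  }
  add_errors <- function(seqs, rate) {
    if (rate <= 0 || !length(seqs)) return(seqs)
    n_err <- rbinom(1, sum(nchar(seqs)), rate)
    if (n_err == 0) return(seqs)
    for (e in seq_len(n_err)) {
      i <- sample(length(seqs), 1)
      p <- sample(nchar(seqs[i]), 1)
      substr(seqs[i], p, p) <- sample(c("A", "C", "G", "T"), 1)
    }
    seqs
  }

  for (L in libs) {
    n <- config$library_sizes[[L]]
    n_qf <- rbinom(1, n, config$quality_fail_rate)
    n_hq <- n - n_qf
    nc <- drop(rmultinom(1, n_hq, c(config$contamination_rates,
                                    1 - sum(config$contamination_rates))))
    names(nc) <- c(names(config$contamination_rates), "clean")
    n_clean <- nc[["clean"]]
    if (n_clean < nrow(species))
      stop("library size too small for the number of planted species")
    contaminants[names(config$contamination_rates), L] <-
      nc[names(config$contamination_rates)]
    contaminants["quality_fail", L] <- n_qf

    w <- abundance[, L]
    if (config$dispersion > 0) {
      g <- rgamma(length(w), shape = 1 / config$dispersion,
                  scale = config$dispersion)
      w <- w * g
    }
    cnt <- drop(rmultinom(1, n_clean, w / sum(w)))
    if (config$min_mirna_reads > 0) {
      mir_i <- which(species$class %in% c("miRNA", "novel"))
      for (i in mir_i) {
        need <- config$min_mirna_reads - cnt[i]
        if (need > 0) {
          top <- which.max(cnt)
          cnt[top] <- cnt[top] - need
          cnt[i] <- cnt[i] + need
        }
      }
    }
    expected[, L] <- cnt

    # clean reads
    ins <- rep(species$seq, cnt)
    is_mir <- rep(species$class %in% c("miRNA", "novel"), cnt)
    trim <- ifelse(is_mir & runif(length(ins)) < config$isomir_rate,
                   sample(1:2, length(ins), replace = TRUE), 0L)
    ins <- substr(ins, 1, nchar(ins) - trim)
    clean_reads <- vapply(ins, finish_read, character(1), USE.NAMES = FALSE)

    # contaminant reads
    mk_no_adapter <- function(k) {
      out <- character(0)
      while (length(out) < k) {
        cand <- vapply(seq_len(k - length(out)),
                       function(i) random_seq(rl), character(1))
        cand <- cand[!vapply(cand, function(s)
          grepl(substr(a3, 1, 12), s, fixed = TRUE), logical(1))]
        out <- c(out, cand)
      }
      out
    }
    contam_reads <- c(
      mk_no_adapter(nc[["adaptor3_null"]]),
      vapply(seq_len(nc[["insert_null"]]), function(i)
        substr(paste0(a3, random_seq(rl)), 1, rl), character(1)),
      vapply(seq_len(nc[["adaptor5_contaminant"]]), function(i)
        finish_read(paste0(substr(a5, 1, 12), random_seq(10))), character(1)),
      vapply(seq_len(nc[["shorter_than_18nt"]]), function(i)
        finish_read(random_seq(sample(10:17, 1))), character(1)),
      vapply(seq_len(nc[["polyA"]]), function(i)
        finish_read(strrep("A", sample(18:25, 1))), character(1)))
    qf_reads <- vapply(seq_len(n_qf), function(i) random_seq(rl), character(1))

    seqs <- add_errors(c(clean_reads, contam_reads), config$error_rate)
    quals <- c(rep(strrep("I", rl), length(seqs)),
               rep(strrep("#", rl), n_qf))
    seqs <- c(seqs, qf_reads)
    ord <- sample(length(seqs))
    reads[[L]] <- data.frame(
      id = sprintf("%s_%06d", L, seq_along(ord)),
      seq = seqs[ord], qual = quals[ord], stringsAsFactors = FALSE)
  }

  structure(list(reads = reads, expected = expected,
                 contaminants = contaminants, species = species,
                 abundance = abundance, fold_changes = fc),
            class = "sim_libraries")
}

#' One-call synthetic dataset
#' @param config a [sim_config()].
#' @return list with `genome` ([simulate_genome()] result) and `libraries`
#'   ([simulate_libraries()] result).
#' @export
simulate_dataset <- function(config = sim_config()) {
  g <- simulate_genome(config)
  list(genome = g, libraries = simulate_libraries(g, config))
}
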