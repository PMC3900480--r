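test_that("flank extraction reports offsets and clips at contig ends", {
  set.seed(81)
  genome <- paste(sample(c("A", "C", "G", "T"), 10000, TRUE), collapse = "")
  fl <- extract_flanks(genome, 1000L, 1022L, "+", flank = 150L)
  expect_equal(nchar(fl$seq), 322L)
  expect_equal(fl$mature_start, 151L)
  expect_equal(substr(fl$seq, fl$mature_start, fl$mature_end),
               substr(genome, 1001, 1022))
  # near the left end the flank is clipped and the offset adjusted
  fl2 <- extract_flanks(genome, 40L, 62L, "+", flank = 150L)
  expect_equal(fl2$mature_start, 41L)
  expect_equal(substr(fl2$seq, fl2$mature_start, fl2$mature_end),
               substr(genome, 41, 62))
  # extracted flank re-aligns to its genomic origin
  expect_equal(regexpr(fl$seq, genome, fixed = TRUE)[1] - 1L, fl$flank_start0)
  # minus strand returns the reverse complement with the mature 5'->3'
  fl3 <- extract_flanks(genome, 1000L, 1022L, "-", flank = 150L)
  expect_equal(substr(fl3$seq, fl3$mature_start, fl3$mature_end),
               revcomp(substr(genome, 1001, 1022)))
  expect_error(extract_flanks(genome, -5L, 20L), "outside genome")
})

# a designed intronic candidate planted in a small genome
planted_candidate <- function(seed = 83) {
  set.seed(seed)
  mature <- simulate_matures(1)
  pr <- mirflow:::design_precursor(mature)
  left <- paste(sample(c("A", "C", "G", "T"), 400, TRUE), collapse = "")
  right <- paste(sample(c("A", "C", "G", "T"), 400, TRUE), collapse = "")
  genome <- paste0(left, pr$seq, right)
  tracks <- data.frame(chrom = "chr1", start = 0L, end = nchar(genome),
                       name = "intron", strand = "+",
                       stringsAsFactors = FALSE)
  start0 <- 400L + pr$mature_start - 1L
  list(mature = mature, genome = genome, tracks = tracks,
       start0 = start0, end0 = start0 + nchar(mature))
}

test_that("a designed intronic hairpin satisfies all seven criteria", {
  pc <- planted_candidate()
  fl <- extract_flanks(pc$genome, pc$start0, pc$end0, "+")
  ev <- evaluate_candidate(pc$mature, fl, "intron_sense", genome_hits = 1L)
  expect_true(ev$verdict)
  expect_true(all(ev$criteria))
  expect_lte(ev$precursor_energy, -18)
  # the implied star lies inside the flank and does not overlap the mature
  expect_false(is.null(ev$star))
  expect_true(ev$star[1] >= 1 && ev$star[2] <= nchar(fl$seq))
  expect_true(ev$star[1] > fl$mature_end || ev$star[2] < fl$mature_start)
})

test_that("single criterion failures flip the verdict", {
  pc <- planted_candidate()
  fl <- extract_flanks(pc$genome, pc$start0, pc$end0, "+")
  # wrong genomic context
  ev1 <- evaluate_candidate(pc$mature, fl, "exon_sense", genome_hits = 1L)
  expect_false(ev1$verdict)
  expect_false(ev1$criteria[["in_intron_or_antisense_exon"]])
  # too many genome hits
  ev2 <- evaluate_candidate(pc$mature, fl, "intron_sense", genome_hits = 11L)
  expect_false(ev2$criteria[["genome_hits_le_10"]])
  # a 19-nt mature fails the length window
  fl19 <- fl; fl19$mature_end <- fl19$mature_start + 18L
  ev3 <- evaluate_candidate(substr(pc$mature, 1, 19), fl19, "intron_sense", 1L)
  expect_false(ev3$criteria[["length_20_22"]])
  expect_false(ev3$verdict)
})

test_that("a mature spanning the terminal loop is rejected", {
  pc <- planted_candidate()
  h <- fold_mfe(pc$mature)
  # position the "mature" across the loop of the planted precursor
  fl <- extract_flanks(pc$genome, pc$start0 + 15L, pc$end0 + 15L, "+")
  ev <- evaluate_candidate(substr(pc$genome, pc$start0 + 16, pc$end0 + 15),
                           fl, "intron_sense", 1L)
  expect_false(ev$criteria[["folds_hairpin_mature_in_arm"]])
})

test_that("unstructured loci fail the hairpin criteria", {
  set.seed(85)
  genome <- paste0(paste(sample(c("A", "C", "G", "T"), 300, TRUE),
                         collapse = ""),
                   strrep("A", 60),
                   paste(sample(c("A", "C", "G", "T"), 300, TRUE),
                         collapse = ""))
  fl <- extract_flanks(genome, 320L, 341L, "+")
  ev <- evaluate_candidate(substr(genome, 321, 341), fl, "intron_sense", 1L)
  expect_false(ev$verdict)
})

test_that("the caller recovers planted loci, honors support, names stably", {
  cfg <- clean_config(seed = 86, n_novel_mirna = 5L, n_decoy_loci = 10L,
                      min_mirna_reads = 10L,
                      library_sizes = c(E13 = 6000L, E19 = 6000L,
                                        E27 = 6000L))
  sim <- simulate_dataset(cfg)
  g <- sim$genome
  prep <- lapply(sim$libraries$reads, preprocess_library,
                 adapter3 = cfg$adapter3, adapter5 = cfg$adapter5)
  refs <- c(list(miRNA = setNames(g$known$seq, g$known$name)), g$decoys)
  ann <- lapply(prep, function(p)
    annotate_hierarchy(p$uniques, refs, g$genome, g$tracks))
  res <- call_novel(ann, g$genome, g$tracks)
  expect_setequal(res$novel$seq, g$novel$seq)
  # names follow descending total counts
  tot <- rowSums(res$novel[, names(cfg$library_sizes)])
  expect_true(all(diff(tot) <= 0))
  expect_equal(res$novel$name, sprintf("novel-mir-%d", seq_along(tot)))
  # per-library counts match the drawn truth
  truth <- sim$libraries$expected[
    g$novel$name[match(res$novel$seq, g$novel$seq)], ]
  expect_equal(unname(as.matrix(res$novel[, names(cfg$library_sizes)])),
               unname(truth))
  # raising the support threshold above the planted counts silences the call
  quiet <- call_novel(ann, g$genome, g$tracks,
                      novel_params(min_reads = 10000L))
  expect_equal(nrow(quiet$novel), 0L)
})

test_that("relaxing any single threshold never removes a called candidate", {
  cfg <- clean_config(seed = 87, n_novel_mirna = 4L, n_decoy_loci = 6L,
                      min_mirna_reads = 10L,
                      library_sizes = c(E13 = 5000L, E19 = 5000L,
                                        E27 = 5000L))
  sim <- simulate_dataset(cfg)
  g <- sim$genome
  prep <- lapply(sim$libraries$reads, preprocess_library,
                 adapter3 = cfg$adapter3, adapter5 = cfg$adapter5)
  refs <- c(list(miRNA = setNames(g$known$seq, g$known$name)), g$decoys)
  ann <- lapply(prep, function(p)
    annotate_hierarchy(p$uniques, refs, g$genome, g$tracks))
  base <- call_novel(ann, g$genome, g$tracks)
  relaxed <- list(novel_params(energy_max = -10),
                  novel_params(max_loop = 8L),
                  novel_params(hit_cap = 20L),
                  novel_params(min_reads = 2L))
  for (par in relaxed) {
    r <- call_novel(ann, g$genome, g$tracks, par)
    expect_true(all(base$novel$seq %in% r$novel$seq))
  }
})
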