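A3 <- "TGGAATTCTCGGGTGCCAAGG"
A5 <- "GTTCAGAGTTCTACAGTCCGACGATC"

test_that("reads land in exactly one category with the documented precedence", {
  insert <- paste(rep(c("A", "C", "G", "T"), length.out = 22), collapse = "")
  reads <- c(
    paste0(insert, A3),                      # retained
    strrep("C", 44),                         # no adapter -> adaptor3_null
    paste0(A3, strrep("G", 23)),             # adapter at position 0 -> insert_null
    paste0(substr(A5, 1, 12), "CCGGCCGGCC", A3),  # 5' adapter contaminant
    paste0("ACGTACGTACGTACG", A3),           # 15-nt insert -> too short
    paste0(strrep("A", 20), A3))             # polyA
  cl <- classify_and_trim(reads, A3, A5)
  expect_equal(as.character(cl$category),
               c("retained", "adaptor3_null", "insert_null",
                 "adaptor5_contaminant", "shorter_than_18nt", "polyA"))
  expect_equal(cl$insert[1], insert)
  expect_true(all(is.na(cl$insert[-1])))
})

test_that("adapter matching falls back to one mismatch", {
  insert <- strrep("CT", 10)
  a3_mut <- paste0("A", substr(A3, 2, 12))   # 1 mismatch in the 12-mer
  cl <- classify_and_trim(paste0(insert, a3_mut), A3, A5)
  expect_equal(as.character(cl$category), "retained")
  expect_equal(cl$insert, insert)
  expect_error(classify_and_trim("ACGT", substr(A3, 1, 5), A5),
               "match_len")
})

test_that("quality screen applies the Phred-fraction and N rules", {
  expect_true(quality_screen("ACGT", "IIII"))
  expect_false(quality_screen("ACGT", "!!!!"))
  expect_false(quality_screen("ANNT", "IIII"))   # two N's
  # on simulated data with 1% degraded reads the fail count is binomial
  set.seed(31)
  n <- 5000
  bad <- runif(n) < 0.01
  quals <- ifelse(bad, strrep("!", 36), strrep("I", 36))
  fails <- sum(!quality_screen(rep(strrep("A", 36), n), quals))
  expect_lt(abs(fails - n * 0.01), 3 * sqrt(n * 0.01 * 0.99) + 1)
})

test_that("collapsing conserves counts and orders by count then sequence", {
  ins <- c(rep(strrep("AC", 10), 3), rep(strrep("GT", 10), 2),
           strrep("CA", 10))
  out <- collapse_reads(ins)
  expect_equal(sum(out$uniques$count), length(ins))
  expect_equal(out$uniques$seq[1], strrep("AC", 10))
  # tie at count 1 vs 2: descending count first
  out2 <- collapse_reads(c("ACGTACGTACGTACGTAC", "ACGTACGTACGTACGTAC",
                           "AAAAAAAACCCCCCCCGG"))
  expect_equal(out2$uniques$count, c(2L, 1L))
  expect_equal(sum(out2$histogram), 3L)
  expect_named(out2$histogram, as.character(18:30))
})

test_that("filter accounting reproduces the published library summaries", {
  e13 <- filter_summary(14794223,
                        c(adaptor3_null = 1986, insert_null = 2620,
                          adaptor5_contaminant = 69355,
                          shorter_than_18nt = 139922, polyA = 225),
                        total_reads = 14881453)
  expect_equal(e13$count[e13$type == "high_quality_reads"], 14580115)
  expect_equal(e13$pct[e13$type == "high_quality_reads"], 98.55)
  e19 <- filter_summary(13376800,
                        c(adaptor3_null = 6332, insert_null = 1613,
                          adaptor5_contaminant = 38647,
                          shorter_than_18nt = 313055, polyA = 183))
  expect_equal(e19$count[e19$type == "high_quality_reads"], 13016970)
  expect_equal(e19$pct[e19$type == "high_quality_reads"], 97.31)
  zero <- filter_summary(1000, c(adaptor3_null = 0, insert_null = 0,
                                 adaptor5_contaminant = 0,
                                 shorter_than_18nt = 0, polyA = 0))
  expect_equal(zero$pct[zero$type == "high_quality_reads"], 100.00)
})

test_that("every read is categorized exactly once and totals are conserved", {
  cfg <- sim_config(seed = 4, library_sizes = c(E13 = 8000L, E19 = 8000L,
                                                E27 = 8000L))
  sim <- simulate_dataset(cfg)
  for (L in names(cfg$library_sizes)) {
    pr <- preprocess_library(sim$libraries$reads[[L]], cfg$adapter3,
                             cfg$adapter5)
    s <- pr$summary
    hq <- s$count[s$type == "high_quality"]
    discards <- s$count[s$type %in% c("adaptor3_null", "insert_null",
                                      "adaptor5_contaminant",
                                      "shorter_than_18nt", "polyA")]
    retained <- s$count[s$type == "high_quality_reads"]
    expect_equal(hq - sum(discards), retained)
    expect_equal(length(pr$categories), hq)
    expect_equal(sum(pr$uniques$count), retained)
    expect_equal(sum(pr$histogram), retained)
    # collapsing then re-expanding reproduces the retained insert multiset
    expect_equal(sort(rep(pr$uniques$seq, pr$uniques$count)),
                 sort(pr$inserts))
  }
})

test_that("a clean simulation retains every read as a planted insert", {
  cfg <- clean_config(seed = 8, library_sizes = c(E13 = 4000L, E19 = 4000L,
                                                  E27 = 4000L))
  sim <- simulate_dataset(cfg)
  pr <- preprocess_library(sim$libraries$reads$E13, cfg$adapter3,
                           cfg$adapter5)
  s <- pr$summary
  expect_equal(s$pct[s$type == "high_quality_reads"], 100.00)
  expect_true(all(pr$uniques$seq %in% sim$libraries$species$seq))
})
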