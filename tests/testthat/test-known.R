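test_that("reads are assigned to the closest reference mature", {
  mats <- c(`miR-a` = "TGGAATGTAAAGAAGTATGTAG",
            `miR-b` = "ACGGCCTTGGAACCTTGGAACC")
  uq <- data.frame(seq = c(mats[["miR-a"]],                  # exact
                           sub("^AC", "CC", mats[["miR-b"]]), # 1 mm to b
                           strrep("GA", 11)),                 # matches nothing
                   count = c(5L, 2L, 1L), stringsAsFactors = FALSE)
  got <- match_known(uq, mats)
  expect_equal(got$mirna, c("miR-a", "miR-b", NA))
  expect_equal(got$mismatches[1:2], c(0L, 1L))
})

test_that("assignment prefers fewer mismatches and agrees with brute force", {
  set.seed(51)
  mats <- setNames(simulate_matures(20), sprintf("miR-%02d", 1:20))
  reads <- character(50)
  for (i in 1:50) {
    base <- mats[[sample(20, 1)]]
    nmut <- sample(0:3, 1)
    for (pp in sample(nchar(base), nmut))
      substr(base, pp, pp) <- sample(c("A", "C", "G", "T"), 1)
    reads[i] <- base
  }
  uq <- data.frame(seq = reads, count = 1L, stringsAsFactors = FALSE)
  got <- match_known(uq, mats)
  nm <- sort(names(mats))
  for (i in 1:50) {
    d <- vapply(nm, function(m) slide_hamming_r(reads[i], mats[[m]]),
                numeric(1))
    if (min(d) > 2) {
      expect_true(is.na(got$mirna[i]))
    } else {
      expect_equal(got$mirna[i], nm[which.min(d)])
      expect_equal(got$mismatches[i], as.integer(min(d)))
    }
  }
})

test_that("family names collapse species prefix, arm and paralog suffixes", {
  expect_equal(mirna_family(c("xdu-let-7f-5p", "miR-133a", "let-7a-2-3p",
                              "gga-miR-103a-3p", "miR-1", "miR-206")),
               c("let-7", "miR-133", "let-7", "miR-103", "miR-1", "miR-206"))
})

test_that("family collapsing picks the highest-expressed member", {
  prof <- matrix(c(10L, 3L, 5L, 5L), 4, 1,
                 dimnames = list(c("miR-9a-5p", "miR-9b-5p",
                                   "miR-20a", "miR-20b"), "E13"))
  fam <- collapse_families(prof)
  expect_equal(fam$representative[fam$family == "miR-9"], "miR-9a-5p")
  # tie at 5 reads: lexicographically smaller name wins
  expect_equal(fam$representative[fam$family == "miR-20"], "miR-20a")
  expect_lte(nrow(fam), nrow(prof))
})

test_that("collapsing preserves totals and recovers planted dominants", {
  cfg <- clean_config(seed = 13, library_sizes = c(E13 = 6000L, E19 = 6000L,
                                                   E27 = 6000L))
  sim <- simulate_dataset(cfg)
  g <- sim$genome
  prep <- lapply(sim$libraries$reads, preprocess_library,
                 adapter3 = cfg$adapter3, adapter5 = cfg$adapter5)
  known <- identify_known(lapply(prep, `[[`, "uniques"),
                          setNames(g$known$seq, g$known$name),
                          precursors = g$known_precursors)
  expect_equal(sum(known$profile), sum(sim$libraries$expected[g$known$name, ]))
  fam <- known$families
  # representative = planted member with the largest drawn total
  truth_tot <- rowSums(sim$libraries$expected[g$known$name, ])
  for (f in fam$family) {
    members <- g$known$name[mirna_family(g$known$name) == f]
    dom <- members[order(-truth_tot[members], members)][1]
    expect_equal(fam$representative[fam$family == f], dom)
  }
})

test_that("hairpin verification passes designed precursors and rejects noise", {
  set.seed(55)
  m <- simulate_matures(1)
  pr <- mirflow:::design_precursor(m)
  expect_true(verify_hairpin(m, pr$seq))
  expect_false(verify_hairpin(strrep("A", 21),
                              paste0(strrep("A", 70))))
  # unverifiable when the mature is not in the precursor
  expect_true(is.na(verify_hairpin(strrep("CA", 11), pr$seq)))
})

test_that("nucleotide bias is a probability vector with the planted 5' U signal", {
  b <- nucleotide_bias(c("UAAA", "UGGG"))
  expect_equal(unname(b$pos1[["U"]]), 1.0)
  b2 <- nucleotide_bias(c("UAAA", "AGGG"))
  expect_equal(unname(b2$pos1[["U"]]), 0.5)
  expect_equal(unname(b2$pos1[["A"]]), 0.5)
  expect_error(nucleotide_bias(character(0)), "nonempty")
  set.seed(57)
  mats <- simulate_matures(500, first_base_u_prob = 0.85)
  bb <- nucleotide_bias(mats)
  expect_true(all(abs(rowSums(bb$freq) - 1) < 1e-9))
  se <- sqrt(0.85 * 0.15 / 500)
  expect_lt(abs(bb$pos1[["U"]] - 0.85), 3 * se)
})

test_that("clean-simulation counts are recovered exactly", {
  cfg <- clean_config(seed = 14, library_sizes = c(E13 = 6000L, E19 = 6000L,
                                                   E27 = 6000L))
  sim <- simulate_dataset(cfg)
  g <- sim$genome
  prep <- lapply(sim$libraries$reads, preprocess_library,
                 adapter3 = cfg$adapter3, adapter5 = cfg$adapter5)
  known <- identify_known(lapply(prep, `[[`, "uniques"),
                          setNames(g$known$seq, g$known$name),
                          precursors = g$known_precursors)
  truth <- sim$libraries$expected[rownames(known$profile), ]
  expect_equal(known$profile + 0L, truth + 0L, ignore_attr = TRUE)
  expect_setequal(rownames(known$profile), g$known$name)
  expect_true(all(known$hairpin_ok[rownames(known$profile)]))
})
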