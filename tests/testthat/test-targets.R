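mk_mir <- function(seq) data.frame(name = "mir", seq = seq,
                                   stringsAsFactors = FALSE)
mk_tx <- function(seq, id = "tx") data.frame(id = id, seq = seq,
                                             stringsAsFactors = FALSE)

test_that("a perfect seed complement is found with zero wobbles", {
  mir <- "TGGAATGTAAAGAAGTATGTAG"
  site <- revcomp(substr(mir, 1, 9))
  tx <- paste0(strrep("C", 40), site, strrep("C", 40))
  hits <- seed_scan(mk_mir(mir), mk_tx(tx))
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$start, 41L)
  expect_equal(hits$gu, 0L)
  expect_equal(hits$pairing, strrep("W", 9))
})

test_that("the G:U cap rejects sites with four wobbles", {
  mir <- paste0("TTTT", "TGTAA", strrep("A", 13))  # seed TTTTTGTAA
  site_wc <- revcomp(substr(mir, 1, 9))
  # wobble the pairs of miRNA positions 1-4 (T->G at site end)
  site4 <- site_wc
  for (k in 6:9) substr(site4, k, k) <- "G"
  tx <- paste0(strrep("C", 20), site4, strrep("C", 20))
  expect_equal(nrow(seed_scan(mk_mir(mir), mk_tx(tx))), 0L)
  # exactly three wobbles pass
  site3 <- site_wc
  for (k in 7:9) substr(site3, k, k) <- "G"
  tx3 <- paste0(strrep("C", 20), site3, strrep("C", 20))
  hits <- seed_scan(mk_mir(mir), mk_tx(tx3))
  expect_equal(hits$gu, 3L)
})

test_that("scanning agrees with exhaustive window enumeration", {
  set.seed(71)
  mirs <- data.frame(name = sprintf("m%d", 1:20),
                     seq = simulate_matures(20),
                     stringsAsFactors = FALSE)
  txs <- data.frame(id = sprintf("t%d", 1:5),
                    seq = vapply(1:5, function(i)
                      paste(sample(c("A", "C", "G", "T"), 300, TRUE),
                            collapse = ""), character(1)),
                    stringsAsFactors = FALSE)
  hits <- seed_scan(mirs, txs)
  for (i in seq_len(nrow(mirs))) for (j in seq_len(nrow(txs))) {
    want <- brute_seed_scan(mirs$seq[i], txs$seq[j])
    got <- hits[hits$mirna == mirs$name[i] & hits$transcript == txs$id[j], ]
    if (is.null(want)) {
      expect_equal(nrow(got), 0L)
    } else {
      expect_equal(got$start, want$start)
      expect_equal(got$gu, want$gu)
    }
  }
})

test_that("every reported site re-verifies base-by-base", {
  set.seed(73)
  mirs <- data.frame(name = "m", seq = simulate_matures(1),
                     stringsAsFactors = FALSE)
  site <- revcomp(substr(mirs$seq, 1, 9))
  site_w <- site
  substr(site_w, 9, 9) <- chartr("AT", "GG", substr(site, 9, 9))  # wobble
  tx <- paste0(paste(sample(c("A", "C", "G", "T"), 2000, TRUE), collapse = ""),
               site, strrep("A", 20), site_w,
               paste(sample(c("A", "C", "G", "T"), 2000, TRUE), collapse = ""))
  hits <- seed_scan(mirs, mk_tx(tx))
  seed <- strsplit(substr(norm_dna(mirs$seq), 1, 9), "")[[1]]
  for (h in seq_len(nrow(hits))) {
    site <- strsplit(substr(tx, hits$start[h], hits$end[h]), "")[[1]]
    gu <- 0
    for (k in 1:9) {
      mb <- seed[k]; tb <- site[9 - k + 1]
      wc <- paste0(mb, tb) %in% c("AT", "TA", "GC", "CG")
      wob <- paste0(mb, tb) %in% c("GT", "TG")
      expect_true(wc || wob)
      gu <- gu + wob
    }
    expect_lte(gu, 3)
    expect_equal(hits$gu[h], gu)
  }
})

test_that("scan results are invariant to U/T encoding and transcript order", {
  set.seed(74)
  mir <- mk_mir(simulate_matures(1))
  txs <- data.frame(id = c("a", "b"),
                    seq = c(paste(sample(c("A", "C", "G", "T"), 200, TRUE),
                                  collapse = ""),
                            paste(sample(c("A", "C", "G", "T"), 200, TRUE),
                                  collapse = "")),
                    stringsAsFactors = FALSE)
  h1 <- seed_scan(mir, txs)
  mir_u <- mir; mir_u$seq <- chartr("T", "U", mir_u$seq)
  txs_u <- txs; txs_u$seq <- chartr("T", "U", txs_u$seq)
  h2 <- seed_scan(mir_u, txs_u)
  expect_equal(h1, h2)
  h3 <- seed_scan(mir, txs[2:1, ])
  expect_equal(h1[order(h1$transcript, h1$start), c("transcript", "start")],
               h3[order(h3$transcript, h3$start), c("transcript", "start")],
               ignore_attr = TRUE)
})

test_that("target and locus tallies count planted sites exactly", {
  mir <- "TGGAATGTAAAGAAGTATGTAG"
  site <- revcomp(substr(mir, 1, 9))
  pad <- strrep("C", 30)
  txs <- data.frame(id = c("t1", "t2"),
                    seq = c(paste0(pad, site, pad, site, pad),  # two sites
                            paste0(pad, site, pad)),            # one site
                    stringsAsFactors = FALSE)
  hits <- seed_scan(mk_mir(mir), txs)
  s <- summarize_targets(hits)
  expect_equal(s$targets, 2L)
  expect_equal(s$loci, 3L)
  expect_gte(s$loci, s$targets)
  # one transcript hit at two sites; no hits at all
  s1 <- summarize_targets(seed_scan(mk_mir(mir), mk_tx(txs$seq[1])))
  expect_equal(unlist(s1[c("targets", "loci")], use.names = FALSE), c(1L, 2L))
  s0 <- summarize_targets(seed_scan(mk_mir(mir), mk_tx(strrep("C", 50))))
  expect_equal(unlist(s0[c("targets", "loci")], use.names = FALSE), c(0L, 0L))
})
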