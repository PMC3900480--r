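# Seed-rule miRNA target scanning: a site is a transcript 9-mer pairing
# antiparallel with miRNA positions 1-9 (5' end) using only Watson-Crick or
# G:U pairs, no mismatches, and at most three G:U wobbles.

# transcript base classes that can pair each miRNA base (DNA alphabet):
# miRNA A -> T; C -> G; G -> C or T (wobble); T/U -> A or G (wobble)
seed_site_regex <- function(mirna_seq, seed_len = 9L) {
  b <- strsplit(norm_dna(substr(mirna_seq, 1, seed_len)), "")[[1]]
  cls <- vapply(b, function(x) switch(x, A = "T", C = "G",
                                      G = "[CT]", T = "[AG]",
                                      stop("seed contains invalid base")),
                character(1))
  # site runs 5'->3' on the transcript, pairing miRNA position seed_len..1
  paste(rev(cls), collapse = "")
}

#' Scan transcripts for seed-rule target sites
#'
#' @param mirnas data.frame `name`, `seq` (miRNAs >= 18 nt).
#' @param transcripts data.frame `id`, `seq` (transcripts >= 9 nt).
#' @param max_gu maximal number of G:U wobbles in the seed (default 3).
#' @param seed_len seed length counted from the miRNA 5' end (default 9).
#' @return data.frame of hits: `mirna`, `transcript`, `start`, `end`
#'   (1-based inclusive on the transcript strand), `gu` (wobble count),
#'   `pairing` (string over W/G for Watson-Crick/wobble, site 5'->3').
#' @export
seed_scan <- function(mirnas, transcripts, max_gu = 3L, seed_len = 9L) {
  stopifnot(all(nchar(mirnas$seq) >= 18), all(nchar(transcripts$seq) >= seed_len))
  hits <- list()
  for (i in seq_len(nrow(mirnas))) {
    mir <- norm_dna(mirnas$seq[i])
    pat <- paste0("(?=", seed_site_regex(mir, seed_len), ")")
    seed_rev <- rev(strsplit(substr(mir, 1, seed_len), "")[[1]])
    for (j in seq_len(nrow(transcripts))) {
      tx <- norm_dna(transcripts$seq[j])
      m <- gregexpr(pat, tx, perl = TRUE)[[1]]
      if (m[1] < 0) next
      for (s in as.integer(m)) {
        site <- strsplit(substr(tx, s, s + seed_len - 1), "")[[1]]
        # wobble where miRNA G pairs T, or miRNA T(U) pairs G
        wob <- (seed_rev == "G" & site == "T") |
               (seed_rev == "T" & site == "G")
        if (sum(wob) > max_gu) next
        hits[[length(hits) + 1]] <- data.frame(
          mirna = mirnas$name[i], transcript = transcripts$id[j],
          start = s, end = s + seed_len - 1L, gu = sum(wob),
          pairing = paste(ifelse(wob, "G", "W"), collapse = ""),
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(hits))
    return(data.frame(mirna = character(0), transcript = character(0),
                      start = integer(0), end = integer(0), gu = integer(0),
                      pairing = character(0), stringsAsFactors = FALSE))
  do.call(rbind, hits)
}

#' Tally targets and target loci
#'
#' @param hits a [seed_scan()] result.
#' @return data.frame with one row: `n_mirna`, `targets` (distinct
#'   transcripts hit), `loci` (distinct transcript/position sites).
#' @export
summarize_targets <- function(hits) {
  data.frame(n_mirna = length(unique(hits$mirna)),
             targets = length(unique(hits$transcript)),
             loci = nrow(unique(hits[, c("transcript", "start")])),
             stringsAsFactors = FALSE)
}
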