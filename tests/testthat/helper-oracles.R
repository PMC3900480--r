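# Independent brute-force oracles used across the suite.  These deliberately
# share no code with the implementation paths they check.

# all nested secondary structures (dot-bracket) with minimal hairpin loop 3
# and canonical WC/GU pairs; exhaustive enumeration for small n
enum_structures <- function(seq) {
  b <- strsplit(chartr("Tt", "Uu", toupper(seq)), "")[[1]]
  n <- length(b)
  can_pair <- function(i, j) {
    p <- paste0(b[i], b[j])
    p %in% c("AU", "UA", "CG", "GC", "GU", "UG")
  }
  memo <- new.env(parent = emptyenv())
  rec <- function(i, j) {
    if (i > j) return(list(integer(0)))
    key <- paste(i, j)
    if (!is.null(memo[[key]])) return(memo[[key]])
    out <- lapply(rec(i + 1, j), identity)          # i unpaired
    ks <- if (j >= i + 4) (i + 4):j else integer(0)
    for (k in ks) {
      if (!can_pair(i, k)) next
      inner <- rec(i + 1, k - 1)
      outer <- rec(k + 1, j)
      for (a in inner) for (z in outer)
        out[[length(out) + 1]] <- c(i, k, a, z)
    }
    memo[[key]] <- out
    out
  }
  structs <- rec(1L, n)
  vapply(structs, function(pr) {
    db <- rep(".", n)
    if (length(pr)) {
      op <- pr[seq(1, length(pr), by = 2)]
      clz <- pr[seq(2, length(pr), by = 2)]
      db[op] <- "("; db[clz] <- ")"
    }
    paste(db, collapse = "")
  }, character(1))
}

# naive minimum sliding Hamming distance (shorter inside longer)
slide_hamming_r <- function(a, b) {
  if (nchar(a) > nchar(b)) { tmp <- a; a <- b; b <- tmp }
  sa <- strsplit(a, "")[[1]]; sb <- strsplit(b, "")[[1]]
  ns <- length(sa); nl <- length(sb)
  best <- ns + 1L
  for (off in 0:(nl - ns))
    best <- min(best, sum(sa != sb[(off + 1):(off + ns)]))
  best
}

# naive full-query ungapped mapping with mismatches, both strands
rc <- function(x) paste(rev(strsplit(chartr("ACGT", "TGCA", x), "")[[1]]),
                        collapse = "")
naive_map <- function(query, refs, max_mm) {
  out <- NULL
  for (nm in names(refs)) {
    sref <- strsplit(refs[[nm]], "")[[1]]
    for (std in c("+", "-")) {
      q <- if (std == "+") query else rc(query)
      sq <- strsplit(q, "")[[1]]
      nq <- length(sq)
      if (nq > length(sref)) next
      for (pos in 1:(length(sref) - nq + 1)) {
        mm <- sum(sq != sref[pos:(pos + nq - 1)])
        if (mm <= max_mm)
          out <- rbind(out, data.frame(ref = nm, pos = pos, strand = std,
                                       mismatches = mm,
                                       stringsAsFactors = FALSE))
      }
    }
  }
  if (is.null(out))
    return(data.frame(ref = character(0), pos = integer(0),
                      strand = character(0), mismatches = integer(0)))
  out <- out[order(out$mismatches, out$ref, out$pos), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# direct term-by-term summation of the count-ratio conditional distribution
ac_pvalue_direct <- function(x, y, n1, n2) {
  r <- n2 / n1
  logterm <- function(k)
    k * log(r) + lgamma(x + k + 1) - lgamma(x + 1) - lgamma(k + 1) -
      (x + k + 1) * log1p(r)
  # both tails by direct summation (the geometric tail ratio r/(1+r) < 1
  # makes the truncation error negligible at this horizon)
  kmax <- y + as.integer(10 * (x + 1) * max(1, r)) + 2000
  terms <- exp(logterm(0:kmax))
  lower <- sum(terms[1:(y + 1)])
  upper <- sum(terms[(y + 1):(kmax + 1)])
  min(1, 2 * min(lower, upper))
}

# brute-force seed scan: check every window base-by-base
brute_seed_scan <- function(mir_seq, tx_seq, max_gu = 3, seed_len = 9) {
  mir <- strsplit(chartr("U", "T", toupper(mir_seq)), "")[[1]][1:seed_len]
  tx <- strsplit(chartr("U", "T", toupper(tx_seq)), "")[[1]]
  hits <- NULL
  if (length(tx) < seed_len) return(hits)
  for (s in 1:(length(tx) - seed_len + 1)) {
    ok <- TRUE; gu <- 0L
    for (k in 1:seed_len) {
      mb <- mir[k]; tb <- tx[s + seed_len - k]  # antiparallel
      wc <- (mb == "A" && tb == "T") || (mb == "T" && tb == "A") ||
            (mb == "G" && tb == "C") || (mb == "C" && tb == "G")
      wob <- (mb == "G" && tb == "T") || (mb == "T" && tb == "G")
      if (wc) next
      if (wob) { gu <- gu + 1L; next }
      ok <- FALSE; break
    }
    if (ok && gu <= max_gu)
      hits <- rbind(hits, data.frame(start = s, gu = gu))
  }
  hits
}

# small clean configuration used by several recovery tests
clean_config <- function(seed = 11L, dispersion = 0, ...) {
  sim_config(seed = seed,
             contamination_rates = c(adaptor3_null = 0, insert_null = 0,
                                     adaptor5_contaminant = 0,
                                     shorter_than_18nt = 0, polyA = 0),
             quality_fail_rate = 0, error_rate = 0, isomir_rate = 0,
             dispersion = dispersion, ...)
}
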