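# RNA secondary structure: bundled minimum-free-energy folder and the shared
# structural tests used by hairpin verification and novel-miRNA calling.

#' Fold an RNA sequence to its minimum-free-energy structure
#'
#' A self-contained dynamic-programming folder over nested (pseudoknot-free)
#' structures using nearest-neighbor stacking energies for Watson-Crick and
#' G:U pairs plus length penalties for hairpin, bulge and internal loops and
#' an affine multiloop penalty.  The energy model is exposed by
#' [fold_energy_model()] so independent re-evaluation of any structure uses
#' the identical parameters.  An optional backend shells out to the
#' `RNAfold` executable when one is available; all package internals use the
#' bundled folder.
#'
#' @param seq a single nucleotide sequence (A/C/G/T/U, case-insensitive),
#'   40-400 nt for typical precursors although any length >= 1 is accepted.
#' @param backend `"bundled"` (default) or `"vienna"`.
#' @return an object of class `mirflow_hairpin`: list with `seq` (as given),
#'   `structure` (dot-bracket), `energy` (kcal/mol), and `pairs` (integer
#'   vector of 1-based partner positions, `NA` where unpaired).
#' @examples
#' fold_mfe("GGGGGGGGGGAAAACCCCCCCCCC")
#' @export
fold_mfe <- function(seq, backend = c("bundled", "vienna")) {
  backend <- match.arg(backend)
  stopifnot(is.character(seq), length(seq) == 1, nchar(seq) >= 1)
  validate_alphabet(seq, "fold_mfe input", allow_n = FALSE)
  rna <- as_rna(seq)
  if (backend == "vienna") {
    res <- fold_vienna(rna)
  } else {
    res <- fold_rna_cpp(rna)
  }
  structure(list(seq = seq, structure = res$structure,
                 energy = res$energy, pairs = pair_table(res$structure)),
            class = "mirflow_hairpin")
}

#' @export
print.mirflow_hairpin <- function(x, ...) {
  cat(as_rna(x$seq), "\n", x$structure, sprintf(" (%.1f kcal/mol)\n", x$energy),
      sep = "")
  invisible(x)
}

fold_vienna <- function(rna) {
  exe <- Sys.which("RNAfold")
  if (!nzchar(exe)) stop("RNAfold executable not found on PATH")
  out <- system2(exe, c("--noPS"), input = rna, stdout = TRUE)
  line <- out[2]
  db <- sub("^([.()]+).*$", "\\1", line)
  en <- as.numeric(sub("^.*\\((\\s*-?[0-9.]+)\\)\\s*$", "\\1", line))
  list(structure = db, energy = en)
}

#' Pair table of a dot-bracket structure
#'
#' @param structure dot-bracket string.
#' @return integer vector, `pairs[i]` is the 1-based partner of position `i`
#'   or `NA` when unpaired.
#' @export
pair_table <- function(structure) {
  ch <- strsplit(structure, "")[[1]]
  n <- length(ch)
  pairs <- rep(NA_integer_, n)
  stk <- integer(0)
  for (i in seq_len(n)) {
    if (ch[i] == "(") {
      stk <- c(stk, i)
    } else if (ch[i] == ")") {
      if (!length(stk)) stop("unbalanced dot-bracket structure")
      j <- stk[length(stk)]
      stk <- stk[-length(stk)]
      pairs[j] <- i
      pairs[i] <- j
    } else if (ch[i] != ".") {
      stop("dot-bracket structure contains invalid character: ", ch[i])
    }
  }
  if (length(stk)) stop("unbalanced dot-bracket structure")
  pairs
}

#' The bundled folding energy model
#'
#' @return list with the stacking-energy matrix (kcal/mol, outer pair by
#'   inner pair), hairpin/bulge/internal loop penalties indexed by unpaired
#'   length 0..30 (with logarithmic extrapolation beyond), and the multiloop
#'   constants.
#' @export
fold_energy_model <- function() fold_energy_model_cpp()

#' Free energy of a given structure under the bundled model
#'
#' Independent R-side evaluator of the same energy model the dynamic program
#' optimizes; used to audit the folder (the traceback structure must evaluate
#' to the reported minimum, and no enumerated structure may do better).
#'
#' @param seq nucleotide sequence.
#' @param structure dot-bracket string of the same length.
#' @return energy in kcal/mol.
#' @export
structure_energy <- function(seq, structure) {
  seq <- norm_dna(seq)
  stopifnot(nchar(seq) == nchar(structure))
  em <- fold_energy_model()
  pairs <- pair_table(structure)
  b <- strsplit(as_rna(seq), "")[[1]]
  pair_name <- function(i, j) paste0(b[i], b[j])
  loop_len_e <- function(tab, n, base_n) {
    if (n <= 30) tab[n + 1] else loop_extrapolate_cpp(tab[base_n + 1], base_n, n)
  }
  total <- 0
  opened <- which(!is.na(pairs) & pairs > seq_along(pairs))
  for (i in opened) {
    j <- pairs[i]
    # direct children pairs inside (i,j)
    k <- i + 1
    children <- list()
    unpaired <- 0
    while (k < j) {
      if (!is.na(pairs[k]) && pairs[k] > k) {
        children[[length(children) + 1]] <- c(k, pairs[k])
        k <- pairs[k] + 1
      } else {
        unpaired <- unpaired + 1
        k <- k + 1
      }
    }
    nb <- length(children)
    if (nb == 0) {
      total <- total + loop_len_e(em$hairpin, j - i - 1, 9)
    } else if (nb == 1) {
      k <- children[[1]][1]; l <- children[[1]][2]
      n1 <- k - i - 1; n2 <- j - l - 1
      if (n1 == 0 && n2 == 0) {
        total <- total + em$stack[pair_name(i, j), pair_name(k, l)]
      } else if (n1 == 0 || n2 == 0) {
        total <- total + loop_len_e(em$bulge, n1 + n2, 6)
      } else {
        total <- total + loop_len_e(em$internal, n1 + n2, 6)
      }
    } else {
      total <- total + em$multi_closing + em$multi_branch * (nb + 1) +
        em$multi_unpaired * unpaired
    }
  }
  total
}

# Does the mature sit inside one arm of a folded stem-loop?  Requires at
# least `min_paired_frac` of the mature bases paired, with every partner on
# the same side of the mature (no pairing into or across the terminal loop),
# and both mature ends within `end_slack` of a paired base.
mature_arm_check <- function(pairs, mstart, mend, min_paired_frac = 0.75,
                             end_slack = 2) {
  idx <- mstart:mend
  part <- pairs[idx]
  paired <- which(!is.na(part))
  if (length(paired) / length(idx) < min_paired_frac) return(FALSE)
  partners <- part[paired]
  if (any(partners >= mstart & partners <= mend)) return(FALSE)
  if (!(all(partners > mend) || all(partners < mstart))) return(FALSE)
  i1 <- idx[min(paired)]; i2 <- idx[max(paired)]
  if ((i1 - mstart) > end_slack || (mend - i2) > end_slack) return(FALSE)
  TRUE
}

# Star coordinates implied by the mature placement plus the canonical
# 2-nt 3' overhang of miRNA/miRNA* duplexes.  Returns c(lo, hi) in 1-based
# coordinates, or NULL when the geometry cannot be formed.
star_coords <- function(pairs, mstart, mend) {
  idx <- mstart:mend
  part <- pairs[idx]
  paired <- which(!is.na(part))
  if (!length(paired)) return(NULL)
  i1 <- idx[min(paired)]  # 5'-most paired mature base
  i2 <- idx[max(paired)]  # 3'-most paired mature base
  # antiparallel duplex: the star runs partner(i2)..partner(i1); its 3' end
  # sits across from the mature 5' end and overhangs it by 2 nt
  lo <- pairs[i2]
  hi <- pairs[i1] + 2L
  if (lo > hi) return(NULL)
  c(lo, hi)
}

# longest run of unpaired bases within positions lo..hi
max_unpaired_run <- function(pairs, lo, hi) {
  if (lo > hi) return(0L)
  un <- is.na(pairs[lo:hi])
  if (!any(un)) return(0L)
  r <- rle(un)
  max(r$lengths[r$values])
}
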