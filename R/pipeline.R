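# End-to-end driver: simulate (or take files), preprocess each library,
# annotate, identify known miRNAs, call novel candidates, test differential
# expression for the stage pairs, and scan targets of the novel set.

#' Run the full pipeline on a synthetic dataset
#'
#' @param config a [sim_config()]; the dataset is generated from it.
#' @param pairs list of library pairs for differential expression; defaults
#'   to first-vs-second and third-vs-second stage (the E13/E19 and E27/E19
#'   contrasts).
#' @param novel_params thresholds for the novel-miRNA caller.
#' @param verbose print stage banners and tallies.
#' @return list of class `mirflow_run` with elements `sim`, `preprocess`,
#'   `annotation`, `tallies`, `known`, `novel`, `de`, `targets`.
#' @export
run_pipeline <- function(config = sim_config(), pairs = NULL,
                         novel_params = mirflow::novel_params(),
                         verbose = TRUE) {
  say <- function(...) if (verbose) message(sprintf(...))
  say("== simulate: genome %d nt, %d+%d miRNA loci",
      config$genome_length, config$n_known_mirna, config$n_novel_mirna)
  sim <- simulate_dataset(config)
  g <- sim$genome
  libs <- names(config$library_sizes)

  say("== preprocess: %s", paste(libs, collapse = ", "))
  prep <- lapply(libs, function(L)
    preprocess_library(sim$libraries$reads[[L]], config$adapter3,
                       config$adapter5))
  names(prep) <- libs
  retained <- vapply(prep, function(p)
    p$summary$count[p$summary$type == "high_quality_reads"], numeric(1))
  for (L in libs)
    say("   %s: retained %d reads, %d uniques", L, as.integer(retained[[L]]),
        nrow(prep[[L]]$uniques))

  say("== annotate")
  refs <- c(list(miRNA = setNames(g$known$seq, g$known$name)), g$decoys)
  ann <- lapply(libs, function(L)
    annotate_hierarchy(prep[[L]]$uniques, refs, g$genome, g$tracks))
  names(ann) <- libs
  tallies <- lapply(ann, class_tally)

  say("== known miRNAs")
  known <- identify_known(lapply(prep, `[[`, "uniques"),
                          setNames(g$known$seq, g$known$name),
                          precursors = g$known_precursors)
  say("   identified %d matures in %d families", nrow(known$profile),
      nrow(known$families))

  say("== novel miRNAs")
  novel <- call_novel(ann, g$genome, g$tracks, novel_params)
  say("   called %d candidates", nrow(novel$novel))

  if (is.null(pairs))
    pairs <- list(c(libs[1], libs[2]), c(libs[3], libs[2]))
  say("== differential expression")
  totals <- retained
  de <- lapply(pairs, function(pr) de_table(known$profile, totals, pr))
  names(de) <- vapply(pairs, paste, character(1), collapse = "_vs_")

  targets <- NULL
  if (!is.null(g$transcripts) && nrow(novel$novel)) {
    say("== target scan (novel set)")
    hits <- seed_scan(novel$novel[, c("name", "seq")], g$transcripts)
    targets <- list(hits = hits, summary = summarize_targets(hits))
  }

  structure(list(sim = sim, preprocess = prep, annotation = ann,
                 tallies = tallies, known = known, novel = novel, de = de,
                 targets = targets, config = config),
            class = "mirflow_run")
}

#' @export
print.mirflow_run <- function(x, ...) {
  libs <- names(x$config$library_sizes)
  cat("mirflow pipeline run\n")
  cat("  libraries:", paste(libs, collapse = ", "), "\n")
  cat("  identified known matures:", nrow(x$known$profile), "\n")
  cat("  novel candidates:", nrow(x$novel$novel), "\n")
  for (nm in names(x$de)) {
    tb <- table(x$de[[nm]]$class)
    cat(sprintf("  DE %s: %d extremely significant, %d significant of %d\n",
                nm, tb[["extremely_significant"]], tb[["significant"]],
                nrow(x$de[[nm]])))
  }
  if (!is.null(x$targets))
    cat(sprintf("  novel targets: %d transcripts, %d loci\n",
                x$targets$summary$targets, x$targets$summary$loci))
  invisible(x)
}
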