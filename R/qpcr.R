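# Relative qPCR quantification by the delta-delta-Ct method with triplicate
# handling, as used for stem-loop miRNA assays against a U6 reference and
# mRNA assays against beta-actin.

#' Read a Ct table
#'
#' TSV with columns `sample`, `assay`, `reference`, `ct` (one row per
#' replicate).
#'
#' @param path file path.
#' @return data.frame.
#' @export
read_ct_table <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  need <- c("sample", "assay", "reference", "ct")
  if (!all(need %in% names(df)))
    stop("Ct table needs columns: ", paste(need, collapse = ", "))
  df
}

#' Relative quantification by 2^-ddCt
#'
#' Replicate Ct values are averaged per (sample, assay); per sample,
#' `dCt = mean(Ct_target) - mean(Ct_reference)`; against the calibrator
#' sample, `ddCt = dCt_sample - dCt_calibrator`; the relative quantity is
#' `N = 2^-ddCt` (so the calibrator's N is exactly 1).  Replicate standard
#' deviations above `sd_max` cycles are flagged, not fatal.
#'
#' @param records data.frame with columns `sample`, `assay`, `reference`,
#'   `ct` (replicates as rows).
#' @param target assay to quantify.
#' @param calibrator calibrator sample id.
#' @param sd_max replicate-SD warning threshold in cycles (default 0.5).
#' @return data.frame: `sample`, `dct`, `ddct`, `N`, `flag_sd`.
#' @export
ddct_quantify <- function(records, target, calibrator, sd_max = 0.5) {
  stopifnot(all(records$ct > 0), all(records$ct < 45))
  tgt <- records[records$assay == target, , drop = FALSE]
  if (!nrow(tgt)) stop("no rows for target assay ", target)
  refassay <- unique(tgt$reference)
  if (length(refassay) != 1)
    stop("target assay must name exactly one reference assay")
  ref <- records[records$assay == refassay, , drop = FALSE]
  if (!nrow(ref)) stop("missing reference assay ", refassay)
  mt <- tapply(tgt$ct, tgt$sample, mean)
  st <- tapply(tgt$ct, tgt$sample, function(z) if (length(z) > 1) sd(z) else 0)
  mr <- tapply(ref$ct, ref$sample, mean)
  sr <- tapply(ref$ct, ref$sample, function(z) if (length(z) > 1) sd(z) else 0)
  samples <- names(mt)
  if (!calibrator %in% samples) stop("calibrator sample not measured: ", calibrator)
  if (!all(samples %in% names(mr)))
    stop("reference assay missing for sample(s): ",
         paste(setdiff(samples, names(mr)), collapse = ", "))
  dct <- mt - mr[samples]
  ddct <- dct - dct[[calibrator]]
  data.frame(sample = samples, dct = unname(dct), ddct = unname(ddct),
             N = unname(2^(-ddct)),
             flag_sd = unname(st > sd_max | sr[samples] > sd_max),
             stringsAsFactors = FALSE, row.names = NULL)
}
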