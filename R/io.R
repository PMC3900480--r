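# Readers and writers for the formats the pipeline touches.  FASTA goes
# through Biostrings; FASTQ uses a strict 4-line-block parser so that
# truncated blocks and quality-length violations are reported with line
# numbers, which the lenient Biostrings reader does not do.

#' Read a FASTA file
#'
#' @param path file path.
#' @return data.frame with columns `id` and `seq`, in file order.  U and T
#'   are both accepted and preserved as read.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  nonempty <- which(nzchar(trimws(lines)))
  if (!length(nonempty))
    return(data.frame(id = character(0), seq = character(0),
                      stringsAsFactors = FALSE))
  if (!startsWith(lines[nonempty[1]], ">"))
    stop(sprintf("malformed FASTA: line %d does not start a record header",
                 nonempty[1]))
  set <- Biostrings::readBStringSet(path)
  data.frame(id = sub("\\s.*$", "", names(set)),
             seq = as.character(set), stringsAsFactors = FALSE,
             row.names = NULL)
}

#' Write a FASTA file
#'
#' @param records data.frame with columns `id` and `seq`.
#' @param path output path.
#' @export
write_fasta <- function(records, path) {
  set <- Biostrings::BStringSet(records$seq)
  names(set) <- records$id
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Read a FASTQ file
#'
#' Strict 4-line-block dialect: `@id`, sequence, `+`, quality.
#'
#' @param path file path (plain or gzipped).
#' @return data.frame with columns `id`, `seq`, `qual`.
#' @export
read_fastq <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  if (length(lines) && !nzchar(lines[length(lines)]))
    lines <- lines[-length(lines)]
  if (length(lines) %% 4 != 0)
    stop(sprintf("truncated FASTQ block starting at line %d",
                 4 * (length(lines) %/% 4) + 1))
  if (!length(lines))
    return(data.frame(id = character(0), seq = character(0),
                      qual = character(0), stringsAsFactors = FALSE))
  idx <- seq(1, length(lines), by = 4)
  bad <- idx[!startsWith(lines[idx], "@")]
  if (length(bad))
    stop(sprintf("malformed FASTQ: line %d does not start with '@'", bad[1]))
  badp <- idx[!startsWith(lines[idx + 2], "+")]
  if (length(badp))
    stop(sprintf("malformed FASTQ: line %d does not start with '+'",
                 badp[1] + 2))
  seqs <- lines[idx + 1]
  quals <- lines[idx + 3]
  badq <- which(nchar(seqs) != nchar(quals))
  if (length(badq))
    stop(sprintf("malformed FASTQ: quality length differs from sequence length at line %d",
                 idx[badq[1]] + 3))
  data.frame(id = sub("\\s.*$", "", substring(lines[idx], 2)),
             seq = seqs, qual = quals, stringsAsFactors = FALSE)
}

#' Write a FASTQ file
#'
#' @param records data.frame with columns `id`, `seq`, `qual`.
#' @param path output path.
#' @export
write_fastq <- function(records, path) {
  stopifnot(all(nchar(records$seq) == nchar(records$qual)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("@", records$id, "\n", records$seq, "\n+\n", records$qual),
             con)
  invisible(path)
}

#' Write unique reads as collapsed FASTA
#'
#' One record per unique insert with header `u<index>_x<count>`, the common
#' collapsed-FASTA dialect whose headers carry the occurrence count.
#'
#' @param unique_reads data.frame with columns `seq` and `count`.
#' @param path output path.
#' @export
write_collapsed_fasta <- function(unique_reads, path) {
  if (nrow(unique_reads) && any(unique_reads$count < 1))
    stop("collapsed FASTA requires counts >= 1")
  if (!nrow(unique_reads)) {
    file.create(path)
    return(invisible(path))
  }
  write_fasta(data.frame(
    id = sprintf("u%d_x%d", seq_len(nrow(unique_reads)), unique_reads$count),
    seq = unique_reads$seq), path)
}

#' Read collapsed FASTA back to (seq, count) pairs
#'
#' @param path file path.
#' @return data.frame with columns `seq` and `count`.
#' @export
read_collapsed_fasta <- function(path) {
  rec <- read_fasta(path)
  if (!nrow(rec))
    return(data.frame(seq = character(0), count = integer(0),
                      stringsAsFactors = FALSE))
  m <- regmatches(rec$id, regexec("_x(\\d+)$", rec$id))
  cnt <- vapply(m, function(g) if (length(g) == 2) as.integer(g[2]) else NA_integer_,
                integer(1))
  if (anyNA(cnt))
    stop("collapsed FASTA header lacks a _x<count> suffix: ",
         rec$id[which(is.na(cnt))[1]])
  data.frame(seq = rec$seq, count = cnt, stringsAsFactors = FALSE)
}

#' Write a count table as TSV
#'
#' @param counts matrix of non-negative counts, row names are feature ids,
#'   column names are library names.
#' @param path output path.
#' @export
write_count_table <- function(counts, path) {
  stopifnot(!is.null(rownames(counts)), !is.null(colnames(counts)))
  df <- data.frame(id = rownames(counts), counts, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a TSV count table
#'
#' @param path file path, first column feature ids, header row present.
#' @return integer matrix with row and column names.
#' @export
read_count_table <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                   stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  mode(m) <- "numeric"
  if (any(m < 0)) stop("count table contains negative values")
  rownames(m) <- df[[1]]
  m
}

#' Read a BED-like track file
#'
#' Columns: chrom, start, end, name, optional strand.  Coordinates are
#' interpreted as 0-based half-open, the arithmetic-friendly convention used
#' internally.
#'
#' @param path file path.
#' @return data.frame with columns `chrom`, `start`, `end`, `name`, `strand`.
#' @export
read_tracks <- function(path) {
  df <- read.table(path, sep = "\t", header = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 4) stop("track file needs at least 4 columns (chrom, start, end, name)")
  names(df)[1:4] <- c("chrom", "start", "end", "name")
  df$strand <- if (ncol(df) >= 5) df[[5]] else "+"
  if (any(df$end <= df$start)) stop("track file has empty or inverted intervals")
  df[, c("chrom", "start", "end", "name", "strand")]
}

#' Write a BED-like track file
#' @param tracks data.frame as returned by [read_tracks()].
#' @param path output path.
#' @export
write_tracks <- function(tracks, path) {
  write.table(tracks[, c("chrom", "start", "end", "name", "strand")], path,
              sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Path to a bundled example data file
#' @param file file name under the package's `extdata`; when missing, lists
#'   the available files.
#' @return file path.
#' @export
mirflow_example <- function(file = NULL) {
  d <- system.file("extdata", package = "mirflow")
  if (is.null(file)) return(list.files(d))
  f <- file.path(d, file)
  if (!file.exists(f)) stop("no such example file: ", file)
  f
}
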