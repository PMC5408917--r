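#' Load a cell's reads from FASTQ or FASTA
#'
#' Reads one file (single-end) or two mate files (paired-end) into a single
#' orientation-agnostic read set. The format is auto-detected from the first
#' character of each file (`@` FASTQ, `>` FASTA); gzip is transparent. Base
#' qualities are discarded and mates are treated as independent reads with
#' `/1` / `/2` id suffixes — assembly never uses pairing information, the
#' second mate simply contributes extra coverage. Reads with more than 20%
#' `N` are dropped (they can neither seed nor verify an overlap).
#'
#' @param paths Character vector of 1 or 2 file paths.
#' @param max_n_frac Maximum tolerated fraction of `N` per read.
#' @return A tibble with columns `id`, `seq`, `length`.
#' @export
read_cell_reads <- function(paths, max_n_frac = 0.2) {
  stopifnot(length(paths) %in% c(1L, 2L))
  sets <- lapply(paths, read_one_seqfile)
  if (length(sets) == 2L) {
    if (nrow(sets[[1]]) != nrow(sets[[2]]))
      abort(sprintf("mate files have unequal record counts (%d vs %d)",
                    nrow(sets[[1]]), nrow(sets[[2]])))
    sets[[1]]$id <- mate_suffix(sets[[1]]$id, "/1")
    sets[[2]]$id <- mate_suffix(sets[[2]]$id, "/2")
    # interleave so mates stay adjacent in the set
    o <- order(rep(seq_len(nrow(sets[[1]])), 2))
    reads <- bind_rows(sets)[o, ]
  } else {
    reads <- sets[[1]]
  }
  if (anyDuplicated(reads$id))
    abort("duplicate read ids after mate-suffix disambiguation")
  n_frac <- (nchar(reads$seq) - nchar(gsub("N", "", reads$seq, fixed = TRUE))) /
    pmax(1L, nchar(reads$seq))
  drop <- n_frac > max_n_frac | nchar(reads$seq) == 0L
  if (any(drop)) {
    inform(sprintf("dropped %d read(s) with > %d%% N", sum(drop),
                   round(100 * max_n_frac)))
    reads <- reads[!drop, ]
  }
  if (nrow(reads) == 0) abort("no reads")
  reads$length <- nchar(reads$seq)
  as_tibble(reads)
}

read_one_seqfile <- function(path) {
  con <- gzfile(path, "rt")
  first <- readLines(con, n = 1L)
  close(con)
  if (length(first) == 0) abort(sprintf("no reads: empty file %s", path))
  fmt <- if (startsWith(first, "@")) "fastq" else if (startsWith(first, ">")) "fasta"
         else abort(sprintf("cannot detect FASTA/FASTQ format of %s", path))
  ss <- Biostrings::readBStringSet(path, format = fmt)
  if (length(ss) == 0) abort(sprintf("no reads in %s", path))
  tibble(id = sub("\\s.*$", "", names(ss)),
         seq = unname(toupper(as.character(ss))))
}

mate_suffix <- function(id, suf) {
  ifelse(endsWith(id, suf), id, paste0(sub("/[12]$", "", id), suf))
}

#' Summary statistics of a read set
#'
#' @param reads Read tibble from [read_cell_reads()] or the simulator.
#' @return One-row tibble: read count, min/median/max length, total bases.
#' @export
read_stats <- function(reads) {
  tibble(n_reads = nrow(reads),
         min_len = min(nchar(reads$seq)),
         median_len = stats::median(nchar(reads$seq)),
         max_len = max(nchar(reads$seq)),
         total_bases = sum(nchar(reads$seq)))
}
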