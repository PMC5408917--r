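#' Build the suffix-prefix overlap index of a read set
#'
#' Two sequences overlap when the prefix of one equals the suffix of the
#' other, in either orientation. To answer "which reads overlap the 3' end
#' of the growing contig" quickly, each read contributes two entries keyed by
#' its first `m` bases: one for its forward sequence and one for its reverse
#' complement. Reads shorter than `m` cannot form a valid overlap and are
#' skipped. Overlaps shorter than 10 bp are too unreliable to seed
#' extension, so `m < 10` is rejected.
#'
#' @param reads Read tibble (`id`, `seq`).
#' @param m Minimum overlap length in bp (default 20, under half a 50 bp
#'   read).
#' @return An `overlap_index` object.
#' @export
overlap_index <- function(reads, m = 20L) {
  m <- as.integer(m)
  if (m < 10L) abort("minimum overlap m must be >= 10")
  keep <- nchar(reads$seq) >= m
  ids <- reads$id[keep]
  fseq <- reads$seq[keep]
  rseq <- revcomp(fseq)
  eid <- c(ids, ids)
  eseq <- c(fseq, rseq)
  eori <- rep(c("forward", "revcomp"), each = length(ids))
  elen <- nchar(eseq)
  keys <- substr(eseq, 1L, m)
  env <- list2env(split(seq_along(keys), keys), hash = TRUE,
                  size = max(1L, length(keys)))
  structure(
    list(m = m, env = env, eid = eid, eseq = eseq, eori = eori, elen = elen,
         max_olen = if (length(elen)) max(elen) - 1L else 0L,
         n_reads = length(ids)),
    class = "overlap_index"
  )
}

#' @export
print.overlap_index <- function(x, ...) {
  cat(sprintf("<overlap_index> %d reads indexed, m = %d\n", x$n_reads, x$m))
  invisible(x)
}

#' Extend a sequence in the 3' direction through read overlaps
#'
#' Greedy one-read-at-a-time extension. At each step, candidate reads are
#' those whose oriented prefix matches the contig 3' end over a proper
#' suffix-prefix overlap of at least `m` bases (the prefix map is probed at
#' every candidate overlap length, longest first, and the full overlap is
#' verified exactly). Among candidates the read with the longest overlap
#' wins (the most conservative extension); ties break to the shortest
#' appended suffix, then the lexicographically smallest oriented sequence,
#' then the smallest read id, so extension is fully deterministic. A read
#' whose entire sequence already lies inside the contig (empty appended
#' suffix) is not a candidate. Extension stops when no read overlaps
#' (`no_overlap`), when the winning read was already incorporated in this
#' pass — the signature of a repeat being re-entered (`repeat`) — or when the
#' contig exceeds `max_len` (`max_length`).
#'
#' @param seed Seed sequence (the anchor window or a partial contig); at
#'   least `m` bases.
#' @param index An [overlap_index()].
#' @param used Character vector of read ids already incorporated in this
#'   extension pass.
#' @param max_len Maximum contig length (default 1500 bp, roughly a
#'   full-length chain transcript; guards runaway extension through
#'   constant-region repeats).
#' @return A list: `seq` (extended sequence), `steps` (tibble of
#'   incorporated reads: `read_id`, `orientation`, `overlap`, `appended`,
#'   `direction`), `stop` (one of `"no_overlap"`, `"repeat"`,
#'   `"max_length"`), `used` (updated id set).
#' @export
extend_3prime <- function(seed, index, used = character(), max_len = 1500L) {
  m <- index$m
  if (nchar(seed) < m) abort("seed is shorter than the minimum overlap m")
  contig <- seed
  steps <- list()
  reason <- NULL
  repeat {
    clen <- nchar(contig)
    if (clen > max_len) { reason <- "max_length"; break }
    best <- find_best_overlap(contig, clen, index)
    if (is.null(best)) { reason <- "no_overlap"; break }
    id <- index$eid[best$ent]
    if (id %in% used) { reason <- "repeat"; break }
    os <- index$eseq[best$ent]
    appended <- substr(os, best$ov + 1L, nchar(os))
    contig <- paste0(contig, appended)
    used <- c(used, id)
    steps[[length(steps) + 1L]] <- list(
      read_id = id, orientation = index$eori[best$ent],
      overlap = best$ov, appended = nchar(appended), direction = "3prime")
  }
  list(seq = contig, steps = steps_tbl(steps), stop = reason, used = used)
}

# Longest proper suffix-prefix overlap between the contig 3' end and any
# indexed read: probe the m-prefix map at each overlap length, descending.
find_best_overlap <- function(contig, clen, index) {
  m <- index$m
  hi <- min(clen, index$max_olen)
  if (hi < m) return(NULL)
  for (ov in hi:m) {
    ent <- index$env[[substr(contig, clen - ov + 1L, clen - ov + m)]]
    if (is.null(ent)) next
    ent <- ent[index$elen[ent] > ov]
    if (length(ent) == 0L) next
    if (ov > m) {
      tail_ <- substr(contig, clen - ov + 1L, clen)
      ent <- ent[substr(index$eseq[ent], 1L, ov) == tail_]
      if (length(ent) == 0L) next
    }
    o <- order(index$elen[ent], index$eseq[ent], index$eid[ent])
    return(list(ent = ent[o[1L]], ov = ov))
  }
  NULL
}

steps_tbl <- function(steps) {
  if (length(steps) == 0) {
    return(tibble(read_id = character(), orientation = character(),
                  overlap = integer(), appended = integer(),
                  direction = character()))
  }
  bind_rows(lapply(steps, as_tibble))
}

#' Extend a sequence in the 5' direction
#'
#' The mirror image of [extend_3prime()]: implemented by reverse-
#' complementing the seed, extending 3', and re-complementing the result.
#' Step records are re-expressed relative to the forward contig (direction
#' `"5prime"`, orientations flipped), so replaying them by prepending each
#' read's non-overlapping prefix reproduces the contig.
#'
#' @inheritParams extend_3prime
#' @return Same shape as [extend_3prime()].
#' @export
extend_5prime <- function(seed, index, used = character(), max_len = 1500L) {
  r <- extend_3prime(revcomp(seed), index, used = used, max_len = max_len)
  steps <- r$steps
  if (nrow(steps) > 0) {
    steps$orientation <- ifelse(steps$orientation == "forward",
                                "revcomp", "forward")
    steps$direction <- "5prime"
  }
  list(seq = revcomp(r$seq), steps = steps, stop = r$stop, used = r$used)
}
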