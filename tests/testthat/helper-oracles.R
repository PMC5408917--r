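# Independent brute-force oracles. These deliberately share no code with the
# package's indexed implementations: they enumerate every possibility
# directly, so agreement is evidence, not tautology.

oracle_rc <- function(s) {
  map <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  paste(rev(map[strsplit(s, "")[[1]]]), collapse = "")
}

rdna <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# All k-mers (with offsets) of a set of sequences, by direct enumeration.
oracle_kmers <- function(seqs, names, k) {
  out <- list()
  for (i in seq_along(seqs)) {
    L <- nchar(seqs[i])
    for (s in seq_len(max(0L, L - k + 1L))) {
      km <- substr(seqs[i], s, s + k - 1L)
      if (grepl("N", km, fixed = TRUE)) next
      out[[length(out) + 1L]] <- data.frame(kmer = km, name = names[i],
                                            offset = s - 1L)
    }
  }
  do.call(rbind, out)
}

# Brute-force read placement: Hamming-scan the read (both orientations)
# against every germline diagonal; emit spans overlapping by >= min_span
# with <= max_mm mismatches.
oracle_place <- function(read, germ_names, germ_seqs, max_mm, min_span) {
  out <- list()
  rlen <- nchar(read)
  for (ori in c("forward", "revcomp")) {
    rs <- if (ori == "forward") read else oracle_rc(read)
    rv <- strsplit(rs, "")[[1]]
    for (gi in seq_along(germ_seqs)) {
      gv <- strsplit(germ_seqs[gi], "")[[1]]
      L <- length(gv)
      for (diag0 in (-(rlen - 1L)):(L - 1L)) {
        lo <- max(0L, diag0); hi <- min(L, diag0 + rlen)
        if (hi - lo < min_span) next
        mm <- sum(rv[(lo - diag0 + 1L):(hi - diag0)] != gv[(lo + 1L):hi])
        if (mm <= max_mm) {
          out[[length(out) + 1L]] <- data.frame(
            germline = germ_names[gi], start = lo, end = hi,
            orientation = ori, mismatches = mm)
        }
      }
    }
  }
  if (length(out) == 0) return(NULL)
  do.call(rbind, out)
}

# Exhaustive (gene, window-start) support enumeration: count placements
# whose span intersects each window by >= 1 bp; return the maximum support.
oracle_best_support <- function(placements, germ_names, germ_lens, w) {
  best <- 0L
  for (gi in seq_along(germ_names)) {
    L <- germ_lens[gi]
    if (L < w) next
    pl <- placements[placements$germline == germ_names[gi], , drop = FALSE]
    for (t in 0:(L - w)) {
      supp <- sum(pl$start < t + w & pl$end > t)
      if (supp > best) best <- supp
    }
  }
  best
}

# Naive greedy extension with no index: scan every read in both orientations
# for the longest proper suffix-prefix overlap with the contig end.
# `side = "3prime"` appends, `side = "5prime"` prepends.
oracle_extend <- function(seed, reads, m, max_len = 1500L, side = "3prime") {
  contig <- seed
  used <- character()
  repeat {
    if (nchar(contig) > max_len) break
    cand <- NULL
    for (i in seq_len(nrow(reads))) {
      for (ori in c("forward", "revcomp")) {
        os <- if (ori == "forward") reads$seq[i] else oracle_rc(reads$seq[i])
        rlen <- nchar(os)
        if (rlen <= m) next
        best_ov <- NA
        for (ov in min(rlen - 1L, nchar(contig)):m) {
          hit <- if (side == "3prime") {
            substr(contig, nchar(contig) - ov + 1L, nchar(contig)) ==
              substr(os, 1L, ov)
          } else {
            substr(contig, 1L, ov) == substr(os, rlen - ov + 1L, rlen)
          }
          if (hit) { best_ov <- ov; break }
        }
        if (is.na(best_ov)) next
        cand <- rbind(cand, data.frame(id = reads$id[i], os = os,
                                       ov = best_ov, rlen = rlen))
      }
    }
    if (is.null(cand)) break
    cand <- cand[order(-cand$ov, cand$rlen, cand$os, cand$id), , drop = FALSE]
    best <- cand[1, ]
    if (best$id %in% used) break
    contig <- if (side == "3prime") {
      paste0(contig, substr(best$os, best$ov + 1L, best$rlen))
    } else {
      paste0(substr(best$os, 1L, best$rlen - best$ov), contig)
    }
    used <- c(used, best$id)
  }
  contig
}

# Replay recorded extension steps from the anchor window (independent of the
# extender: uses only the step log and the raw reads).
replay_steps <- function(anchor_window, steps, reads) {
  seq_of <- setNames(reads$seq, reads$id)
  contig <- anchor_window
  for (i in seq_len(nrow(steps))) {
    os <- seq_of[[steps$read_id[i]]]
    if (steps$orientation[i] == "revcomp") os <- oracle_rc(os)
    ov <- steps$overlap[i]
    contig <- if (steps$direction[i] == "3prime") {
      stopifnot(substr(contig, nchar(contig) - ov + 1L, nchar(contig)) ==
                  substr(os, 1L, ov))
      paste0(contig, substr(os, ov + 1L, nchar(os)))
    } else {
      stopifnot(substr(contig, 1L, ov) ==
                  substr(os, nchar(os) - ov + 1L, nchar(os)))
      paste0(substr(os, 1L, nchar(os) - ov), contig)
    }
  }
  contig
}

# Small shared fixtures -------------------------------------------------

toy_db <- function() {
  if (is.null(.toy_cache$db)) .toy_cache$db <- sim_germline_db(seed = 101)
  .toy_cache$db
}
.toy_cache <- new.env()

write_tmp_fasta <- function(recs, path = tempfile(fileext = ".fasta")) {
  writeLines(as.vector(rbind(paste0(">", names(recs)), unname(recs))), path)
  path
}

write_tmp_fastq <- function(ids, seqs, path = tempfile(fileext = ".fastq")) {
  writeLines(as.vector(rbind(paste0("@", ids), seqs, "+",
                             strrep("I", nchar(seqs)))), path)
  path
}

# Error-free reads tiling a transcript with a fixed start step (gap between
# adjacent starts = `step`), alternating strands.
tiling_reads <- function(transcript, read_len = 50L, step = 10L) {
  starts <- seq(1L, nchar(transcript) - read_len + 1L, by = step)
  if (starts[length(starts)] != nchar(transcript) - read_len + 1L)
    starts <- c(starts, nchar(transcript) - read_len + 1L)
  seqs <- substring(transcript, starts, starts + read_len - 1L)
  flip <- seq_along(seqs) %% 2L == 0L
  seqs[flip] <- vapply(seqs[flip], oracle_rc, character(1))
  tibble::tibble(id = sprintf("t%04d", seq_along(seqs)), seq = seqs)
}
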