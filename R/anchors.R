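#' Map reads to one germline component by k-mer seed and verify
#'
#' Stage 1 mapping. Each read is scanned in both orientations: every k-mer of
#' the read is looked up in the component index, and hits vote for a
#' (germline, diagonal) placement. Each candidate placement is then verified
#' by Hamming comparison over the span where read and germline overlap
#' (reads may overhang germline ends; at least `min_span` bases must
#' overlap). Placements with at most `max_mismatches` substitutions are
#' returned; a read may place on several germlines. Indels are not modelled:
#' anchors only need approximate location, and the verification tolerance
#' absorbs somatic hypermutation and sequencing error.
#'
#' @param reads Read tibble (`id`, `seq`).
#' @param db A [germline_db()].
#' @param component One of `"IGHV"`, `"IGHC"`, `"IGKLV"`, `"IGKLC"`.
#' @param max_mismatches Maximum substitutions in the overlapping span
#'   (default 3, tuned for 50 bp reads with hypermutation).
#' @param min_span Minimum read/germline overlap in bp (default: the index k).
#' @return Tibble of placements: `read_id`, `component`, `germline`,
#'   `start`, `end` (0-based half-open aligned span on the germline),
#'   `orientation` (`"forward"`/`"revcomp"`), `mismatches`.
#' @export
map_reads_component <- function(reads, db, component, max_mismatches = 3L,
                                min_span = NULL) {
  component <- match.arg(component, ASSEMBLY_COMPONENTS)
  idx <- db$index[[component]]
  germ <- db_component(db, component)
  gseq <- setNames(germ$seq, germ$name)
  glen <- setNames(germ$length, germ$name)
  if (is.null(min_span)) min_span <- idx$k
  k <- idx$k

  out <- vector("list", 2L)
  oris <- c(forward = 1L, revcomp = 2L)
  seqs_by_ori <- list(forward = reads$seq, revcomp = revcomp(reads$seq))
  for (ori in names(oris)) {
    seqs <- seqs_by_ori[[ori]]
    rlen <- nchar(seqs)
    maxp <- max(rlen) - k + 1L
    if (maxp < 1L) next
    hit_list <- vector("list", maxp)
    for (p in seq_len(maxp)) {
      sel <- which(rlen >= p + k - 1L)
      if (length(sel) == 0) next
      kid <- match(substring(seqs[sel], p, p + k - 1L), idx$keys)
      ok <- !is.na(kid)
      if (!any(ok)) next
      hit_list[[p]] <- tibble(row = sel[ok], p = p, kmer_id = kid[ok])
    }
    hits <- bind_rows(hit_list)
    if (nrow(hits) == 0) next
    cand <- inner_join(hits, idx$post, by = "kmer_id",
                       relationship = "many-to-many")
    cand$diag0 <- cand$offset - (cand$p - 1L)
    cand <- distinct(cand, .data$row, .data$name, .data$diag0)

    # verify each (read, germline, diagonal) over the intersecting span
    L <- unname(glen[cand$name])
    rl <- rlen[cand$row]
    lo <- pmax(0L, cand$diag0)
    hi <- pmin(L, cand$diag0 + rl)
    keep <- (hi - lo) >= min_span
    cand <- cand[keep, ]; lo <- lo[keep]; hi <- hi[keep]
    if (nrow(cand) == 0) next
    rsub <- substring(seqs[cand$row], lo - cand$diag0 + 1L, hi - cand$diag0)
    gsub_ <- substring(gseq[cand$name], lo + 1L, hi)
    mm <- vapply(seq_len(nrow(cand)),
                 function(i) hamming(rsub[i], gsub_[i]), integer(1))
    pass <- mm <= max_mismatches
    if (!any(pass)) next
    out[[oris[[ori]]]] <- tibble(
      read_id = reads$id[cand$row[pass]],
      component = component,
      germline = cand$name[pass],
      start = lo[pass], end = hi[pass],
      orientation = ori,
      mismatches = mm[pass]
    )
  }
  res <- bind_rows(out)
  if (nrow(res) == 0) {
    res <- tibble(read_id = character(), component = character(),
                  germline = character(), start = integer(), end = integer(),
                  orientation = character(), mismatches = integer())
  }
  res
}

#' Select the anchor window of one component
#'
#' Scans every window of length `w` on every germline of the component and
#' counts the placements whose aligned span intersects the window by at
#' least 1 bp. The (germline, start) pair with maximal support becomes the
#' anchor; ties break to the lexicographically smallest germline name, then
#' the smallest start, so selection is deterministic. Returns no anchor when
#' the best support is below `min_support` — a guard against spurious
#' single-read anchors.
#'
#' @param placements Tibble from [map_reads_component()].
#' @param germlines Gene tibble of the same component.
#' @param w Window length in bp (default 50, one read length).
#' @param min_support Minimum supporting placements (default 3).
#' @return One-row tibble (`component`, `germline`, `start`, `window`,
#'   `support`) or `NULL` when no window qualifies.
#' @export
select_anchor_window <- function(placements, germlines, w = 50L,
                                 min_support = 3L) {
  w <- as.integer(w)
  best <- NULL
  for (gi in order(germlines$name)) {
    g <- germlines$name[gi]
    L <- germlines$length[gi]
    if (L < w) next
    nw <- L - w + 1L
    pl <- placements[placements$germline == g, ]
    if (nrow(pl) == 0) next
    d <- integer(nw + 1L)
    t_lo <- pmax(0L, pl$start - w + 1L)
    t_hi <- pmin(L - w, pl$end - 1L)
    ok <- t_lo <= t_hi
    for (i in which(ok)) {
      d[t_lo[i] + 1L] <- d[t_lo[i] + 1L] + 1L
      d[t_hi[i] + 2L] <- d[t_hi[i] + 2L] - 1L
    }
    counts <- cumsum(d[seq_len(nw)])
    m <- max(counts)
    if (is.null(best) || m > best$support) {
      s <- which.max(counts) - 1L
      best <- tibble(component = germlines$component[1], germline = g,
                     start = s,
                     window = substr(germlines$seq[gi], s + 1L, s + w),
                     support = m)
    }
  }
  if (is.null(best) || best$support < min_support) return(NULL)
  best
}

#' Find the four assembly anchors of a cell
#'
#' Runs mapping and window selection for each of the four components and
#' reports the anchors found. Per-component support is logged. A cell whose
#' reads anchor none of the four components carries no immunoglobulin
#' signal, which is a hard error.
#'
#' @param reads Read tibble.
#' @param db A [germline_db()].
#' @param w Anchor window length (bp).
#' @param max_mismatches Mapping mismatch tolerance.
#' @param min_anchor_support Minimum reads supporting a window.
#' @param quiet Suppress per-component log messages.
#' @return Tibble with one row per anchored component (0 rows never
#'   returned: all-absent is an error).
#' @examples
#' db <- sim_germline_db(seed = 1)
#' cell <- sim_cell(db, seed = 7)
#' find_anchors(cell$reads, db)
#' @export
find_anchors <- function(reads, db, w = 50L, max_mismatches = 3L,
                         min_anchor_support = 3L, quiet = FALSE) {
  rows <- list()
  for (comp in ASSEMBLY_COMPONENTS) {
    pl <- map_reads_component(reads, db, comp, max_mismatches = max_mismatches)
    a <- select_anchor_window(pl, db_component(db, comp), w = w,
                              min_support = min_anchor_support)
    if (!quiet) {
      if (is.null(a)) inform(sprintf("%-6s: no anchor (support < %d)",
                                     comp, min_anchor_support))
      else inform(sprintf("%-6s: anchor %s:%d, support %d", comp,
                          a$germline, a$start, a$support))
    }
    rows[[comp]] <- a
  }
  anchors <- bind_rows(rows)
  if (nrow(anchors) == 0)
    abort("no immunoglobulin signal in reads: no component could be anchored",
          class = "bcrasm_no_signal")
  anchors
}
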