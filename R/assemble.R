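#' Assemble one chain from its variable and constant anchors
#'
#' Each anchor present is extended 3' then 5' with its own used-read set
#' (the two anchors extend independently: the reporting rule below implies
#' two potentially complete sequences). When both contigs exist they are
#' stitched into a single chain sequence if one contains the other or if
#' they share an exact suffix-prefix overlap of at least `m` bases
#' (`status = "merged"`); otherwise both are reported separately
#' (`status = "split"`). A single anchor yields `status = "partial"`, no
#' anchor `status = "absent"`.
#'
#' @param anchor_v,anchor_c One-row anchor tibbles from [find_anchors()]
#'   (or `NULL` when the component had no anchor).
#' @param index An [overlap_index()] over the cell's reads.
#' @param chain `"heavy"` or `"light"` (label only).
#' @param max_len Maximum contig length passed to the extenders.
#' @return A `chain_assembly` object: `chain`, `status`, `seq` (merged
#'   sequence or `NULL`), `contig_v`, `contig_c` (each `NULL` or a list
#'   with `seq`, `anchor`, `steps`, `stop3`, `stop5`).
#' @export
assemble_chain <- function(anchor_v, anchor_c, index, chain = "heavy",
                           max_len = 1500L) {
  grow <- function(anchor) {
    if (is.null(anchor) || nrow(anchor) == 0) return(NULL)
    e3 <- extend_3prime(anchor$window, index, used = character(),
                        max_len = max_len)
    e5 <- extend_5prime(e3$seq, index, used = e3$used, max_len = max_len)
    list(seq = e5$seq, anchor = anchor,
         steps = bind_rows(e3$steps, e5$steps),
         stop3 = e3$stop, stop5 = e5$stop)
  }
  cv <- grow(anchor_v)
  cc <- grow(anchor_c)
  if (is.null(cv) && is.null(cc)) {
    status <- "absent"; seq <- NULL
  } else if (is.null(cv) || is.null(cc)) {
    status <- "partial"; seq <- NULL
  } else {
    seq <- merge_contigs(cv$seq, cc$seq, index$m)
    status <- if (is.null(seq)) "split" else "merged"
  }
  structure(list(chain = chain, status = status, seq = seq,
                 contig_v = cv, contig_c = cc),
            class = "chain_assembly")
}

# Stitch the variable- and constant-anchored contigs: containment, or an
# exact suffix(V)-prefix(C) overlap of >= m bases (the variable region lies
# 5' of the constant region on the transcript).
merge_contigs <- function(vseq, cseq, m) {
  if (grepl(vseq, cseq, fixed = TRUE)) return(cseq)
  if (grepl(cseq, vseq, fixed = TRUE)) return(vseq)
  nv <- nchar(vseq); nc <- nchar(cseq)
  for (ov in min(nv, nc):m) {
    if (substr(vseq, nv - ov + 1L, nv) == substr(cseq, 1L, ov))
      return(paste0(vseq, substr(cseq, ov + 1L, nc)))
  }
  NULL
}

#' @export
print.chain_assembly <- function(x, ...) {
  cat(sprintf("<chain_assembly> %s chain, status %s", x$chain, x$status))
  if (!is.null(x$seq)) cat(sprintf(", %d bp", nchar(x$seq)))
  cat("\n")
  invisible(x)
}

#' Assemble the heavy and light chains of one cell
#'
#' The end-to-end per-cell assembly: anchor discovery on the four germline
#' components, overlap indexing of the reads, then independent assembly of
#' the heavy chain (IGHV/IGHC anchors) and the light chain (IGKLV/IGKLC
#' anchors). The two chains never share state, so the result is identical
#' regardless of execution order, and reruns on the same input are
#' byte-identical (assembly uses no randomness).
#'
#' @param reads Read tibble (`id`, `seq`), e.g. from [read_cell_reads()] or
#'   [sim_cell()].
#' @param db A [germline_db()].
#' @param w Anchor window length (bp).
#' @param m Minimum read overlap (bp).
#' @param max_mismatches Mapping mismatch tolerance.
#' @param min_anchor_support Minimum reads supporting an anchor window.
#' @param max_len Maximum contig length (bp).
#' @param quiet Suppress progress messages.
#' @return A `bcr_assembly` object with elements `heavy` and `light`
#'   (each a `chain_assembly`), `anchors`, and the parameters used.
#'   Summarise with [tidy()] / [glance()], plot with [autoplot()].
#' @examples
#' db <- sim_germline_db(seed = 1)
#' cell <- sim_cell(db, seed = 7)
#' asm <- assemble_cell(cell$reads, db, quiet = TRUE)
#' tidy(asm)
#' @export
assemble_cell <- function(reads, db, w = 50L, m = 20L, max_mismatches = 3L,
                          min_anchor_support = 3L, max_len = 1500L,
                          quiet = FALSE) {
  anchors <- find_anchors(reads, db, w = w, max_mismatches = max_mismatches,
                          min_anchor_support = min_anchor_support,
                          quiet = quiet)
  idx <- overlap_index(reads, m = m)
  pick <- function(comp) {
    a <- anchors[anchors$component == comp, ]
    if (nrow(a) == 0) NULL else a
  }
  res <- structure(
    list(heavy = assemble_chain(pick("IGHV"), pick("IGHC"), idx,
                                chain = "heavy", max_len = max_len),
         light = assemble_chain(pick("IGKLV"), pick("IGKLC"), idx,
                                chain = "light", max_len = max_len),
         anchors = anchors,
         params = list(w = w, m = m, max_mismatches = max_mismatches,
                       min_anchor_support = min_anchor_support,
                       max_len = max_len)),
    class = "bcr_assembly")
  if (!quiet) {
    inform(sprintf("heavy: %s; light: %s",
                   res$heavy$status, res$light$status))
  }
  res
}

#' @export
print.bcr_assembly <- function(x, ...) {
  cat("<bcr_assembly>\n")
  print(x$heavy); print(x$light)
  invisible(x)
}

#' Tidy summary of an assembly
#'
#' One row per chain: status, sequence lengths, anchor genes and supports,
#' stop reasons and the number of reads incorporated.
#'
#' @param x A `bcr_assembly`.
#' @param ... Unused.
#' @method tidy bcr_assembly
#' @export
tidy.bcr_assembly <- function(x, ...) {
  chain_row <- function(ca) {
    info <- function(ct, f) if (is.null(ct)) NA else f(ct)
    tibble(
      chain = ca$chain, status = ca$status,
      merged_len = if (is.null(ca$seq)) NA_integer_ else nchar(ca$seq),
      v_len = info(ca$contig_v, function(c) nchar(c$seq)),
      c_len = info(ca$contig_c, function(c) nchar(c$seq)),
      v_anchor = info(ca$contig_v, function(c) c$anchor$germline),
      c_anchor = info(ca$contig_c, function(c) c$anchor$germline),
      v_support = info(ca$contig_v, function(c) c$anchor$support),
      c_support = info(ca$contig_c, function(c) c$anchor$support),
      v_stop = info(ca$contig_v, function(c) paste(c$stop5, c$stop3, sep = "/")),
      c_stop = info(ca$contig_c, function(c) paste(c$stop5, c$stop3, sep = "/")),
      n_reads_used = sum(info(ca$contig_v, function(c) nrow(c$steps)),
                         info(ca$contig_c, function(c) nrow(c$steps)),
                         na.rm = TRUE)
    )
  }
  bind_rows(chain_row(x$heavy), chain_row(x$light))
}

#' One-line summary of an assembly
#' @param x A `bcr_assembly`.
#' @param ... Unused.
#' @method glance bcr_assembly
#' @export
glance.bcr_assembly <- function(x, ...) {
  tibble(heavy_status = x$heavy$status, light_status = x$light$status,
         n_anchors = nrow(x$anchors),
         heavy_len = if (is.null(x$heavy$seq)) NA_integer_ else nchar(x$heavy$seq),
         light_len = if (is.null(x$light$seq)) NA_integer_ else nchar(x$light$seq))
}

#' Plot the layout of an assembly
#'
#' Horizontal bars for each assembled sequence with the anchor windows
#' overlaid, one panel per chain. Coordinates are contig-local (bp).
#'
#' @param object A `bcr_assembly`.
#' @param ... Unused.
#' @method autoplot bcr_assembly
#' @export
autoplot.bcr_assembly <- function(object, ...) {
  rows <- list()
  for (ca in list(object$heavy, object$light)) {
    y <- 0
    for (side in c("contig_v", "contig_c")) {
      ct <- ca[[side]]
      if (is.null(ct)) next
      y <- y + 1
      lab <- if (side == "contig_v") "variable contig" else "constant contig"
      apos <- regexpr(ct$anchor$window, ct$seq, fixed = TRUE)
      rows[[length(rows) + 1L]] <- tibble(
        chain = ca$chain, piece = lab, y = y,
        xmin = 0, xmax = nchar(ct$seq),
        amin = as.integer(apos) - 1L,
        amax = as.integer(apos) - 1L + nchar(ct$anchor$window))
    }
    if (!is.null(ca$seq)) {
      rows[[length(rows) + 1L]] <- tibble(
        chain = ca$chain, piece = "merged", y = 0,
        xmin = 0, xmax = nchar(ca$seq), amin = NA_integer_, amax = NA_integer_)
    }
  }
  d <- bind_rows(rows)
  if (nrow(d) == 0) abort("nothing to plot: both chains absent")
  ggplot2::ggplot(d) +
    ggplot2::geom_rect(ggplot2::aes(xmin = .data$xmin, xmax = .data$xmax,
                                    ymin = .data$y - 0.3, ymax = .data$y + 0.3,
                                    fill = .data$piece)) +
    ggplot2::geom_rect(
      data = d[!is.na(d$amin), ],
      ggplot2::aes(xmin = .data$amin, xmax = .data$amax,
                   ymin = .data$y - 0.3, ymax = .data$y + 0.3),
      fill = "black", alpha = 0.35) +
    ggplot2::facet_wrap(~chain, ncol = 1) +
    ggplot2::scale_y_continuous(breaks = NULL) +
    ggplot2::labs(x = "position (bp)", y = NULL, fill = NULL,
                  title = "assembled chains (anchor windows shaded)")
}

#' Write assembled sequences to FASTA
#'
#' Merged chains are written as `<cell>_<chain>_merged`; split or partial
#' chains as `<cell>_<chain>_variable` / `<cell>_<chain>_constant`.
#'
#' @param asm A `bcr_assembly`.
#' @param cell_id Cell identifier used in record names.
#' @param path Output FASTA path.
#' @return The path, invisibly.
#' @export
write_assembly_fasta <- function(asm, cell_id, path) {
  recs <- character()
  for (ca in list(asm$heavy, asm$light)) {
    if (ca$status == "merged") {
      recs[sprintf("%s_%s_merged", cell_id, ca$chain)] <- ca$seq
    } else {
      if (!is.null(ca$contig_v))
        recs[sprintf("%s_%s_variable", cell_id, ca$chain)] <- ca$contig_v$seq
      if (!is.null(ca$contig_c))
        recs[sprintf("%s_%s_constant", cell_id, ca$chain)] <- ca$contig_c$seq
    }
  }
  write_fasta(tibble(name = names(recs), seq = unname(recs)), path)
}
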