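#' Score an assembly against simulator ground truth
#'
#' Per chain: assembly status, whether an assembled sequence contains the
#' full true transcript (`truth_contained`: merged sequence preferred, any
#' contig otherwise), whether any contig contains enough signal to recover
#' the true V gene, and correctness of the V/J/C gene calls.
#'
#' @param asm A `bcr_assembly`.
#' @param truth Truth tibble for the same cell (rows per chain, as from
#'   [sim_cell()]).
#' @param calls Call tibble from [annotate_assembly()]; computed here when
#'   omitted and `db` is given.
#' @param db A [germline_db()] (only needed to compute `calls`).
#' @return Tibble, one row per truth chain: `cell_id`, `chain`, `status`,
#'   `truth_contained`, `v_correct`, `j_correct`, `c_correct`.
#' @export
evaluate_assembly <- function(asm, truth, calls = NULL, db = NULL) {
  if (is.null(calls)) {
    if (is.null(db)) abort("supply either `calls` or `db`")
    calls <- annotate_assembly(asm, db)
  }
  rows <- lapply(seq_len(nrow(truth)), function(i) {
    ch <- truth$chain[i]
    ca <- asm[[ch]]
    seqs <- c(if (!is.null(ca$seq)) ca$seq,
              if (!is.null(ca$contig_v)) ca$contig_v$seq,
              if (!is.null(ca$contig_c)) ca$contig_c$seq)
    contained <- length(seqs) > 0 &&
      any(vapply(seqs, grepl, logical(1), x = truth$post_seq[i],
                 fixed = TRUE) |
            vapply(seqs, function(s) grepl(truth$post_seq[i], s, fixed = TRUE),
                   logical(1)))
    seg_ok <- function(seg, true_gene) {
      g <- calls$gene[calls$chain == ch & calls$segment == seg]
      if (is.na(true_gene) || length(g) == 0) return(NA)
      g[1] == true_gene
    }
    tibble(cell_id = truth$cell_id[i], chain = ch, status = ca$status,
           truth_contained = contained,
           v_correct = seg_ok("V", truth$v_gene[i]),
           j_correct = seg_ok("J", truth$j_gene[i]),
           c_correct = seg_ok("C", truth$c_gene[i]))
  })
  bind_rows(rows)
}

#' Assemble, annotate and score a cohort of simulated cells
#'
#' Convenience loop over [sim_cells()] output: assembles every cell,
#' annotates it, and scores it against truth. Cells whose reads carry no
#' anchorable immunoglobulin signal are reported with status
#' `"no_signal"` rather than aborting the cohort.
#'
#' @param cohort List from [sim_cells()].
#' @param db A [germline_db()].
#' @param ... Assembly tunables passed to [assemble_cell()].
#' @return Tibble with one row per simulated chain.
#' @export
evaluate_cohort <- function(cohort, db, ...) {
  rows <- lapply(names(cohort$cells), function(cid) {
    truth <- cohort$truth[cohort$truth$cell_id == cid, ]
    asm <- tryCatch(
      assemble_cell(cohort$cells[[cid]], db, quiet = TRUE, ...),
      bcrasm_no_signal = function(e) NULL)
    if (is.null(asm)) {
      return(tibble(cell_id = cid, chain = truth$chain, status = "no_signal",
                    truth_contained = FALSE, v_correct = FALSE,
                    j_correct = FALSE, c_correct = FALSE))
    }
    evaluate_assembly(asm, truth, db = db)
  })
  bind_rows(rows)
}
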