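#' Generate a synthetic toy germline reference set
#'
#' Builds a small self-contained germline database for simulation and
#' testing: uniform-random gene segments with IMGT-like names carrying a
#' `-syn` suffix to make clear they are synthetic, NOT real human alleles.
#' Defaults approximate real segment scales: ~300 bp V genes, ~16 bp D,
#' ~50 bp J, and constant regions truncated to ~300 bp (assembly only ever
#' needs the constant-region prefix adjacent to the junction). Light-chain
#' kappa and lambda genes are pooled into the IGK/LV and IGK/LC components,
#' as the anchor competition expects.
#'
#' @param seed Integer seed; the set is fully determined by it.
#' @param n_v Variable genes per locus (heavy; and per light locus).
#' @param v_len,d_len,j_len,c_len Segment lengths in bp.
#' @param k Seed k-mer length for the component indices.
#' @return A [germline_db()] including J and D sets.
#' @export
sim_germline_db <- function(seed = 101L, n_v = 6L, v_len = 300L, d_len = 16L,
                            j_len = 50L, c_len = 300L, k = 16L) {
  with_seed(seed, {
    gen <- function(names, len) {
      tibble(name = names,
             seq = unname(vapply(names, function(...) rand_dna(len),
                                 character(1))),
             length = len)
    }
    ighv <- gen(sprintf("IGHV%d-syn", seq_len(n_v)), v_len)
    ighc <- gen(c("IGHM-syn", "IGHG-syn", "IGHA-syn"), c_len)
    d_heavy <- gen(sprintf("IGHD%d-syn", 1:4), d_len)
    j_heavy <- gen(sprintf("IGHJ%d-syn", 1:4), j_len)
    nk <- max(1L, n_v %/% 2L); nl <- max(1L, n_v - nk)
    igklv <- bind_rows(gen(sprintf("IGKV%d-syn", seq_len(nk)), v_len),
                       gen(sprintf("IGLV%d-syn", seq_len(nl)), v_len))
    igklc <- gen(c("IGKC-syn", "IGLC1-syn"), c_len)
    j_light <- bind_rows(gen(sprintf("IGKJ%d-syn", 1:2), j_len),
                         gen(sprintf("IGLJ%d-syn", 1:2), j_len))
    germline_db(ighv = ighv, ighc = ighc, igklv = igklv, igklc = igklc,
                j_heavy = j_heavy, j_light = j_light, d_heavy = d_heavy,
                k = k)
  })
}

#' Simulate one rearranged receptor (both chains)
#'
#' Emulates V(D)J recombination: per requested chain a V, (D,) J and C gene
#' are chosen uniformly; 0-`trim_max` bases are trimmed at each junction
#' end; untemplated nucleotides of length drawn uniformly from `ins_range`
#' are inserted at each junction (heavy: V-D and D-J; light: V-J); the
#' rearrangement is concatenated with its constant region; somatic
#' hypermutation is applied as i.i.d. substitutions over the V(D)J span at
#' `shm_rate`. Light-chain genes are drawn coherently from one locus
#' (kappa or lambda), chosen uniformly. Uses the current RNG state — wrap
#' in a seed (as [sim_cell()] does) for reproducibility.
#'
#' @param db A [germline_db()] carrying J sets and heavy D segments.
#' @param chains Subset of `c("heavy", "light")`.
#' @param shm_rate Per-base substitution probability over the V(D)J span.
#' @param trim_max Maximum junctional trimming per segment end (bases).
#' @param ins_range Length-2 integer range of junctional insert lengths.
#' @return Ground-truth tibble, one row per chain: gene choices, junction
#'   inserts, pre-/post-mutation transcript, mutated positions.
#' @export
sim_receptor <- function(db, chains = c("heavy", "light"), shm_rate = 0,
                         trim_max = 3L, ins_range = c(0L, 10L)) {
  chains <- match.arg(chains, several.ok = TRUE)
  need <- c(if ("heavy" %in% chains) c("J_HEAVY", "D_HEAVY"),
            if ("light" %in% chains) "J_LIGHT")
  for (comp in need) {
    if (nrow(db_component(db, comp)) == 0)
      abort(sprintf("germline_db lacks required component '%s'", comp))
  }
  pick <- function(tbl) tbl[sample.int(nrow(tbl), 1L), ]
  trim3 <- function(s, n) substr(s, 1L, nchar(s) - n)
  trim5 <- function(s, n) substr(s, n + 1L, nchar(s))
  ins <- function() {
    n <- sample(seq.int(ins_range[1], ins_range[2]), 1L)
    if (n == 0L) "" else rand_dna(n)
  }
  tr <- function() sample.int(trim_max + 1L, 1L) - 1L

  rows <- lapply(chains, function(chain) {
    if (chain == "heavy") {
      v <- pick(db_component(db, "IGHV")); d <- pick(db_component(db, "D_HEAVY"))
      j <- pick(db_component(db, "J_HEAVY")); cc <- pick(db_component(db, "IGHC"))
      i1 <- ins(); i2 <- ins()
      vdj <- paste0(trim3(v$seq, tr()), i1, trim5(trim3(d$seq, tr()), tr()),
                    i2, trim5(j$seq, tr()))
      inserts <- paste(i1, i2, sep = ",")
      d_gene <- d$name
    } else {
      locus <- sample(c("IGK", "IGL"), 1L)
      of_locus <- function(comp) {
        tbl <- db_component(db, comp)
        tbl[startsWith(tbl$name, locus), ]
      }
      v <- pick(of_locus("IGKLV")); j <- pick(of_locus("J_LIGHT"))
      cc <- pick(of_locus("IGKLC"))
      i1 <- ins()
      vdj <- paste0(trim3(v$seq, tr()), i1, trim5(j$seq, tr()))
      inserts <- i1
      d_gene <- NA_character_
    }
    pre <- paste0(vdj, cc$seq)
    vdj_len <- nchar(vdj)
    mut_at <- which(runif(vdj_len) < shm_rate)
    post <- pre
    for (p in mut_at) {
      substr(post, p, p) <- sample(setdiff(c("A", "C", "G", "T"),
                                           substr(pre, p, p)), 1L)
    }
    tibble(chain = chain, v_gene = v$name, d_gene = d_gene, j_gene = j$name,
           c_gene = cc$name, junction_inserts = inserts, vdj_len = vdj_len,
           n_shm = length(mut_at),
           shm_positions = paste(mut_at, collapse = ","),
           pre_seq = pre, post_seq = post)
  })
  bind_rows(rows)
}

#' Fragment a transcript into error-bearing short reads
#'
#' Read starts are uniform over the transcript, strands uniform, and
#' sequencing errors are i.i.d. substitutions at `error_rate` applied to
#' the read as sequenced. `round(depth * length / read_len)` reads are
#' drawn. Paired mode emits mates from opposite ends of a
#' normally-distributed fragment. An optional `drop_interval` removes every
#' read overlapping a transcript interval, creating a controlled coverage
#' gap (used to exercise the split-assembly fallback). Uses the current
#' RNG state.
#'
#' @param transcript DNA string to sequence.
#' @param read_len Read length in bp (default 50).
#' @param depth Mean fold-coverage (default 100).
#' @param error_rate Per-base substitution error probability.
#' @param paired Emit mate pairs instead of single-end reads.
#' @param frag_mean,frag_sd Fragment length distribution (paired mode).
#' @param drop_interval Optional 0-based half-open interval `c(a, b)`;
#'   reads overlapping it are discarded.
#' @param id_prefix Prefix for read ids.
#' @return Read tibble: `id`, `seq`, plus provenance columns `start`
#'   (0-based on the transcript), `strand`, `n_errors`.
#' @export
sim_reads <- function(transcript, read_len = 50L, depth = 100, error_rate = 0,
                      paired = FALSE, frag_mean = 200L, frag_sd = 20L,
                      drop_interval = NULL, id_prefix = "r") {
  tl <- nchar(transcript)
  if (read_len > tl) abort("read length exceeds transcript length")
  n <- max(1L, round(depth * tl / read_len))
  if (paired) {
    nf <- max(1L, round(n / 2))
    fl <- pmin(tl, pmax(read_len, round(rnorm(nf, frag_mean, frag_sd))))
    fs <- vapply(tl - fl + 1L, function(hi) sample.int(hi, 1L), integer(1))
    starts <- c(fs, fs + fl - read_len)
    strand <- rep(c("+", "-"), each = nf)
    ids <- c(sprintf("%s%04d/1", id_prefix, seq_len(nf)),
             sprintf("%s%04d/2", id_prefix, seq_len(nf)))
  } else {
    starts <- sample.int(tl - read_len + 1L, n, replace = TRUE)
    strand <- sample(c("+", "-"), n, replace = TRUE)
    ids <- sprintf("%s%05d", id_prefix, seq_len(n))
  }
  seqs <- substring(transcript, starts, starts + read_len - 1L)
  neg <- strand == "-"
  if (any(neg)) seqs[neg] <- revcomp(seqs[neg])
  n_err <- integer(length(seqs))
  if (error_rate > 0) {
    err <- matrix(runif(length(seqs) * read_len) < error_rate,
                  nrow = length(seqs))
    n_err <- rowSums(err)
    for (i in which(n_err > 0L)) {
      for (p in which(err[i, ])) {
        substr(seqs[i], p, p) <- sample(setdiff(c("A", "C", "G", "T"),
                                                substr(seqs[i], p, p)), 1L)
      }
    }
  }
  reads <- tibble(id = ids, seq = seqs, start = starts - 1L, strand = strand,
                  n_errors = as.integer(n_err))
  if (!is.null(drop_interval)) {
    keep <- !(reads$start < drop_interval[2] &
                reads$start + read_len > drop_interval[1])
    reads <- reads[keep, ]
  }
  reads
}

#' Simulate a complete ground-truthed cell
#'
#' One seeded call produces a cell's receptor truth ([sim_receptor()]) and
#' its reads ([sim_reads()], one batch per chain, pooled). The same seed
#' always reproduces the identical cell.
#'
#' @param db A [germline_db()] from [sim_germline_db()] or equivalent.
#' @param seed Integer seed for this cell.
#' @param cell_id Cell identifier (prefixes read ids).
#' @param chains Subset of `c("heavy", "light")`.
#' @param shm_rate,trim_max,ins_range Passed to [sim_receptor()].
#' @param read_len,depth,error_rate,paired,frag_mean,frag_sd,drop_interval
#'   Passed to [sim_reads()].
#' @return List: `truth` (tibble with `cell_id`), `reads` (pooled tibble).
#' @examples
#' db <- sim_germline_db(seed = 1)
#' cell <- sim_cell(db, seed = 3, shm_rate = 0.03, error_rate = 0.005)
#' cell$truth[, c("chain", "v_gene", "j_gene", "c_gene", "n_shm")]
#' @export
sim_cell <- function(db, seed, cell_id = "cell1",
                     chains = c("heavy", "light"), shm_rate = 0,
                     trim_max = 3L, ins_range = c(0L, 10L), read_len = 50L,
                     depth = 100, error_rate = 0, paired = FALSE,
                     frag_mean = 200L, frag_sd = 20L, drop_interval = NULL) {
  with_seed(seed, {
    truth <- sim_receptor(db, chains = chains, shm_rate = shm_rate,
                          trim_max = trim_max, ins_range = ins_range)
    truth <- mutate(truth, cell_id = cell_id, .before = 1)
    reads <- bind_rows(lapply(seq_len(nrow(truth)), function(i) {
      sim_reads(truth$post_seq[i], read_len = read_len, depth = depth,
                error_rate = error_rate, paired = paired,
                frag_mean = frag_mean, frag_sd = frag_sd,
                drop_interval = drop_interval,
                id_prefix = sprintf("%s_%s_", cell_id, truth$chain[i]))
    }))
    list(truth = truth, reads = reads)
  })
}

#' Simulate a cohort of cells
#'
#' Per-cell seeds are derived deterministically from `seed`, so the cohort
#' is reproducible while cells stay independent.
#'
#' @param db A [germline_db()].
#' @param n_cells Number of cells.
#' @param seed Cohort seed.
#' @param ... Passed to [sim_cell()].
#' @return List: `truth` (all cells), `cells` (named list of read tibbles).
#' @export
sim_cells <- function(db, n_cells, seed, ...) {
  cell_seeds <- with_seed(seed, sample.int(.Machine$integer.max - 1L, n_cells))
  out <- lapply(seq_len(n_cells), function(i) {
    sim_cell(db, seed = cell_seeds[i], cell_id = sprintf("cell%03d", i), ...)
  })
  list(truth = bind_rows(lapply(out, `[[`, "truth")),
       cells = setNames(lapply(out, `[[`, "reads"),
                        sprintf("cell%03d", seq_len(n_cells))))
}

#' Write reads to FASTQ
#'
#' Qualities are constant `I` (Phred 40): assembly never uses them.
#'
#' @param reads Read tibble (`id`, `seq`).
#' @param path Output path (`.gz` supported).
#' @return The path, invisibly.
#' @export
write_fastq <- function(reads, path) {
  lines <- as.vector(rbind(paste0("@", reads$id), reads$seq, "+",
                           strrep("I", nchar(reads$seq))))
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wt") else file(path, "wt")
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}

#' Write sequences to FASTA
#' @param tbl Tibble with `name` and `seq` columns.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_fasta <- function(tbl, path) {
  writeLines(as.vector(rbind(paste0(">", tbl$name), tbl$seq)), path)
  invisible(path)
}

#' Write a germline database to per-component FASTA files
#' @param db A [germline_db()].
#' @param dir Output directory (created if absent).
#' @return Named character vector of file paths.
#' @export
write_germline_fasta <- function(db, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  comps <- unique(db$genes$component)
  paths <- vapply(comps, function(comp) {
    p <- file.path(dir, paste0(tolower(comp), ".fasta"))
    write_fasta(db_component(db, comp), p)
    p
  }, character(1))
  setNames(paths, comps)
}
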