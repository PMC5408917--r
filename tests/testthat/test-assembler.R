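test_that("overlap index stores forward and reverse-complement m-prefixes", {
  reads <- tibble::tibble(id = "r1", seq = "ACGTACGTACGTACG")
  idx <- overlap_index(reads, m = 10)
  expect_equal(idx$n_reads, 1L)
  expect_setequal(ls(idx$env),
                  c("ACGTACGTAC", substr(oracle_rc(reads$seq), 1, 10)))

  dup <- tibble::tibble(id = c("a", "b"), seq = "ACGTACGTACGTACG")
  idx2 <- overlap_index(dup, m = 10)
  expect_equal(sort(idx2$eid[idx2$env[["ACGTACGTAC"]]]), c("a", "b"))

  short <- tibble::tibble(id = "s", seq = strrep("A", 9))
  expect_equal(overlap_index(short, m = 10)$n_reads, 0L)

  expect_error(overlap_index(reads, m = 9), ">= 10")
})

test_that("3' extension appends a single overlapping read and stops cleanly", {
  seed <- "AAAACCCCGGGGTT"
  reads <- tibble::tibble(id = "r1", seq = "CCCCGGGGTTACGT")  # 10 bp overlap
  idx <- overlap_index(reads, m = 10)
  r <- extend_3prime(seed, idx)
  expect_equal(r$seq, "AAAACCCCGGGGTTACGT")
  expect_equal(nrow(r$steps), 1L)
  expect_equal(r$steps$overlap, 10L)
  expect_equal(r$stop, "no_overlap")

  none <- tibble::tibble(id = "x", seq = "TTTTTTTTTTTTTT")
  r0 <- extend_3prime(seed, overlap_index(none, m = 10))
  expect_equal(r0$seq, seed)
  expect_equal(nrow(r0$steps), 0L)
  expect_equal(r0$stop, "no_overlap")

  expect_error(extend_3prime("ACGT", idx), "shorter than the minimum overlap")
})

test_that("tiling reads reconstruct a transcript in both directions", {
  set.seed(3)
  transcript <- rdna(300)
  reads <- tiling_reads(transcript, read_len = 50, step = 25)  # gap 25 < 50-20
  idx <- overlap_index(reads, m = 20)

  r3 <- extend_3prime(substr(transcript, 1, 50), idx)
  expect_equal(r3$seq, transcript)
  expect_equal(r3$stop, "no_overlap")

  r5 <- extend_5prime(substr(transcript, 251, 300), idx)
  expect_equal(r5$seq, transcript)

  mid <- substr(transcript, 126, 175)
  both <- extend_5prime(extend_3prime(mid, idx)$seq, idx,
                        used = extend_3prime(mid, idx)$used)
  expect_equal(both$seq, transcript)
})

test_that("greedy extension matches the naive no-index oracle", {
  set.seed(13)
  for (rep in 1:25) {
    transcript <- rdna(sample(120:260, 1))
    step <- sample(5:28, 1)
    reads <- tiling_reads(transcript, read_len = 50, step = step)
    # corrupt a few reads so not every instance is a clean tiling
    for (i in sample(nrow(reads), min(2, nrow(reads)))) {
      p <- sample(50, 1)
      substr(reads$seq[i], p, p) <-
        setdiff(c("A", "C", "G", "T"), substr(reads$seq[i], p, p))[1]
    }
    idx <- overlap_index(reads, m = 20)
    seed3 <- substr(transcript, 1, 50)
    expect_equal(extend_3prime(seed3, idx)$seq,
                 oracle_extend(seed3, reads, m = 20, side = "3prime"))
    seed5 <- substr(transcript, nchar(transcript) - 49, nchar(transcript))
    expect_equal(extend_5prime(seed5, idx)$seq,
                 oracle_extend(seed5, reads, m = 20, side = "5prime"))
  }
})

test_that("5' extension is the reverse-complement mirror of 3' extension", {
  set.seed(17)
  for (rep in 1:10) {
    transcript <- rdna(200)
    reads <- tiling_reads(transcript, read_len = 50, step = 15)
    idx <- overlap_index(reads, m = 20)
    seed <- substr(transcript, 76, 125)
    expect_equal(extend_5prime(seed, idx)$seq,
                 revcomp(extend_3prime(revcomp(seed), idx)$seq))
  }
})

test_that("re-entering a repeat stops extension with reason 'repeat'", {
  # reads tile a circular sequence, so greedy extension cycles back to the
  # first read it used
  set.seed(29)
  circ <- rdna(120)
  wrapped <- paste0(circ, substr(circ, 1, 49))
  starts <- seq(1, 120, by = 15)
  reads <- tibble::tibble(id = sprintf("c%02d", seq_along(starts)),
                          seq = substring(wrapped, starts, starts + 49))
  idx <- overlap_index(reads, m = 20)
  r <- extend_3prime(substr(circ, 1, 50), idx, max_len = 5000)
  expect_equal(r$stop, "repeat")
  expect_lte(nchar(r$seq), 120 + 50 + 50)
  expect_equal(anyDuplicated(r$steps$read_id), 0L)
})

test_that("max_length bounds runaway extension", {
  set.seed(37)
  transcript <- rdna(400)
  reads <- tiling_reads(transcript, read_len = 50, step = 10)
  idx <- overlap_index(reads, m = 20)
  r <- extend_3prime(substr(transcript, 1, 50), idx, max_len = 150)
  expect_equal(r$stop, "max_length")
  expect_lte(nchar(r$seq), 150 + 50)
})

test_that("chain assembly reports merged, split and partial correctly", {
  db <- toy_db()
  cell <- sim_cell(db, seed = 41, chains = "heavy")
  asm <- assemble_cell(cell$reads, db, quiet = TRUE)
  expect_equal(asm$heavy$status, "merged")
  expect_true(grepl(cell$truth$post_seq, asm$heavy$seq, fixed = TRUE))
  expect_equal(asm$light$status, "absent")

  # a masked interval between the V and C regions forces a split
  set.seed(43)
  truth <- sim_receptor(db, chains = "heavy")
  gap <- c(truth$vdj_len - 50L, truth$vdj_len - 10L)  # 40 bp, > 50 - 20
  reads <- sim_reads(truth$post_seq, depth = 100, drop_interval = gap,
                     id_prefix = "h_")
  anchors <- find_anchors(reads, db, quiet = TRUE)
  idx <- overlap_index(reads, m = 20)
  ca <- assemble_chain(anchors[anchors$component == "IGHV", ],
                       anchors[anchors$component == "IGHC", ], idx,
                       chain = "heavy")
  expect_equal(ca$status, "split")
  expect_false(is.null(ca$contig_v))
  expect_false(is.null(ca$contig_c))

  # single anchor -> partial
  cp <- assemble_chain(anchors[anchors$component == "IGHV", ], NULL, idx)
  expect_equal(cp$status, "partial")
  expect_null(cp$contig_c)
  ab <- assemble_chain(NULL, NULL, idx)
  expect_equal(ab$status, "absent")
})

test_that("assembly invariants hold: anchor containment, replay, read reuse", {
  db <- toy_db()
  cell <- sim_cell(db, seed = 47)
  asm <- assemble_cell(cell$reads, db, quiet = TRUE)
  for (ca in list(asm$heavy, asm$light)) {
    for (side in c("contig_v", "contig_c")) {
      ct <- ca[[side]]
      expect_true(grepl(ct$anchor$window, ct$seq, fixed = TRUE))
      expect_equal(anyDuplicated(ct$steps$read_id), 0L)
      expect_true(all(ct$steps$overlap >= 20))
      expect_equal(replay_steps(ct$anchor$window, ct$steps, cell$reads),
                   ct$seq)
    }
  }
})

test_that("assembly is deterministic and orientation-canonical", {
  db <- toy_db()
  cell <- sim_cell(db, seed = 53)
  a1 <- assemble_cell(cell$reads, db, quiet = TRUE)
  a2 <- assemble_cell(cell$reads, db, quiet = TRUE)
  expect_identical(a1$heavy$seq, a2$heavy$seq)
  expect_identical(a1$light$seq, a2$light$seq)
  expect_identical(tidy(a1), tidy(a2))

  flipped <- tibble::tibble(id = cell$reads$id, seq = revcomp(cell$reads$seq))
  af <- assemble_cell(flipped, db, quiet = TRUE)
  expect_identical(af$heavy$seq, a1$heavy$seq)
  expect_identical(af$light$seq, a1$light$seq)
})

test_that("assembly output helpers write FASTA and tidy summaries", {
  db <- toy_db()
  cell <- sim_cell(db, seed = 59)
  asm <- assemble_cell(cell$reads, db, quiet = TRUE)
  td <- tidy(asm)
  expect_equal(td$chain, c("heavy", "light"))
  expect_true(all(c("status", "v_support", "c_stop") %in% names(td)))
  expect_equal(nrow(glance(asm)), 1L)

  fa <- tempfile(fileext = ".fasta")
  write_assembly_fasta(asm, "cellX", fa)
  recs <- Biostrings::readDNAStringSet(fa)
  expect_equal(length(recs), 2L)
  expect_setequal(names(recs), c("cellX_heavy_merged", "cellX_light_merged"))

  p <- autoplot(asm)
  expect_s3_class(p, "ggplot")
})
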