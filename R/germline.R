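#' Read one germline component from a FASTA file
#'
#' Loads a multi-FASTA of germline gene segments and tags every record with
#' its component. Sequences are uppercased; IMGT-style gap characters (`.`
#' and `-`) are stripped; IUPAC ambiguity codes other than `N` are replaced
#' by `N` with a warning so the k-mer alphabet stays `{A,C,G,T,N}`. Records
#' shorter than `k` cannot be indexed and are dropped with a warning.
#'
#' @param path Path to a FASTA file (gzip transparently supported).
#' @param component One of `"IGHV"`, `"IGHC"`, `"IGKLV"`, `"IGKLC"`,
#'   `"J_HEAVY"`, `"J_LIGHT"`, `"D_HEAVY"`. Kappa and lambda genes are pooled
#'   into the `IGKLV`/`IGKLC` components, so the light-chain locus is decided
#'   by the anchor competition, not by a prior choice.
#' @param k Minimum usable sequence length (the seed k-mer size).
#' @return A tibble with columns `name`, `component`, `seq`, `length`.
#' @export
read_germline_fasta <- function(path, component, k = 16L) {
  component <- match.arg(component, ALL_COMPONENTS)
  ss <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) abort(sprintf("not readable as FASTA: %s (%s)",
                                      path, conditionMessage(e)))
  )
  if (length(ss) == 0) abort(sprintf("no records in FASTA: %s", path))
  nm <- sub("\\s.*$", "", names(ss))
  if (anyDuplicated(nm)) {
    abort(sprintf("duplicate name(s) in %s component '%s': %s", path,
                  component, paste(unique(nm[duplicated(nm)]), collapse = ", ")))
  }
  seq <- unname(toupper(as.character(ss)))
  seq <- gsub("[.\\-]", "", seq)
  has_iupac <- grepl("[^ACGTN]", seq)
  if (any(has_iupac)) {
    warn(sprintf("%d record(s) in component '%s' contain IUPAC codes other than N; replaced by N",
                 sum(has_iupac), component))
    seq <- gsub("[^ACGTN]", "N", seq)
  }
  tbl <- tibble(name = nm, component = component, seq = seq,
                length = nchar(seq))
  short <- tbl$length < k
  if (any(short)) {
    warn(sprintf("dropping %d record(s) shorter than k = %d in component '%s'",
                 sum(short), k, component))
    tbl <- tbl[!short, ]
  }
  if (nrow(tbl) == 0) abort(sprintf("no usable records (all shorter than k) in %s", path))
  tbl
}

#' Build an exact k-mer index over one germline component
#'
#' Every length-`k` substring of every sequence is indexed with its 0-based
#' offset; k-mers containing `N` are skipped. The index supports the
#' seed-and-verify read mapping in [map_reads_component()]. It plays the role
#' an external aligner's index would, but keeps the package self-contained
#' and deterministic.
#'
#' @param germlines Tibble from [read_germline_fasta()] (one component).
#' @param k Seed length in bp, at least 8. Default 16.
#' @return A `kmer_index` object.
#' @export
build_kmer_index <- function(germlines, k = 16L) {
  k <- as.integer(k)
  if (k < 8L) abort("k must be >= 8")
  if (nrow(germlines) == 0) abort("no sequences to index")
  if (length(unique(germlines$component)) > 1)
    abort("all sequences in one index must share a component")
  if (all(nchar(germlines$seq) < k))
    abort(sprintf("k = %d exceeds the length of every sequence", k))
  rows <- purrr::map(seq_len(nrow(germlines)), function(i) {
    s <- germlines$seq[i]
    L <- nchar(s)
    if (L < k) return(NULL)
    starts <- seq_len(L - k + 1L)
    km <- substring(s, starts, starts + k - 1L)
    keep <- !grepl("N", km, fixed = TRUE)
    if (!any(keep)) return(NULL)
    tibble(kmer = km[keep], name = germlines$name[i], offset = starts[keep] - 1L)
  })
  post <- bind_rows(rows)
  keys <- unique(post$kmer)
  post$kmer_id <- match(post$kmer, keys)
  post$kmer <- NULL
  structure(
    list(k = k, component = germlines$component[1], keys = keys,
         post = post[order(post$kmer_id), ]),
    class = "kmer_index"
  )
}

#' @export
print.kmer_index <- function(x, ...) {
  cat(sprintf("<kmer_index> component %s, k = %d, %d distinct k-mers, %d postings\n",
              x$component, x$k, length(x$keys), nrow(x$post)))
  invisible(x)
}

#' Assemble a germline reference database
#'
#' Bundles the four anchor components (heavy variable/constant, pooled
#' kappa+lambda light variable/constant) with optional J and D sets, and
#' builds a k-mer index per anchor component. Each argument is either a FASTA
#' path or a tibble as returned by [read_germline_fasta()].
#'
#' @param ighv,ighc,igklv,igklc The four anchor components (required).
#' @param j_heavy,j_light Optional J segment sets, used for annotation and
#'   by the simulator.
#' @param d_heavy Optional heavy-chain D segment set (simulator only).
#' @param k Seed k-mer length used for the component indices.
#' @return A `germline_db` object: `$genes` (one tibble over all components),
#'   `$index` (named list of `kmer_index` for the anchor components), `$k`.
#' @examples
#' db <- sim_germline_db(seed = 1)
#' db
#' @export
germline_db <- function(ighv, ighc, igklv, igklc,
                        j_heavy = NULL, j_light = NULL, d_heavy = NULL,
                        k = 16L) {
  k <- as.integer(k)
  comp_in <- list(IGHV = ighv, IGHC = ighc, IGKLV = igklv, IGKLC = igklc,
                  J_HEAVY = j_heavy, J_LIGHT = j_light, D_HEAVY = d_heavy)
  tbls <- purrr::imap(comp_in, function(x, comp) {
    if (is.null(x)) return(NULL)
    if (is.character(x)) return(read_germline_fasta(x, comp, k = k))
    x$component <- comp
    x
  })
  genes <- bind_rows(tbls)
  genes <- genes[, c("name", "component", "seq", "length")]
  for (comp in ASSEMBLY_COMPONENTS) {
    if (!any(genes$component == comp))
      abort(sprintf("assembly component '%s' is empty", comp))
  }
  idx <- lapply(setNames(nm = ASSEMBLY_COMPONENTS), function(comp) {
    build_kmer_index(genes[genes$component == comp, ], k = k)
  })
  structure(list(genes = genes, index = idx, k = k), class = "germline_db")
}

#' @export
print.germline_db <- function(x, ...) {
  cnt <- table(factor(x$genes$component, levels = ALL_COMPONENTS))
  cat(sprintf("<germline_db> k = %d\n", x$k))
  for (comp in names(cnt)) {
    if (cnt[[comp]] > 0) cat(sprintf("  %-8s %3d gene(s)\n", comp, cnt[[comp]]))
  }
  invisible(x)
}

# Subset of the gene table for one component (internal).
db_component <- function(db, component) {
  db$genes[db$genes$component == component, ]
}
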