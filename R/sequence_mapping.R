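#' Pairwise percent identity between two DNA sequences
#'
#' Global alignment with free terminal gaps ("overlap" alignment): match +1,
#' mismatch -1, gap -2 per gapped position. Identity is the fraction of
#' matching columns over all aligned columns, terminal-gap columns excluded.
#' Ambiguity codes (including N) never match anything and count as
#' mismatches, a deliberately conservative rule.
#'
#' @param a,b DNA sequences (character strings, IUPAC alphabet).
#' @param match,mismatch,gap alignment scores; `gap` is the per-position
#'   gap penalty (positive number, subtracted).
#' @return identity as a fraction in \[0, 1\]; symmetric in its arguments.
#' @export
percent_identity <- function(a, b, match = 1, mismatch = -1, gap = 2) {
  if (!nzchar(a) || !nzchar(b)) stop("sequences must be non-empty")
  .align_identity_cpp(a, b, match, mismatch, gap)$identity
}

#' Map query 16S sequences to their closest reference sequence
#'
#' Each query is assigned its maximum-identity reference; it is `mapped`
#' only when that identity reaches `threshold` (default 0.97, the standard
#' species-level 16S cutoff). Ties are broken by lexicographically smaller
#' reference id so results are deterministic.
#'
#' @param queries,references named character vectors of DNA sequences
#'   (e.g. from [read_fasta()]).
#' @param threshold minimum identity for a mapping, fraction.
#' @param min_coverage minimum fraction of the shorter sequence the
#'   alignment must span. Ends-free alignment of two unrelated sequences
#'   degenerates to a few perfectly matching columns with spurious identity
#'   1; requiring the alignment to cover most of the amplicon (default 50%)
#'   removes such hits before the identity is compared.
#' @return data.frame with columns `query`, `reference` (best hit, `NA` when
#'   below threshold), `identity`, `mapped`.
#' @export
map_sequences <- function(queries, references, threshold = 0.97,
                          min_coverage = 0.5) {
  if (length(references) == 0) stop("reference set must be non-empty")
  if (length(queries) == 0) stop("query set must be non-empty")
  if (is.null(names(queries))) names(queries) <- paste0("q", seq_along(queries))
  if (is.null(names(references))) names(references) <- paste0("r", seq_along(references))
  idmat <- matrix(NA_real_, length(queries), length(references),
                  dimnames = list(names(queries), names(references)))
  for (i in seq_along(queries)) {
    for (j in seq_along(references)) {
      a <- .align_identity_cpp(queries[[i]], references[[j]])
      cov <- a$columns / min(nchar(queries[[i]]), nchar(references[[j]]))
      idmat[i, j] <- if (cov >= min_coverage) a$identity else 0
    }
  }
  refs_sorted <- sort(colnames(idmat))  # lexicographic tie-break
  best <- apply(idmat[, refs_sorted, drop = FALSE], 1, function(z) {
    k <- which.max(z)  # first maximum = smallest id on ties
    c(k, z[k])
  })
  data.frame(
    query = rownames(idmat),
    reference = ifelse(best[2, ] >= threshold, refs_sorted[best[1, ]], NA_character_),
    identity = unname(best[2, ]),
    mapped = unname(best[2, ] >= threshold),
    row.names = NULL)
}

#' Build a per-sample model community from counts and a sequence mapping
#'
#' Counts of taxa mapping to the same model are summed, relative abundances
#' are computed, entries below `min_abundance` (default 2%) are dropped and
#' the remainder renormalized to 1. The fraction of reads that mapped to any
#' model is reported so the information lost to unmapped taxa is kept.
#'
#' @param table an `abundance_table` (see [abundance_table()]) or a plain
#'   taxa x samples count matrix.
#' @param mapping data.frame from [map_sequences()].
#' @param sample sample id (column) to build the community for.
#' @param min_abundance drop models below this relative abundance.
#' @param unmapped `"exclude_first"` (default) removes unmapped reads before
#'   the abundance cutoff; `"exclude_after"` applies the cutoff on total-read
#'   relative abundances first.
#' @return object of class `community`: list with `sample`, `abundance`
#'   (named, sums to 1) and `mapped_fraction`.
#' @export
build_community <- function(table, mapping, sample, min_abundance = 0.02,
                            unmapped = c("exclude_first", "exclude_after")) {
  unmapped <- match.arg(unmapped)
  counts <- if (inherits(table, "abundance_table")) table$counts else table
  if (!sample %in% colnames(counts)) stop("unknown sample '", sample, "'")
  x <- counts[, sample]
  total <- sum(x)
  if (total == 0) stop("sample '", sample, "' has no reads")
  map <- mapping[mapping$mapped & mapping$query %in% rownames(counts), , drop = FALSE]
  per_model <- tapply(x[map$query], map$reference, sum)
  per_model <- per_model[per_model > 0]
  mapped_fraction <- sum(per_model) / total
  if (length(per_model) == 0) {
    stop("empty community: no mapped taxon with nonzero counts in sample '",
         sample, "'")
  }
  denom <- if (unmapped == "exclude_first") sum(per_model) else total
  ab <- per_model / denom
  ab <- ab[ab >= min_abundance]
  if (length(ab) == 0) {
    stop("empty community: no model above min_abundance in sample '",
         sample, "'")
  }
  ab <- ab / sum(ab)
  structure(list(sample = sample,
                 abundance = setNames(as.numeric(ab), names(ab)),
                 mapped_fraction = mapped_fraction),
            class = "community")
}

#' @export
print.community <- function(x, ...) {
  cat(sprintf("<community> sample %s: %d models, %.1f%% of reads mapped\n",
              x$sample, length(x$abundance), 100 * x$mapped_fraction))
  invisible(x)
}

#' Read / write FASTA sequence files
#'
#' @param path file path.
#' @return `read_fasta`: named character vector of sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(as.character(x), names(x))
}

#' @rdname read_fasta
#' @param seqs named character vector of sequences.
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}
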