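.sort_hits <- function(hits) {
  hits[order(-hits$identity_pct, -hits$score, hits$subject_acc), , drop = FALSE]
}

.empty_hits <- function() {
  data.frame(query_acc = character(0), subject_acc = character(0),
             identity_pct = numeric(0), score = numeric(0),
             aln_length = integer(0), source = character(0),
             stringsAsFactors = FALSE)
}

#' Search an in-memory pool for homologs of a query record
#'
#' Exhaustive all-vs-all local alignment (BLOSUM62, affine gaps) of the
#' query against every pool entry — the desk-scale stand-in for a BLAST
#' search against a large unreviewed section. Identity is computed
#' BLAST-style over all columns of the local alignment.
#'
#' @param query a one-row protein record table (or a row of one).
#' @param pool protein record table to search.
#' @param min_identity keep hits with `identity_pct >= min_identity`
#'   (percent, default 80).
#' @param max_hits truncate the ranked hit list (default 1000).
#' @param organism_filter optional substring that hit organisms must
#'   contain (case-insensitive).
#' @param coverage_min optional minimum fraction (0-1) of the query
#'   length covered by the local alignment, for the stricter
#'   full-query reading of the identity threshold.
#' @param min_aln_length minimal local-alignment span (columns) for a
#'   hit to count, capped at the shorter input length (default 30).
#'   The built-in search computes no E-values, and without a floor any
#'   shared tetramer scores 100% identity; the floor plays the role of
#'   the significance filter an external BLAST run applies.
#' @return data.frame of hits (`query_acc`, `subject_acc`,
#'   `identity_pct`, `score`, `aln_length`, `source`), sorted by identity
#'   desc, score desc, accession asc. The query itself is never returned.
#' @export
search_pool <- function(query, pool, min_identity = 80, max_hits = 1000,
                        organism_filter = NULL, coverage_min = NULL,
                        min_aln_length = 30) {
  if (nrow(pool) == 0) return(.empty_hits())
  stopifnot(nrow(query) == 1)
  cand <- pool[pool$accession != query$accession, , drop = FALSE]
  if (!is.null(organism_filter)) {
    org <- ifelse(is.na(cand$organism), "", cand$organism)
    cand <- cand[grepl(organism_filter, org, ignore.case = TRUE, fixed = FALSE), , drop = FALSE]
  }
  if (nrow(cand) == 0) return(.empty_hits())
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAStringSet(setNames(cand$sequence, cand$accession)),
    Biostrings::AAString(query$sequence),
    type = "local", substitutionMatrix = blosum62_extended(),
    gapOpening = 11, gapExtension = 1
  )
  ncol_aln <- Biostrings::nchar(aln)
  nmatch <- Biostrings::nmatch(aln)
  identity <- ifelse(ncol_aln > 0, 100 * nmatch / ncol_aln, 0)
  hits <- data.frame(
    query_acc = query$accession, subject_acc = cand$accession,
    identity_pct = identity, score = Biostrings::score(aln),
    aln_length = as.integer(ncol_aln), source = "builtin",
    stringsAsFactors = FALSE
  )
  floor_len <- pmin(min_aln_length, nchar(query$sequence), nchar(cand$sequence))
  keep <- hits$aln_length >= floor_len
  if (!is.null(coverage_min)) {
    qlen <- nchar(query$sequence)
    span <- Biostrings::width(Biostrings::subject(aln))
    keep <- keep & (span / qlen >= coverage_min)
  }
  hits <- hits[keep, , drop = FALSE]
  hits <- hits[hits$identity_pct >= min_identity, , drop = FALSE]
  hits <- .sort_hits(hits)
  head(hits, max_hits)
}

#' Convert ingested BLAST tabular rows into ranked search hits
#'
#' Applies the same identity threshold and ordering contract as
#' [search_pool()], taking identity from the file rather than
#' recomputing it. Rows whose subject is absent from the pool are an
#' error (the pool is needed downstream to materialise cluster members).
#'
#' @param rows data.frame from [read_blast_tabular()].
#' @param pool protein record table the subjects must come from.
#' @param min_identity percent identity threshold (default 80).
#' @param max_hits per-query truncation (default 1000).
#' @param max_evalue optional pass-through E-value filter applied to the
#'   file's `evalue` column (the built-in search computes no E-values).
#' @return data.frame of hits as in [search_pool()], `source =
#'   "blast_tabular"`.
#' @export
hits_from_blast <- function(rows, pool, min_identity = 80, max_hits = 1000,
                            max_evalue = NULL) {
  missing_acc <- setdiff(unique(rows$subject_acc), pool$accession)
  if (length(missing_acc)) {
    stop("BLAST subjects absent from pool FASTA: ",
         paste(sort(missing_acc), collapse = ", "))
  }
  if (!is.null(max_evalue)) rows <- rows[rows$evalue <= max_evalue, , drop = FALSE]
  rows <- rows[rows$subject_acc != rows$query_acc, , drop = FALSE]
  hits <- data.frame(
    query_acc = rows$query_acc, subject_acc = rows$subject_acc,
    identity_pct = rows$percent_identity, score = rows$bitscore,
    aln_length = rows$aln_length, source = "blast_tabular",
    stringsAsFactors = FALSE
  )
  hits <- hits[hits$identity_pct >= min_identity, , drop = FALSE]
  out <- lapply(split(hits, hits$query_acc), function(h) head(.sort_hits(h), max_hits))
  res <- do.call(rbind, c(out, list(make.row.names = FALSE)))
  if (is.null(res)) .empty_hits() else res
}
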