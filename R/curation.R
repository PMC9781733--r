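#' Default description keywords excluding storage (gluten) proteins
#'
#' Case-insensitive substrings; the stem "prolamin" also catches the
#' plural form.
#' @export
GLUTEN_KEYWORDS <- c("gluten", "gliadin", "glutenin", "avenin", "prolamin")

#' Exclude records whose description matches storage-protein keywords
#'
#' A record is removed iff its description, case-insensitively, contains
#' any keyword as a substring. Both returned tables preserve input order.
#'
#' @param db protein record table.
#' @param keywords character vector of substrings (default
#'   [GLUTEN_KEYWORDS]).
#' @return list with `kept` and `removed` record tables.
#' @export
exclude_by_keywords <- function(db, keywords = GLUTEN_KEYWORDS) {
  desc <- tolower(ifelse(is.na(db$description), "", db$description))
  hit <- Reduce(`|`, lapply(tolower(keywords), function(k) grepl(k, desc, fixed = TRUE)),
                accumulate = FALSE, init = rep(FALSE, nrow(db)))
  list(kept = db[!hit, , drop = FALSE], removed = db[hit, , drop = FALSE])
}

.verdict <- function(candidate_acc, reference_acc, verdict,
                     identity_pct = NA_real_, mismatch_positions = integer(0),
                     containment_position = NA_integer_) {
  structure(list(candidate_acc = candidate_acc, reference_acc = reference_acc,
                 verdict = verdict,
                 evidence = list(identity_pct = identity_pct,
                                 mismatch_positions = mismatch_positions,
                                 containment_position = containment_position)),
            class = "redundancy_verdict")
}

#' @export
print.redundancy_verdict <- function(x, ...) {
  cat(sprintf("%s vs %s: %s", x$candidate_acc, x$reference_acc, x$verdict))
  if (!is.na(x$evidence$identity_pct)) cat(sprintf(" (identity %.1f%%)", x$evidence$identity_pct))
  cat("\n")
  invisible(x)
}

#' Classify a candidate sequence against a reference
#'
#' Decision cascade, first rule that applies wins:
#' 1. byte-identical sequences -> `duplicate`;
#' 2. one sequence an exact contiguous subsequence of the other (and
#'    strictly shorter) -> `fragment` (the shorter one is the fragment);
#' 3. the reference has a known mature start, the candidate carries an
#'    identical mature region, and every difference lies upstream of it
#'    -> `redundant_precursor_only` (a precursor/signal-peptide-only
#'    variant contributes no new mature sequence);
#' 4. global identity at or above `min_identity` -> `variant_keep`
#'    (point mutations or short indels: genuinely new sequence);
#' 5. otherwise `unrelated`.
#'
#' @param candidate,reference one-row protein record tables.
#' @param min_identity percent global identity separating variants from
#'   unrelated sequences (default 80).
#' @return a `redundancy_verdict`: `candidate_acc`, `reference_acc`,
#'   `verdict`, and `evidence` (identity, 1-based mismatch positions in
#'   reference coordinates, containment position for fragments).
#' @export
classify_redundancy <- function(candidate, reference, min_identity = 80) {
  stopifnot(nrow(candidate) == 1, nrow(reference) == 1)
  cs <- candidate$sequence
  rs <- reference$sequence
  if (identical(cs, rs)) {
    return(.verdict(candidate$accession, reference$accession, "duplicate",
                    identity_pct = 100))
  }
  if (nchar(cs) < nchar(rs)) {
    hit <- is_exact_subsequence(cs, rs)
    if (hit$found) {
      return(.verdict(candidate$accession, reference$accession, "fragment",
                      identity_pct = 100, containment_position = hit$position))
    }
  } else if (nchar(rs) < nchar(cs)) {
    hit <- is_exact_subsequence(rs, cs)
    if (hit$found) {
      return(.verdict(candidate$accession, reference$accession, "fragment",
                      identity_pct = 100, containment_position = hit$position))
    }
  }
  aln <- pairwise_align(cs, rs, mode = "global")
  mm <- alignment_mismatch_positions(aln)
  ms <- reference$mature_start
  if (!is.na(ms) && ms > 1) {
    mature <- substr(rs, ms, nchar(rs))
    if (nchar(cs) > nchar(mature) && endsWith(cs, mature)) {
      return(.verdict(candidate$accession, reference$accession,
                      "redundant_precursor_only",
                      identity_pct = aln$identity_pct, mismatch_positions = mm))
    }
  }
  if (aln$identity_pct >= min_identity) {
    return(.verdict(candidate$accession, reference$accession, "variant_keep",
                    identity_pct = aln$identity_pct, mismatch_positions = mm))
  }
  .verdict(candidate$accession, reference$accession, "unrelated",
           identity_pct = aln$identity_pct, mismatch_positions = mm)
}

#' Assemble a family cluster from a query and its search hits
#'
#' Materialises the hit subjects from the pool and attaches the query as
#' first member. The family label comes from a query-to-family map when
#' available, else falls back to `"FAM_" + query accession`.
#'
#' @param query one-row protein record table.
#' @param hits data.frame from [search_pool()] / [hits_from_blast()]
#'   (rows for this query).
#' @param pool protein record table the subjects come from.
#' @param family_map optional named character vector (accession -> label).
#' @return a `family_cluster`: list with `query_acc`, `family_label`,
#'   `members` (record table, query first), `discards` (empty).
#' @export
build_cluster <- function(query, hits, pool, family_map = NULL) {
  stopifnot(nrow(query) == 1)
  subjects <- pool[match(setdiff(hits$subject_acc, query$accession), pool$accession), , drop = FALSE]
  members <- rbind(query, subjects)
  label <- if (!is.null(family_map) && query$accession %in% names(family_map)) {
    unname(family_map[[query$accession]])
  } else {
    paste0("FAM_", query$accession)
  }
  structure(list(query_acc = query$accession, family_label = label,
                 members = members, discards = list()),
            class = "family_cluster")
}

#' @export
print.family_cluster <- function(x, ...) {
  cat(sprintf("family cluster %s (query %s): %d member(s), %d discard(s)\n",
              x$family_label, x$query_acc, nrow(x$members), length(x$discards)))
  invisible(x)
}

# Bidirectional redundancy check used during cluster deduplication: the
# precursor rule needs the record with the known mature start on the
# reference side, whichever of the pair that is.
.pair_redundancy <- function(x, y, min_identity) {
  v <- classify_redundancy(x, y, min_identity)
  if (v$verdict %in% c("duplicate", "fragment", "redundant_precursor_only")) return(v)
  if (!is.na(x$mature_start)) {
    v2 <- classify_redundancy(y, x, min_identity)
    if (v2$verdict == "redundant_precursor_only") {
      return(.verdict(x$accession, y$accession, "redundant_precursor_only",
                      identity_pct = v2$evidence$identity_pct,
                      mismatch_positions = v2$evidence$mismatch_positions))
    }
  }
  NULL
}

#' Remove duplicate, fragment and precursor-only members from a cluster
#'
#' All-vs-all redundancy classification. Members are considered in
#' retention-priority order (reviewed before unreviewed, then longer
#' sequence, then lexicographically smaller accession); a member that is
#' a duplicate, fragment or precursor-only variant of any already
#' retained member is moved to `discards`. The result contains no two
#' identical sequences and no member that is an exact subsequence of
#' another, and is independent of the input member order.
#'
#' @param cluster a `family_cluster` from [build_cluster()].
#' @param min_identity percent identity threshold passed through to
#'   [classify_redundancy()] (default 80).
#' @return the cluster with `members` reduced and `discards` filled with
#'   `redundancy_verdict` objects.
#' @export
deduplicate_cluster <- function(cluster, min_identity = 80) {
  m <- cluster$members
  if (nrow(m) <= 1) return(cluster)
  ord <- order(m$db_section != "reviewed", -nchar(m$sequence), m$accession)
  m <- m[ord, , drop = FALSE]
  retained_idx <- integer(0)
  discards <- cluster$discards
  for (i in seq_len(nrow(m))) {
    verdict <- NULL
    for (j in retained_idx) {
      verdict <- .pair_redundancy(m[i, , drop = FALSE], m[j, , drop = FALSE], min_identity)
      if (!is.null(verdict)) break
    }
    if (is.null(verdict)) {
      retained_idx <- c(retained_idx, i)
    } else {
      discards <- c(discards, list(verdict))
    }
  }
  kept <- m[retained_idx, , drop = FALSE]
  # keep original member order among the retained
  kept <- kept[order(match(kept$accession, cluster$members$accession)), , drop = FALSE]
  cluster$members <- kept
  cluster$discards <- discards
  cluster
}

#' Map a cross-species homologue query onto its best same-organism entry
#'
#' Finds, among pool entries whose organism matches `organism_filter`,
#' the highest-identity hit of the homologue query. Ties are broken by
#' longer alignment, then accession ascending. Returns `NULL` when no
#' hit reaches `min_identity`.
#'
#' @param homologue_query one-row protein record table (typically a
#'   reviewed entry from a related species).
#' @param pool protein record table to search.
#' @param organism_filter organism substring (default "Triticum aestivum").
#' @param min_identity percent identity threshold (default 80).
#' @return a one-row record table, or `NULL`.
#' @export
map_homologue_to_wheat <- function(homologue_query, pool,
                                   organism_filter = "Triticum aestivum",
                                   min_identity = 80) {
  hits <- search_pool(homologue_query, pool, min_identity = min_identity,
                      max_hits = .Machine$integer.max,
                      organism_filter = organism_filter)
  if (nrow(hits) == 0) return(NULL)
  best <- hits[order(-hits$identity_pct, -hits$aln_length, hits$subject_acc), , drop = FALSE][1, ]
  pool[pool$accession == best$subject_acc, , drop = FALSE]
}

#' Borrow a provisional gene symbol from the closest ortholog
#'
#' When a record carries no gene symbol, the highest-identity
#' cross-species hit that does carry one lends its symbol. The result is
#' an annotation aid, not ground truth, and is flagged provisional.
#'
#' @param record one-row protein record table.
#' @param cross_species_pool record table of candidate orthologs.
#' @param min_identity percent identity threshold (default 80).
#' @return `NULL`, or a list with `gene`, `source_accession`,
#'   `identity_pct`, `provisional = TRUE`.
#' @export
infer_gene_from_ortholog <- function(record, cross_species_pool, min_identity = 80) {
  pool <- cross_species_pool[!is.na(cross_species_pool$gene), , drop = FALSE]
  if (nrow(pool) == 0) return(NULL)
  hits <- search_pool(record, pool, min_identity = min_identity,
                      max_hits = .Machine$integer.max)
  if (nrow(hits) == 0) return(NULL)
  best <- hits[order(-hits$identity_pct, -hits$aln_length, hits$subject_acc), , drop = FALSE][1, ]
  list(gene = pool$gene[pool$accession == best$subject_acc],
       source_accession = best$subject_acc,
       identity_pct = best$identity_pct,
       provisional = TRUE)
}

#' Flag entries that need human review
#'
#' Lists kept records whose description suggests incompleteness or weak
#' annotation ("Fragment", "Uncharacterized", "Predicted"). Flagged
#' entries are reported for manual inspection, never auto-deleted:
#' irreproducible human judgement must not silently change outputs.
#'
#' @param db protein record table.
#' @param patterns character substrings (case-insensitive).
#' @return character vector of flagged accessions.
#' @export
flag_for_review <- function(db, patterns = c("Fragment", "Uncharacterized", "Predicted")) {
  desc <- tolower(ifelse(is.na(db$description), "", db$description))
  hit <- Reduce(`|`, lapply(tolower(patterns), function(p) grepl(p, desc, fixed = TRUE)),
                init = rep(FALSE, nrow(db)))
  db$accession[hit]
}
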