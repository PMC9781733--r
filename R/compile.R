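#' Compile a curated non-redundant database
#'
#' The end-to-end curation workflow:
#' 1. storage-protein keyword exclusion on the stage-a (reviewed seed)
#'    queries;
#' 2. per-query homolog search over the pool (or ingested BLAST hits),
#'    cluster assembly and within-cluster redundancy elimination;
#' 3. stage-b: each cross-species homologue query is mapped to its best
#'    same-organism pool entry, which is then treated as a new query and
#'    given the same per-query treatment;
#' 4. merge of all retained members, cross-cluster deduplication first by
#'    accession then by exact sequence (reviewed, then lexicographically
#'    earlier accession wins; the loser is recorded in the winner's
#'    `collected_accessions`);
#' 5. report and annotation table.
#'
#' @param stage_a_queries reviewed seed record table.
#' @param pool unreviewed candidate record table.
#' @param stage_b_homologue_queries optional record table of
#'   cross-species homologue queries.
#' @param config a [run_config()] list (identity threshold, max hits,
#'   keywords, organism filter, ...).
#' @param blast_hits optional pre-computed hit table
#'   ([hits_from_blast()] format, all queries mixed); when given, the
#'   built-in search is skipped for queries present in it.
#' @param family_map optional named vector accession -> family label.
#' @return a `curation_result`: list with `records` (kept, curated
#'   order), `report` (counts, per-cluster rows, flagged accessions) and
#'   `annotation` (one row per kept record). The report satisfies
#'   `n_kept + n_discarded = n_compared`.
#' @export
compile_database <- function(stage_a_queries, pool,
                             stage_b_homologue_queries = NULL,
                             config = run_config(),
                             blast_hits = NULL,
                             family_map = NULL) {
  validate_protein_db(stage_a_queries)
  validate_protein_db(pool)
  collide <- intersect(stage_a_queries$accession, pool$accession)
  for (acc in collide) {
    if (!identical(stage_a_queries$sequence[stage_a_queries$accession == acc],
                   pool$sequence[pool$accession == acc])) {
      stop(sprintf("query accession '%s' collides with a pool entry of different sequence", acc))
    }
  }
  filt <- exclude_by_keywords(stage_a_queries, config$keywords)
  queries <- filt$kept

  # stage-b: map each homologue query onto the organism of interest,
  # then treat the mapped entries as new queries
  if (!is.null(stage_b_homologue_queries) && nrow(stage_b_homologue_queries) > 0) {
    mapped <- lapply(seq_len(nrow(stage_b_homologue_queries)), function(i) {
      map_homologue_to_wheat(stage_b_homologue_queries[i, , drop = FALSE], pool,
                             organism_filter = config$organism_filter,
                             min_identity = config$identity_min)
    })
    mapped <- do.call(rbind, mapped[!vapply(mapped, is.null, logical(1))])
    if (!is.null(mapped)) {
      mapped <- mapped[!duplicated(mapped$accession), , drop = FALSE]
      mapped <- mapped[!(mapped$accession %in% queries$accession), , drop = FALSE]
      queries <- rbind(queries, mapped)
    }
  }

  clusters <- vector("list", nrow(queries))
  for (i in seq_len(nrow(queries))) {
    q <- queries[i, , drop = FALSE]
    hits <- if (!is.null(blast_hits) && q$accession %in% blast_hits$query_acc) {
      blast_hits[blast_hits$query_acc == q$accession, , drop = FALSE]
    } else {
      search_pool(q, pool, min_identity = config$identity_min,
                  max_hits = config$max_hits,
                  organism_filter = config$organism_filter)
    }
    cl <- build_cluster(q, hits, pool, family_map = family_map)
    clusters[[i]] <- deduplicate_cluster(cl, min_identity = config$identity_min)
  }

  all_members <- unique(unlist(lapply(clusters, function(cl) {
    c(cl$members$accession, vapply(cl$discards, function(v) v$candidate_acc, character(1)))
  })))
  verdict_of <- list()     # first verdict seen per discarded accession
  absorbed_by <- list()    # discarded accession -> reference accession
  for (cl in clusters) {
    for (v in cl$discards) {
      if (is.null(verdict_of[[v$candidate_acc]])) {
        verdict_of[[v$candidate_acc]] <- v$verdict
        absorbed_by[[v$candidate_acc]] <- v$reference_acc
      }
    }
  }

  # merge retained members, deduplicating by accession
  kept <- do.call(rbind, lapply(clusters, `[[`, "members"))
  fam_of <- unlist(lapply(clusters, function(cl)
    setNames(rep(cl$family_label, nrow(cl$members)), cl$members$accession)))
  kept <- kept[!duplicated(kept$accession), , drop = FALSE]
  # ...then by exact sequence: reviewed first, then accession ascending wins
  ord <- order(kept$db_section != "reviewed", kept$accession)
  kept <- kept[ord, , drop = FALSE]
  dup_seq <- duplicated(kept$sequence)
  for (i in which(dup_seq)) {
    winner <- kept$accession[match(kept$sequence[i], kept$sequence)]
    verdict_of[[kept$accession[i]]] <- "duplicate"
    absorbed_by[[kept$accession[i]]] <- winner
  }
  kept <- kept[!dup_seq, , drop = FALSE]
  kept <- kept[order(kept$accession), , drop = FALSE]
  # an accession retained in one cluster but discarded in another stays
  # kept; drop any stale verdict bookkeeping for it
  for (acc in kept$accession) {
    verdict_of[[acc]] <- NULL
    absorbed_by[[acc]] <- NULL
  }

  n_compared <- length(all_members)
  n_kept <- nrow(kept)
  discarded_accs <- setdiff(all_members, kept$accession)
  cats <- vapply(discarded_accs, function(a) {
    v <- verdict_of[[a]]
    if (is.null(v)) "duplicate" else v
  }, character(1))
  by_cat <- table(factor(cats, levels = c("duplicate", "fragment",
                                          "redundant_precursor_only")))

  # trace each discarded accession to the kept representative absorbing it
  absorbing <- setNames(rep(NA_character_, length(discarded_accs)), discarded_accs)
  for (a in discarded_accs) {
    ref <- absorbed_by[[a]]
    seen <- a
    while (!is.null(ref) && !(ref %in% kept$accession) && !(ref %in% seen)) {
      seen <- c(seen, ref)
      ref <- absorbed_by[[ref]]
    }
    if (!is.null(ref) && ref %in% kept$accession) absorbing[a] <- ref
  }

  collected <- lapply(kept$accession, function(acc)
    sort(names(absorbing)[!is.na(absorbing) & absorbing == acc]))
  annotation <- data.frame(
    accession = kept$accession,
    description = kept$description,
    organism = kept$organism,
    gene = kept$gene,
    status = ifelse(kept$is_fragment, "fragment", "complete"),
    protein_family = unname(fam_of[kept$accession]),
    allergen_name = NA_character_,
    last_update = NA_character_,
    stringsAsFactors = FALSE
  )
  annotation$collected_accessions <- collected

  per_cluster <- data.frame(
    query_acc = vapply(clusters, `[[`, character(1), "query_acc"),
    family_label = vapply(clusters, `[[`, character(1), "family_label"),
    n_members = vapply(clusters, function(cl) nrow(cl$members), integer(1)),
    n_discarded = vapply(clusters, function(cl) length(cl$discards), integer(1)),
    stringsAsFactors = FALSE
  )

  report <- list(
    n_compared = n_compared,
    n_kept = n_kept,
    n_discarded = n_compared - n_kept,
    discards_by_category = as.list(by_cat),
    per_cluster = per_cluster,
    flagged_for_review = flag_for_review(kept),
    keyword_removed = filt$removed$accession
  )
  structure(list(records = kept, report = report, annotation = annotation,
                 clusters = clusters),
            class = "curation_result")
}

#' @export
print.curation_result <- function(x, ...) {
  r <- x$report
  cat(sprintf("curated database: %d kept of %d compared (%d discarded)\n",
              r$n_kept, r$n_compared, r$n_discarded))
  cat(sprintf("  discards: %s\n",
              paste(sprintf("%s=%d", names(r$discards_by_category),
                            unlist(r$discards_by_category)), collapse = ", ")))
  if (length(r$flagged_for_review))
    cat("  flagged for review:", paste(r$flagged_for_review, collapse = ", "), "\n")
  invisible(x)
}
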