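#' Venn comparison of two final protein lists
#'
#' @param result_a,result_b `inference_result` objects (or character
#'   vectors of accessions).
#' @return a `venn_comparison`: list with disjoint sets `only_a`,
#'   `only_b`, `common`.
#' @export
compare_searches <- function(result_a, result_b) {
  a <- if (inherits(result_a, "inference_result")) result_a$final else as.character(result_a)
  b <- if (inherits(result_b, "inference_result")) result_b$final else as.character(result_b)
  a <- unique(a); b <- unique(b)
  structure(list(only_a = sort(setdiff(a, b)),
                 only_b = sort(setdiff(b, a)),
                 common = sort(intersect(a, b))),
            class = "venn_comparison")
}

#' @export
print.venn_comparison <- function(x, ...) {
  cat(sprintf("venn: %d only in A, %d common, %d only in B\n",
              length(x$only_a), length(x$common), length(x$only_b)))
  invisible(x)
}

#' Explain why a protein is absent from the other search's final list
#'
#' Inspects the other search's database and per-replicate group
#' statuses:
#' * `absent_from_database` — no record with that accession was
#'   searched;
#' * `subset_of_top_protein` — its group's peptides were a strict subset
#'   of another group's (parsimony case a);
#' * `intersection_protein` — covered by the union of other groups with
#'   no unique peptide (parsimony case b);
#' * `insufficient_peptides` — fewer matched peptides than required (or
#'   none at all);
#' * `no_unique_peptide` — enough peptides but none unique;
#' * `failed_replicate_consensus` — reported in some replicates but
#'   fewer than the consensus minimum.
#'
#' @param accession the protein to explain.
#' @param other_result the `inference_result` of the search it is
#'   missing from.
#' @param other_database the record table that search used.
#' @return an `absence_explanation`: list with `accession`, `reason`,
#'   `supporting_group` (group id, when a discarding group exists),
#'   `replicates_reported`.
#' @export
explain_absence <- function(accession, other_result, other_database) {
  mk <- function(reason, group = NA_character_, reps = 0L) {
    structure(list(accession = accession, reason = reason,
                   supporting_group = group, replicates_reported = reps),
              class = "absence_explanation")
  }
  if (!accession %in% other_database$accession) {
    return(mk("absent_from_database"))
  }
  n_reported <- 0L
  statuses <- character(0)
  support <- NA_character_
  for (r in names(other_result$groups)) {
    g <- other_result$groups[[r]]
    idx <- which(vapply(g$member_accs, function(m) accession %in% m, logical(1)))
    if (!length(idx)) next
    st <- g$status[idx[1]]
    if (st == "reported") {
      n_reported <- n_reported + 1L
    } else {
      statuses <- c(statuses, st)
      if (is.na(support)) support <- g$group_id[idx[1]]
    }
  }
  min_rep <- other_result$settings$min_replicates
  if (n_reported >= min_rep) {
    stop(sprintf("'%s' is in the other search's consensus; nothing to explain", accession))
  }
  if (n_reported > 0) {
    return(mk("failed_replicate_consensus", support, n_reported))
  }
  if (!length(statuses)) {
    # present in the database but matched by no peptide group at all
    return(mk("insufficient_peptides"))
  }
  # most frequent non-reported status across replicates decides
  st <- names(sort(table(statuses), decreasing = TRUE))[1]
  reason <- switch(st,
                   subset_discarded = "subset_of_top_protein",
                   intersection_discarded = "intersection_protein",
                   failed_min_peptides = "insufficient_peptides",
                   failed_no_unique = "no_unique_peptide",
                   "insufficient_peptides")
  mk(reason, support, n_reported)
}

#' @export
print.absence_explanation <- function(x, ...) {
  cat(sprintf("%s: %s", x$accession, x$reason))
  if (!is.na(x$supporting_group)) cat(sprintf(" (group %s)", x$supporting_group))
  cat("\n")
  invisible(x)
}
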