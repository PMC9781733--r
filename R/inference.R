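# A peptide occurrence is "tryptic" when its upstream boundary is the
# protein start or follows K/R not before P, and its downstream boundary
# is the protein end or a K/R cut not before P.
.tryptic_occurrence <- function(protein_seq, pos, pep_len) {
  n <- nchar(protein_seq)
  end <- pos + pep_len - 1L
  up_ok <- pos == 1L ||
    (substr(protein_seq, pos - 1L, pos - 1L) %in% c("K", "R") &&
       substr(protein_seq, pos, pos) != "P")
  down_ok <- end == n ||
    (substr(protein_seq, end, end) %in% c("K", "R") &&
       substr(protein_seq, end + 1L, end + 1L) != "P")
  up_ok && down_ok
}

.find_occurrences <- function(pattern, subject) {
  hits <- gregexpr(pattern, subject, fixed = TRUE)[[1]]
  if (hits[1] == -1) integer(0) else as.integer(hits)
}

#' Map peptides onto the proteins of a searched database
#'
#' A peptide maps to a protein iff it occurs as a contiguous substring
#' with tryptic boundaries on both sides (or anywhere, when
#' `require_tryptic = FALSE`). Uniqueness is computed against the
#' protein *groups* of the whole database (see [group_proteins()]): a
#' peptide is unique iff all its proteins fall into a single group.
#'
#' @param peptides character vector of peptide sequences.
#' @param database protein record table.
#' @param require_tryptic enforce tryptic boundaries (default TRUE).
#' @param il_equivalent fold I and L together before matching (default
#'   FALSE: high-resolution search engines distinguish them
#'   spectrally).
#' @return data.frame with `peptide`, `protein_accs` (list column),
#'   `n_proteins`, `is_unique`.
#' @export
map_peptides <- function(peptides, database, require_tryptic = TRUE,
                         il_equivalent = FALSE) {
  peptides <- unique(toupper(peptides))
  bad <- !.valid_sequence(peptides)
  if (any(bad)) {
    stop(sprintf("peptide with non-amino-acid letters: '%s'", peptides[which(bad)[1]]))
  }
  fold <- function(x) if (il_equivalent) gsub("I", "L", x, fixed = TRUE) else x
  seqs <- fold(database$sequence)
  accs <- database$accession
  assignments <- lapply(peptides, function(p) {
    pf <- fold(p)
    hit <- character(0)
    for (k in seq_along(seqs)) {
      occ <- .find_occurrences(pf, seqs[k])
      if (!length(occ)) next
      if (!require_tryptic ||
          any(vapply(occ, function(pos) .tryptic_occurrence(seqs[k], pos, nchar(pf)), logical(1)))) {
        hit <- c(hit, accs[k])
      }
    }
    sort(hit)
  })
  out <- data.frame(peptide = peptides, stringsAsFactors = FALSE)
  out$protein_accs <- assignments
  out$n_proteins <- lengths(assignments)
  groups <- group_proteins(out, database)
  group_of <- list()
  for (i in seq_len(nrow(groups))) {
    for (a in groups$member_accs[[i]]) group_of[[a]] <- groups$group_id[i]
  }
  out$is_unique <- vapply(seq_len(nrow(out)), function(i) {
    gs <- unique(unlist(group_of[out$protein_accs[[i]]]))
    length(gs) == 1
  }, logical(1))
  out
}

#' Group proteins that share an identical peptide set
#'
#' Proteins matched by exactly the same peptides cannot be
#' differentiated by the observed data and are merged into one group.
#' The group representative ("top protein") is the reviewed member if
#' any, else the lexicographically smallest accession. Proteins with no
#' matched peptide are dropped.
#'
#' @param assignments peptide-to-protein table from [map_peptides()]
#'   (only `peptide` and `protein_accs` are used).
#' @param database optional record table providing reviewed status for
#'   the top-protein tie-break.
#' @return data.frame with `group_id`, `top_protein`, `member_accs`,
#'   `peptides`, `unique_peptides` (list columns), `n_peptides`,
#'   `n_unique`, `status` (`"candidate"`).
#' @export
group_proteins <- function(assignments, database = NULL) {
  prot_peps <- list()
  for (i in seq_len(nrow(assignments))) {
    for (a in assignments$protein_accs[[i]]) {
      prot_peps[[a]] <- c(prot_peps[[a]], assignments$peptide[i])
    }
  }
  if (!length(prot_peps)) {
    return(data.frame(group_id = character(0), top_protein = character(0),
                      n_peptides = integer(0), n_unique = integer(0),
                      status = character(0),
                      member_accs = I(list()), peptides = I(list()),
                      unique_peptides = I(list()), stringsAsFactors = FALSE))
  }
  prot_peps <- lapply(prot_peps, function(x) sort(unique(x)))
  keys <- vapply(prot_peps, paste, character(1), collapse = "\x1f")
  member_sets <- split(names(prot_peps), keys)
  reviewed <- if (!is.null(database)) {
    setNames(database$db_section == "reviewed", database$accession)
  } else NULL
  tops <- vapply(member_sets, function(members) {
    members <- sort(members)
    if (!is.null(reviewed)) {
      rev_members <- members[!is.na(reviewed[members]) & reviewed[members]]
      if (length(rev_members)) return(rev_members[1])
    }
    members[1]
  }, character(1))
  ord <- order(tops)
  member_sets <- member_sets[ord]
  tops <- tops[ord]
  peps <- lapply(member_sets, function(m) prot_peps[[m[1]]])
  groups <- data.frame(group_id = paste0("G", seq_along(tops)),
                       top_protein = unname(tops),
                       stringsAsFactors = FALSE)
  groups$member_accs <- lapply(member_sets, sort)
  groups$peptides <- peps
  # a peptide is unique to a group when it occurs in no other group
  pep_groups <- list()
  for (i in seq_len(nrow(groups))) {
    for (p in groups$peptides[[i]]) pep_groups[[p]] <- c(pep_groups[[p]], i)
  }
  groups$unique_peptides <- lapply(seq_len(nrow(groups)), function(i) {
    ps <- groups$peptides[[i]]
    ps[vapply(ps, function(p) length(unique(pep_groups[[p]])) == 1, logical(1))]
  })
  groups$n_peptides <- lengths(groups$peptides)
  groups$n_unique <- lengths(groups$unique_peptides)
  groups$status <- "candidate"
  rownames(groups) <- NULL
  groups
}

#' Apply Occam's razor to a set of protein groups
#'
#' Sets the parsimony status of every group:
#' * a group whose peptide set is a strict subset of another single
#'   group's set becomes `subset_discarded` (no independent evidence);
#' * a group with no unique peptide whose set is covered by the union of
#'   the other non-discarded groups' sets — but is not a strict subset
#'   of any single one — becomes `intersection_discarded`;
#' * all other groups remain `candidate`.
#'
#' Subset discards are determined first (simultaneously: the strict
#' superset always survives). Intersection candidates are then examined
#' from the smallest peptide set upwards, each against the groups still
#' standing, so that mutually covering cycles cannot discard each other
#' and every peptide remains covered by at least one non-discarded
#' group — the defining property of a minimal explanatory list.
#'
#' @param groups data.frame from [group_proteins()].
#' @return the groups with `status` updated.
#' @export
apply_parsimony <- function(groups) {
  n <- nrow(groups)
  if (n == 0) return(groups)
  peps <- groups$peptides
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      if (length(peps[[i]]) < length(peps[[j]]) && all(peps[[i]] %in% peps[[j]])) {
        groups$status[i] <- "subset_discarded"
        break
      }
    }
  }
  for (i in order(lengths(peps), seq_len(n))) {
    if (groups$status[i] != "candidate" || groups$n_unique[i] > 0) next
    standing <- setdiff(which(groups$status %in% c("candidate")), i)
    others <- unique(unlist(peps[standing]))
    if (length(peps[[i]]) && all(peps[[i]] %in% others)) {
      groups$status[i] <- "intersection_discarded"
    }
  }
  groups
}

#' Acceptance rules for one replicate's report
#'
#' A candidate group is reported when (i) it holds at least
#' `min_peptides` matched peptides and (ii) at least one of them is
#' unique to the group. Failing groups get status `failed_min_peptides`
#' or `failed_no_unique`.
#'
#' @param groups data.frame from [apply_parsimony()] (or directly from
#'   [group_proteins()]).
#' @param min_peptides minimum peptide count (default 2).
#' @param require_unique require a unique peptide (default TRUE).
#' @return list with `groups` (statuses finalised) and `reported`
#'   (character vector of top-protein accessions).
#' @export
accept_proteins <- function(groups, min_peptides = 2, require_unique = TRUE) {
  for (i in seq_len(nrow(groups))) {
    if (groups$status[i] != "candidate") next
    if (groups$n_peptides[i] < min_peptides) {
      groups$status[i] <- "failed_min_peptides"
    } else if (require_unique && groups$n_unique[i] == 0) {
      groups$status[i] <- "failed_no_unique"
    } else {
      groups$status[i] <- "reported"
    }
  }
  list(groups = groups, reported = groups$top_protein[groups$status == "reported"])
}

#' Replicate consensus over per-replicate reports
#'
#' @param per_replicate_reports list of character vectors (one reported
#'   accession list per replicate).
#' @param min_replicates minimum number of replicates an accession must
#'   be reported in (default 2, i.e. the 2-of-3 rule).
#' @return sorted character vector of consensus accessions.
#' @export
replicate_consensus <- function(per_replicate_reports, min_replicates = 2) {
  counts <- table(unlist(lapply(per_replicate_reports, unique)))
  if (!length(counts)) return(character(0))
  sort(names(counts)[counts >= min_replicates])
}

#' Strip modification notation from peptide strings
#'
#' Search-engine exports often decorate peptides with in-line
#' modification masses, e.g. `"PEPT(+15.99)IDE"`. Mapping works on the
#' bare sequence.
#' @param peptides character vector.
#' @param pattern regular expression removed before mapping.
#' @return bare uppercase peptide strings.
#' @export
strip_modifications <- function(peptides, pattern = "\\([^)]*\\)|\\[[^]]*\\]") {
  toupper(gsub(pattern, "", peptides))
}

#' Run the full inference pipeline on a PSM table
#'
#' Target-decoy q-value filtering of the pooled table, then per
#' replicate: peptide-to-protein mapping, grouping, parsimony and the
#' acceptance rules; finally the replicate consensus.
#'
#' @param psms PSM data.frame (`peptide`, `score`, `replicate_id`,
#'   `is_decoy`).
#' @param database protein record table that was searched.
#' @param settings a [run_config()] list (`q_threshold`, `min_peptides`,
#'   `min_replicates`, `require_tryptic`, `il_equivalent`,
#'   `mod_pattern`).
#' @return an `inference_result`: list with `groups` (named list of
#'   per-replicate group tables), `reports` (per-replicate accession
#'   vectors), `final` (consensus accessions), `accepted_psms`,
#'   `settings`. Deterministic given inputs and settings.
#' @export
run_inference <- function(psms, database, settings = run_config()) {
  validate_protein_db(database)
  if (nrow(psms) == 0) {
    return(structure(list(groups = list(), reports = list(), final = character(0),
                          accepted_psms = psms, settings = settings),
                     class = "inference_result"))
  }
  psms$peptide <- strip_modifications(psms$peptide, settings$mod_pattern)
  accepted <- filter_psms_by_fdr(psms, q_threshold = settings$q_threshold)
  replicates <- sort(unique(as.character(accepted$replicate_id)))
  groups <- list()
  reports <- list()
  for (r in replicates) {
    peps <- unique(accepted$peptide[accepted$replicate_id == r])
    assignments <- map_peptides(peps, database,
                                require_tryptic = settings$require_tryptic,
                                il_equivalent = settings$il_equivalent)
    g <- group_proteins(assignments, database)
    g <- apply_parsimony(g)
    acc <- accept_proteins(g, min_peptides = settings$min_peptides,
                           require_unique = settings$require_unique)
    groups[[r]] <- acc$groups
    reports[[r]] <- acc$reported
  }
  final <- replicate_consensus(reports, min_replicates = settings$min_replicates)
  structure(list(groups = groups, reports = reports, final = final,
                 accepted_psms = accepted, settings = settings),
            class = "inference_result")
}

#' @export
print.inference_result <- function(x, ...) {
  cat(sprintf("inference result: %d replicate(s), %d consensus protein(s)\n",
              length(x$reports), length(x$final)))
  for (r in names(x$reports)) {
    cat(sprintf("  replicate %s: %d reported\n", r, length(x$reports[[r]])))
  }
  invisible(x)
}

#' Write an inference result as JSON lines
#'
#' One JSON object per protein group per replicate (`replicate`,
#' `group_id`, `top_protein`, `members`, `peptides`, `unique_peptides`,
#' `status`), followed by one object with the final consensus list.
#'
#' @param result an `inference_result`.
#' @param path output file.
#' @return the lines, invisibly.
#' @export
write_inference_report <- function(result, path) {
  lines <- character(0)
  for (r in names(result$groups)) {
    g <- result$groups[[r]]
    for (i in seq_len(nrow(g))) {
      lines <- c(lines, jsonlite::toJSON(list(
        replicate = r, group_id = g$group_id[i], top_protein = g$top_protein[i],
        members = g$member_accs[[i]], peptides = g$peptides[[i]],
        unique_peptides = g$unique_peptides[[i]], status = g$status[i]
      ), auto_unbox = TRUE))
    }
  }
  lines <- c(lines, jsonlite::toJSON(list(final = result$final,
                                          min_replicates = result$settings$min_replicates),
                                     auto_unbox = TRUE))
  writeLines(lines, path)
  invisible(lines)
}

#' Read an inference report written by [write_inference_report()]
#'
#' Reconstructs the group tables and final list (enough to drive
#' [compare_searches()] and [explain_absence()]).
#' @param path JSON-lines file.
#' @return an `inference_result` (without `accepted_psms`).
#' @export
read_inference_report <- function(path) {
  lines <- readLines(path, warn = FALSE)
  objs <- lapply(lines, jsonlite::fromJSON)
  is_final <- vapply(objs, function(o) !is.null(o$final) || !is.null(o$min_replicates), logical(1))
  final_obj <- if (any(is_final)) objs[[which(is_final)[1]]] else list(final = character(0))
  rows <- objs[!is_final]
  groups <- list()
  reports <- list()
  for (o in rows) {
    r <- as.character(o$replicate)
    row <- data.frame(group_id = o$group_id, top_protein = o$top_protein,
                      stringsAsFactors = FALSE)
    row$member_accs <- list(as.character(o$members))
    row$peptides <- list(as.character(o$peptides))
    row$unique_peptides <- list(as.character(unlist(o$unique_peptides)))
    row$n_peptides <- length(o$peptides)
    row$n_unique <- length(unlist(o$unique_peptides))
    row$status <- o$status
    groups[[r]] <- rbind(groups[[r]], row)
  }
  for (r in names(groups)) {
    reports[[r]] <- groups[[r]]$top_protein[groups[[r]]$status == "reported"]
  }
  settings <- run_config()
  if (!is.null(final_obj$min_replicates)) settings$min_replicates <- final_obj$min_replicates
  structure(list(groups = groups, reports = reports,
                 final = sort(as.character(unlist(final_obj$final))),
                 settings = settings),
            class = "inference_result")
}
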