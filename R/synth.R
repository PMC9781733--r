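.local_seed <- function(seed) {
  if (!is.null(seed)) set.seed(as.integer(seed) %% .Machine$integer.max)
}

#' Random protein sequence
#'
#' Residues drawn i.i.d. from a background composition (uniform over the
#' 20 standard residues by default). Uses R's global RNG; pass `seed`
#' for a self-contained deterministic draw.
#'
#' @param length sequence length (>= 1).
#' @param composition optional named probability vector over residues.
#' @param seed optional integer seed.
#' @return an uppercase sequence string.
#' @export
random_protein <- function(length, composition = NULL, seed = NULL) {
  if (length < 1) stop("random_protein: length must be >= 1")
  .local_seed(seed)
  prob <- if (is.null(composition)) NULL else composition[AA_LETTERS]
  paste(sample(AA_LETTERS, length, replace = TRUE, prob = prob), collapse = "")
}

.mutate_positions <- function(sequence, positions) {
  chars <- strsplit(sequence, "")[[1]]
  for (p in positions) {
    chars[p] <- sample(setdiff(AA_LETTERS, chars[p]), 1)
  }
  paste(chars, collapse = "")
}

#' Generate one synthetic protein family with planted redundancy
#'
#' Starting from a seed sequence, emits a reviewed parent plus
#' unreviewed children of each planted category: exact duplicates,
#' contiguous fragments (length >= 30% of the parent), precursor
#' variants (mutations confined to the signal region, mature region
#' identical) and mature-region variants (point mutations at
#' `mutation_rate`). Ground-truth labels are recorded so downstream
#' classification can be scored exactly. With `mutation_rate = 0` a
#' "variant" carries no change and is labelled a duplicate instead.
#'
#' @param seed_seq parent amino-acid sequence (longer than
#'   `signal_len`).
#' @param family_id short string used to build accessions
#'   (`<family_id>P` parent, `<family_id>D1` ... children).
#' @param n_duplicates,n_fragments,n_precursor_variants,n_variants
#'   planted counts.
#' @param mutation_rate per-residue substitution probability in the
#'   mature region of variants (default 0.02).
#' @param signal_len signal-peptide length; the parent's `mature_start`
#'   is `signal_len + 1` (default 20).
#' @param organism organism string stamped on every member.
#' @param seed optional integer seed.
#' @return list with `records` (protein table, parent first) and
#'   `truth` (data.frame `accession`, `label`, `parent`), where `label`
#'   is one of `seed`, `duplicate_of`, `fragment_of`,
#'   `precursor_variant_of`, `variant_of`.
#' @export
make_family <- function(seed_seq, family_id,
                        n_duplicates = 2, n_fragments = 1,
                        n_precursor_variants = 1, n_variants = 2,
                        mutation_rate = 0.02, signal_len = 20,
                        organism = "Triticum aestivum", seed = NULL) {
  .local_seed(seed)
  seed_seq <- toupper(seed_seq)
  n <- nchar(seed_seq)
  stopifnot(n > signal_len + 10)
  parent_acc <- paste0(family_id, "P")
  recs <- protein_db(parent_acc, seed_seq, db_section = "reviewed",
                     entry_name = paste0(family_id, "_WHEAT"),
                     description = paste("synthetic family", family_id, "parent"),
                     organism = organism,
                     mature_start = if (n_precursor_variants > 0 || signal_len > 0)
                       signal_len + 1L else NA_integer_)
  truth <- data.frame(accession = parent_acc, label = "seed", parent = NA_character_,
                      stringsAsFactors = FALSE)
  add <- function(acc, sequence, label, mature_start = NA_integer_) {
    rec <- protein_db(acc, sequence, db_section = "unreviewed",
                      description = paste("synthetic family", family_id, label),
                      organism = organism, mature_start = mature_start)
    recs <<- rbind(recs, rec)
    truth <<- rbind(truth, data.frame(accession = acc, label = label,
                                      parent = parent_acc, stringsAsFactors = FALSE))
  }
  for (k in seq_len(n_duplicates)) {
    add(paste0(family_id, "D", k), seed_seq, "duplicate_of")
  }
  for (k in seq_len(n_fragments)) {
    min_len <- max(2L, ceiling(0.3 * n))
    len <- sample(min_len:(n - 1L), 1)
    start <- sample(seq_len(n - len + 1L), 1)
    add(paste0(family_id, "F", k), substr(seed_seq, start, start + len - 1L), "fragment_of")
  }
  for (k in seq_len(n_precursor_variants)) {
    n_mut <- sample(1:min(3L, signal_len), 1)
    pos <- sample(seq_len(signal_len), n_mut)
    add(paste0(family_id, "S", k), .mutate_positions(seed_seq, pos),
        "precursor_variant_of", mature_start = signal_len + 1L)
  }
  for (k in seq_len(n_variants)) {
    mature_pos <- (signal_len + 1L):n
    mutate <- mature_pos[stats::runif(length(mature_pos)) < mutation_rate]
    if (mutation_rate > 0 && length(mutate) == 0) mutate <- sample(mature_pos, 1)
    if (length(mutate) == 0) {
      add(paste0(family_id, "V", k), seed_seq, "duplicate_of")
    } else {
      add(paste0(family_id, "V", k), .mutate_positions(seed_seq, mutate), "variant_of")
    }
  }
  list(records = recs, truth = truth)
}

#' Assemble a shuffled synthetic pool
#'
#' Union of family members and unrelated random proteins, shuffled.
#' Unrelated entries get synthetic accessions (`SYN00001`, ...).
#'
#' @param families list of [make_family()] results.
#' @param n_unrelated number of unrelated random proteins.
#' @param length_range lengths of unrelated proteins (uniform draw).
#' @param organism organism string for unrelated entries.
#' @param seed optional integer seed.
#' @return list with `records` and `truth` (unrelated entries labelled
#'   `"unrelated"`).
#' @export
make_pool <- function(families, n_unrelated = 20, length_range = c(150, 400),
                      organism = "Triticum aestivum", seed = NULL) {
  .local_seed(seed)
  recs <- do.call(rbind, lapply(families, `[[`, "records"))
  truth <- do.call(rbind, lapply(families, `[[`, "truth"))
  if (is.null(recs)) recs <- .empty_protein_db()
  if (n_unrelated > 0) {
    lens <- sample(length_range[1]:length_range[2], n_unrelated, replace = TRUE)
    un <- protein_db(sprintf("SYN%05d", seq_len(n_unrelated)),
                     vapply(lens, function(L) random_protein(L), character(1)),
                     db_section = "unreviewed",
                     description = "synthetic unrelated protein",
                     organism = organism)
    recs <- rbind(recs, un)
    truth <- rbind(truth, data.frame(accession = un$accession, label = "unrelated",
                                     parent = NA_character_, stringsAsFactors = FALSE))
  }
  idx <- sample(nrow(recs))
  list(records = recs[idx, , drop = FALSE], truth = truth)
}

#' Simulate replicate-structured PSM tables with decoys
#'
#' Emulates what a database search engine exports for a multi-replicate
#' shotgun run: for each true protein, its tryptic peptides are detected
#' in each replicate with probability `detect_prob` and scored from the
#' target score distribution; decoy PSMs carry peptides digested from
#' the reversed database sequences and low scores; optional noise PSMs
#' are false target matches (random peptides absent from the database)
#' scored like decoys, so realised FDR can be measured.
#'
#' @param true_accessions accessions of the proteins present in the
#'   sample.
#' @param database protein record table that will be searched.
#' @param n_replicates number of LC-MS/MS replicates (default 3).
#' @param detect_prob per-peptide per-replicate detection probability
#'   (default 0.8).
#' @param n_decoys decoy PSMs per replicate (default 50).
#' @param n_noise false-target PSMs per replicate (default 0).
#' @param target_score,decoy_score `c(mean, sd)` of the normal score
#'   distributions (defaults 35/5 and 10/5: well separated, as a tuned
#'   search-engine score threshold achieves).
#' @param max_missed,min_len,max_len digestion parameters (defaults 1,
#'   6, 30).
#' @param seed optional integer seed.
#' @return list with `psms` (PSM data.frame; decoy and noise rows
#'   flagged in `truth`), and `truth` (list: `true_proteins`,
#'   `peptide_origin` map, `noise_peptides`).
#' @export
simulate_psms <- function(true_accessions, database, n_replicates = 3,
                          detect_prob = 0.8, n_decoys = 50, n_noise = 0,
                          target_score = c(35, 5), decoy_score = c(10, 5),
                          max_missed = 1, min_len = 6, max_len = 30,
                          seed = NULL) {
  .local_seed(seed)
  validate_protein_db(database)
  stopifnot(all(true_accessions %in% database$accession))
  digest_of <- function(s) digest_tryptic(s, max_missed = max_missed,
                                          min_len = min_len, max_len = max_len)$peptide
  target_peps <- unique(unlist(lapply(
    database$sequence[database$accession %in% true_accessions], digest_of)))
  all_db_peps <- unique(unlist(lapply(database$sequence, digest_of)))
  peptide_origin <- lapply(setNames(target_peps, target_peps), function(p) {
    database$accession[vapply(database$sequence, function(s)
      is_exact_subsequence(p, s)$found, logical(1))]
  })
  decoy_pool <- setdiff(unique(unlist(lapply(
    vapply(database$sequence, function(s)
      paste(rev(strsplit(s, "")[[1]]), collapse = ""), character(1)),
    digest_of))), all_db_peps)
  rows <- list()
  noise_peps <- character(0)
  for (r in seq_len(n_replicates)) {
    detected <- target_peps[stats::runif(length(target_peps)) < detect_prob]
    if (length(detected)) {
      rows[[length(rows) + 1]] <- data.frame(
        peptide = detected,
        score = stats::rnorm(length(detected), target_score[1], target_score[2]),
        replicate_id = as.character(r), is_decoy = FALSE,
        spectrum_id = sprintf("R%d_T%04d", r, seq_along(detected)),
        stringsAsFactors = FALSE)
    }
    if (n_decoys > 0 && length(decoy_pool)) {
      dp <- sample(decoy_pool, min(n_decoys, length(decoy_pool)))
      rows[[length(rows) + 1]] <- data.frame(
        peptide = dp, score = stats::rnorm(length(dp), decoy_score[1], decoy_score[2]),
        replicate_id = as.character(r), is_decoy = TRUE,
        spectrum_id = sprintf("R%d_D%04d", r, seq_along(dp)),
        stringsAsFactors = FALSE)
    }
    if (n_noise > 0) {
      np <- vapply(seq_len(n_noise), function(i) {
        repeat {
          p <- random_protein(sample(min_len:max_len, 1))
          if (!p %in% all_db_peps) return(p)
        }
      }, character(1))
      noise_peps <- unique(c(noise_peps, np))
      rows[[length(rows) + 1]] <- data.frame(
        peptide = np, score = stats::rnorm(length(np), decoy_score[1], decoy_score[2]),
        replicate_id = as.character(r), is_decoy = FALSE,
        spectrum_id = sprintf("R%d_N%04d", r, seq_len(n_noise)),
        stringsAsFactors = FALSE)
    }
  }
  psms <- if (length(rows)) do.call(rbind, rows) else
    data.frame(peptide = character(0), score = numeric(0),
               replicate_id = character(0), is_decoy = logical(0),
               spectrum_id = character(0), stringsAsFactors = FALSE)
  list(psms = psms,
       truth = list(true_proteins = sort(unique(true_accessions)),
                    peptide_origin = peptide_origin,
                    noise_peptides = noise_peps))
}
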