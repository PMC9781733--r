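# Independent oracles and fixture builders used across the suite.

# Exhaustive global affine-gap alignment score by enumerating every
# monotone set of aligned column pairs (any residue pair may share a
# column); for each matching the cheapest arrangement groups the
# unaligned residues between consecutive pairs into one gap run per
# sequence. Independent of the DP implementation under test.
enum_global_score <- function(a, b, mat = blosum62_extended(),
                              gap_open = 11, gap_extend = 1) {
  A <- strsplit(a, "")[[1]]
  B <- strsplit(b, "")[[1]]
  na <- length(A)
  nb <- length(B)
  gapcost <- function(k) if (k > 0) gap_open + k * gap_extend else 0
  best <- -Inf
  rec <- function(i, j, acc) {
    total <- acc - gapcost(na - i) - gapcost(nb - j)
    if (total > best) best <<- total
    if (i < na && j < nb) {
      for (ii in (i + 1):na) {
        for (jj in (j + 1):nb) {
          rec(ii, jj, acc + mat[A[ii], B[jj]] - gapcost(ii - i - 1) - gapcost(jj - j - 1))
        }
      }
    }
  }
  rec(0L, 0L, 0)
  best
}

# Naive parsimony + acceptance classifier over per-group peptide sets:
# plain nested loops and set algebra, no shared code with the engine.
# Phase 1 marks strict subsets; phase 2 examines unique-less groups from
# the smallest set upwards against the groups still standing, so that
# mutually covering cycles cannot discard each other.
oracle_statuses <- function(pepsets, min_peptides = 2, require_unique = TRUE) {
  n <- length(pepsets)
  status <- rep("candidate", n)
  in_others <- function(p, skip) {
    for (j in seq_len(n)) {
      if (j != skip && p %in% pepsets[[j]]) return(TRUE)
    }
    FALSE
  }
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      if (all(pepsets[[i]] %in% pepsets[[j]]) &&
          !all(pepsets[[j]] %in% pepsets[[i]])) {
        status[i] <- "subset_discarded"
      }
    }
  }
  sizes <- vapply(pepsets, length, integer(1))
  for (i in order(sizes, seq_len(n))) {
    if (status[i] != "candidate") next
    uniques <- sum(!vapply(pepsets[[i]], in_others, logical(1), skip = i))
    if (uniques > 0) next
    covered <- TRUE
    for (p in pepsets[[i]]) {
      hit <- FALSE
      for (j in seq_len(n)) {
        if (j != i && status[j] == "candidate" && p %in% pepsets[[j]]) hit <- TRUE
      }
      if (!hit) covered <- FALSE
    }
    if (covered) status[i] <- "intersection_discarded"
  }
  for (i in seq_len(n)) {
    if (status[i] != "candidate") next
    uniques <- sum(!vapply(pepsets[[i]], in_others, logical(1), skip = i))
    if (length(pepsets[[i]]) < min_peptides) {
      status[i] <- "failed_min_peptides"
    } else if (require_unique && uniques == 0) {
      status[i] <- "failed_no_unique"
    } else {
      status[i] <- "reported"
    }
  }
  status
}

# Random protein-peptide membership instance (proteins with identical
# peptide sets are expected; empty proteins dropped as in the engine).
random_parsimony_instance <- function(n_prot_max = 6, n_pep_max = 12) {
  n_prot <- sample(2:n_prot_max, 1)
  n_pep <- sample(2:n_pep_max, 1)
  peps <- sprintf("PEP%02d", seq_len(n_pep))
  prots <- sprintf("PR%02d", seq_len(n_prot))
  assignments <- data.frame(peptide = peps, stringsAsFactors = FALSE)
  assignments$protein_accs <- lapply(seq_len(n_pep), function(i) {
    sort(sample(prots, sample(seq_len(n_prot), 1)))
  })
  assignments
}

# Random protein record table with optional fields present or absent,
# exercising the full FASTA header dialect.
random_record_db <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  alphabet <- c(rep(protcurate:::AA_LETTERS, 5), "U", "B", "Z", "X")
  seqs <- vapply(seq_len(n), function(i) {
    paste(sample(alphabet, sample(30:150, 1), replace = TRUE), collapse = "")
  }, character(1))
  maybe <- function(vals) ifelse(stats::runif(n) < 0.5, vals, NA)
  protein_db(
    accession = sprintf("RND%04d", seq_len(n)),
    sequence = seqs,
    db_section = sample(c("reviewed", "unreviewed"), n, replace = TRUE),
    entry_name = maybe(sprintf("RND%04d_WHEAT", seq_len(n))),
    description = maybe(sprintf("random test protein %d", seq_len(n))),
    organism = maybe(rep("Triticum aestivum", n)),
    taxon_id = as.integer(maybe(rep(4565L, n))),
    gene = maybe(sprintf("gene%d", seq_len(n)))
  )
}

# The standard development-scale curation fixture: four families, each
# planted with 2 duplicates, 1 fragment, 1 precursor variant and 2
# mature variants, on a background of 20 unrelated proteins.
curation_fixture <- function(seed = 42) {
  set.seed(seed)
  families <- lapply(1:4, function(i) {
    make_family(random_protein(sample(200:400, 1)), sprintf("FAM%02d", i),
                n_duplicates = 2, n_fragments = 1,
                n_precursor_variants = 1, n_variants = 2)
  })
  pool <- make_pool(families, n_unrelated = 20)
  queries <- do.call(rbind, lapply(families, function(f) f$records[1, , drop = FALSE]))
  list(families = families, pool = pool, queries = queries)
}

# Build an assignments table directly from a named list
# protein -> peptide vector (used for printed parsimony configurations).
assignments_from_sets <- function(sets) {
  peps <- sort(unique(unlist(sets)))
  assignments <- data.frame(peptide = peps, stringsAsFactors = FALSE)
  assignments$protein_accs <- lapply(peps, function(p) {
    sort(names(sets)[vapply(sets, function(s) p %in% s, logical(1))])
  })
  assignments
}
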