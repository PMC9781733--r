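test_that("keyword exclusion is a case-insensitive substring match on descriptions", {
  db <- protein_db(sprintf("P%d", 1:4), rep("MKWVTFISLLK", 4),
                   description = c("Glutenin, low molecular weight subunit",
                                   "ATP synthase subunit alpha",
                                   "AVENIN-like protein",
                                   "Alpha-gliadin"))
  res <- exclude_by_keywords(db)
  expect_equal(res$removed$accession, c("P1", "P3", "P4"))
  expect_equal(res$kept$accession, "P2")
  # order preserved; no keywords means nothing removed
  expect_equal(nrow(exclude_by_keywords(db, character(0))$removed), 0)
})

test_that("classify_redundancy reproduces the documented verdict cascade", {
  dup <- scenario_duplicate_pair()
  v <- classify_redundancy(dup$records[2, ], dup$records[1, ])
  expect_equal(v$verdict, "duplicate")

  frg <- scenario_fragment_pair()
  expect_equal(nchar(frg$records$sequence), c(236, 206))
  v <- classify_redundancy(frg$records[2, ], frg$records[1, ])
  expect_equal(v$verdict, "fragment")
  expect_equal(v$evidence$containment_position, 16L)

  pre <- scenario_precursor_pair()
  v <- classify_redundancy(pre$records[2, ], pre$records[1, ])
  expect_equal(v$verdict, "redundant_precursor_only")
  expect_equal(v$evidence$mismatch_positions, c(8L, 19L, 33L))
  expect_true(all(v$evidence$mismatch_positions < pre$mature_start))

  # one substitution inside the mature region -> a variant worth keeping
  seqs <- pre$records$sequence
  chars <- strsplit(seqs[1], "")[[1]]
  chars[100] <- setdiff(c("A", "C"), chars[100])[1]
  mut <- protein_db("MUT1", paste(chars, collapse = ""))
  v <- classify_redundancy(mut, pre$records[1, ])
  expect_equal(v$verdict, "variant_keep")
  expect_true(all(v$evidence$mismatch_positions >= pre$mature_start))

  # unrelated random sequences
  set.seed(4)
  u <- classify_redundancy(protein_db("U1", random_protein(150)),
                           protein_db("U2", random_protein(150)))
  expect_equal(u$verdict, "unrelated")
})

test_that("deduplicate_cluster retains the planted non-redundant members in any order", {
  pre <- scenario_precursor_pair()
  parent <- pre$records[1, ]
  dup <- protein_db("COPY1", parent$sequence)
  frag <- protein_db("FRAG1", substr(parent$sequence, 10, 150))
  chars <- strsplit(parent$sequence, "")[[1]]
  chars[120] <- setdiff(c("A", "C"), chars[120])[1]
  variant <- protein_db("VAR1", paste(chars, collapse = ""))
  members <- rbind(parent, dup, frag, variant, pre$records[2, ])
  cl <- structure(list(query_acc = parent$accession, family_label = "FAM_TEST",
                       members = members, discards = list()),
                  class = "family_cluster")
  dd <- deduplicate_cluster(cl)
  expect_setequal(dd$members$accession, c(parent$accession, "VAR1"))
  verdicts <- vapply(dd$discards, `[[`, character(1), "verdict")
  expect_setequal(verdicts, c("duplicate", "fragment", "redundant_precursor_only"))
  # permutation invariance of the retained set
  for (perm in list(c(5, 4, 3, 2, 1), c(2, 5, 1, 3, 4))) {
    cl2 <- cl
    cl2$members <- members[perm, ]
    expect_setequal(deduplicate_cluster(cl2)$members$accession,
                    dd$members$accession)
  }
  # singleton in, singleton out
  single <- structure(list(query_acc = "X", family_label = "F",
                           members = parent, discards = list()),
                      class = "family_cluster")
  expect_equal(nrow(deduplicate_cluster(single)$members), 1)
})

test_that("build_cluster materialises hits and falls back to a query-derived label", {
  set.seed(5)
  pool <- protein_db(c("H1", "H2"), c(random_protein(100), random_protein(100)))
  q <- protein_db("Q1", random_protein(100), db_section = "reviewed")
  hits <- data.frame(query_acc = "Q1", subject_acc = c("H1", "H2"),
                     identity_pct = c(95, 90), score = c(500, 450),
                     aln_length = c(100L, 100L), source = "builtin")
  cl <- build_cluster(q, hits, pool)
  expect_equal(nrow(cl$members), 3)
  expect_equal(cl$members$accession[1], "Q1")
  expect_equal(cl$family_label, "FAM_Q1")
  expect_equal(build_cluster(q, hits, pool, family_map = c(Q1 = "PF00123"))$family_label,
               "PF00123")
  expect_equal(nrow(build_cluster(q, hits[0, ], pool)$members), 1)
})

test_that("map_homologue_to_wheat picks the best organism-matching hit deterministically", {
  set.seed(6)
  base <- random_protein(150)
  hom <- protein_db("HOMOLOG1", base, db_section = "reviewed",
                    organism = "Hordeum vulgare")
  # two wheat entries with identical sequences (equal identity): accession breaks the tie
  pool <- protein_db(c("W2", "W1", "B1"), c(base, base, base),
                     organism = c("Triticum aestivum", "Triticum aestivum",
                                  "Hordeum vulgare"))
  best <- map_homologue_to_wheat(hom, pool)
  expect_equal(best$accession, "W1")
  expect_null(map_homologue_to_wheat(hom, pool[0, ]))
  expect_null(map_homologue_to_wheat(hom, pool[3, ]))  # no wheat entry at all
})

test_that("infer_gene_from_ortholog borrows the closest GN-carrying hit", {
  set.seed(8)
  base <- random_protein(150)
  rec <- protein_db("Q1", base)
  no_gn <- protein_db(c("X1", "X2"), c(base, base), organism = "Oryza sativa")
  expect_null(infer_gene_from_ortholog(rec, no_gn))
  chars <- strsplit(base, "")[[1]]
  chars[10] <- setdiff(c("A", "C"), chars[10])[1]
  with_gn <- protein_db(c("G2", "G1"), c(paste(chars, collapse = ""), base),
                        gene = c("psbA", "rbcL"), organism = "Oryza sativa")
  got <- infer_gene_from_ortholog(rec, with_gn)
  expect_equal(got$gene, "rbcL")     # exact match beats the 1-substitution one
  expect_true(got$provisional)
})

test_that("compile_database recovers the planted truth and keeps its arithmetic", {
  fx <- curation_fixture(seed = 42)
  res <- compile_database(fx$queries, fx$pool$records)
  truth <- fx$pool$truth
  expected <- truth$accession[truth$label %in% c("seed", "variant_of")]
  expect_setequal(res$records$accession, expected)
  rep <- res$report
  expect_equal(rep$n_kept + rep$n_discarded, rep$n_compared)
  expect_equal(sum(unlist(rep$discards_by_category)), rep$n_discarded)
  expect_equal(rep$discards_by_category$duplicate, 8)
  expect_equal(rep$discards_by_category$fragment, 4)
  expect_equal(rep$discards_by_category$redundant_precursor_only, 4)
  # no duplicate sequences and no intra-cluster containment among kept records
  expect_equal(anyDuplicated(res$records$sequence), 0)
  for (cl in res$clusters) {
    accs <- intersect(cl$members$accession, res$records$accession)
    seqs <- res$records$sequence[match(accs, res$records$accession)]
    if (length(seqs) < 2) next
    for (i in seq_along(seqs)) for (j in seq_along(seqs)) {
      if (i != j && nchar(seqs[i]) < nchar(seqs[j])) {
        expect_false(is_exact_subsequence(seqs[i], seqs[j])$found)
      }
    }
  }
  # every discarded accession is absorbed by exactly one kept representative
  collected <- unlist(res$annotation$collected_accessions)
  expect_equal(anyDuplicated(collected), 0)
  expect_equal(sort(collected), sort(setdiff(truth$accession[truth$label != "unrelated"], expected)))
})

test_that("compile_database is idempotent and order-invariant", {
  fx <- curation_fixture(seed = 42)
  res <- compile_database(fx$queries, fx$pool$records)
  # rerun with its own output as pool: nothing new discarded
  res2 <- compile_database(fx$queries, res$records)
  expect_equal(res2$report$n_discarded, 0)
  expect_setequal(res2$records$accession, res$records$accession)
  # pool order must not matter
  perm <- sample(nrow(fx$pool$records))
  res3 <- compile_database(fx$queries, fx$pool$records[perm, ])
  expect_equal(res3$records$accession, res$records$accession)
  expect_equal(res3$report$n_compared, res$report$n_compared)
})

test_that("compile_database trivial and error cases", {
  q <- protein_db("Q1", strrep("ACDEFGHIK", 10), db_section = "reviewed",
                  description = "seed protein")
  empty_pool <- q[0, ]
  res <- compile_database(q, empty_pool)
  expect_equal(res$records$accession, "Q1")
  expect_equal(res$report$n_discarded, 0)
  expect_equal(res$report$n_compared, 1)
  clash <- protein_db("Q1", strrep("WYWYWYWYK", 10))
  expect_error(compile_database(q, clash), "collides")
})

test_that("stage-b homologue queries bring their wheat counterparts into the build", {
  set.seed(12)
  wheat_seq <- random_protein(200)
  pool <- rbind(
    protein_db("WHT01", wheat_seq, organism = "Triticum aestivum",
               description = "wheat counterpart"),
    protein_db("WHT02", {
      ch <- strsplit(wheat_seq, "")[[1]]; ch[50] <- setdiff(c("A", "C"), ch[50])[1]
      paste(ch, collapse = "")
    }, organism = "Triticum aestivum", description = "wheat variant")
  )
  barley <- protein_db("BAR01", wheat_seq, db_section = "reviewed",
                       organism = "Hordeum vulgare", description = "barley homologue")
  seed_q <- protein_db("Q0", random_protein(180), db_section = "reviewed",
                       description = "unrelated seed", organism = "Triticum aestivum")
  res <- compile_database(seed_q, pool, stage_b_homologue_queries = barley)
  expect_true("WHT01" %in% res$records$accession)
  expect_true("WHT02" %in% res$records$accession)   # a genuine variant is kept
  expect_false("BAR01" %in% res$records$accession)  # the homologue query itself is not
})

test_that("flag_for_review lists suspicious descriptions without deleting them", {
  db <- protein_db(c("P1", "P2", "P3"), rep("MKWVTFISLLK", 3),
                   description = c("Uncharacterized protein", "ATP synthase",
                                   "Predicted protein (Fragment)"))
  expect_setequal(flag_for_review(db), c("P1", "P3"))
})
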