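test_that("peptides map only to proteins containing them with tryptic boundaries", {
  db <- protein_db(c("P1", "P2"), c("MKSEPTIDERAAAK", "SEPTIDER"))
  asn <- map_peptides(c("SEPTIDER", "MKSEPTIDERAAAK", "EPTIDER", "KSEPTIDER"), db)
  hit <- function(p) asn$protein_accs[[match(p, asn$peptide)]]
  expect_setequal(hit("SEPTIDER"), c("P1", "P2"))   # after K2 in P1; whole P2
  expect_equal(hit("MKSEPTIDERAAAK"), "P1")         # a peptide equal to the whole protein maps
  expect_equal(hit("EPTIDER"), character(0))        # interior start: not tryptic
  expect_equal(hit("KSEPTIDER"), character(0))      # upstream M is not a cleavage site
  expect_error(map_peptides("PEP1IDE", db), "non-amino-acid")
  # non-tryptic matching when the boundary rule is relaxed
  asn2 <- map_peptides("EPTIDER", db, require_tryptic = FALSE)
  expect_setequal(asn2$protein_accs[[1]], c("P1", "P2"))
  # I/L folding is off by default and available on demand
  db3 <- protein_db("P3", "AAAILAAAK")
  expect_equal(map_peptides("AAALLAAAK", db3)$n_proteins, 0L)
  expect_equal(map_peptides("AAALLAAAK", db3, il_equivalent = TRUE)$n_proteins, 1L)
})

test_that("the isoform trio reproduces the database-dependent uniqueness flip", {
  tr <- scenario_isoform_trio()
  swissprot_like <- tr$records[1:2, ]   # reviewed pair only
  full <- tr$records                    # pair + unreviewed isoform
  p6 <- tr$peptides[["p6"]]
  p8 <- tr$peptides[["p8"]]
  asn_sp <- map_peptides(tr$peptides, swissprot_like)
  expect_equal(asn_sp$protein_accs[[match(p6, asn_sp$peptide)]], "SYNISOA")
  expect_true(asn_sp$is_unique[match(p6, asn_sp$peptide)])
  expect_equal(asn_sp$protein_accs[[match(p8, asn_sp$peptide)]], character(0))
  asn_full <- map_peptides(tr$peptides, full)
  expect_setequal(asn_full$protein_accs[[match(p6, asn_full$peptide)]],
                  c("SYNISOA", "SYNISOC"))
  expect_false(asn_full$is_unique[match(p6, asn_full$peptide)])
  expect_equal(asn_full$protein_accs[[match(p8, asn_full$peptide)]], "SYNISOC")
  expect_true(asn_full$is_unique[match(p8, asn_full$peptide)])
})

test_that("group_proteins merges identical peptide sets and prefers reviewed representatives", {
  sets <- list(A = c("p1", "p2", "p3"), B = c("p1", "p2", "p3"), C = c("p2", "p4"))
  g <- group_proteins(assignments_from_sets(sets))
  expect_equal(nrow(g), 2)
  merged <- g[vapply(g$member_accs, length, integer(1)) == 2, ]
  expect_setequal(merged$member_accs[[1]], c("A", "B"))
  expect_equal(merged$top_protein, "A")
  db <- protein_db(c("A", "B", "C"), rep("MKWV", 3),
                   db_section = c("unreviewed", "reviewed", "unreviewed"))
  g2 <- group_proteins(assignments_from_sets(sets), db)
  expect_equal(sort(g2$top_protein), c("B", "C"))
  # all-distinct sets give one group each; grouping equals a partition oracle
  set.seed(31)
  for (i in 1:20) {
    asn <- random_parsimony_instance()
    g3 <- group_proteins(asn)
    # oracle partition: proteins keyed by their sorted peptide vectors
    prot_peps <- list()
    for (k in seq_len(nrow(asn))) {
      for (a in asn$protein_accs[[k]]) prot_peps[[a]] <- union(prot_peps[[a]], asn$peptide[k])
    }
    keys <- vapply(prot_peps, function(x) paste(sort(x), collapse = "|"), character(1))
    expect_equal(sort(unname(vapply(g3$member_accs, paste, character(1), collapse = ","))),
                 sort(unname(vapply(split(names(keys), keys), function(m)
                   paste(sort(m), collapse = ","), character(1)))))
  }
})

test_that("parsimony handles the printed subset and intersection configurations", {
  # case a: B's peptides nest inside A's
  g <- apply_parsimony(group_proteins(assignments_from_sets(
    list(A = paste0("p", 1:5), B = c("p2", "p3")))))
  expect_equal(g$status[g$top_protein == "B"], "subset_discarded")
  expect_equal(g$status[g$top_protein == "A"], "candidate")
  # case b: C covered by A and B jointly but by neither alone
  g <- apply_parsimony(group_proteins(assignments_from_sets(
    list(A = paste0("p", 1:3), B = paste0("p", 4:6), C = c("p2", "p4")))))
  expect_equal(g$status[g$top_protein == "C"], "intersection_discarded")
  expect_setequal(g$status[g$top_protein != "C"], "candidate")
})

test_that("the trio database search discards the intersection isoform only", {
  tr <- scenario_isoform_trio()
  asn <- map_peptides(tr$peptides, tr$records)
  g <- apply_parsimony(group_proteins(asn, tr$records))
  expect_equal(g$status[g$top_protein == "SYNISOA"], "intersection_discarded")
  expect_setequal(g$top_protein[g$status == "candidate"], c("SYNISOB", "SYNISOC"))
  res <- accept_proteins(g)
  expect_setequal(res$reported, c("SYNISOB", "SYNISOC"))
  # against the reviewed pair alone, both isoforms are reported
  asn_sp <- map_peptides(tr$peptides, tr$records[1:2, ])
  res_sp <- accept_proteins(apply_parsimony(group_proteins(asn_sp, tr$records[1:2, ])))
  expect_setequal(res_sp$reported, c("SYNISOA", "SYNISOB"))
})

test_that("parsimony plus acceptance equals the exhaustive classifier on random instances", {
  set.seed(91)
  for (i in 1:200) {
    asn <- random_parsimony_instance()
    g <- accept_proteins(apply_parsimony(group_proteins(asn)))$groups
    want <- oracle_statuses(g$peptides)
    expect_equal(g$status, want,
                 info = paste("instance", i, ":",
                              paste(vapply(g$peptides, paste, character(1),
                                           collapse = "+"), collapse = " / ")))
    # coverage: every peptide stays covered by a non-discarded group
    kept_peps <- unique(unlist(g$peptides[!g$status %in%
                                            c("subset_discarded", "intersection_discarded")]))
    expect_true(setequal(kept_peps, unique(unlist(g$peptides))))
  }
})

test_that("acceptance requires two peptides and a unique peptide", {
  g <- accept_proteins(group_proteins(assignments_from_sets(
    list(A = "p1", B = c("p2", "p3")))))
  expect_equal(g$groups$status[g$groups$top_protein == "A"], "failed_min_peptides")
  expect_equal(g$groups$status[g$groups$top_protein == "B"], "reported")
  expect_equal(g$reported, "B")
  # without parsimony first, a shared-only group fails the unique-peptide rule
  g2 <- accept_proteins(group_proteins(assignments_from_sets(
    list(A = c("p1", "p2", "p3"), B = c("p4", "p5", "p6"), C = c("p2", "p4")))))
  expect_equal(g2$groups$status[g2$groups$top_protein == "C"], "failed_no_unique")
})

test_that("replicate consensus keeps proteins seen in enough replicates", {
  reports <- list(c("A", "B", "C"), c("A", "C"), c("A", "D"))
  expect_equal(replicate_consensus(reports, 2), c("A", "C"))
  expect_equal(replicate_consensus(reports, 3), "A")
  expect_equal(replicate_consensus(reports, 1), c("A", "B", "C", "D"))
  expect_equal(replicate_consensus(list(), 2), character(0))
  # random membership matrices against a counting oracle
  set.seed(41)
  for (i in 1:20) {
    accs <- sprintf("P%02d", 1:8)
    mat <- matrix(stats::runif(24) < 0.5, nrow = 8)
    reports <- lapply(1:3, function(r) accs[mat[, r]])
    expect_equal(replicate_consensus(reports, 2),
                 sort(accs[rowSums(mat) >= 2]))
  }
})

test_that("run_inference recovers planted proteins and is deterministic", {
  set.seed(55)
  db <- protein_db(sprintf("DB%02d", 1:12),
                   vapply(1:12, function(i) random_protein(sample(150:300, 1)),
                          character(1)))
  true_accs <- db$accession[c(2, 5, 7, 11)]
  sim <- simulate_psms(true_accs, db, n_replicates = 3, detect_prob = 0.8,
                       n_decoys = 30, seed = 99)
  res <- run_inference(sim$psms, db)
  expect_setequal(res$final, true_accs)
  # shuffled input rows give the identical result
  perm <- sample(nrow(sim$psms))
  res2 <- run_inference(sim$psms[perm, ], db)
  expect_equal(res2$final, res$final)
  expect_equal(res2$reports, res$reports)
  # empty PSM table
  empty <- run_inference(sim$psms[0, ], db)
  expect_equal(empty$final, character(0))
  # modified peptides are stripped before mapping
  psms_mod <- sim$psms
  psms_mod$peptide <- sub("^(..)", "\\1(+15.99)", psms_mod$peptide)
  expect_equal(run_inference(psms_mod, db)$final, res$final)
})

test_that("inference reports round-trip through the JSON-lines format", {
  tr <- scenario_isoform_trio()
  sim <- simulate_psms("SYNISOB", tr$records, n_replicates = 2, detect_prob = 1,
                       n_decoys = 10, seed = 3)
  res <- run_inference(sim$psms, tr$records)
  path <- withr::local_tempfile(fileext = ".jsonl")
  write_inference_report(res, path)
  back <- read_inference_report(path)
  expect_equal(back$final, res$final)
  expect_equal(names(back$groups), names(res$groups))
  for (r in names(res$groups)) {
    expect_equal(back$groups[[r]]$status, res$groups[[r]]$status)
    expect_equal(back$groups[[r]]$peptides, res$groups[[r]]$peptides,
                 ignore_attr = TRUE)
  }
})

test_that("compare_searches partitions accessions into disjoint Venn cells", {
  v <- compare_searches(c("A", "B", "C"), c("B", "C", "D"))
  expect_equal(v$only_a, "A")
  expect_equal(v$only_b, "D")
  expect_equal(v$common, c("B", "C"))
  expect_equal(length(intersect(v$only_a, v$common)), 0)
  same <- compare_searches(c("A", "B"), c("B", "A"))
  expect_equal(same$only_a, character(0))
  expect_equal(same$common, c("A", "B"))
  expect_equal(compare_searches(c("A"), c("B"))$common, character(0))
})

test_that("explain_absence returns the correct reason for every failure mode", {
  tr <- scenario_isoform_trio()
  sub <- scenario_subset_pair()
  # run the trio search: SYNISOA ends up an intersection protein
  sim <- list(psms = data.frame(
    peptide = rep(unname(tr$peptides), 2),
    score = 50, replicate_id = rep(c("1", "2"), each = length(tr$peptides)),
    is_decoy = FALSE, stringsAsFactors = FALSE))
  res_tr <- suppressWarnings(run_inference(sim$psms, tr$records,
                                           settings = run_config(q_threshold = 1)))
  ex <- explain_absence("SYNISOA", res_tr, tr$records)
  expect_equal(ex$reason, "intersection_protein")
  # subset pair: the reviewed entry nests inside the unreviewed isoform
  psms_sub <- data.frame(peptide = rep(sub$peptides, 2), score = 50,
                         replicate_id = rep(c("1", "2"), each = length(sub$peptides)),
                         is_decoy = FALSE, stringsAsFactors = FALSE)
  res_sub <- suppressWarnings(run_inference(psms_sub, sub$records,
                                            settings = run_config(q_threshold = 1)))
  expect_equal(res_sub$final, "SYNSUBB")
  ex <- explain_absence("SYNSUBA", res_sub, sub$records)
  expect_equal(ex$reason, "subset_of_top_protein")
  # absent from the database entirely
  expect_equal(explain_absence("NOTTHERE", res_sub, sub$records)$reason,
               "absent_from_database")
  # a single-peptide protein fails the minimum-peptide rule
  db1 <- protein_db(c("ONE", "OTHER"), c("AAAWWWYYYK", "CCCDDDEEEKFFFGGGHHHK"))
  psms1 <- data.frame(peptide = rep(c("AAAWWWYYYK", "CCCDDDEEEK", "FFFGGGHHHK"), 2),
                      score = 50, replicate_id = rep(c("1", "2"), each = 3),
                      is_decoy = FALSE, stringsAsFactors = FALSE)
  res1 <- suppressWarnings(run_inference(psms1, db1, settings = run_config(q_threshold = 1)))
  expect_equal(res1$final, "OTHER")
  expect_equal(explain_absence("ONE", res1, db1)$reason, "insufficient_peptides")
  # in the database but never matched at all
  db2 <- rbind(db1, protein_db("SILENT", "MMMNNNQQQK"))
  res2 <- suppressWarnings(run_inference(psms1, db2, settings = run_config(q_threshold = 1)))
  expect_equal(explain_absence("SILENT", res2, db2)$reason, "insufficient_peptides")
  # reported in one replicate only: fails the consensus
  db3 <- rbind(db1, protein_db("TWO", "AAATTTVVVKLLLMMMNNNK"))
  psms3 <- data.frame(peptide = c("AAATTTVVVK", "LLLMMMNNNK", "CCCDDDEEEK", "FFFGGGHHHK",
                                  "CCCDDDEEEK", "FFFGGGHHHK"),
                      score = 50, replicate_id = c("1", "1", "1", "1", "2", "2"),
                      is_decoy = FALSE, stringsAsFactors = FALSE)
  res3 <- suppressWarnings(run_inference(psms3, db3, settings = run_config(q_threshold = 1)))
  expect_false("TWO" %in% res3$final)
  expect_equal(explain_absence("TWO", res3, db3)$reason, "failed_replicate_consensus")
  # no unique peptide, flagged when acceptance runs without parsimony
  g <- accept_proteins(group_proteins(assignments_from_sets(
    list(A = c("p1", "p2", "p3"), B = c("p4", "p5", "p6"), C = c("p2", "p4")))))
  manual <- structure(list(groups = list(`1` = g$groups, `2` = g$groups),
                           reports = list(`1` = g$reported, `2` = g$reported),
                           final = sort(g$reported),
                           settings = run_config()),
                      class = "inference_result")
  dbC <- protein_db(c("A", "B", "C"), rep("MKWV", 3))
  expect_equal(explain_absence("C", manual, dbC)$reason, "no_unique_peptide")
  # asking about a protein that IS in the consensus is an error
  expect_error(explain_absence("OTHER", res1, db1), "nothing to explain")
})
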