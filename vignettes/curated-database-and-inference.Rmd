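---
title: "Curating a non-redundant protein database and inferring proteins by parsimony"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Curating a non-redundant protein database and inferring proteins by parsimony}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(protcurate)
```

## The problem

Shotgun proteomics of organisms with large, partially annotated genomes —
hexaploid bread wheat (*Triticum aestivum*) is the motivating case — is
limited by the databases the spectra are searched against. The reviewed
(Swiss-Prot) section is small and incomplete; the unreviewed (TrEMBL)
section is huge but full of duplicated, fragmentary and poorly annotated
translations. A practical remedy is a manually curated, organism-specific
database: start from the reviewed entries, pull in their unreviewed
homologs, remove everything that adds no sequence information, and keep
genuine variants. `protcurate` automates that workflow and ships the
inference machinery needed to evaluate the result: target-decoy PSM
filtering, parsimony protein grouping, replicate consensus, and a
two-database comparison that explains, protein by protein, why an entry
present in one final report is missing from the other.

## The curation model

Curation operates on *protein record tables* (`protein_db()`): accession,
reviewed/unreviewed status, description, organism, gene, sequence, and an
optional 1-based `mature_start` marking where the mature chain begins
after signal/transit peptide cleavage. The workflow (`compile_database()`):

1. **Keyword exclusion.** Seed queries whose description contains a
   storage-protein keyword (`gluten`, `gliadin`, `glutenin`, `avenin`,
   `prolamin`; case-insensitive substrings, so the stem also catches
   plurals) are set aside — the target is the metabolic fraction, and
   dedicated gluten databases exist.
2. **Homolog collection.** Each query is aligned against the candidate
   pool (`search_pool()`) and hits with ≥ 80% identity are collected into
   a per-query family cluster, capped at 1000 hits. Alternatively,
   pre-computed BLAST tabular output is ingested (`hits_from_blast()`)
   with the same threshold and ordering contract, plus a pass-through
   E-value filter.
3. **Redundancy elimination.** Within each cluster, candidates are
   classified against the retained members (`classify_redundancy()`), in
   a fixed cascade: byte-identical → *duplicate*; exact contiguous
   subsequence → *fragment*; identical mature region with all
   differences upstream of `mature_start` → *redundant precursor-only
   variant*; ≥ 80% global identity → *variant* (kept: point mutations or
   short indels are new sequence); otherwise unrelated. Retention
   priority when two members are mutually redundant: reviewed over
   unreviewed, then the longer sequence, then the smaller accession.
4. **Cross-species stage.** Homologue queries from related species are
   first mapped to their best same-organism pool entry
   (`map_homologue_to_wheat()`), which is then treated as a new query.
5. **Merge and report.** Retained members are merged, de-duplicated by
   accession and then by exact sequence (reviewed/earlier accession
   wins; the loser is recorded in the winner's `collected_accessions`),
   and written as FASTA plus a nine-column annotation table. The report
   satisfies `n_kept + n_discarded = n_compared` by construction, where
   `n_compared` counts the distinct accessions that entered any cluster.

Suspicious entries (descriptions containing "Fragment",
"Uncharacterized", "Predicted") are *flagged* for human review, never
auto-deleted: an irreproducible judgement step must not silently change
outputs.

## Alignment choices

Alignments use BLOSUM62 with affine gap penalties, gap open 11 and gap
extend 1 (a gap of length $L$ costs $11 + L$) — the BLAST protein
defaults, since the thresholds being honoured were defined by BLAST
searches. Identity is BLAST-style `pident`: matches divided by all
columns of the (local) aligned region, gap columns included. The rare
codes U/O are scored like X rather than rejected, because they occur in
unreviewed pools and dropping such records would silently shrink the
candidate set.

Two deliberate guards:

* The built-in search computes **no E-values** (Karlin–Altschul
  calibration is meaningless on desk-scale pools). Without one, any
  shared tetramer is a "100% identity" local hit; `search_pool()`
  therefore requires a minimal alignment span (`min_aln_length`, default
  30 columns, capped at the shorter input so short test sequences still
  match). Thirty residues is the conventional shortest span treated as
  homology evidence; an external BLAST path exists for real pools.
* `coverage_min` optionally requires the local alignment to cover a
  fraction of the query, for the stricter reading in which the identity
  threshold applies over the whole query length. The default keeps the
  local-alignment reading.

Where several alignments are co-optimal, the reported gapped strings
follow the alignment engine's deterministic traceback; scores, identity
and column counts — everything the classifiers consume — do not depend
on the choice.

## The inference model

Input is a PSM table: peptide, score (higher is better), replicate id,
decoy flag. The pipeline (`run_inference()`):

1. **q-value filtering** (`filter_psms_by_fdr()`). For each score cutoff
   $t$, $\widehat{FDR}(t) = \#\{decoys \ge t\} / \#\{targets \ge t\}$;
   a PSM's q-value is the minimum estimated FDR over cutoffs at or below
   its score; targets with $q \le 0.001$ (FDR 0.1%) are accepted. The
   filter runs once on the pooled table — replicate scores from one
   search engine share a scale, and pooling gives the estimator more
   decoys to work with; per-replicate filtering would only lower its
   resolution.
2. **Peptide mapping** (`map_peptides()`). A peptide maps to a protein
   iff it occurs as a substring with tryptic boundaries on both sides
   (after K/R not before P, or a terminus). In-line modification
   notation is stripped first. I/L folding is off by default (modern
   engines distinguish them spectrally) but available.
3. **Grouping** (`group_proteins()`). Proteins with identical peptide
   sets are indistinguishable and merged; the representative "top
   protein" is the reviewed member if any, else the smallest accession.
   A peptide is *unique* when all its proteins fall in one group —
   computed against the whole searched database before any discard, so
   uniqueness is database-relative: the same peptide can be decisive in
   a small reviewed database and uninformative in a curated one.
4. **Parsimony** (`apply_parsimony()`). A group whose peptides are a
   strict subset of another single group's is discarded (*subset
   protein*); a group with no unique peptide whose set is covered by the
   union of the other standing groups is discarded (*intersection
   protein*). Subset discards are simultaneous (the superset always
   survives); intersection candidates are then examined smallest-first
   against the groups still standing. The ordering matters only in
   degenerate cycles of mutually covering, unique-less groups, where
   simultaneous discarding would orphan peptides; the sequential rule
   guarantees every accepted peptide remains covered by a reported or
   candidate group — the defining property of a minimal explanatory
   list.
5. **Acceptance.** A candidate group is reported when it has ≥ 2
   peptides and ≥ 1 unique peptide.
6. **Consensus** (`replicate_consensus()`). The final list keeps
   accessions reported in ≥ 2 replicates (the 2-of-3 rule), matched by
   top-protein accession; matching by group-membership overlap is a
   conceivable alternative but makes the final list depend on group
   composition in other replicates, which is harder to audit.

`compare_searches()` partitions two final lists into exclusive and
common sets, and `explain_absence()` assigns each exclusive accession
one of six reasons by inspecting the other search: absent from that
database, subset of a top protein, intersection protein, too few
peptides, no unique peptide, or reported in too few replicates.

## Synthetic data and what passing tests mean

The generators produce every input with known truth:

* `make_family()` plants, around a reviewed parent, exact duplicates,
  contiguous fragments (≥ 30% of the parent), precursor variants
  (mutations confined to the signal region, default length 20) and
  mature-region variants (per-residue mutation rate 0.02 — a few point
  substitutions, like real cultivar variants). `make_pool()` adds an
  unrelated uniform-composition background and shuffles.
* `simulate_psms()` detects each tryptic peptide of each true protein
  per replicate with probability 0.8 (a realistic per-peptide
  observability for an abundant protein), scores targets from N(35, 5)
  and decoys — reversed-sequence peptides — from N(10, 5): well
  separated, as a tuned engine threshold achieves. Optional *noise* rows
  are false target matches scored like decoys, so realised FDR is
  measurable. Leakage checks keep the decoy pool an order of magnitude
  larger than the noise, mirroring a real search in which the decoy
  database models the whole database while genuinely high-scoring false
  matches are few; the estimator's granularity is 1/#accepted, so the
  realised-FDR bound is only meaningful with enough accepted PSMs.
* The `scenario_*` fixtures are deterministic synthetic stand-ins for
  the classic worked situations: a precursor pair differing at exactly
  three signal-region positions, a 206-residue exact fragment of a
  236-residue parent, a duplicate pair, an isoform trio (> 95% pairwise
  identity) whose parsimony outcome flips between a two-entry and a
  three-entry database, and a reviewed/unreviewed pair whose peptide
  sets nest. They are constructions, not downloads: passing them shows
  the classifiers implement the intended relations, not that any
  particular public entry is classified correctly.

What the synthetic conditions do *not* model: shared peptides between
unrelated real proteins, homologous families in the background,
modification-induced mapping ambiguity, intensity-dependent detection,
and score distributions with heavy overlap. Recovery results on fixtures
are therefore upper bounds on real-data behaviour.

## Problem sizes

The shipped tests and the acceptance script use: four families × 7
members + 20 unrelated proteins for curation (48-record pool); 1000
random instances (≤ 6 proteins, ≤ 12 peptides) for the parsimony-oracle
comparison; 60 proteins / 50 true for inference recovery; 200 seeded
simulations for FDR leakage. These sizes exercise every code path while
keeping a full run in the tens of seconds; the algorithms themselves are
exact at any size, with the all-vs-all built-in search (quadratic in
pool size) being the only step one would replace — with an external
BLAST run — for pools beyond a few thousand sequences.

## Known limitations

* The built-in homolog search is exhaustive DP with no heuristic
  seeding; use the BLAST tabular path for large pools.
* `mature_start` comes from a sidecar table; feature-table parsing of
  UniProt records is out of scope, so precursor-only redundancy is
  detected only where that annotation is supplied.
* Gene symbols borrowed from orthologs (`infer_gene_from_ortholog()`)
  are provisional annotations, not ground truth.
* Spectrum-level quantities (masses, tolerances, modifications as
  evidence) are out of scope: the pipeline starts from PSM tables.
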