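# protcurate

Build a non-redundant, annotated protein sequence database from a
reviewed seed list plus a large unreviewed candidate pool, and evaluate
it with parsimony-based protein inference — the workflow behind manually
curated, organism-specific proteomics databases such as those used for
bread wheat (*Triticum aestivum*), whose reviewed UniProt section is
small while the unreviewed section is large and highly redundant.

The package is for proteomics researchers who need (a) a reproducible
version of the curation steps usually done by hand — homolog collection
at ≥ 80% identity, elimination of duplicates, fragments and
precursor-only variants, merge and annotation — and (b) the matching
search-report machinery: target-decoy q-value filtering of
peptide-spectrum matches, Occam's-razor protein grouping, replicate
consensus, and a comparison of two database searches that explains every
exclusive identification.

## The core procedures

**Redundancy classification.** A candidate is compared with a reference
in a fixed cascade: byte-identical sequences are *duplicates*; an exact
contiguous subsequence is a *fragment*; identical mature regions with
all differences upstream of the mature start (signal/transit peptide)
are *redundant precursor-only variants*; sequences at ≥ 80% global
identity (BLOSUM62, affine gaps 11/1) with real sequence differences are
*variants* and kept; the rest are unrelated.

**Parsimony inference.** With accepted peptides mapped to proteins under
full-tryptic boundaries (cleavage after K/R except before P), proteins
carrying identical peptide sets are grouped; a group whose peptides nest
strictly inside another's is a *subset protein*, and a group with no
unique peptide covered by the union of the other standing groups is an
*intersection protein* — both are dropped, so the report is the smallest
set of entries explaining all peptides. A protein is reported when its
group has ≥ 2 peptides including ≥ 1 unique, and enters the final list
when reported in ≥ 2 of 3 replicates. PSMs are filtered beforehand at
q ≤ 0.001, with q-values from the target-decoy estimate
FDR(t) = #decoys≥t / #targets≥t.

## Worked example

```r
library(protcurate)
set.seed(20)

# a synthetic pool with planted redundancy: two families (parent + 2
# duplicates + fragment + precursor variant + 2 variants) on a
# background of 10 unrelated proteins
families <- lapply(1:2, function(i)
  make_family(random_protein(250), sprintf("FAM%02d", i)))
pool <- make_pool(families, n_unrelated = 10)
queries <- do.call(rbind, lapply(families, function(f) f$records[1, , drop = FALSE]))

compile_database(queries, pool$records)
#> curated database: 6 kept of 14 compared (8 discarded)
#>   discards: duplicate=4, fragment=2, redundant_precursor_only=2
```

Fourteen entries entered the clusters (2 × 7 family members; the
unrelated background never reaches 80% identity); per family, the two
exact copies, the fragment and the signal-peptide-only variant carry no
new sequence and are discarded, while the parent and the two
mature-region variants are kept: 6 kept + 8 discarded = 14 compared.

```r
sim <- simulate_psms(c("SYN00002", "SYN00003", "SYN00007"), pool$records, seed = 21)
inf <- run_inference(sim$psms, pool$records)
inf
#> inference result: 3 replicate(s), 3 consensus protein(s)
#>   replicate 1: 3 reported
#>   replicate 2: 3 reported
#>   replicate 3: 3 reported
inf$final
#> [1] "SYN00002" "SYN00003" "SYN00007"
```

The three planted proteins — and nothing else — survive q-value
filtering, parsimony and the 2-of-3 replicate rule.

```r
pre <- scenario_precursor_pair()
classify_redundancy(pre$records[2, ], pre$records[1, ])
#> SYNPRE02 vs SYNPRE01: redundant_precursor_only (identity 98.8%)
```

A command-line wrapper with `curate`, `infer`, `compare` and `simulate`
subcommands is installed at `inst/cli/protcurate`.

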