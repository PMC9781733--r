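# Deterministic synthetic worked-example fixtures.
#
# Each scenario reproduces, on synthetic sequences, a documented
# curation or inference situation: a precursor-only variant pair, an
# exact fragment pair (206 of 236 residues), a duplicate pair, a
# near-identical isoform trio whose peptide evidence flips between a
# two-entry and a three-entry database, and a reviewed/unreviewed pair
# where the reviewed entry's peptides are a strict subset of the
# unreviewed one's. All sequences are synthetic; no real database entry
# is reproduced.

.SCEN_P240 <- "KQTDDKDDCYTQNAPGSLMYQIIYGHLLKFTNDKDLYCAPSQNVRVTNCKLFQCVRFDMKLHYTIYLEEWKNPVHFIGWQSENDNNRFMRVYEKPMDHRWSVGAQMYWPITFFYKIPHQHAFMSMFNMYATFQFKWKLNFYQEQWCLDGMAHWPSQCRYLNSAVGMRIPPANRFAAYLNGKCSTCINHGFKSGFQIINVQTAMEEHDMARRQKGLPQKMWQYIRPRIKHQEDKEDARWWN"
.SCEN_P236 <- "QAYIRTSLWMFDRQREEIAGHRCVDIEWTPRRHWEIDTSHKCRWLLAECYFCTQLTMEHRDRYNLLALFMGVQKNKAYNIVQWCYEEVCQEHIFQHLKAPCLTVVLWIFFLNYKGQFKGVLLWFLEVKEWSQVVTFHGSSPGMQNHPSIPMRHGKDWEVQCNHRAFKIRYRHSYHPNWDRLSTGYRCDTQWTFPIYDLWNQLTHWQQWQEHDMCLMNFKINMLQCGNGMSADKHYK"
.SCEN_P150 <- "INQQPNGPVFTSRKNQQCNVDQQVQRCGIHECTVSFNDVHMERQDCWRAHFGRKISYTRTIYFNHYMTKLSCSVWWIQFKPPQFNNMSALGPHTWAAGINQYMCGESSVGKKIGNGWFGLLGIVKMYAFSQKSHTYVVMKVWERNPWSRN"

.substitute_at <- function(sequence, positions, replacements) {
  chars <- strsplit(sequence, "")[[1]]
  chars[positions] <- replacements
  paste(chars, collapse = "")
}

#' Precursor-pair scenario: mature regions identical, signal differs
#'
#' A reviewed parent (240 aa, mature chain starting at residue 46) and
#' an unreviewed variant differing at exactly three positions (8, 19,
#' 33), all upstream of the mature start — the canonical
#' "redundant precursor" situation where the mature protein carries no
#' new sequence.
#'
#' @return list with `records` (parent first), `mismatch_positions`,
#'   `mature_start`.
#' @export
scenario_precursor_pair <- function() {
  pos <- c(8L, 19L, 33L)
  variant <- .substitute_at(.SCEN_P240, pos, c("E", "L", "N"))
  parent <- protein_db("SYNPRE01", .SCEN_P240, db_section = "reviewed",
                       entry_name = "SYNPRE_WHEAT",
                       description = "synthetic precursor-pair parent",
                       organism = "Triticum aestivum", mature_start = 46L)
  child <- protein_db("SYNPRE02", variant, db_section = "unreviewed",
                      description = "synthetic precursor-only variant",
                      organism = "Triticum aestivum")
  list(records = rbind(parent, child), mismatch_positions = pos, mature_start = 46L)
}

#' Fragment-pair scenario: a 206-residue exact fragment of a 236-residue parent
#'
#' @return list with `records` (parent first), `fragment_start` (1-based
#'   position of the fragment within the parent).
#' @export
scenario_fragment_pair <- function() {
  frag <- substr(.SCEN_P236, 16, 221)
  parent <- protein_db("SYNFRG01", .SCEN_P236, db_section = "reviewed",
                       entry_name = "SYNFRG_WHEAT",
                       description = "synthetic fragment-pair parent",
                       organism = "Triticum aestivum")
  child <- protein_db("SYNFRG02", frag, db_section = "unreviewed",
                      description = "synthetic fragment (Fragment)",
                      organism = "Triticum aestivum")
  list(records = rbind(parent, child), fragment_start = 16L)
}

#' Duplicate-pair scenario: two accessions, one sequence
#'
#' @return list with `records` (reviewed entry first).
#' @export
scenario_duplicate_pair <- function() {
  a <- protein_db("SYNDUP01", .SCEN_P150, db_section = "reviewed",
                  entry_name = "SYNDUP_WHEAT",
                  description = "synthetic duplicate-pair original",
                  organism = "Triticum aestivum")
  b <- protein_db("SYNDUP02", .SCEN_P150, db_section = "unreviewed",
                  description = "synthetic duplicate-pair copy",
                  organism = "Triticum aestivum")
  list(records = rbind(a, b))
}

# 14 tryptic building blocks of the isoform trio; blocks 6 and 8 are the
# two distinctive peptides of the scenario. Each block ends in K/R, has
# no internal cleavage site, and no block starts with P.
.TRIO_PEPTIDES <- c(
  p1  = "ADGSTVNLEQMGK",
  p2  = "TLSDEAGHVNIAK",
  p3  = "GVDETNALSQWFR",
  p4  = "ESATLNVDGHMQK",
  p5  = "DLGANTVESHIQR",
  p6  = "YGWTAFCGPAGAHGQAACGK",
  p7  = "SVDNLGETAHMQK",
  p8  = "VTNPATGAQVTAR",
  p9  = "NTEGSVALDHMQK",
  p10 = "GDSLTANVEHWFK",
  p11 = "LSTGEDANVHMQR",
  p12 = "TGNSDVALEHYFK",
  p13 = "AVSDTGNLEHMQK",
  p14 = "SGTDNVALEHWLK"
)

# single-substitution variants (position 3) used where a protein does
# NOT carry the corresponding analyzed peptide
.TRIO_VARIANTS <- c(
  p1 = "ADASTVNLEQMGK",
  p4 = "ESTTLNVDGHMQK",
  p6 = "YGFTAFCGPAGAHGQAACGK",
  p7 = "SVENLGETAHMQK",
  p8 = "VTSPATGAQVTAR"
)

.trio_sequence <- function(carries) {
  blocks <- vapply(names(.TRIO_PEPTIDES), function(nm) {
    if (nm %in% carries) .TRIO_PEPTIDES[[nm]]
    else if (nm %in% names(.TRIO_VARIANTS)) .TRIO_VARIANTS[[nm]]
    else .TRIO_PEPTIDES[[nm]]
  }, character(1))
  paste(blocks, collapse = "")
}

#' Isoform-trio scenario: parsimony flips with the searched database
#'
#' Three synthetic isoforms sharing > 95% identity, built from 14
#' tryptic blocks. Protein A carries analyzed peptides
#' {1,2,3,5,6,9..14}, protein B {1..5,7,9..14}, protein C
#' {2,3,5,6,8,9..14}; where a protein lacks an analyzed peptide its
#' block carries a single point substitution. Searched against the
#' reviewed pair {A, B}, peptide 6 is unique to A and peptides 4/7 to B,
#' so both are reported and peptide 8 stays unmatched. Searched against
#' the full trio, peptide 8 becomes unique to C, peptide 6 is shared
#' between A and C, and A — with no unique peptide left but full
#' coverage by B and C — becomes an intersection protein.
#'
#' @return list with `records` (A reviewed, B reviewed, C unreviewed),
#'   `peptides` (the 14 analyzed peptide sequences, named p1..p14),
#'   `carries` (membership list).
#' @export
scenario_isoform_trio <- function() {
  carries <- list(
    SYNISOA = c("p1", "p2", "p3", "p5", "p6", paste0("p", 9:14)),
    SYNISOB = c(paste0("p", 1:5), "p7", paste0("p", 9:14)),
    SYNISOC = c("p2", "p3", "p5", "p6", "p8", paste0("p", 9:14))
  )
  recs <- rbind(
    protein_db("SYNISOA", .trio_sequence(carries$SYNISOA), db_section = "reviewed",
               entry_name = "SYNISOA_WHEAT",
               description = "synthetic isoform A", organism = "Triticum aestivum"),
    protein_db("SYNISOB", .trio_sequence(carries$SYNISOB), db_section = "reviewed",
               entry_name = "SYNISOB_WHEAT",
               description = "synthetic isoform B", organism = "Triticum aestivum"),
    protein_db("SYNISOC", .trio_sequence(carries$SYNISOC), db_section = "unreviewed",
               description = "synthetic isoform C", organism = "Triticum aestivum")
  )
  list(records = recs, peptides = .TRIO_PEPTIDES, carries = carries)
}

#' Subset-pair scenario: the reviewed entry's peptides nest in the unreviewed one's
#'
#' A reviewed protein and a near-identical unreviewed isoform built
#' from ten tryptic blocks; the isoform differs by one substitution in
#' each of the last two blocks. The analyzed peptides are the eight
#' shared blocks plus the isoform's two distinctive ones: searched
#' alone, the reviewed entry is supported by eight (unique) peptides;
#' searched together, its peptide set is a strict subset of the
#' isoform's and it is dropped as a subset protein.
#'
#' @return list with `records` (reviewed first), `peptides` (the ten
#'   analyzed peptides).
#' @export
scenario_subset_pair <- function() {
  shared <- .TRIO_PEPTIDES[paste0("p", c(2, 3, 5, 9, 10, 11, 12, 13))]
  a_last <- c(.TRIO_PEPTIDES[["p1"]], .TRIO_PEPTIDES[["p4"]])
  b_last <- c(.TRIO_VARIANTS[["p1"]], .TRIO_VARIANTS[["p4"]])
  seq_a <- paste(c(shared, a_last), collapse = "")
  seq_b <- paste(c(shared, b_last), collapse = "")
  recs <- rbind(
    protein_db("SYNSUBA", seq_a, db_section = "reviewed",
               entry_name = "SYNSUBA_WHEAT",
               description = "synthetic subset-pair reviewed entry",
               organism = "Triticum aestivum"),
    protein_db("SYNSUBB", seq_b, db_section = "unreviewed",
               description = "synthetic subset-pair unreviewed isoform",
               organism = "Triticum aestivum")
  )
  list(records = recs, peptides = unname(c(shared, b_last)))
}
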