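#' Amino-acid alphabet accepted in sequences
#'
#' The 20 standard residues plus ambiguity/rare codes B, Z, X, U, O.
#' @keywords internal
AA_LETTERS <- c("A","C","D","E","F","G","H","I","K","L",
                "M","N","P","Q","R","S","T","V","W","Y")
AA_EXTRA <- c("B", "Z", "X", "U", "O")

.valid_sequence <- function(x) {
  nzchar(x) & !grepl(paste0("[^", paste(c(AA_LETTERS, AA_EXTRA), collapse = ""), "]"), x)
}

#' Construct a table of protein records
#'
#' A protein record set is a plain `data.frame` with one row per entry
#' and columns `accession`, `entry_name`, `db_section` (`"reviewed"` or
#' `"unreviewed"`), `description`, `organism`, `taxon_id`, `gene`,
#' `sequence`, `is_fragment`, `mature_start`. All character columns use
#' `NA` for absent optional fields; `mature_start` is the 1-based residue
#' index where the mature chain begins (NA when unknown).
#'
#' @param accession character vector of accessions (non-empty, unique).
#' @param sequence uppercase amino-acid sequences (letters ACDEFGHIKLMNPQRSTVWY
#'   plus B/Z/X/U/O).
#' @param db_section `"reviewed"` or `"unreviewed"` (recycled).
#' @param entry_name,description,organism,gene optional character metadata.
#' @param taxon_id optional integer NCBI taxon.
#' @param is_fragment logical; defaults to whether `description` contains
#'   `"(Fragment)"`.
#' @param mature_start optional 1-based index of the first mature residue.
#' @return a `data.frame` of protein records.
#' @examples
#' protein_db("P00001", "MKWVTFISLLK", db_section = "reviewed")
#' @export
protein_db <- function(accession, sequence,
                       db_section = "unreviewed",
                       entry_name = NA_character_,
                       description = NA_character_,
                       organism = NA_character_,
                       taxon_id = NA_integer_,
                       gene = NA_character_,
                       is_fragment = NULL,
                       mature_start = NA_integer_) {
  n <- length(accession)
  sequence <- toupper(as.character(sequence))
  if (is.null(is_fragment)) {
    is_fragment <- !is.na(description) & grepl("(Fragment)", description, fixed = TRUE)
  }
  db <- data.frame(
    accession = as.character(accession),
    entry_name = rep_len(as.character(entry_name), n),
    db_section = rep_len(as.character(db_section), n),
    description = rep_len(as.character(description), n),
    organism = rep_len(as.character(organism), n),
    taxon_id = rep_len(as.integer(taxon_id), n),
    gene = rep_len(as.character(gene), n),
    sequence = sequence,
    is_fragment = rep_len(as.logical(is_fragment), n),
    mature_start = rep_len(as.integer(mature_start), n),
    stringsAsFactors = FALSE
  )
  validate_protein_db(db)
}

#' Validate a protein record table
#'
#' Checks the protein-record invariants: non-empty unique accessions,
#' non-empty sequences over the accepted alphabet, `db_section` one of
#' reviewed/unreviewed, and `mature_start` within `[1, nchar(sequence)]`
#' where present.
#'
#' @param db a data.frame as built by [protein_db()] or [read_fasta()].
#' @return `db`, invisibly unchanged, or an error.
#' @export
validate_protein_db <- function(db) {
  needed <- c("accession", "entry_name", "db_section", "description", "organism",
              "taxon_id", "gene", "sequence", "is_fragment", "mature_start")
  missing_cols <- setdiff(needed, names(db))
  if (length(missing_cols)) {
    stop("protein record table lacks columns: ", paste(missing_cols, collapse = ", "))
  }
  if (any(!nzchar(db$accession) | is.na(db$accession))) {
    stop("empty accession in protein record table")
  }
  dup <- duplicated(db$accession)
  if (any(dup)) {
    first <- match(db$accession[dup][1], db$accession)
    stop(sprintf("duplicate accession '%s' (entries %d and %d)",
                 db$accession[dup][1], first, which(dup)[1]))
  }
  bad <- !.valid_sequence(db$sequence)
  if (any(bad)) {
    stop(sprintf("invalid or empty sequence for accession '%s'",
                 db$accession[which(bad)[1]]))
  }
  if (!all(db$db_section %in% c("reviewed", "unreviewed"))) {
    stop("db_section must be 'reviewed' or 'unreviewed'")
  }
  ms <- db$mature_start
  bad_ms <- !is.na(ms) & (ms < 1L | ms > nchar(db$sequence))
  if (any(bad_ms)) {
    stop(sprintf("mature_start out of range for accession '%s'",
                 db$accession[which(bad_ms)[1]]))
  }
  invisible(db)
}

.empty_protein_db <- function() {
  protein_db(character(0), character(0))
}

#' Attach mature-chain start positions from a sidecar table
#'
#' UniProt-style signal/transit peptide annotation is supplied out of
#' band as a two-column delimited file (accession, 1-based mature start).
#' Accessions absent from the table keep `mature_start = NA`.
#'
#' @param db protein record table.
#' @param table data.frame with columns `accession` and `mature_start`,
#'   e.g. from [read_mature_starts()].
#' @return `db` with `mature_start` filled in.
#' @export
apply_mature_starts <- function(db, table) {
  idx <- match(db$accession, table$accession)
  hit <- !is.na(idx)
  db$mature_start[hit] <- as.integer(table$mature_start[idx[hit]])
  validate_protein_db(db)
  db
}
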