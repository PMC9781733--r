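BLAST_COLUMNS <- c("query_acc", "subject_acc", "percent_identity", "aln_length",
                   "mismatches", "gap_opens", "q_start", "q_end",
                   "s_start", "s_end", "evalue", "bitscore")

#' Read NCBI BLAST tabular output (outfmt 6)
#'
#' @param source file path or character vector of lines. Comment lines
#'   starting with `#` are skipped.
#' @return data.frame with the 12 standard columns
#'   (`query_acc`, `subject_acc`, `percent_identity`, `aln_length`,
#'   `mismatches`, `gap_opens`, `q_start`, `q_end`, `s_start`, `s_end`,
#'   `evalue`, `bitscore`); coordinates stay 1-based inclusive as in the
#'   file.
#' @export
read_blast_tabular <- function(source) {
  lines <- .as_lines(source)
  keep <- !grepl("^#", lines) & nzchar(trimws(lines))
  lineno <- which(keep)
  lines <- lines[keep]
  if (!length(lines)) {
    out <- as.data.frame(setNames(rep(list(character(0)), 12), BLAST_COLUMNS))
    num <- BLAST_COLUMNS[3:12]
    out[num] <- lapply(out[num], as.numeric)
    return(out)
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nfield <- lengths(parts)
  if (any(nfield != 12)) {
    bad <- which(nfield != 12)[1]
    stop(sprintf("BLAST tabular line %d has %d fields (12 expected)",
                 lineno[bad], nfield[bad]))
  }
  m <- do.call(rbind, parts)
  out <- data.frame(query_acc = m[, 1], subject_acc = m[, 2], stringsAsFactors = FALSE)
  out$percent_identity <- as.numeric(m[, 3])
  out$aln_length <- as.integer(m[, 4])
  out$mismatches <- as.integer(m[, 5])
  out$gap_opens  <- as.integer(m[, 6])
  out$q_start <- as.integer(m[, 7]); out$q_end <- as.integer(m[, 8])
  out$s_start <- as.integer(m[, 9]); out$s_end <- as.integer(m[, 10])
  out$evalue <- as.numeric(m[, 11]); out$bitscore <- as.numeric(m[, 12])
  out
}

#' Write BLAST tabular rows (outfmt 6)
#'
#' Counterpart of [read_blast_tabular()], used for round-trips and for
#' materialising synthetic hit tables.
#' @param rows data.frame with the 12 standard columns.
#' @param path output file, or `NULL` to return lines.
#' @export
write_blast_tabular <- function(rows, path = NULL) {
  stopifnot(all(BLAST_COLUMNS %in% names(rows)))
  fmt <- function(x) ifelse(x == floor(x) & abs(x) < 1e15, format(x, scientific = FALSE, trim = TRUE), as.character(x))
  m <- cbind(rows$query_acc, rows$subject_acc,
             as.character(rows$percent_identity), rows$aln_length, rows$mismatches,
             rows$gap_opens, rows$q_start, rows$q_end, rows$s_start, rows$s_end,
             as.character(rows$evalue), as.character(rows$bitscore))
  lines <- apply(m, 1, paste, collapse = "\t")
  if (!length(lines)) lines <- character(0)
  if (is.null(path)) return(lines)
  writeLines(lines, path)
  invisible(lines)
}

#' Read a peptide-spectrum-match (PSM) table
#'
#' Reads a delimited text export of scored peptide observations (one row
#' per PSM) into the standard PSM layout: `peptide`, `score`,
#' `replicate_id`, `is_decoy`, `spectrum_id`.
#'
#' @param source file path or character vector of lines; first row is a
#'   header.
#' @param column_map named list binding the required fields `peptide`,
#'   `score`, `replicate_id` and one of `is_decoy` (a logical column) or
#'   `decoy_from_accession` (a column of protein accessions whose prefix
#'   flags decoys); optionally `spectrum_id`.
#' @param sep field separator (default tab).
#' @param decoy_prefix accession prefix marking decoys when
#'   `decoy_from_accession` is used (default `"DECOY_"`).
#' @return data.frame of PSM records.
#' @export
read_psm_table <- function(source,
                           column_map = list(peptide = "peptide", score = "score",
                                             replicate_id = "replicate_id",
                                             is_decoy = "is_decoy"),
                           sep = "\t", decoy_prefix = "DECOY_") {
  lines <- .as_lines(source)
  tab <- read.delim(text = paste(lines, collapse = "\n"), sep = sep,
                    stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("peptide", "score", "replicate_id")
  for (f in need) {
    col <- column_map[[f]]
    if (is.null(col) || !col %in% names(tab)) {
      stop(sprintf("PSM column for '%s' not found; available columns: %s",
                   f, paste(names(tab), collapse = ", ")))
    }
  }
  if (nrow(tab) == 0) {
    return(data.frame(peptide = character(0), score = numeric(0),
                      replicate_id = character(0), is_decoy = logical(0),
                      spectrum_id = character(0), stringsAsFactors = FALSE))
  }
  score <- suppressWarnings(as.numeric(tab[[column_map$score]]))
  if (anyNA(score)) {
    stop(sprintf("non-numeric score at PSM table row %d", which(is.na(score))[1]))
  }
  if (!is.null(column_map$is_decoy) && column_map$is_decoy %in% names(tab)) {
    raw <- tab[[column_map$is_decoy]]
    is_decoy <- if (is.logical(raw)) raw else toupper(as.character(raw)) %in% c("TRUE", "T", "1", "YES")
  } else if (!is.null(column_map$decoy_from_accession) &&
             column_map$decoy_from_accession %in% names(tab)) {
    is_decoy <- startsWith(as.character(tab[[column_map$decoy_from_accession]]), decoy_prefix)
  } else {
    stop(sprintf("PSM column for decoy status not found; available columns: %s",
                 paste(names(tab), collapse = ", ")))
  }
  out <- data.frame(
    peptide = toupper(as.character(tab[[column_map$peptide]])),
    score = score,
    replicate_id = as.character(tab[[column_map$replicate_id]]),
    is_decoy = is_decoy,
    spectrum_id = if (!is.null(column_map$spectrum_id) && column_map$spectrum_id %in% names(tab))
      as.character(tab[[column_map$spectrum_id]]) else NA_character_,
    stringsAsFactors = FALSE
  )
  bad <- !nzchar(out$peptide) | !is.finite(out$score)
  if (any(bad)) stop(sprintf("invalid PSM at row %d", which(bad)[1]))
  out
}

#' Write a PSM table
#'
#' @param psms data.frame with columns `peptide`, `score`, `replicate_id`,
#'   `is_decoy` (and optionally `spectrum_id`).
#' @param path output file, or `NULL` to return lines.
#' @export
write_psm_table <- function(psms, path = NULL) {
  cols <- c("peptide", "score", "replicate_id", "is_decoy")
  stopifnot(all(cols %in% names(psms)))
  if (!"spectrum_id" %in% names(psms)) psms$spectrum_id <- NA_character_
  tab <- psms[c(cols, "spectrum_id")]
  lines <- c(paste(names(tab), collapse = "\t"),
             if (nrow(tab)) do.call(paste, c(lapply(tab, as.character), sep = "\t")))
  if (is.null(path)) return(lines)
  writeLines(lines, path)
  invisible(lines)
}

ANNOTATION_COLUMNS <- c("accession", "description", "organism", "gene", "status",
                        "protein_family", "allergen_name", "last_update",
                        "collected_accessions")

#' Write the annotation table of a curated database
#'
#' Tab-separated, fixed column order: accession, description, organism,
#' gene, status (complete/fragment), protein_family, allergen_name,
#' last_update, collected_accessions (semicolon-joined accessions of the
#' redundant entries each kept representative absorbed). A header row is
#' emitted.
#'
#' @param rows data.frame of annotation rows; `collected_accessions` may
#'   be a list column of character vectors or a pre-joined string.
#' @param path output file, or `NULL` to return lines.
#' @export
write_annotation_table <- function(rows, path = NULL) {
  stopifnot(all(ANNOTATION_COLUMNS %in% names(rows)))
  coll <- rows$collected_accessions
  if (is.list(coll)) {
    coll <- vapply(coll, function(x) paste(x, collapse = ";"), character(1))
  }
  na2empty <- function(x) ifelse(is.na(x), "", as.character(x))
  body <- if (nrow(rows)) {
    paste(na2empty(rows$accession), na2empty(rows$description), na2empty(rows$organism),
          na2empty(rows$gene), na2empty(rows$status), na2empty(rows$protein_family),
          na2empty(rows$allergen_name), na2empty(rows$last_update), na2empty(coll),
          sep = "\t")
  } else character(0)
  lines <- c(paste(ANNOTATION_COLUMNS, collapse = "\t"), body)
  if (is.null(path)) return(lines)
  writeLines(lines, path)
  invisible(lines)
}

#' Read an annotation table written by [write_annotation_table()]
#'
#' @param source file path or character vector of lines.
#' @return data.frame with `collected_accessions` as a list column.
#' @export
read_annotation_table <- function(source) {
  lines <- .as_lines(source)
  tab <- read.delim(text = paste(lines, collapse = "\n"), sep = "\t",
                    stringsAsFactors = FALSE, check.names = FALSE,
                    colClasses = "character")
  stopifnot(identical(names(tab), ANNOTATION_COLUMNS))
  empty2na <- function(x) ifelse(nzchar(x), x, NA_character_)
  for (cl in setdiff(ANNOTATION_COLUMNS, "collected_accessions")) tab[[cl]] <- empty2na(tab[[cl]])
  tab$collected_accessions <- lapply(tab$collected_accessions, function(x) {
    if (!nzchar(x)) character(0) else strsplit(x, ";", fixed = TRUE)[[1]]
  })
  tab
}

#' Read a two-column mature-start sidecar table
#'
#' @param source file path or lines; tab- or whitespace-separated
#'   `accession  mature_start` pairs, `#` comments allowed, no header.
#' @return data.frame with columns `accession`, `mature_start`.
#' @export
read_mature_starts <- function(source) {
  lines <- .as_lines(source)
  lines <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  if (!length(lines)) {
    return(data.frame(accession = character(0), mature_start = integer(0)))
  }
  parts <- strsplit(trimws(lines), "[ \t]+")
  data.frame(accession = vapply(parts, `[`, character(1), 1),
             mature_start = as.integer(vapply(parts, `[`, character(1), 2)),
             stringsAsFactors = FALSE)
}

#' Read a two-column query-to-family label map
#'
#' @param source file path or lines; `accession  family_label` pairs.
#' @return named character vector (accession -> label).
#' @export
read_family_map <- function(source) {
  lines <- .as_lines(source)
  lines <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  if (!length(lines)) return(setNames(character(0), character(0)))
  parts <- strsplit(trimws(lines), "[ \t]+")
  setNames(vapply(parts, `[`, character(1), 2),
           vapply(parts, `[`, character(1), 1))
}
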