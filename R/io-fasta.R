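.as_lines <- function(source) {
  if (length(source) == 1 && !grepl("\n", source) && file.exists(source)) {
    readLines(source, warn = FALSE)
  } else {
    unlist(strsplit(as.character(source), "\n", fixed = TRUE), use.names = FALSE)
  }
}

# Parse one UniProt-dialect header line (without the leading '>').
# Returns a list of fields or NULL if the header is malformed.
.parse_uniprot_header <- function(header) {
  out <- list(accession = NA_character_, entry_name = NA_character_,
              db_section = "unreviewed", description = NA_character_,
              organism = NA_character_, taxon_id = NA_integer_,
              gene = NA_character_, warn_prefix = FALSE)
  m <- regmatches(header, regexec("^([A-Za-z0-9]+)\\|([^|[:space:]]+)\\|(\\S*)[ \t]*(.*)$", header))[[1]]
  if (length(m)) {
    prefix <- m[2]
    out$accession <- m[3]
    out$entry_name <- if (nzchar(m[4])) m[4] else NA_character_
    rest <- m[5]
    if (prefix == "sp") {
      out$db_section <- "reviewed"
    } else if (prefix != "tr") {
      out$warn_prefix <- TRUE
    }
  } else {
    if (grepl("|", header, fixed = TRUE)) return(NULL)   # pipes but not the sp|ACC|NAME shape
    acc <- sub("[ \t].*$", "", header)
    if (!nzchar(acc)) return(NULL)
    out$accession <- acc
    rest <- sub("^\\S+[ \t]*", "", header)
  }
  # split off OS= / OX= / GN= key fields; description is the text before OS=
  key_at <- regexpr("(^|[ \t])(OS|OX|GN|PE|SV)=", rest)
  if (key_at > 0) {
    out$description <- if (key_at > 1) substr(rest, 1, key_at - 1) else ""
    kv_start <- if (substr(rest, key_at, key_at) %in% c(" ", "\t")) key_at + 1 else key_at
    kv <- substr(rest, kv_start, nchar(rest))
  } else {
    out$description <- if (nzchar(rest)) rest else NA_character_
    kv <- ""
  }
  if (!is.na(out$description) && !nzchar(out$description)) out$description <- NA_character_
  grab <- function(key, upto = " (?:OX|GN|PE|SV)=|$") {
    m <- regmatches(kv, regexec(paste0(key, "=(.*?)(?=", upto, ")"), kv, perl = TRUE))[[1]]
    if (length(m)) m[2] else NA_character_
  }
  out$organism <- grab("OS")
  ox <- grab("OX", upto = " (?:GN|PE|SV)=|$")
  out$taxon_id <- if (!is.na(ox)) suppressWarnings(as.integer(ox)) else NA_integer_
  gn <- grab("GN", upto = " (?:PE|SV)=|$")
  out$gene <- gn
  out
}

#' Read a FASTA file of protein records
#'
#' @param source a file path, or a character vector holding FASTA text.
#' @param dialect `"uniprot"` parses `>sp|ACC|NAME desc OS=... OX=... GN=...`
#'   headers (bare-accession headers are also accepted and treated as
#'   unreviewed); `"plain"` takes the first whitespace-delimited token as
#'   accession and stores the whole header in `description`.
#' @param on_error `"fail"` stops at the first malformed header (with its
#'   line number); `"skip"` drops the record with a warning.
#' @return a protein record table (see [protein_db()]), in file order.
#' @details A header prefix other than `sp`/`tr` is accepted with a
#'   warning and the entry is marked unreviewed. `"(Fragment)"` in the
#'   description sets `is_fragment`. Sequence lines are concatenated and
#'   upper-cased; content is otherwise never altered.
#' @examples
#' fa <- c(">sp|P12345|TEST_WHEAT ATP synthase OS=Triticum aestivum", "MKWVTFISLLK")
#' read_fasta(fa)
#' @export
read_fasta <- function(source, dialect = c("uniprot", "plain"),
                       on_error = c("fail", "skip")) {
  dialect <- match.arg(dialect)
  on_error <- match.arg(on_error)
  lines <- .as_lines(source)
  lines <- lines[!grepl("^;", lines)]
  hdr_idx <- grep("^>", lines)
  if (!length(hdr_idx)) return(.empty_protein_db())
  seq_end <- c(hdr_idx[-1] - 1L, length(lines))
  recs <- vector("list", length(hdr_idx))
  warned_prefix <- FALSE
  for (i in seq_along(hdr_idx)) {
    header <- sub("^>", "", lines[hdr_idx[i]])
    seq_lines <- if (seq_end[i] > hdr_idx[i]) lines[(hdr_idx[i] + 1L):seq_end[i]] else character(0)
    sequence <- toupper(gsub("[ \t\r]", "", paste(seq_lines, collapse = "")))
    if (dialect == "plain") {
      acc <- sub("[ \t].*$", "", header)
      f <- list(accession = acc, entry_name = NA_character_,
                db_section = "unreviewed", description = header,
                organism = NA_character_, taxon_id = NA_integer_,
                gene = NA_character_, warn_prefix = FALSE)
      if (!nzchar(acc)) f <- NULL
    } else {
      f <- .parse_uniprot_header(header)
    }
    if (is.null(f) || !nzchar(sequence)) {
      msg <- sprintf("malformed FASTA record at line %d: '%s'", hdr_idx[i], lines[hdr_idx[i]])
      if (on_error == "fail") stop(msg) else { warning(msg); next }
    }
    if (f$warn_prefix && !warned_prefix) {
      warning(sprintf("unknown header prefix at line %d; entry treated as unreviewed",
                      hdr_idx[i]))
      warned_prefix <- TRUE
    }
    recs[[i]] <- data.frame(
      accession = f$accession, entry_name = f$entry_name, db_section = f$db_section,
      description = f$description, organism = f$organism, taxon_id = f$taxon_id,
      gene = f$gene, sequence = sequence,
      is_fragment = !is.na(f$description) && grepl("(Fragment)", f$description, fixed = TRUE),
      mature_start = NA_integer_, stringsAsFactors = FALSE
    )
  }
  recs <- recs[!vapply(recs, is.null, logical(1))]
  if (!length(recs)) return(.empty_protein_db())
  db <- do.call(rbind, recs)
  dup <- duplicated(db$accession)
  if (any(dup)) {
    a <- db$accession[dup][1]
    stop(sprintf("duplicate accession '%s' (records %d and %d)",
                 a, match(a, db$accession), which(dup)[1]))
  }
  validate_protein_db(db)
  db
}

#' Write protein records as FASTA
#'
#' @param db protein record table.
#' @param path output file; when `NULL` the FASTA text is returned as a
#'   character vector of lines.
#' @param dialect `"uniprot"` emits `>sp|ACC|NAME desc OS=... OX=... GN=...`
#'   headers (absent optional fields are omitted); `"plain"` emits
#'   `>ACC description`.
#' @param width sequence line width (default 60).
#' @return the lines (invisibly when `path` is given). Output re-parses
#'   to an identical record table via [read_fasta()].
#' @export
write_fasta <- function(db, path = NULL, dialect = c("uniprot", "plain"), width = 60) {
  dialect <- match.arg(dialect)
  validate_protein_db(db)
  out <- character(0)
  for (i in seq_len(nrow(db))) {
    if (dialect == "uniprot") {
      prefix <- if (db$db_section[i] == "reviewed") "sp" else "tr"
      name <- if (is.na(db$entry_name[i])) "" else db$entry_name[i]
      header <- paste0(">", prefix, "|", db$accession[i], "|", name)
      if (!is.na(db$description[i])) header <- paste(header, db$description[i])
      if (!is.na(db$organism[i]))    header <- paste0(header, " OS=", db$organism[i])
      if (!is.na(db$taxon_id[i]))    header <- paste0(header, " OX=", db$taxon_id[i])
      if (!is.na(db$gene[i]))        header <- paste0(header, " GN=", db$gene[i])
    } else {
      header <- paste0(">", db$accession[i])
      if (!is.na(db$description[i])) header <- paste(header, db$description[i])
    }
    seq <- db$sequence[i]
    starts <- seq(1L, nchar(seq), by = width)
    out <- c(out, header, substring(seq, starts, pmin(starts + width - 1L, nchar(seq))))
  }
  if (is.null(path)) return(out)
  writeLines(out, path)
  invisible(out)
}
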