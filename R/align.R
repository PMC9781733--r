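# Substitution matrix: BLOSUM62 extended so U (selenocysteine) and O
# (pyrrolysine) score like X. Built once per session.
.matrix_cache <- new.env(parent = emptyenv())

#' BLOSUM62 substitution matrix with U/O columns
#'
#' The standard BLOSUM62 matrix from Biostrings, extended so the rare
#' codes U and O are scored like the ambiguity code X. Ambiguity codes
#' occur in unreviewed sequence pools and are treated as ordinary
#' letters rather than discarded.
#' @return integer substitution matrix.
#' @export
blosum62_extended <- function() {
  if (!is.null(.matrix_cache$blosum62)) return(.matrix_cache$blosum62)
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  m <- e$BLOSUM62
  for (aa in c("U", "O")) {
    if (!aa %in% rownames(m)) {
      m <- rbind(m, m["X", , drop = FALSE])
      rownames(m)[nrow(m)] <- aa
      m <- cbind(m, m[, "X", drop = FALSE])
      colnames(m)[ncol(m)] <- aa
    }
  }
  .matrix_cache$blosum62 <- m
  m
}

.column_counts <- function(aligned_a, aligned_b) {
  ca <- strsplit(aligned_a, "")[[1]]
  cb <- strsplit(aligned_b, "")[[1]]
  gap <- ca == "-" | cb == "-"
  list(matches = sum(!gap & ca == cb),
       mismatches = sum(!gap & ca != cb),
       gap_columns = sum(gap),
       length = length(ca))
}

#' Optimal pairwise alignment with affine gaps
#'
#' Global (Needleman-Wunsch) or local (Smith-Waterman) alignment under
#' BLOSUM62 with affine gap penalties; a gap of length L costs
#' `gap_open + L * gap_extend` (the BLAST protein convention, defaults
#' 11/1). Identity is BLAST-style: matches over all alignment columns of
#' the aligned region, gap columns included.
#'
#' @param a,b amino-acid sequences (non-empty strings).
#' @param mode `"global"` or `"local"`.
#' @param matrix substitution matrix; defaults to [blosum62_extended()].
#' @param gap_open,gap_extend affine gap penalties (positive costs).
#' @return an object of class `pairwise_alignment`: a list with
#'   `aligned_a`, `aligned_b` (equal-length gapped strings), `score`,
#'   `matches`, `mismatches`, `gap_columns`, `identity_pct`, `mode`, and
#'   for local alignments `a_span`/`b_span` (1-based inclusive).
#' @examples
#' aln <- pairwise_align("PEPTIDE", "PEPSIDE")
#' aln$identity_pct
#' @export
pairwise_align <- function(a, b, mode = c("global", "local"),
                           matrix = NULL, gap_open = 11, gap_extend = 1) {
  mode <- match.arg(mode)
  if (!is.character(a)) a <- as.character(a)
  if (!is.character(b)) b <- as.character(b)
  if (!nzchar(a) || !nzchar(b)) stop("pairwise_align: empty sequence")
  if (is.null(matrix)) matrix <- blosum62_extended()
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b),
    type = mode, substitutionMatrix = matrix,
    gapOpening = gap_open, gapExtension = gap_extend
  )
  aligned_a <- as.character(Biostrings::alignedPattern(aln))
  aligned_b <- as.character(Biostrings::alignedSubject(aln))
  cc <- .column_counts(aligned_a, aligned_b)
  res <- list(
    aligned_a = aligned_a,
    aligned_b = aligned_b,
    score = Biostrings::score(aln),
    matches = cc$matches,
    mismatches = cc$mismatches,
    gap_columns = cc$gap_columns,
    identity_pct = if (cc$length > 0) 100 * cc$matches / cc$length else 0,
    mode = mode
  )
  if (mode == "local") {
    p <- Biostrings::pattern(aln)
    s <- Biostrings::subject(aln)
    res$a_span <- c(Biostrings::start(p), Biostrings::end(p))
    res$b_span <- c(Biostrings::start(s), Biostrings::end(s))
  }
  class(res) <- "pairwise_alignment"
  res
}

#' @export
print.pairwise_alignment <- function(x, ...) {
  cat(sprintf("%s alignment: score %.1f, identity %.1f%% (%d match / %d mismatch / %d gap columns)\n",
              x$mode, x$score, x$identity_pct, x$matches, x$mismatches, x$gap_columns))
  cat(x$aligned_a, "\n", x$aligned_b, "\n", sep = "")
  invisible(x)
}

#' Positions (in the second sequence's coordinates) where an alignment differs
#'
#' Walks the aligned columns of a [pairwise_align()] result and reports
#' the 1-based residue positions of `aligned_b` (the reference) at every
#' difference column (mismatch or gap). For columns where the reference
#' itself is gapped, the position of the last consumed reference residue
#' is reported.
#' @param aln a `pairwise_alignment`.
#' @return integer vector of 1-based reference positions.
#' @keywords internal
alignment_mismatch_positions <- function(aln) {
  ca <- strsplit(aln$aligned_a, "")[[1]]
  cb <- strsplit(aln$aligned_b, "")[[1]]
  pos_b <- cumsum(cb != "-")
  if (!is.null(aln$b_span)) pos_b <- pos_b + aln$b_span[1] - 1L
  diff <- ca != cb
  unique(pmax(pos_b[diff], 1L))
}

#' Exact contiguous subsequence test
#'
#' @param short,long non-empty amino-acid sequences.
#' @return list with `found` (logical) and `position` (leftmost 1-based
#'   start of `short` within `long`, NA when absent).
#' @examples
#' is_exact_subsequence("BCD", "ABCDE")
#' @export
is_exact_subsequence <- function(short, long) {
  if (!nzchar(short) || !nzchar(long)) stop("is_exact_subsequence: empty sequence")
  at <- regexpr(short, long, fixed = TRUE)
  list(found = at > 0, position = if (at > 0) as.integer(at) else NA_integer_)
}
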