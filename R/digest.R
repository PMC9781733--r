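#' In-silico tryptic digestion
#'
#' Cleaves after K or R except when the next residue is P, and emits all
#' full-tryptic products with up to `max_missed` internal missed
#' cleavage sites and length within bounds. Order is deterministic:
#' by start position, then product length.
#'
#' @param sequence amino-acid sequence.
#' @param max_missed maximum internal uncleaved K/R sites (default 3).
#' @param min_len,max_len product length bounds (defaults 5 and 60,
#'   roughly the detectable range of a shotgun experiment).
#' @return data.frame with `peptide`, `start` (1-based), `end`,
#'   `n_missed`.
#' @examples
#' digest_tryptic("AKRPGK", max_missed = 1, min_len = 1)
#' @export
digest_tryptic <- function(sequence, max_missed = 3, min_len = 5, max_len = 60) {
  sequence <- toupper(sequence)
  if (!.valid_sequence(sequence)) stop("digest_tryptic: invalid sequence")
  n <- nchar(sequence)
  chars <- strsplit(sequence, "")[[1]]
  sites <- which(chars %in% c("K", "R"))
  sites <- sites[sites == n | chars[pmin(sites + 1L, n)] != "P"]
  bounds <- unique(c(0L, sites, n))
  out <- list()
  for (i in seq_len(length(bounds) - 1L)) {
    for (j in (i + 1L):length(bounds)) {
      missed <- j - i - 1L
      if (missed > max_missed) break
      start <- bounds[i] + 1L
      end <- bounds[j]
      len <- end - start + 1L
      if (len < min_len || len > max_len) next
      out[[length(out) + 1L]] <- list(peptide = substr(sequence, start, end),
                                      start = start, end = end, n_missed = missed)
    }
  }
  if (!length(out)) {
    return(data.frame(peptide = character(0), start = integer(0),
                      end = integer(0), n_missed = integer(0)))
  }
  df <- data.frame(peptide = vapply(out, `[[`, character(1), "peptide"),
                   start = vapply(out, `[[`, integer(1), "start"),
                   end = vapply(out, `[[`, integer(1), "end"),
                   n_missed = vapply(out, `[[`, integer(1), "n_missed"),
                   stringsAsFactors = FALSE)
  df[order(df$start, df$end - df$start), , drop = FALSE]
}

#' Filter PSMs by target-decoy q-value
#'
#' For every score cutoff `t`, `FDR(t) = #decoys >= t / #targets >= t`;
#' the q-value of a PSM is the minimum FDR over all cutoffs at or below
#' its score. Accepted PSMs are the target PSMs with `q <= q_threshold`;
#' decoys are never returned.
#'
#' @param psms PSM data.frame (`peptide`, `score`, `replicate_id`,
#'   `is_decoy`, ...).
#' @param q_threshold q-value cutoff (default 0.001, i.e. FDR 0.1%).
#' @return the accepted target rows, with a `q_value` column, sorted by
#'   decreasing score. Zero targets give an empty result; zero decoys
#'   accept every target at q = 0 with a warning.
#' @export
filter_psms_by_fdr <- function(psms, q_threshold = 0.001) {
  stopifnot(all(c("peptide", "score", "is_decoy") %in% names(psms)))
  targets <- psms[!psms$is_decoy, , drop = FALSE]
  if (nrow(targets) == 0) {
    targets$q_value <- numeric(0)
    return(targets)
  }
  if (!any(psms$is_decoy)) {
    warning("no decoy PSMs: all targets accepted at q = 0")
    targets$q_value <- 0
    return(targets[order(-targets$score), , drop = FALSE])
  }
  ord <- order(-psms$score, psms$is_decoy)  # decoys after targets at ties
  dec <- psms$is_decoy[ord]
  n_dec <- cumsum(dec)
  n_tgt <- cumsum(!dec)
  fdr <- ifelse(n_tgt > 0, n_dec / n_tgt, Inf)
  q <- rev(cummin(rev(fdr)))
  q_of_row <- numeric(nrow(psms))
  q_of_row[ord] <- q
  targets <- psms[!psms$is_decoy, , drop = FALSE]
  targets$q_value <- q_of_row[!psms$is_decoy]
  accepted <- targets[targets$q_value <= q_threshold, , drop = FALSE]
  accepted[order(-accepted$score), , drop = FALSE]
}
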