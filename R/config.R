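#' Run configuration
#'
#' One flat list of the tunable parameters shared by the curation and
#' inference workflows. Defaults follow standard practice for this kind
#' of curation/search pipeline: homologs collected at >= 80% identity
#' with at most 1000 hits per query, PSMs filtered at FDR <= 0.1%,
#' proteins accepted with >= 2 peptides including a unique one, and a
#' 2-of-3 replicate consensus.
#'
#' @param identity_min percent identity threshold for homolog collection
#'   and variant classification (default 80).
#' @param max_hits per-query hit cap (default 1000).
#' @param q_threshold PSM q-value cutoff (default 0.001).
#' @param min_peptides minimum peptides per reported protein (default 2).
#' @param min_replicates replicate-consensus minimum (default 2).
#' @param require_unique require a unique peptide per reported protein.
#' @param require_tryptic enforce tryptic boundaries when mapping.
#' @param il_equivalent fold I/L when mapping peptides.
#' @param keywords storage-protein exclusion keywords.
#' @param organism_filter organism substring restricting pool hits
#'   (NULL: no restriction).
#' @param mod_pattern regex stripped from peptide strings before
#'   mapping.
#' @param decoy_prefix accession prefix marking decoys in PSM tables.
#' @param seed integer seed for any stochastic step (NULL: leave RNG
#'   alone).
#' @return a named list of class `run_config`.
#' @export
run_config <- function(identity_min = 80, max_hits = 1000, q_threshold = 0.001,
                       min_peptides = 2, min_replicates = 2,
                       require_unique = TRUE, require_tryptic = TRUE,
                       il_equivalent = FALSE,
                       keywords = GLUTEN_KEYWORDS,
                       organism_filter = NULL,
                       mod_pattern = "\\([^)]*\\)|\\[[^]]*\\]",
                       decoy_prefix = "DECOY_",
                       seed = NULL) {
  stopifnot(identity_min >= 0, identity_min <= 100,
            q_threshold >= 0, q_threshold <= 1,
            min_peptides >= 1, min_replicates >= 1, max_hits >= 1)
  structure(list(identity_min = identity_min, max_hits = max_hits,
                 q_threshold = q_threshold, min_peptides = min_peptides,
                 min_replicates = min_replicates,
                 require_unique = require_unique,
                 require_tryptic = require_tryptic,
                 il_equivalent = il_equivalent,
                 keywords = keywords, organism_filter = organism_filter,
                 mod_pattern = mod_pattern, decoy_prefix = decoy_prefix,
                 seed = seed),
            class = "run_config")
}

#' Read a flat key=value configuration file
#'
#' Unknown keys are an error; values are coerced to the type of the
#' corresponding [run_config()] default. List-valued fields
#' (`keywords`) are comma-separated. The file round-trips through
#' [write_run_config()].
#'
#' @param path configuration file.
#' @param base a `run_config` supplying defaults for absent keys.
#' @return a `run_config`.
#' @export
read_run_config <- function(path, base = run_config()) {
  lines <- .as_lines(path)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  cfg <- unclass(base)
  numeric_keys <- c("identity_min", "max_hits", "q_threshold", "min_peptides",
                    "min_replicates", "seed")
  logical_keys <- c("require_unique", "require_tryptic", "il_equivalent")
  for (ln in lines) {
    kv <- regmatches(ln, regexec("^\\s*([A-Za-z_]+)\\s*=\\s*(.*?)\\s*$", ln))[[1]]
    if (length(kv) != 3) stop("malformed config line: ", ln)
    key <- kv[2]; val <- kv[3]
    if (!key %in% names(cfg)) stop("unknown config key: ", key)
    cfg[[key]] <- if (key %in% numeric_keys) as.numeric(val)
      else if (key %in% logical_keys) toupper(val) %in% c("TRUE", "T", "1", "YES")
      else if (key == "keywords") strsplit(val, ",\\s*")[[1]]
      else if (nzchar(val)) val else NULL
  }
  do.call(run_config, cfg[!vapply(cfg, is.null, logical(1))])
}

#' Write a [run_config()] as a flat key=value file
#'
#' @param config a `run_config`.
#' @param path output file, or `NULL` to return lines.
#' @export
write_run_config <- function(config, path = NULL) {
  fmt <- function(v) {
    if (is.null(v)) "" else if (is.logical(v)) ifelse(v, "TRUE", "FALSE")
    else paste(as.character(v), collapse = ",")
  }
  keys <- setdiff(names(config), character(0))
  lines <- vapply(keys, function(k) paste0(k, "=", fmt(config[[k]])), character(1))
  if (is.null(path)) return(lines)
  writeLines(lines, path)
  invisible(lines)
}
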