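## Multi-database disease-target integration.
##
## Evidence rows come from five sources (genecards, omim, ttd, drugbank,
## pharmgkb); only GeneCards rows carry a relevance score.  The pipeline
## filters GeneCards by score, standardizes symbols offline against a
## user-supplied alias table, merges to one entry per gene with its
## supporting sources, flags genes attested by >= 2 sources as
## high-confidence, and intersects with predicted compound targets.

.target_sources <- c("genecards", "omim", "ttd", "drugbank", "pharmgkb")

#' Filter GeneCards evidence by relevance score
#'
#' GeneCards entries with `relevance_score >= threshold` are retained
#' (inclusive boundary); entries from every other source pass unchanged.
#' GeneCards entries without a score are rejected with a warning.
#'
#' @param evidence Data.frame with columns `symbol`, `source` and (for
#'   genecards rows) `relevance_score`.
#' @param threshold Minimum relevance score (default 37.5).
#' @return The filtered evidence table.
#' @export
filter_by_relevance <- function(evidence, threshold = 37.5) {
  stopifnot(is.finite(threshold))
  if (nrow(evidence) == 0) return(evidence)
  stopifnot(all(c("symbol", "source") %in% names(evidence)))
  if (!"relevance_score" %in% names(evidence)) {
    evidence$relevance_score <- NA_real_
  }
  gc <- evidence$source == "genecards"
  unscored <- gc & is.na(evidence$relevance_score)
  if (any(unscored)) {
    warning(sum(unscored), " genecards entr(ies) without a relevance score ",
            "rejected", call. = FALSE)
  }
  keep <- !gc | (!is.na(evidence$relevance_score) &
                 evidence$relevance_score >= threshold)
  evidence[keep, , drop = FALSE]
}

#' Standardize gene symbols against an offline alias table
#'
#' Aliases are rewritten to their canonical symbol; lookup is
#' case-insensitive. Symbols absent from the map are kept verbatim and
#' counted (attribute `n_unmapped` on the result, plus a warning).
#'
#' @param evidence Data.frame with a `symbol` column.
#' @param synonym_map Data.frame with columns `alias`, `canonical`. An alias
#'   mapped to two different canonical symbols is a configuration error.
#' @return `evidence` with canonical symbols; attribute `n_unmapped` holds
#'   the pass-through count.
#' @export
standardize_symbols <- function(evidence, synonym_map) {
  stopifnot(all(c("alias", "canonical") %in% names(synonym_map)))
  key <- tolower(synonym_map$alias)
  dup <- duplicated(key)
  if (any(dup)) {
    conflicting <- vapply(unique(key[dup]), function(k) {
      length(unique(synonym_map$canonical[key == k])) > 1
    }, logical(1))
    if (any(conflicting)) {
      stop("conflicting aliases in synonym map: ",
           paste(unique(key[dup])[conflicting], collapse = ", "),
           call. = FALSE)
    }
    synonym_map <- synonym_map[!dup, , drop = FALSE]
    key <- key[!dup]
  }
  idx <- match(tolower(evidence$symbol), key)
  mapped <- !is.na(idx)
  evidence$symbol[mapped] <- synonym_map$canonical[idx[mapped]]
  n_unmapped <- sum(!mapped)
  if (n_unmapped > 0) {
    # unmapped symbols pass through verbatim; only their count is reported
    attr(evidence, "n_unmapped") <- n_unmapped
  } else {
    attr(evidence, "n_unmapped") <- 0L
  }
  evidence
}

#' Merge multi-source evidence into a disease-target set
#'
#' Deduplicates to one entry per gene symbol, records the distinct sources
#' attesting it, and flags genes supported by at least two sources as
#' high-confidence. Single-source genes are annotated, not removed;
#' downstream stages may filter on the flag.
#'
#' @param evidence Data.frame with columns `symbol`, `source` (symbols
#'   already standardized).
#' @return A data.frame of class `disease_target_set` with columns `symbol`,
#'   `sources` (semicolon-joined), `support_count`, `high_confidence`,
#'   sorted by symbol.
#' @export
merge_sources <- function(evidence) {
  if (nrow(evidence) == 0) {
    out <- data.frame(symbol = character(0), sources = character(0),
                      support_count = integer(0),
                      high_confidence = logical(0))
    class(out) <- c("disease_target_set", class(out))
    return(out)
  }
  sp <- split(evidence$source, evidence$symbol)
  srcs <- lapply(sp, function(s) sort(unique(s)))
  out <- data.frame(symbol = names(sp),
                    sources = vapply(srcs, paste, character(1),
                                     collapse = ";"),
                    support_count = vapply(srcs, length, integer(1)),
                    stringsAsFactors = FALSE)
  out$high_confidence <- out$support_count >= 2
  out <- out[order(out$symbol), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("disease_target_set", class(out))
  out
}

#' Intersect predicted compound targets with a disease-target set
#'
#' Exact set intersection on canonical symbols, with the Venn counts needed
#' for reporting.
#'
#' @param predicted Character vector of predicted target symbols, or a
#'   data.frame with a `symbol` column (a `compound` column, if present, is
#'   aggregated per gene into the overlap table).
#' @param disease A [merge_sources()] result or character vector of disease
#'   gene symbols.
#' @return A list with `overlap` (data.frame: `symbol`, plus supporting
#'   `compounds` and `sources` when available) and `venn`
#'   (`n_predicted`, `n_disease`, `n_overlap`).
#' @export
intersect_targets <- function(predicted, disease) {
  pred_df <- NULL
  if (is.data.frame(predicted)) {
    pred_df <- predicted
    predicted <- unique(predicted$symbol)
  } else {
    predicted <- unique(predicted)
  }
  dis_df <- NULL
  if (is.data.frame(disease)) {
    dis_df <- disease
    disease <- unique(disease$symbol)
  } else {
    disease <- unique(disease)
  }
  ov <- sort(intersect(predicted, disease))
  overlap <- data.frame(symbol = ov, stringsAsFactors = FALSE)
  if (!is.null(pred_df) && "compound" %in% names(pred_df)) {
    cmp <- split(pred_df$compound, pred_df$symbol)
    overlap$compounds <- vapply(ov, function(s) {
      paste(sort(unique(cmp[[s]])), collapse = ";")
    }, character(1))
  }
  if (!is.null(dis_df) && "sources" %in% names(dis_df)) {
    overlap$sources <- dis_df$sources[match(ov, dis_df$symbol)]
  }
  list(overlap = overlap,
       venn = c(n_predicted = length(predicted),
                n_disease = length(disease),
                n_overlap = length(ov)))
}

#' Load per-source disease evidence tables from a directory
#'
#' Expects one TSV per source named `<source>.tsv` (sources: genecards, omim,
#' ttd, drugbank, pharmgkb), each with a `symbol` column and, for genecards,
#' a `relevance_score` column. Missing source files are skipped.
#'
#' @param dir Directory of source tables.
#' @return A combined evidence data.frame with a `source` column.
#' @export
load_disease_sources <- function(dir) {
  out <- list()
  for (s in .target_sources) {
    path <- file.path(dir, paste0(s, ".tsv"))
    if (!file.exists(path)) next
    df <- read_tsv_table(path, required_cols = "symbol")
    df$source <- s
    if (!"relevance_score" %in% names(df)) df$relevance_score <- NA_real_
    out[[s]] <- df[, c("symbol", "source", "relevance_score")]
  }
  if (length(out) == 0) stop("no source tables found in ", dir, call. = FALSE)
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}
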