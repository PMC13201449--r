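## Hypergeometric over-representation analysis against GMT gene-set
## collections, reporting the Count / fold-Enrichment / log10 p convention
## used by term-annotation services.

#' Load a GMT gene-set file
#'
#' GMT dialect: one term per line, tab-separated -- term id, description,
#' then member genes. Empty gene lists and duplicate term ids are errors.
#'
#' @param path Path to a `.gmt` file.
#' @param category Optional category label attached to every term (e.g.
#'   `"BP"`, `"pathway"`); defaults to the file's base name.
#' @return A list of annotation sets, each `list(term_id, description,
#'   category, genes)`.
#' @export
load_gmt <- function(path, category = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (is.null(category)) {
    category <- sub("\\.gmt$", "", basename(path))
  }
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  out <- vector("list", length(lines))
  seen <- character(0)
  for (i in seq_along(lines)) {
    parts <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(parts) < 3) {
      stop("malformed GMT line ", i, " in ", basename(path),
           ": need term, description and at least one gene", call. = FALSE)
    }
    id <- parts[1]
    if (id %in% seen) {
      stop("duplicate term id '", id, "' at line ", i, " in ",
           basename(path), call. = FALSE)
    }
    seen <- c(seen, id)
    genes <- unique(parts[-(1:2)])
    genes <- genes[nzchar(genes)]
    if (length(genes) == 0) {
      stop("term '", id, "' at line ", i, " has no genes", call. = FALSE)
    }
    out[[i]] <- list(term_id = id, description = parts[2],
                     category = category, genes = genes)
  }
  out
}

#' Hypergeometric upper-tail probability
#'
#' `P(X >= k)` for `X ~ Hypergeometric(N, K, n)`: the probability of drawing
#' at least `k` annotated genes when `n` genes are drawn without replacement
#' from a universe of `N` genes of which `K` are annotated. Computed in log
#' space via [stats::phyper()] for numerical stability.
#'
#' @param k Observed overlap.
#' @param n Drawn list size.
#' @param K Annotated (term) size.
#' @param N Universe (background) size.
#' @return The upper-tail p-value.
#' @examples
#' hypergeom_upper_tail(5, 5, 5, 20)  # 1 / choose(20, 5)
#' @export
hypergeom_upper_tail <- function(k, n, K, N) {
  stopifnot(k >= 0, n >= 0, K >= 0, n <= N, K <= N, k <= min(n, K))
  if (k == 0) return(1)
  lp <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE, log.p = TRUE)
  exp(lp)
}

#' Over-representation analysis of a gene list
#'
#' One hypergeometric upper-tail test per annotation term with non-empty
#' overlap (`k >= 1`). Fold enrichment is `(k/n) / (K/N)`; `log_p` is the
#' log10 of the unadjusted p; `q_value` is the Benjamini-Hochberg adjusted p
#' computed within each category. Genes outside the background are dropped
#' from the list with a warning, and when the background is an explicit gene
#' vector, term sizes count only background members. Results are sorted by p
#' ascending (ties by term id).
#'
#' @param gene_list Character vector of gene symbols.
#' @param annotations List of annotation sets from [load_gmt()] (several
#'   files may be concatenated with `c()`).
#' @param background Gene universe: a character vector, or a single integer
#'   taken as the universe size (e.g. `20000`). Defaults to the union of all
#'   genes in `annotations`.
#' @return Data.frame with columns `term_id`, `description`, `category`,
#'   `Count`, `term_size`, `input_size`, `background_size`, `Enrichment`,
#'   `LogP`, `p_value`, `q_value`.
#' @export
ora <- function(gene_list, annotations, background = NULL) {
  stopifnot(length(annotations) >= 1)
  all_genes <- unique(unlist(lapply(annotations, `[[`, "genes")))
  if (is.null(background)) {
    background <- all_genes
  }
  if (is.numeric(background)) {
    N <- as.integer(background)
    if (N < length(all_genes)) {
      stop("numeric background smaller than the annotated gene union",
           call. = FALSE)
    }
    in_bg <- function(g) rep(TRUE, length(g))
  } else {
    background <- unique(background)
    N <- length(background)
    in_bg <- function(g) g %in% background
  }
  if (N == 0) stop("empty background", call. = FALSE)
  gene_list <- unique(gene_list)
  outside <- !in_bg(gene_list)
  if (any(outside)) {
    warning(sum(outside), " gene(s) outside the background dropped",
            call. = FALSE)
    gene_list <- gene_list[!outside]
  }
  n <- length(gene_list)
  rows <- lapply(annotations, function(a) {
    genes <- a$genes
    if (is.character(background)) genes <- intersect(genes, background)
    k <- length(intersect(gene_list, genes))
    if (k < 1) return(NULL)
    K <- length(genes)
    p <- hypergeom_upper_tail(k, n, K, N)
    data.frame(term_id = a$term_id, description = a$description,
               category = a$category, Count = k, term_size = K,
               input_size = n, background_size = N,
               Enrichment = (k / n) / (K / N),
               LogP = log10(p), p_value = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    return(data.frame(term_id = character(0), description = character(0),
                      category = character(0), Count = integer(0),
                      term_size = integer(0), input_size = integer(0),
                      background_size = integer(0), Enrichment = numeric(0),
                      LogP = numeric(0), p_value = numeric(0),
                      q_value = numeric(0)))
  }
  out$q_value <- NA_real_
  for (cat in unique(out$category)) {
    idx <- out$category == cat
    out$q_value[idx] <- stats::p.adjust(out$p_value[idx], method = "BH")
  }
  out <- out[order(out$p_value, out$term_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Select the top enriched terms
#'
#' @param results Output of [ora()].
#' @param n Number of terms to keep (default 20).
#' @param per_category Apply the cutoff within each category (default TRUE).
#' @return The trimmed results, sorted by p ascending (ties by term id).
#' @export
top_terms <- function(results, n = 20, per_category = TRUE) {
  take <- function(df) {
    df <- df[order(df$p_value, df$term_id), , drop = FALSE]
    df[seq_len(min(n, nrow(df))), , drop = FALSE]
  }
  out <- if (per_category && nrow(results) > 0) {
    do.call(rbind, lapply(split(results, results$category), take))
  } else {
    take(results)
  }
  out <- out[order(out$p_value, out$term_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
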