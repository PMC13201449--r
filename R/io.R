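#' Read a tab-separated table
#'
#' Thin wrapper over [utils::read.delim()] with the conventions used by every
#' table this package consumes: header row, tab separator, no factors, no
#' name mangling, `#` not treated as a comment character (STRING exports use
#' `#node1` headers).
#'
#' @param path Path to a TSV file.
#' @param required_cols Character vector of column names that must be present;
#'   a missing column raises an error naming it.
#' @return A `data.frame`.
#' @export
read_tsv_table <- function(path, required_cols = NULL) {
  if (!file.exists(path)) {
    stop("file not found: ", path, call. = FALSE)
  }
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE,
                          comment.char = "", quote = "")
  if (!is.null(required_cols)) {
    missing <- setdiff(required_cols, names(df))
    if (length(missing) > 0) {
      stop("missing required column(s) in ", basename(path), ": ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
  }
  df
}

#' Write a tab-separated table
#'
#' @param df A data.frame.
#' @param path Output path; parent directories are created.
#' @return `path`, invisibly.
#' @export
write_tsv_table <- function(df, path) {
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Locate a packaged example data file
#'
#' @param filename File name under `extdata/`; with no argument, lists the
#'   available files.
#' @return Full path to the file.
#' @export
netpharm_example <- function(filename = NULL) {
  if (is.null(filename)) {
    return(dir(system.file("extdata", package = "netpharm")))
  }
  path <- system.file("extdata", filename, package = "netpharm")
  if (!nzchar(path)) stop("no packaged file named ", filename, call. = FALSE)
  path
}

#' Reference compound network profile of the 49 I. hispidus constituents
#'
#' Loads the packaged 49-compound reference set: per-compound average
#' shortest-path length, normalized betweenness, closeness and degree within
#' the drug--compound--target network. Used as the degree-sequence preset
#' `"ih49"` by [gen_compound_target_edges()] and as a convention fixture for
#' the centrality code (closeness is the reciprocal of the average
#' shortest-path length for every row).
#'
#' @return A data.frame with columns `mol_id`, `compound`, `aspl`,
#'   `betweenness`, `closeness`, `degree`.
#' @export
ih49_profiles <- function() {
  read_tsv_table(netpharm_example("ih49_compound_profiles.tsv"),
                 required_cols = c("mol_id", "compound", "aspl",
                                   "betweenness", "closeness", "degree"))
}

#' Reference MS constituent table of I. hispidus
#'
#' High-resolution mass-spectrometry constituents: retention time, observed
#' m/z, candidate molecular formula, three MS/MS fragment masses (stored but
#' never matched -- precursor-only annotation), and compound name.
#'
#' @return A data.frame with columns `rt_min`, `mz`, `formula`,
#'   `frag1`..`frag3`, `compound`.
#' @export
ih_ms_constituents <- function() {
  read_tsv_table(netpharm_example("ih_ms_constituents.tsv"),
                 required_cols = c("rt_min", "mz", "formula", "compound"))
}

#' Synthetic docking score table
#'
#' A 25-pair ligand x receptor docking worklist for the five hub compounds
#' against the five top core targets (with their PDB structure ids). The
#' three withanolide energies against EGFR (-9.3), BCL2 (-9.1) and STAT3
#' (-8.8 kcal/mol) are the reported reference values; every other energy is
#' a synthetic placeholder, as the file name indicates.
#'
#' @return A data.frame with columns `ligand`, `receptor`, `pdb_id`,
#'   `energy_kcal_mol`.
#' @export
synthetic_docking_scores <- function() {
  read_tsv_table(netpharm_example("synthetic_docking_scores.tsv"),
                 required_cols = c("ligand", "receptor", "pdb_id",
                                   "energy_kcal_mol"))
}
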