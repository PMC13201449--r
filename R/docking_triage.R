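## Docking-candidate selection and score triage.  Docking itself is run by
## an external engine; this module selects the ligand/receptor candidates by
## network rank, emits the pairing worklist, and classifies the returned
## binding energies against the favorability threshold.

#' Select docking ligand and receptor candidates by network rank
#'
#' Ligands are the top-`n` compounds by degree in the compound--target
#' network (ties by raw betweenness descending then id ascending); receptors
#' are the top-`n` core targets by degree in the PPI core profile (same tie
#' rules on the `betweenness` column). The full `n x n` pairing is emitted
#' as a docking worklist.
#'
#' @param compound_profiles [node_centralities()] output including compound
#'   nodes.
#' @param core_targets Core-target profile (the `core` element of
#'   [core_target_screen()], or any data.frame with `node_id`, `degree` and
#'   optionally `betweenness`).
#' @param n Number of candidates on each side (default 5; truncated with a
#'   warning when fewer are available).
#' @return List with `ligands`, `receptors` (character vectors) and
#'   `worklist` (data.frame `ligand`, `receptor`).
#' @export
select_candidates <- function(compound_profiles, core_targets, n = 5) {
  stopifnot(nrow(compound_profiles) >= 1)
  if (is.null(core_targets) || nrow(core_targets) == 0) {
    stop("empty core-target list", call. = FALSE)
  }
  ligands <- top_compounds(compound_profiles, k = n)$node_id
  bt <- if ("betweenness" %in% names(core_targets)) {
    core_targets$betweenness
  } else {
    rep(0, nrow(core_targets))
  }
  ord <- order(-core_targets$degree, -bt, core_targets$node_id)
  receptors <- core_targets$node_id[ord][seq_len(min(n, nrow(core_targets)))]
  if (length(ligands) < n || length(receptors) < n) {
    warning("fewer than ", n, " candidates available; worklist truncated",
            call. = FALSE)
  }
  wl <- expand.grid(ligand = ligands, receptor = receptors,
                    stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
  list(ligands = ligands, receptors = receptors, worklist = wl)
}

#' Flag energetically favorable docking scores
#'
#' A pose is favorable when its binding energy is at or below the threshold
#' (inclusive; default -5.0 kcal/mol). Rows with non-numeric energies are
#' rejected with a warning.
#'
#' @param records Data.frame with columns `ligand`, `receptor`,
#'   `energy_kcal_mol` (an optional `pdb_id` column is carried through).
#' @param threshold Favorability threshold in kcal/mol (default -5.0).
#' @return List with `records` (input plus logical `favorable`), `summary`
#'   (per-ligand and per-receptor favorable counts) and `best` (the most
#'   negative pair).
#' @export
flag_favorable <- function(records, threshold = -5.0) {
  stopifnot(all(c("ligand", "receptor", "energy_kcal_mol") %in%
                names(records)))
  e <- suppressWarnings(as.numeric(records$energy_kcal_mol))
  bad <- !is.finite(e)
  if (any(bad)) {
    warning(sum(bad), " row(s) with non-numeric energy rejected",
            call. = FALSE)
    records <- records[!bad, , drop = FALSE]
    e <- e[!bad]
  }
  records$energy_kcal_mol <- e
  records$favorable <- e <= threshold
  per_ligand <- stats::aggregate(favorable ~ ligand, records, sum)
  per_receptor <- stats::aggregate(favorable ~ receptor, records, sum)
  best <- records[which.min(records$energy_kcal_mol), , drop = FALSE]
  list(records = records,
       summary = list(per_ligand = per_ligand, per_receptor = per_receptor,
                      n_favorable = sum(records$favorable),
                      n_total = nrow(records)),
       best = best)
}
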