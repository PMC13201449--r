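## End-to-end orchestration: screen -> merge/intersect -> build networks ->
## PPI screen -> enrichment -> docking triage, with a JSON run manifest
## recording parameters, per-stage cardinalities and content hashes.

#' Default pipeline configuration
#'
#' Returns the configuration skeleton consumed by [run_pipeline()]: input
#' paths (NULL entries must be filled in), the documented thresholds
#' (GeneCards relevance 37.5, PPI confidence 0.7, two screening rounds at a
#' strict 4-of-6 quorum, ppm tolerance 5, docking favorability -5.0
#' kcal/mol, rule quorum 2, top-5 candidates, top-20 terms) and the run
#' seed.
#'
#' @param out_dir Output directory for stage results.
#' @return A named list.
#' @export
default_config <- function(out_dir = "netpharm_run") {
  list(
    descriptors = NULL,          # compound descriptor TSV
    compound_target_edges = NULL, # compound->target edge TSV
    disease_source_dir = NULL,   # directory of per-source TSVs
    synonym_map = NULL,          # optional alias->canonical TSV
    ppi_edges = NULL,            # STRING-style scored edge TSV
    gmt = NULL,                  # one or more GMT files
    docking_scores = NULL,       # optional external docking score TSV
    min_rules = 2,
    genecards_min = 37.5,
    ppi_min_score = 0.7,
    screen_rounds = 2,
    screen_quorum = 4,
    ora_background = NULL,       # NULL = union of GMT genes
    docking_threshold = -5.0,
    ppm_tolerance = 5,
    top_n_compounds = 5,
    top_n_terms = 20,
    seed = 1,
    out_dir = out_dir
  )
}

.validate_config <- function(config) {
  req <- c("descriptors", "compound_target_edges", "disease_source_dir",
           "ppi_edges", "gmt")
  for (k in req) {
    if (is.null(config[[k]])) {
      stop("config entry '", k, "' is required", call. = FALSE)
    }
    for (p in config[[k]]) {
      if (!file.exists(p)) {
        stop("config entry '", k, "' points to a missing path: ", p,
             call. = FALSE)
      }
    }
  }
  stopifnot(config$min_rules >= 0, config$min_rules <= 5,
            config$ppi_min_score >= 0, config$ppi_min_score <= 1,
            config$screen_rounds >= 1,
            all(config$screen_quorum >= 0), all(config$screen_quorum <= 6),
            config$ppm_tolerance > 0)
  invisible(TRUE)
}

#' Run the full network-pharmacology pipeline
#'
#' Executes, in order: compound drug-likeness screening; disease-target
#' integration and intersection with the accepted compounds' predicted
#' targets; compound--target and intersection network construction with
#' centrality profiles; PPI confidence filtering and iterative core-target
#' screening; over-representation analysis of the overlap genes; docking
#' candidate selection and score triage (skipped without a score table).
#' Every stage writes its outputs under `config$out_dir` and is recorded in
#' `manifest.json` with row counts and md5 content hashes; a rerun with
#' identical config and inputs reproduces identical hashes.
#'
#' @param config A configuration list as from [default_config()] with the
#'   input paths filled in.
#' @return The manifest, invisibly (a named list; also written as JSON).
#' @export
run_pipeline <- function(config) {
  .validate_config(config)
  out_dir <- config$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(parameters = config[setdiff(names(config), "out_dir")],
                   stages = list())
  note <- function(stage, outputs, counts) {
    manifest$stages[[stage]] <<- list(
      outputs = as.list(outputs),
      counts = as.list(counts),
      md5 = as.list(unname(tools::md5sum(outputs))))
    message(sprintf("[%s] %s", stage,
                    paste(names(counts), unlist(counts), sep = "=",
                          collapse = ", ")))
  }

  # 1. compound screening
  descriptors <- read_tsv_table(config$descriptors)
  report <- screen_compounds(descriptors, min_rules = config$min_rules)
  accepted <- accepted_compounds(report)
  f_screen <- file.path(out_dir, "compound_screen.tsv")
  write_tsv_table(report, f_screen)
  note("screen_compounds", f_screen,
       c(compounds_in = nrow(report), compounds_kept = nrow(accepted)))
  if (nrow(accepted) == 0) stop("screening accepted no compounds",
                                call. = FALSE)

  # 2. target integration and intersection
  edges <- read_tsv_table(config$compound_target_edges,
                          required_cols = c("compound", "target"))
  edges <- edges[edges$compound %in% accepted$compound_id, , drop = FALSE]
  evidence <- load_disease_sources(config$disease_source_dir)
  evidence <- filter_by_relevance(evidence, config$genecards_min)
  if (!is.null(config$synonym_map)) {
    smap <- read_tsv_table(config$synonym_map,
                           required_cols = c("alias", "canonical"))
    evidence <- standardize_symbols(evidence, smap)
  }
  disease <- merge_sources(evidence)
  predicted <- data.frame(symbol = edges$target, compound = edges$compound,
                          stringsAsFactors = FALSE)
  inter <- intersect_targets(predicted, disease)
  f_merged <- file.path(out_dir, "disease_targets.tsv")
  f_overlap <- file.path(out_dir, "overlap_targets.tsv")
  f_venn <- file.path(out_dir, "venn.json")
  write_tsv_table(disease, f_merged)
  write_tsv_table(inter$overlap, f_overlap)
  jsonlite::write_json(as.list(inter$venn), f_venn, auto_unbox = TRUE)
  note("merge_intersect", c(f_merged, f_overlap, f_venn),
       c(targets_merged = nrow(disease),
         high_confidence = sum(disease$high_confidence),
         predicted = inter$venn[["n_predicted"]],
         overlap = inter$venn[["n_overlap"]]))

  # 3. networks and compound ranking
  net_ct <- build_compound_target_network(edges)
  prof_ct <- node_centralities(net_ct)
  net_int <- build_intersection_network(edges, inter$overlap$symbol)
  f_prof <- file.path(out_dir, "compound_target_profiles.tsv")
  write_tsv_table(prof_ct, f_prof)
  paths_ct <- export_network(net_ct, file.path(out_dir, "compound_target"))
  paths_int <- export_network(net_int, file.path(out_dir, "intersection"))
  note("build_networks", c(f_prof, paths_ct, paths_int),
       c(ct_nodes = igraph::vcount(net_ct),
         ct_edges = igraph::ecount(net_ct),
         int_nodes = igraph::vcount(net_int),
         int_edges = igraph::ecount(net_int)))

  # 4. PPI screen
  ppi <- load_ppi_edges(config$ppi_edges)
  ppi_net <- build_ppi_network(ppi, min_score = config$ppi_min_score,
                               drop_isolated = TRUE,
                               universe = inter$overlap$symbol)
  screen <- core_target_screen(ppi_net, rounds = config$screen_rounds,
                               quorum = config$screen_quorum)
  f_core <- file.path(out_dir, "core_targets.tsv")
  write_tsv_table(screen$core, f_core)
  f_rounds <- file.path(out_dir, "screen_rounds.json")
  jsonlite::write_json(screen$rounds, f_rounds)
  note("ppi_screen", c(f_core, f_rounds),
       c(ppi_nodes = igraph::vcount(ppi_net),
         ppi_edges = igraph::ecount(ppi_net),
         isolated_removed = ppi_net$n_isolated_removed,
         core_targets = nrow(screen$core)))

  # 5. enrichment of the overlap genes
  anns <- do.call(c, lapply(config$gmt, load_gmt))
  enr <- ora(inter$overlap$symbol, anns, background = config$ora_background)
  enr_top <- top_terms(enr, n = config$top_n_terms)
  f_enr <- file.path(out_dir, "enrichment.tsv")
  f_enr_top <- file.path(out_dir, "enrichment_top.tsv")
  write_tsv_table(enr, f_enr)
  write_tsv_table(enr_top, f_enr_top)
  note("enrichment", c(f_enr, f_enr_top),
       c(terms_tested = nrow(enr), terms_reported = nrow(enr_top)))

  # 6. docking triage
  cand <- select_candidates(prof_ct, screen$core,
                            n = config$top_n_compounds)
  f_wl <- file.path(out_dir, "docking_worklist.tsv")
  write_tsv_table(cand$worklist, f_wl)
  outs <- f_wl
  counts <- c(worklist_pairs = nrow(cand$worklist))
  if (!is.null(config$docking_scores)) {
    scores <- read_tsv_table(config$docking_scores,
                             required_cols = c("ligand", "receptor",
                                               "energy_kcal_mol"))
    triage <- flag_favorable(scores, threshold = config$docking_threshold)
    f_dock <- file.path(out_dir, "docking_triage.tsv")
    write_tsv_table(triage$records, f_dock)
    outs <- c(outs, f_dock)
    counts <- c(counts, favorable = triage$summary$n_favorable,
                scored = triage$summary$n_total)
  }
  note("docking_triage", outs, counts)

  f_manifest <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, f_manifest, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(manifest)
}

#' Generate a complete synthetic input bundle for the pipeline
#'
#' Writes, under `dir`, every file [run_pipeline()] consumes, generated at
#' the reference study cardinalities by default: descriptor table, the
#' `ih49` compound--target preset over a 608-target universe, five disease
#' source tables with a 2,367-gene union and a 169-gene planted overlap, a
#' scored PPI table over the overlap with 6 isolated nodes and a planted
#' 20-protein core, a GMT collection with a planted term, and a docking
#' score table. Returns a filled configuration plus the ground truth.
#'
#' @param dir Directory to write inputs into.
#' @param seed Integer seed driving every generator.
#' @param union_size,overlap_size,n_isolated,core_size Study cardinalities.
#' @return List with `config` (ready for [run_pipeline()]) and `truth`.
#' @export
gen_pipeline_bundle <- function(dir, seed = 1, union_size = 2367,
                                overlap_size = 169, n_isolated = 6,
                                core_size = 20) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  edges <- gen_compound_target_edges(preset = "ih49", seed = seed)
  prof <- ih49_profiles()
  # descriptor table covering the 49 preset compounds, all accept-eligible
  desc <- gen_descriptor_table(nrow(prof), frac_pass = 1, seed = seed + 1)
  desc$compound_id <- prof$mol_id
  desc$name <- prof$compound
  predicted <- unique(edges$target)
  # source sizes scale with the requested union, in proportions typical of
  # the five databases (GeneCards dominating)
  sizes <- round(union_size * c(genecards = 0.85, omim = 0.13, ttd = 0.11,
                                drugbank = 0.105, pharmgkb = 0.093))
  dis <- gen_disease_sources(source_sizes = sizes,
                             union_size = union_size, predicted = predicted,
                             overlap_size = overlap_size, seed = seed + 2)
  overlap <- dis$truth$overlap
  ppi <- gen_ppi(n_nodes = overlap_size, n_isolated = n_isolated,
                 core_size = core_size, seed = seed + 3)
  # PPI generator names map onto the overlap genes (sorted, positional)
  name_map <- stats::setNames(sort(overlap), sort(ppi$universe))
  ppi$edges$protein_a <- unname(name_map[ppi$edges$protein_a])
  ppi$edges$protein_b <- unname(name_map[ppi$edges$protein_b])
  ppi$truth$core <- sort(unname(name_map[ppi$truth$core]))
  ppi$truth$isolated <- sort(unname(name_map[ppi$truth$isolated]))
  swap <- ppi$edges$protein_a > ppi$edges$protein_b
  tmp <- ppi$edges$protein_a[swap]
  ppi$edges$protein_a[swap] <- ppi$edges$protein_b[swap]
  ppi$edges$protein_b[swap] <- tmp
  planted <- .with_seed(seed + 6, sample(overlap, 30))
  ann <- gen_annotations(n_terms = 60, term_size_range = c(10, 60),
                         planted_genes = planted,
                         background_size = 3000, seed = seed + 4)
  dock <- gen_docking_table(ligands = prof$mol_id[1:5],
                            receptors = ppi$truth$core[1:5],
                            seed = seed + 5)

  paths <- list(
    descriptors = file.path(dir, "descriptors.tsv"),
    compound_target_edges = file.path(dir, "compound_target_edges.tsv"),
    disease_source_dir = file.path(dir, "disease_sources"),
    ppi_edges = file.path(dir, "ppi_edges.tsv"),
    gmt = file.path(dir, "annotations.gmt"),
    docking_scores = file.path(dir, "docking_scores.tsv"))
  write_tsv_table(desc, paths$descriptors)
  write_tsv_table(edges, paths$compound_target_edges)
  dir.create(paths$disease_source_dir, showWarnings = FALSE)
  for (s in unique(dis$evidence$source)) {
    write_tsv_table(dis$evidence[dis$evidence$source == s,
                                 c("symbol", "relevance_score")],
                    file.path(paths$disease_source_dir, paste0(s, ".tsv")))
  }
  write_tsv_table(ppi$edges, paths$ppi_edges)
  write_gmt(ann$annotations, paths$gmt)
  write_tsv_table(dock, paths$docking_scores)

  config <- utils::modifyList(default_config(file.path(dir, "out")), paths)
  config$seed <- seed
  list(config = config,
       truth = list(disease = dis$truth, ppi = ppi$truth,
                    planted_term = ann$truth$planted_term_id))
}
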