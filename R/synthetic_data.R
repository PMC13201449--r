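## Seeded generators for every pipeline input, with ground truth known by
## construction.  Each generator is a pure function of its arguments:
## identical spec and seed give identical output.  Synthetic gene symbols are
## drawn from a fixed fake namespace (G000001, ...) so synthetic runs can
## never be mistaken for biological claims.

# Run `expr` under a fixed RNG seed without disturbing the caller's RNG.
.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

.gene_ns <- function(i) sprintf("G%06d", i)

#' Generate a compound descriptor table with known screening labels
#'
#' Each row is, with probability `frac_pass`, drawn from comfortable
#' in-bounds descriptor ranges (passing Lipinski, Veber and Egan, and inside
#' the GI-absorption ellipse) and otherwise from a high-TPSA region that is
#' GI-low and violates the TPSA-bounded rules. The constructed intent is
#' recorded in the `truth_accept` column and agrees with
#' [screen_compounds()] verdicts row by row.
#'
#' @param n Number of compounds.
#' @param frac_pass Target share of accept-eligible compounds in `[0,1]`
#'   (default 0.5).
#' @param seed Integer seed.
#' @return Descriptor data.frame with a logical `truth_accept` column.
#' @export
gen_descriptor_table <- function(n, frac_pass = 0.5, seed = 1) {
  stopifnot(n > 0, frac_pass >= 0, frac_pass <= 1)
  .with_seed(seed, {
    pass <- stats::runif(n) < frac_pass
    mk <- function(lo, hi) stats::runif(n, lo, hi)
    mki <- function(lo, hi) sample(lo:hi, n, replace = TRUE)
    df <- data.frame(
      compound_id = sprintf("C%04d", seq_len(n)),
      mw = ifelse(pass, mk(220, 450), mk(520, 900)),
      mlogp = ifelse(pass, mk(0.5, 3.5), mk(4.5, 7)),
      wlogp = ifelse(pass, mk(0.5, 3.0), mk(-3, 0)),
      xlogp = mk(-1, 4.5),
      tpsa = ifelse(pass, mk(20, 110), mk(180, 300)),
      hbd = ifelse(pass, mki(0, 4), mki(6, 9)),
      hba = ifelse(pass, mki(2, 8), mki(11, 15)),
      rotb = ifelse(pass, mki(0, 8), mki(12, 20)),
      mr = mk(40, 125),
      heavy_atoms = mki(20, 45),
      carbons = mki(10, 25),
      heteroatoms = mki(2, 8),
      rings = mki(1, 4),
      truth_accept = pass,
      stringsAsFactors = FALSE)
    df
  })
}

#' Generate compound--target edges realizing an exact degree sequence
#'
#' Each compound is assigned `degree - 1` distinct targets (the remaining
#' unit of its degree is the drug-hub edge added at network-build time) by a
#' deterministic round-robin walk over a seeded shuffle of the target
#' universe, which guarantees that the degree sequence is realized exactly
#' and that every one of the `n_targets` targets appears at least once.
#'
#' @param degree_seq Integer vector of compound degrees (drug edge
#'   included), or `NULL` with `preset`.
#' @param n_targets Size of the target universe.
#' @param preset `"ih49"` uses the packaged 49-compound reference degree
#'   sequence (with its compound names) over a 608-target universe.
#' @param seed Integer seed.
#' @return Data.frame with columns `compound`, `target`.
#' @export
gen_compound_target_edges <- function(degree_seq = NULL, n_targets = NULL,
                                      preset = NULL, seed = 1) {
  compounds <- NULL
  if (!is.null(preset)) {
    if (preset != "ih49") stop("unknown preset: ", preset, call. = FALSE)
    prof <- ih49_profiles()
    degree_seq <- prof$degree
    compounds <- prof$mol_id
    if (is.null(n_targets)) n_targets <- 608L
  }
  stopifnot(!is.null(degree_seq), !is.null(n_targets), n_targets >= 1)
  degree_seq <- as.integer(degree_seq)
  if (is.null(compounds)) compounds <- sprintf("C%03d", seq_along(degree_seq))
  if (any(degree_seq < 1)) {
    stop("degrees must be >= 1 (the drug edge)", call. = FALSE)
  }
  slots <- degree_seq - 1L
  if (any(slots > n_targets)) {
    stop("infeasible degree sequence: a compound needs more distinct ",
         "targets than the universe holds", call. = FALSE)
  }
  if (sum(slots) < n_targets) {
    stop("infeasible degree sequence: ", sum(slots), " target slots cannot ",
         "cover a universe of ", n_targets, call. = FALSE)
  }
  .with_seed(seed, {
    universe <- sample(.gene_ns(seq_len(n_targets)))
    total <- sum(slots)
    pick <- universe[(seq_len(total) - 1L) %% n_targets + 1L]
    edges <- data.frame(compound = rep(compounds, times = slots),
                        target = pick, stringsAsFactors = FALSE)
    edges
  })
}

#' Generate five disease-target source tables with a planted overlap
#'
#' Builds a disease gene universe of exactly `union_size` genes of which
#' exactly `overlap_size` are drawn from the supplied `predicted` set, and
#' distributes the universe over the five sources so that every gene is
#' attested at least once and each source has its requested size. GeneCards
#' rows in the universe carry relevance scores at or above 37.5; in addition
#' `n_decoys` decoy GeneCards rows for genes outside the universe carry
#' sub-threshold scores, so relevance filtering has a known effect.
#'
#' @param source_sizes Named or positional integer vector of 5 sizes
#'   (genecards, omim, ttd, drugbank, pharmgkb).
#' @param union_size Exact size of the merged disease-target union.
#' @param predicted Character vector of predicted compound-target symbols.
#' @param overlap_size Exact size of the intersection with `predicted`.
#' @param n_decoys Number of sub-threshold GeneCards decoy rows (default 25).
#' @param seed Integer seed.
#' @return List with `evidence` (combined evidence data.frame: `symbol`,
#'   `source`, `relevance_score`) and `truth` (`union`, `overlap`, `decoys`).
#' @export
gen_disease_sources <- function(source_sizes, union_size, predicted,
                                overlap_size, n_decoys = 25, seed = 1) {
  sources <- c("genecards", "omim", "ttd", "drugbank", "pharmgkb")
  stopifnot(length(source_sizes) == 5)
  if (is.null(names(source_sizes))) names(source_sizes) <- sources
  source_sizes <- source_sizes[sources]
  predicted <- unique(predicted)
  if (overlap_size > min(union_size, length(predicted))) {
    stop("infeasible overlap: larger than union or predicted set",
         call. = FALSE)
  }
  if (sum(source_sizes) < union_size || max(source_sizes) > union_size) {
    stop("infeasible source sizes for a union of ", union_size, call. = FALSE)
  }
  .with_seed(seed, {
    shared <- sample(predicted, overlap_size)
    # disease-only symbols live in a namespace block disjoint from any
    # generated predicted set (offset 10^6 of the fake namespace)
    rest <- .gene_ns(1e6 + seq_len(union_size - overlap_size))
    universe <- sample(c(shared, rest))
    # first pass: each gene attested once, filling sources in turn
    assign_source <- rep(sources, times = source_sizes)[seq_len(union_size)]
    evidence <- data.frame(symbol = universe, source = assign_source,
                           stringsAsFactors = FALSE)
    # second pass: top up each source to its size with distinct extra genes
    for (s in sources) {
      have <- evidence$symbol[evidence$source == s]
      need <- source_sizes[[s]] - length(have)
      if (need > 0) {
        extra <- sample(setdiff(universe, have), need)
        evidence <- rbind(evidence, data.frame(symbol = extra, source = s,
                                               stringsAsFactors = FALSE))
      }
    }
    evidence$relevance_score <- NA_real_
    gc <- evidence$source == "genecards"
    evidence$relevance_score[gc] <- stats::runif(sum(gc), 37.5, 100)
    decoys <- character(0)
    if (n_decoys > 0) {
      decoys <- .gene_ns(2e6 + seq_len(n_decoys))
      evidence <- rbind(evidence, data.frame(
        symbol = decoys, source = "genecards",
        relevance_score = stats::runif(n_decoys, 0, 37.49),
        stringsAsFactors = FALSE))
    }
    rownames(evidence) <- NULL
    list(evidence = evidence,
         truth = list(union = sort(universe), overlap = sort(shared),
                      decoys = decoys))
  })
}

#' Generate a scored PPI edge table with a planted dense core and an exact
#' isolated count
#'
#' Over a universe of `n_nodes` proteins, `n_isolated` designated nodes
#' receive no edge at or above the 0.7 confidence threshold (only optional
#' sub-threshold noise edges); among the rest, the `core_size` planted core
#' nodes are pairwise connected with probability `p_core` and every other
#' pair with probability `p_background`, all with scores in
#' `score_above`. Non-isolated nodes left without a qualifying edge by the
#' random draw are patched with one high-confidence edge to a random
#' non-isolated partner, so the isolated count is exact.
#'
#' @param n_nodes Universe size (default 169).
#' @param n_isolated Exact number of isolated proteins (default 6).
#' @param core_size Planted core size (default 20).
#' @param p_core,p_background Edge probabilities (`p_core > p_background`).
#' @param score_above,score_below Uniform score bands for qualifying and
#'   sub-threshold edges.
#' @param seed Integer seed.
#' @return List with `edges` (`protein_a`, `protein_b`, `combined_score`),
#'   `universe`, and `truth` (`core`, `isolated`).
#' @export
gen_ppi <- function(n_nodes = 169, n_isolated = 6, core_size = 20,
                    p_core = 0.8, p_background = 0.03,
                    score_above = c(0.7, 0.99), score_below = c(0.15, 0.69),
                    seed = 1) {
  stopifnot(n_isolated >= 0, core_size >= 0,
            n_isolated + core_size <= n_nodes,
            p_core > p_background, p_background >= 0)
  .with_seed(seed, {
    universe <- sprintf("P%04d", seq_len(n_nodes))
    isolated <- if (n_isolated > 0) {
      sample(universe, n_isolated)
    } else character(0)
    active <- setdiff(universe, isolated)
    core <- if (core_size > 0) sample(active, core_size) else character(0)
    el <- matrix(character(0), 0, 2)
    if (length(active) >= 2) {
      pairs <- t(utils::combn(active, 2))
      both_core <- pairs[, 1] %in% core & pairs[, 2] %in% core
      p <- ifelse(both_core, p_core, p_background)
      on <- stats::runif(nrow(pairs)) < p
      el <- pairs[on, , drop = FALSE]
    }
    # patch nodes the random draw left without a qualifying edge; partners
    # are core nodes (when a core exists) so patching can never manufacture
    # spurious background hubs
    covered <- unique(c(el))
    orphan <- setdiff(active, covered)
    for (o in orphan) {
      pool <- if (length(setdiff(core, o)) > 0) setdiff(core, o)
              else setdiff(active, o)
      partner <- if (length(pool) == 1) pool else sample(pool, 1)
      el <- rbind(el, c(o, partner))
    }
    edges <- data.frame(protein_a = pmin(el[, 1], el[, 2]),
                        protein_b = pmax(el[, 1], el[, 2]),
                        combined_score = stats::runif(nrow(el),
                                                      score_above[1],
                                                      score_above[2]),
                        stringsAsFactors = FALSE)
    # sub-threshold noise: give each isolated node a couple of weak edges
    if (n_isolated > 0 && nrow(edges) > 0) {
      weak <- do.call(rbind, lapply(isolated, function(iso) {
        partners <- sample(active, min(2, length(active)))
        data.frame(protein_a = pmin(iso, partners),
                   protein_b = pmax(iso, partners),
                   combined_score = stats::runif(length(partners),
                                                 score_below[1],
                                                 score_below[2]),
                   stringsAsFactors = FALSE)
      }))
      edges <- rbind(edges, weak)
    }
    edges <- edges[!duplicated(edges[, 1:2]), , drop = FALSE]
    rownames(edges) <- NULL
    list(edges = edges, universe = universe,
         truth = list(core = sort(core), isolated = sort(isolated)))
  })
}

#' Generate a GMT annotation collection with one planted enriched term
#'
#' The planted term consists of the supplied genes (a subset of the list the
#' enrichment will be run on); the remaining `n_terms - 1` terms are sampled
#' uniformly from the background namespace.
#'
#' @param n_terms Total number of terms (>= 1).
#' @param term_size_range Two integers: min/max size of the random terms.
#' @param planted_genes Character vector forming the planted term.
#' @param background_size Size of the background gene namespace.
#' @param category Category label for all terms (default `"BP"`).
#' @param seed Integer seed.
#' @return List with `annotations` (as from [load_gmt()]), `background`
#'   (character vector) and `truth` (`planted_term_id`).
#' @export
gen_annotations <- function(n_terms, term_size_range = c(10, 50),
                            planted_genes, background_size = 2000,
                            category = "BP", seed = 1) {
  stopifnot(n_terms >= 1, length(planted_genes) >= 1,
            length(planted_genes) <= background_size,
            term_size_range[1] >= 1,
            term_size_range[2] <= background_size)
  .with_seed(seed, {
    background <- unique(c(planted_genes,
                           .gene_ns(seq_len(background_size))))
    background <- background[seq_len(background_size)]
    anns <- vector("list", n_terms)
    anns[[1]] <- list(term_id = "T0001_planted",
                      description = "planted enriched term",
                      category = category, genes = planted_genes)
    if (n_terms > 1) {
      sizes <- sample(term_size_range[1]:term_size_range[2], n_terms - 1,
                      replace = TRUE)
      for (i in seq_len(n_terms - 1)) {
        anns[[i + 1]] <- list(term_id = sprintf("T%04d", i + 1),
                              description = "random term",
                              category = category,
                              genes = sample(background, sizes[i]))
      }
    }
    list(annotations = anns, background = background,
         truth = list(planted_term_id = "T0001_planted"))
  })
}

#' Generate a docking score table
#'
#' Uniform binding energies for every ligand x receptor pair, with a
#' configurable share below the favorability threshold.
#'
#' @param ligands,receptors Character vectors.
#' @param frac_favorable Expected share of favorable pairs (default 0.6).
#' @param threshold Favorability threshold (default -5.0 kcal/mol).
#' @param seed Integer seed.
#' @return Data.frame `ligand`, `receptor`, `energy_kcal_mol`.
#' @export
gen_docking_table <- function(ligands, receptors, frac_favorable = 0.6,
                              threshold = -5.0, seed = 1) {
  stopifnot(length(ligands) >= 1, length(receptors) >= 1)
  .with_seed(seed, {
    wl <- expand.grid(ligand = ligands, receptor = receptors,
                      stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
    fav <- stats::runif(nrow(wl)) < frac_favorable
    wl$energy_kcal_mol <- ifelse(fav,
                                 stats::runif(nrow(wl), threshold - 5,
                                              threshold),
                                 stats::runif(nrow(wl), threshold + 0.1,
                                              threshold + 3))
    wl
  })
}

#' Write a GMT annotation collection to file
#'
#' @param annotations List of annotation sets ([load_gmt()] structure).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(annotations, path) {
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  lines <- vapply(annotations, function(a) {
    paste(c(a$term_id, a$description, a$genes), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
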