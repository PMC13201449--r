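## Compound--target and compound--disease--target network assembly and
## per-node centrality profiles.
##
## Networks are simple undirected igraph objects with a `node_type` vertex
## attribute (drug / disease / compound / target / protein).  Distances are
## unweighted hop counts.  Conventions:
##   * aspl(v)     = mean hop distance from v to all other *reachable* nodes
##                   (NA for an isolated node);
##   * closeness   = 1 / aspl (0 for an isolated node), so closeness * aspl
##                   is exactly 1 for nodes that reach the whole graph;
##   * betweenness = raw pair counts (each unordered pair once, endpoints
##                   excluded), with a normalized companion
##                   raw / ((n-1)(n-2)/2).

#' Build the drug--compound--target network
#'
#' One drug hub node is linked to every compound; compound--target edges are
#' added with target nodes deduplicated across compounds. Under this
#' convention a compound's degree is 1 (drug edge) plus its number of
#' distinct targets.
#'
#' @param edges Data.frame with columns `compound`, `target`.
#' @param drug_label Name of the drug hub node.
#' @return An igraph object with vertex attribute `node_type`.
#' @export
build_compound_target_network <- function(edges, drug_label = "drug") {
  if (nrow(edges) == 0) stop("empty compound-target edge list", call. = FALSE)
  stopifnot(all(c("compound", "target") %in% names(edges)))
  compounds <- unique(edges$compound)
  targets <- unique(edges$target)
  if (drug_label %in% c(compounds, targets)) {
    stop("drug_label collides with a compound/target id", call. = FALSE)
  }
  el <- rbind(cbind(drug_label, compounds),
              unique(as.matrix(edges[, c("compound", "target")])))
  g <- igraph::graph_from_edgelist(el, directed = FALSE)
  g <- igraph::simplify(g)
  igraph::V(g)$node_type <- ifelse(igraph::V(g)$name == drug_label, "drug",
                            ifelse(igraph::V(g)$name %in% compounds,
                                   "compound", "target"))
  g
}

#' Build the drug--compound--disease--target intersection network
#'
#' Compound--target edges are restricted to the overlap gene set; the drug
#' node links to every compound (compounds whose targets are all outside the
#' overlap are retained, attached only to the drug node) and the disease node
#' links to every overlap gene.
#'
#' @param edges Data.frame with columns `compound`, `target`.
#' @param overlap Character vector of shared (disease-intersected) genes.
#' @param drug_label,disease_label Hub node names.
#' @return An igraph object with vertex attribute `node_type` and graph
#'   attribute `edge_classes` (counts of drug--compound, compound--target and
#'   disease--target edges).
#' @export
build_intersection_network <- function(edges, overlap, drug_label = "drug",
                                       disease_label = "disease") {
  if (length(overlap) == 0) stop("empty overlap gene set", call. = FALSE)
  stopifnot(all(c("compound", "target") %in% names(edges)))
  overlap <- unique(overlap)
  compounds <- unique(edges$compound)
  kept <- unique(as.matrix(edges[edges$target %in% overlap,
                                 c("compound", "target"), drop = FALSE]))
  if (nrow(kept) == 0) {
    warning("overlap set shares no gene with the edge targets", call. = FALSE)
  }
  el <- rbind(cbind(drug_label, compounds),
              kept,
              cbind(disease_label, overlap))
  g <- igraph::simplify(igraph::graph_from_edgelist(el, directed = FALSE))
  nm <- igraph::V(g)$name
  igraph::V(g)$node_type <- ifelse(nm == drug_label, "drug",
                            ifelse(nm == disease_label, "disease",
                            ifelse(nm %in% compounds, "compound", "target")))
  g$edge_classes <- c(drug_compound = length(compounds),
                      compound_target = nrow(kept),
                      disease_target = length(overlap))
  g
}

#' Per-node degree, path-length, closeness and betweenness profile
#'
#' @param net An igraph network with at least two nodes.
#' @return Data.frame with columns `node_id`, `node_type` (if present),
#'   `degree`, `aspl`, `closeness`, `betweenness_raw`, `betweenness_norm`.
#' @export
node_centralities <- function(net) {
  n <- igraph::vcount(net)
  stopifnot(n >= 2)
  nm <- igraph::V(net)$name
  d <- igraph::distances(net)
  aspl <- apply(d, 1, function(row) {
    reach <- row[is.finite(row) & row > 0]
    if (length(reach) == 0) NA_real_ else mean(reach)
  })
  clo <- ifelse(is.na(aspl), 0, 1 / aspl)
  btw <- igraph::betweenness(net, directed = FALSE)
  out <- data.frame(node_id = nm,
                    degree = as.integer(igraph::degree(net)),
                    aspl = as.numeric(aspl),
                    closeness = as.numeric(clo),
                    betweenness_raw = as.numeric(btw),
                    betweenness_norm = as.numeric(btw) /
                      ((n - 1) * (n - 2) / 2),
                    stringsAsFactors = FALSE)
  if ("node_type" %in% igraph::vertex_attr_names(net)) {
    out <- cbind(out[, "node_id", drop = FALSE],
                 node_type = igraph::V(net)$node_type,
                 out[, -1, drop = FALSE])
  }
  rownames(out) <- NULL
  out
}

#' Top compounds by network degree
#'
#' Ranks compound nodes by degree descending; ties are broken by raw
#' betweenness descending, then node id ascending.
#'
#' @param profiles Output of [node_centralities()] including a `node_type`
#'   column.
#' @param k Number of compounds to return (default 5; `k` larger than the
#'   number of compounds returns all).
#' @return The top-`k` compound rows of `profiles`, ranked.
#' @export
top_compounds <- function(profiles, k = 5) {
  stopifnot("node_type" %in% names(profiles))
  cmp <- profiles[profiles$node_type == "compound", , drop = FALSE]
  ord <- order(-cmp$degree, -cmp$betweenness_raw, cmp$node_id)
  out <- cmp[ord, , drop = FALSE][seq_len(min(k, nrow(cmp))), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Export a network in SIF and GraphML formats
#'
#' Writes `<prefix>.sif` (source, interaction `"pp"`, target), a GraphML file
#' `<prefix>.graphml` for network viewers, and a node-attribute TSV
#' `<prefix>_nodes.tsv`.
#'
#' @param net An igraph network.
#' @param prefix Output path prefix.
#' @return Character vector of the written paths, invisibly.
#' @export
export_network <- function(net, prefix) {
  dir.create(dirname(prefix), showWarnings = FALSE, recursive = TRUE)
  el <- igraph::as_edgelist(net)
  sif <- file.path(paste0(prefix, ".sif"))
  utils::write.table(data.frame(source = el[, 1], interaction = "pp",
                                target = el[, 2]),
                     sif, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  gml <- paste0(prefix, ".graphml")
  igraph::write_graph(net, gml, format = "graphml")
  nodes <- paste0(prefix, "_nodes.tsv")
  nt <- if ("node_type" %in% igraph::vertex_attr_names(net)) {
    igraph::V(net)$node_type
  } else NA_character_
  write_tsv_table(data.frame(node_id = igraph::V(net)$name, node_type = nt),
                  nodes)
  invisible(c(sif, gml, nodes))
}
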