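# Network assembly conventions and degree/path-length/closeness/betweenness
# profiles.

test_that("compound-target network adds the drug hub and deduplicates targets", {
  e <- data.frame(compound = c("c1", "c1"), target = c("t1", "t2"))
  g <- build_compound_target_network(e, "drug")
  expect_equal(igraph::vcount(g), 4)  # hub + compound + 2 targets
  expect_equal(igraph::ecount(g), 3)
  # two compounds sharing one target store it once
  e2 <- data.frame(compound = c("c1", "c2"), target = c("t1", "t1"))
  g2 <- build_compound_target_network(e2)
  expect_equal(igraph::vcount(g2), 4)
  expect_error(build_compound_target_network(e[0, ]), "empty")
})

test_that("the ih49 preset realizes the reference node and edge counts", {
  e <- gen_compound_target_edges(preset = "ih49", seed = 2)
  g <- build_compound_target_network(e)
  expect_equal(igraph::vcount(g), 658)
  expect_equal(igraph::ecount(g), 2463)
  # exact degree sequence: compound degree = drug edge + distinct targets
  prof <- ih49_profiles()
  deg <- igraph::degree(g)[prof$mol_id]
  expect_equal(unname(deg), prof$degree)
  # every target covered
  expect_equal(sum(igraph::V(g)$node_type == "target"), 608)
  # handshake identity
  expect_equal(sum(igraph::degree(g)), 2 * igraph::ecount(g))
  # determinism and feasibility validation
  expect_identical(e, gen_compound_target_edges(preset = "ih49", seed = 2))
  expect_error(gen_compound_target_edges(degree_seq = 2, n_targets = 5),
               "infeasible")
  expect_error(gen_compound_target_edges(degree_seq = 10, n_targets = 4),
               "infeasible")
})

test_that("intersection network restricts targets and links both hubs", {
  e <- data.frame(compound = c("c1", "c1", "c2"),
                  target = c("t1", "t2", "t2"))
  g <- build_intersection_network(e, overlap = c("t2"))
  # drug, disease, c1, c2, t2
  expect_equal(igraph::vcount(g), 5)
  # c1 keeps only its overlap target; compounds with no surviving target
  # stay attached to the drug hub
  e3 <- data.frame(compound = c("c1", "c2"), target = c("t1", "t2"))
  g3 <- build_intersection_network(e3, overlap = "t1")
  expect_true("c2" %in% igraph::V(g3)$name)
  expect_equal(igraph::degree(g3)[["c2"]], 1)
  # overlap equal to all targets reproduces the full target set
  gall <- build_intersection_network(e, overlap = c("t1", "t2"))
  expect_equal(sum(igraph::V(gall)$node_type == "target"), 2)
  expect_error(build_intersection_network(e, overlap = character(0)),
               "empty")
  expect_warning(build_intersection_network(e, overlap = "zz"), "no gene")
})

test_that("profiles follow the reciprocal-mean closeness and raw betweenness conventions", {
  # star with 3 leaves: center adjacent to all
  A <- matrix(0, 4, 4); A[1, 2:4] <- 1; A <- A + t(A)
  g <- graph_from_adj(A)
  prof <- node_centralities(g)
  ctr <- prof[prof$node_id == "V1", ]
  expect_equal(ctr$aspl, 1.0)
  expect_equal(ctr$closeness, 1.0)
  # path of 3: middle node brokers exactly one pair
  P <- matrix(0, 3, 3); P[1, 2] <- P[2, 3] <- 1; P <- P + t(P)
  pp <- node_centralities(graph_from_adj(P))
  expect_equal(pp$betweenness_raw[pp$node_id == "V2"], 1.0)
  expect_equal(pp$betweenness_norm[pp$node_id == "V2"], 1.0)  # 1/((3-1)(3-2)/2)
  # printed-profile convention: closeness is the reciprocal of aspl
  expect_equal(round(1 / 2.595129376, 9), 0.385337243)
  # isolated node: aspl missing, closeness 0
  I <- matrix(0, 3, 3); I[1, 2] <- 1; I <- I + t(I)
  pi <- node_centralities(graph_from_adj(I))
  expect_true(is.na(pi$aspl[pi$node_id == "V3"]))
  expect_equal(pi$closeness[pi$node_id == "V3"], 0)
})

test_that("top compounds rank by degree with betweenness then id tie-breaks", {
  e <- gen_compound_target_edges(preset = "ih49", seed = 4)
  g <- build_compound_target_network(e)
  prof <- node_centralities(g)
  top5 <- top_compounds(prof, k = 5)
  ih <- ih49_profiles()
  expect_equal(top5$node_id, ih$mol_id[1:5])
  expect_equal(ih$compound[1:5],
               c("cerevisterol",
                 "(22E,24R)-ergosta-7,22-diene-3b,5a,6b,9a-tetrol",
                 "withanolide", "Inonoterpene A", "Polyporusterone D"))
  expect_equal(nrow(top_compounds(prof, k = 0)), 0)
  expect_equal(nrow(top_compounds(prof, k = 1000)), 49)
  # explicit tie: equal degree ordered by betweenness, then id
  tie <- data.frame(node_id = c("b", "a", "c"), node_type = "compound",
                    degree = c(3, 3, 3), aspl = 1, closeness = 1,
                    betweenness_raw = c(5, 5, 9), betweenness_norm = 0)
  expect_equal(top_compounds(tie, 3)$node_id, c("c", "a", "b"))
})

test_that("network export writes SIF, GraphML and node attributes", {
  e <- data.frame(compound = "c1", target = c("t1", "t2"))
  g <- build_compound_target_network(e)
  prefix <- file.path(withr::local_tempdir(), "net")
  paths <- export_network(g, prefix)
  expect_true(all(file.exists(paths)))
  sif <- read.delim(paths[1], header = FALSE)
  expect_equal(nrow(sif), igraph::ecount(g))
  expect_true(all(sif$V2 == "pp"))
  reread <- igraph::read_graph(paths[2], format = "graphml")
  expect_equal(igraph::vcount(reread), igraph::vcount(g))
})
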