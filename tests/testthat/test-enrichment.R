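# GMT parsing, the hypergeometric tail and over-representation analysis.

test_that("GMT parsing enforces the dialect", {
  dir <- withr::local_tempdir()
  path <- file.path(dir, "sets.gmt")
  writeLines(c("T1\tdesc\tA\tB\tC", "T2\tdesc\tB"), path)
  anns <- load_gmt(path, category = "BP")
  expect_length(anns, 2)
  expect_equal(anns[[1]]$genes, c("A", "B", "C"))
  expect_equal(anns[[2]]$category, "BP")
  writeLines(c("T1\tdesc\tA", "T1\tdesc\tB"), path)
  expect_error(load_gmt(path), "duplicate term id")
  writeLines("T1\tdesc", path)
  expect_error(load_gmt(path), "line 1")
})

test_that("hypergeometric upper tail matches closed forms and exact enumeration", {
  # single-term closed form: all 5 draws annotated out of 5 in 20
  expect_equal(hypergeom_upper_tail(5, 5, 5, 20), 1 / choose(20, 5),
               tolerance = 1e-12)
  expect_equal(hypergeom_upper_tail(0, 5, 5, 20), 1.0)
  expect_equal(hypergeom_upper_tail(4, 4, 4, 4), 1.0)  # degenerate population
  # exact binomial-coefficient summation, all (k,n,K,N) shapes for N <= 60
  set.seed(3)
  for (rep in 1:300) {
    N <- sample(2:60, 1)
    n <- sample(1:N, 1)
    K <- sample(1:N, 1)
    k <- sample(0:min(n, K), 1)
    want <- oracle_hyper_upper(k, n, K, N)
    got <- hypergeom_upper_tail(k, n, K, N)
    expect_equal(got, want, tolerance = 1e-12,
                 label = sprintf("k=%d n=%d K=%d N=%d", k, n, K, N))
  }
  expect_error(hypergeom_upper_tail(6, 5, 5, 20))
})

test_that("ORA reports fold enrichment, log10 p and within-category BH", {
  anns <- list(list(term_id = "T1", description = "d", category = "BP",
                    genes = c("A", "B", "C", "D", "E")),
               list(term_id = "T2", description = "d", category = "BP",
                    genes = c("F", "G")),
               list(term_id = "T3", description = "d", category = "pathway",
                    genes = c("A", "H")))
  res <- ora(c("A", "B", "C", "D", "E"), anns, background = 20)
  t1 <- res[res$term_id == "T1", ]
  expect_equal(t1$Enrichment, 4.0)         # (5/5)/(5/20)
  expect_equal(t1$Count, 5)
  expect_equal(t1$p_value, 1 / choose(20, 5), tolerance = 1e-12)
  expect_equal(t1$LogP, log10(t1$p_value))
  # zero-overlap terms are absent
  expect_false("T2" %in% res$term_id)
  # q within category, monotone in p-rank and >= p
  expect_true(all(res$q_value >= res$p_value - 1e-15))
  expect_true(all(diff(res$q_value[res$category == "BP"]) >= -1e-15))
  # enlarging the background never decreases fold enrichment
  res2 <- ora(c("A", "B", "C", "D", "E"), anns, background = 200)
  expect_gte(res2$Enrichment[res2$term_id == "T1"], t1$Enrichment)
  # genes outside an explicit background are dropped with a warning
  expect_warning(ora(c("A", "ZZZ"), anns, background = c("A", "B", "H")),
                 "outside the background")
  expect_error(ora("A", anns, background = character(0)), "empty background")
})

test_that("top-term selection trims per category with deterministic ties", {
  res <- data.frame(term_id = sprintf("T%02d", 1:30),
                    description = "d", category = rep(c("BP", "MF"), 15),
                    Count = 1, term_size = 5, input_size = 10,
                    background_size = 100, Enrichment = 1,
                    LogP = 0, p_value = rep(c(0.01, 0.01, 0.5), 10),
                    q_value = 0.5)
  top <- top_terms(res, n = 5)
  expect_equal(sum(top$category == "BP"), 5)
  expect_equal(sum(top$category == "MF"), 5)
  # equal p resolved by term id
  tied <- top[top$p_value == 0.01 & top$category == "BP", "term_id"]
  expect_equal(tied, sort(tied))
  expect_equal(nrow(top_terms(res[1:3, ], n = 20)), 3)
})

test_that("a planted term ranks first by p across seeded replicates", {
  first <- logical(100)
  for (s in 1:100) {
    gene_list <- sprintf("G%06d", 1:50)
    g <- gen_annotations(n_terms = 40, term_size_range = c(10, 60),
                         planted_genes = gene_list[1:30],
                         background_size = 2000, seed = s)
    res <- ora(gene_list, g$annotations, background = g$background)
    first[s] <- res$term_id[1] == g$truth$planted_term_id
  }
  expect_gte(mean(first), 0.95)
})
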