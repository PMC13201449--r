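# Drug-likeness rules, GI-absorption ellipse and the compound screen.

# A descriptor set comfortably inside every rule's bounds.
good_descriptors <- function() {
  list(mw = 300, wlogp = 2, mlogp = 2, xlogp = 2, tpsa = 80, hbd = 2,
       hba = 5, rotb = 4, mr = 80, heavy_atoms = 25, carbons = 15,
       heteroatoms = 5, rings = 2)
}

test_that("rule verdicts match published bounds, inclusively at the bound", {
  # all thresholds satisfied
  v <- evaluate_rule("lipinski", list(mw = 480, mlogp = 3.0, hbd = 2,
                                      hba = 8))
  expect_true(v$passed)
  expect_length(v$violations, 0)

  # every Lipinski condition violated
  v <- evaluate_rule("lipinski", list(mw = 600, hbd = 6, hba = 11,
                                      mlogp = 5.0))
  expect_false(v$passed)
  expect_length(v$violations, 4)

  # boundary values satisfy non-strict inequalities
  expect_true(evaluate_rule("veber", list(rotb = 10, tpsa = 140))$passed)
  expect_true(evaluate_rule("lipinski",
                            list(mw = 500, mlogp = 4.15, hbd = 5,
                                 hba = 10))$passed)
  # Muegge's strict published minima stay strict
  d <- good_descriptors()
  d$carbons <- 4
  expect_equal(evaluate_rule("muegge", d)$violations, "carbons_gt_4")
  d$carbons <- 5
  expect_true(evaluate_rule("muegge", d)$passed)
})

test_that("perturbing any single tested quantity yields exactly its named violation", {
  rules <- dl_rules()
  for (i in seq_len(nrow(rules))) {
    d <- good_descriptors()
    row <- rules[i, ]
    d[[row$descriptor]] <- switch(row$side,
                                  le = row$bound + 1,
                                  ge = row$bound - 1,
                                  gt = row$bound - 1)
    v <- evaluate_rule(row$rule, d)
    expect_equal(v$violations, row$condition,
                 label = paste("perturbed", row$condition))
    expect_false(v$passed)
  }
})

test_that("unknown rules and missing descriptors raise informative errors", {
  expect_error(evaluate_rule("pfizer", good_descriptors()), "unknown rule")
  expect_error(evaluate_rule("veber", list(rotb = 5)), "tpsa")
})

test_that("GI classification agrees with direct ellipse evaluation", {
  # independent evaluation of the published HIA ellipse
  ellipse_value <- function(tpsa, wlogp) {
    th <- -1.031425 * pi / 180
    dx <- tpsa - 71.051; dy <- wlogp - 2.292
    xr <- cos(th) * dx + sin(th) * dy
    yr <- -sin(th) * dx + cos(th) * dy
    (xr / (142.081 / 2))^2 + (yr / (8.740 / 2))^2
  }
  grid <- expand.grid(tpsa = seq(0, 220, by = 10),
                      wlogp = seq(-4, 8, by = 0.5))
  got <- classify_gi(grid$tpsa, grid$wlogp)
  want <- ifelse(ellipse_value(grid$tpsa, grid$wlogp) <= 1, "high", "low")
  expect_equal(got, want)
  expect_equal(classify_gi(30, 1.0), "high")
  expect_equal(classify_gi(200, 0.0), "low")
})

test_that("screening requires the GI gate plus the rule quorum and preserves order", {
  d <- good_descriptors()
  tbl <- data.frame(compound_id = c("A", "B", "C"),
                    mw = c(300, 300, 5000),
                    wlogp = c(2, 5.6, 2), mlogp = 2, xlogp = 2,
                    tpsa = c(80, 0, 80), hbd = 2, hba = 5,
                    rotb = c(4, 4, 25),
                    mr = 80, heavy_atoms = 25, carbons = 15,
                    heteroatoms = 5, rings = 2)
  rep <- screen_compounds(tbl, min_rules = 2)
  expect_equal(rep$compound_id, c("A", "B", "C"))  # order preserved
  # A passes everything and is GI-high
  expect_true(rep$accepted[1])
  # B passes all five rules (wlogp exactly at the Ghose bound) but the
  # point (tpsa 0, wlogp 5.6) lies outside the absorption ellipse
  expect_equal(rep$n_rules_passed[2], 5)
  expect_equal(rep$gi_class[2], "low")
  expect_false(rep$accepted[2])
  # C is GI-high but mw 5000 and rotb 25 leave only one passing rule
  expect_equal(rep$gi_class[3], "high")
  expect_lt(rep$n_rules_passed[3], 2)
  expect_false(rep$accepted[3])
  # every record carries all five verdicts
  expect_true(all(c("lipinski", "ghose", "veber", "egan", "muegge") %in%
                  names(rep)))
})

test_that("raising min_rules never enlarges the accepted set", {
  tbl <- gen_descriptor_table(60, frac_pass = 0.6, seed = 11)
  prev <- NULL
  for (k in 0:5) {
    acc <- screen_compounds(tbl, min_rules = k)$accepted
    if (!is.null(prev)) expect_true(all(acc <= prev))
    prev <- acc
  }
})

test_that("empty input screens to an empty report, not an error", {
  tbl <- gen_descriptor_table(3, seed = 1)[0, ]
  expect_equal(nrow(screen_compounds(tbl)), 0)
})
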