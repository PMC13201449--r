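---
title: "Methods: network-pharmacology screening with netpharm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: network-pharmacology screening with netpharm}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(netpharm)
```

## Overview

netpharm implements the computational half of a network-pharmacology study
of a multi-component natural product (the medicinal fungus *Inonotus
hispidus* against renal cell carcinoma is the reference system): candidate
compounds are filtered by drug-likeness and predicted gastrointestinal
absorption; their predicted protein targets are intersected with a
multi-database disease gene set; the resulting compound–target and
protein–protein interaction (PPI) networks are profiled topologically; core
targets are screened by an iterative above-median quorum over six
centrality metrics; the overlap genes are tested for annotation-term
over-representation; and externally computed docking energies are triaged
against a favorability threshold. Because the original study's inputs came
from live web services (SwissTargetPrediction, GeneCards, STRING,
Metascape) whose snapshots are not deposited, a family of seeded
synthetic-data generators reproduces every input format with ground truth
known by construction.

## Compound screening

Each compound is described by thirteen physicochemical descriptors
(molecular weight in Da, three logP variants, TPSA in Å², H-bond
donor/acceptor counts, rotatable bonds, molar refractivity, heavy-atom /
carbon / heteroatom / ring counts). Five published rule sets — Lipinski,
Ghose, Veber, Egan, Muegge — are stored as a single table of per-condition
bounds (`dl_rules()`), not scattered through code. Conventions:

* every inequality the original publications state as ≤/≥ is evaluated
  **non-strictly**, so a descriptor exactly on a bound does not violate
  (the common behaviour of screening tools); Muegge's strictly published
  minima (">4 carbons", ">1 heteroatom") stay strict;
* a rule passes only with **zero** violations — in particular no
  one-violation allowance for Lipinski;
* each rule reads one logP variant (Lipinski → MLOGP, Ghose/Egan → WLOGP,
  Muegge → XLOGP). The original screening platform does not document its
  variant choice, so the mapping lives in the rule table and is
  user-editable.

Gastrointestinal absorption is classified by the BOILED-Egg model's HIA
("egg white") ellipse in (TPSA, WLOGP) space, with the digitized published
parameters (centre (71.051, 2.292), axes 142.081 × 8.740, rotation
−1.031°); boundary points classify as high. Only the HIA ellipse is
implemented — the brain-penetration yolk is out of scope. A compound is
accepted iff it is GI-high **and** passes at least `min_rules` (default 2)
of the five rule sets.

## Mass annotation

Identification follows the accurate-mass rule of high-resolution ESI work:
a peak is annotated with a candidate formula when the observed m/z is
within 5 ppm (default) of the theoretical adduct mass. Theoretical masses
are monoisotopic sums over an isotope table carrying ≥ 7 decimals; the
protonation shift is the **electron-corrected proton mass**
(1.00727646688 Da) rather than the hydrogen-atom mass — the ~0.5 mDa
difference matters at sub-ppm accuracy and is required to reproduce the
reference constituent table to < 0.5 ppm. Both `[M+H]+` and `[M−H]−` are
tried for every peak, since row-level polarity is not recorded; matches
are ranked by |ppm error|. MS/MS fragment columns are carried through but
never matched, and some reference rows (the ergostane ketones) are
legitimately unmatched because their printed ions are not simple ±H
adducts of the printed formula.

## Target integration

Disease evidence arrives as five per-source tables. GeneCards rows are
filtered by relevance score ≥ 37.5 (inclusive); the other four sources
carry no scores and pass unchanged. Symbols are standardized offline
against a user-supplied alias table (case-insensitive; unmapped symbols
pass through verbatim and are counted). Merging deduplicates to one entry
per gene and flags genes attested by ≥ 2 sources as high-confidence — an
annotation, not a removal, since the reference union count (2,367) is the
full merged set. The intersection with predicted compound targets is an
exact set intersection with Venn counts.

## Network construction and centrality conventions

The compound–target network links one drug hub to every accepted compound
and each compound to its distinct predicted targets, so a compound's
degree is 1 + its target count; under this convention the 49 reference
compound degrees sum exactly to the printed 2,463-edge total. The
intersection network adds a disease hub linked to every overlap gene and
restricts compound edges to the overlap; compounds left without targets
stay attached to the drug hub. Distances are unweighted hop counts, and:

* `aspl` is the mean distance to all other **reachable** nodes (missing
  for an isolated node);
* closeness is `1 / aspl` (0 for isolated nodes), which reproduces the
  reference per-compound closeness column from its path-length column to
  the 9 printed decimals;
* betweenness counts each unordered pair's shortest-path contributions
  once, endpoints excluded (raw scale), with a normalized companion
  `raw / ((n−1)(n−2)/2)` — the two scales mirror the two conventions seen
  in published per-node tables.

## PPI core-target screening

STRING-style edge tables are accepted in both the 0–1 and the 0–1000
score dialects (auto-rescaled), deduplicated keeping the maximum score,
with self-loops dropped. Edges with combined score ≥ 0.7 (inclusive) are
kept and universe proteins without a qualifying edge are removed and
counted. Six per-node metrics are computed:

* degree, raw betweenness, reciprocal-mean closeness as above;
* eigenvector: the principal eigenvector of the largest connected
  component's adjacency matrix, unit Euclidean norm, by power iteration
  (tolerance 1e−10, ≤ 10,000 iterations) applied to `A + I` — the shift
  leaves eigenvectors unchanged but makes the Perron root strictly
  dominant, so the iteration cannot oscillate on bipartite components;
  nodes outside the largest component score 0;
* LAC: the mean degree of a node's neighbours within the subgraph induced
  by its neighbourhood;
* NC: the sum over incident edges of the edge clustering coefficient
  `ECC(v,u) = triangles(v,u) / min(deg(v)−1, deg(u)−1)`, defined as 0
  when the denominator is 0, so leaves score low.

The screen runs in rounds: each round profiles the subgraph induced by the
previous survivors, recomputes the per-metric medians on those fresh
profiles (median of an even count = mean of the two central values), and
retains nodes strictly above the median in at least `quorum` of the six
metrics. The default is **two rounds at quorum 4**, the "above the median
in ≥ 4 of 6 metrics" rule under which the reference screen reported its
20 core targets. A full 6-of-6 quorum is available but deliberately not
the default: betweenness within a dense core concentrates on a few bridge
nodes, so demanding above-median betweenness of every retained node cuts
legitimate core members — in the extreme planted-clique case it even
rejects most of a perfect core. A round that would eliminate every node
(e.g. a clique, where all metrics tie at the median) stops the screen and
returns the previous survivors. Survivors contract monotonically and the
outcome is invariant to node input order.

Simulation with the planted-core generator (169 proteins, 6 isolated,
20-node core, within-core edge probability 0.8 against background 0.03)
shows the two-round default recovers the planted core with a mean Jaccard
index of ≈ 0.77 over 20 seeds: round 1 retains the full core plus the
~20 best-connected background nodes, and the recomputed round-2 medians
then fall inside the core's own betweenness distribution, trimming a few
true members. This is an intrinsic property of median-recomputing screens
on planted-core graphs at these densities, not a numerical artefact; users
wanting maximal recall should stop after one round or lower the
second-round quorum.

## Enrichment

Over-representation uses the hypergeometric upper tail
`P(X ≥ k)` computed in log space (`phyper(..., log.p = TRUE)`), reported
alongside fold enrichment `(k/n)/(K/N)` and `log10 p` — the Count /
Enrichment / LogP convention of annotation services. The background
defaults to the union of all genes in the loaded GMT collection and may be
overridden by a fixed integer (e.g. 20,000) or an explicit gene vector (in
which case term sizes count only background members). Multiple-testing
correction is Benjamini–Hochberg within each category, labelled as such in
the output; terms with zero overlap are omitted; top-N selection (default
20) is per category by ascending p with term-id tie-breaks.

## Docking triage

Docking itself is an external engine's job; the package selects the top-5
compounds by network degree and the top-5 core targets by PPI degree
(deterministic tie-breaks: betweenness descending, then id), emits the
5 × 5 worklist, and classifies returned binding energies as favorable at
or below −5.0 kcal/mol (inclusive).

## Synthetic-data generators

Every generator is a pure function of its arguments and seed (byte-identical
reruns, caller's RNG untouched) and validates feasibility before producing
anything. Defaults are the reference study's cardinalities: the `ih49`
degree-sequence preset over a 608-target universe (round-robin assignment
over a seeded shuffle guarantees the exact degree sequence and full
universe coverage — rejection sampling can stall on tight sequences);
a 2,367-gene disease union with a 169-gene planted overlap distributed
over five sources in GeneCards-dominated proportions, with sub-threshold
GeneCards decoys so relevance filtering has a known effect; a 169-protein
PPI with exactly 6 isolated nodes and a planted 20-node core (orphan nodes
are patched to a core partner so patching cannot manufacture background
hubs); GMT collections with one planted term; and uniform docking-energy
tables. Scores are uniform within bands above/below the 0.7 threshold,
since the screen depends only on thresholded topology.

What the generators deliberately do **not** emulate: realistic PPI degree
distributions beyond the planted-core model, chemically realistic joint
descriptor distributions, correlated multi-source evidence, or annotation
redundancy between terms. Passing tests therefore demonstrate correctness
of the algorithms under known ground truth, not biological performance on
real web-service data.

## Problem sizes and runtime choices

The test suite exercises the metric implementations against brute-force
oracles (Floyd–Warshall distances with a path-count DP, dense
eigen-decomposition, explicit triangle counting) on every labeled graph
with up to 4 nodes and on a few hundred random graphs of up to 30 nodes;
the hypergeometric tail is checked against exact binomial-coefficient
summation for universes up to 60. Reference-scale runs (658-node networks,
169-protein PPIs, 2,367-gene unions) are used where the study's printed
cardinalities are being reproduced; integration tests run a scaled-down
pipeline (union 300–400) to keep the suite fast.

## Known limitations

* The reference per-protein centrality table cannot be reproduced: its
  closeness values are inconsistent with any single connected 163-node
  graph under standard conventions, so the package documents its own
  disconnected-graph convention instead of fitting that table.
* The printed enrichment values of the reference study depend on a
  proprietary annotation snapshot and are out of scope; only the
  statistic's definition is reproduced.
* Whether the reference union count was taken before or after
  the ≥ 2-database prioritization is not recorded; the package reports
  both the merged count and the high-confidence count.
* Mass annotation is precursor-only; fragment-spectrum matching and
  isotope-pattern scoring are out of scope.
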