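---
title: "Linking sequence conservation modules to protein functions by co-emergence"
author: "phyloModules"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Linking sequence conservation modules to protein functions by co-emergence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phyloModules)
```

## The problem

Multi-functional protein families — paralog groups, multi-domain proteins —
carry different functions on different sequence regions, and those regions
are often conserved only within a subset of the family. A classical global
alignment averages over all of this; domain databases only see regions that
have already been named. `phyloModules` takes the complementary route: find
the family's *local* conservation blocks (modules) directly from the
sequences, reconstruct the evolutionary history of both the modules and the
binary functional annotations on the family's gene tree, and propose a
module set as the candidate sequence basis of a function whenever the two
were gained at the same ancestral gene.

The package expects three inputs: the family's protein sequences (FASTA with
an NCBI taxid as the trailing `_`-separated token of each identifier), a
rooted binary gene tree over exactly those proteins (newick), and a CSV of
binary annotations (`protein_id,function_id`, one row per observed
function). Proteins appearing in the CSV form the *annotated subset* (this
can be overridden with an explicit id list): for those proteins an unlisted
function is taken as genuinely absent, while all other proteins are treated
as unknown — they may or may not carry each function — and enter the
likelihood as missing data.

## Module detection

A *module* is an ungapped block: a set of equal-width segments from at least
two distinct proteins, mutually similar under a substitution matrix
(BLOSUM62 by default). Detection proceeds in three steps.

1. **Anchoring.** Every identical k-mer (`k = 4`) shared by two proteins
   seeds an anchor, greedily extended left and right while the per-column
   substitution score stays positive.
2. **Clustering.** Anchor segments are single-linkage clustered: anchor
   partners are linked with their starts aligned, and two segments of the
   same protein are linked when they overlap by at least 50% *of the longer
   segment* (measuring against the shorter one lets 4-residue chance
   anchors bridge unrelated blocks). Each cluster is laid out in a common
   coordinate frame by a union-find that processes links by decreasing
   anchor length, so long anchors dictate the frame when a periodic repeat
   suggests a conflicting shift. One contiguous interval is kept per
   protein and the cluster is trimmed to the widest window that every
   member covers in full. Clusters narrower than `minWidth` (default 6),
   with fewer than 2 proteins, or containing a member scoring below
   `minPairScore` against the cluster's best segment are discarded. The
   default threshold, half the matrix's mean diagonal per column
   (`0.5 * width * 5.8` for BLOSUM62), is a deliberate stand-in: the
   original partial local multiple alignment tools use a dedicated
   significance model that is out of scope here, and the threshold is
   exposed so users can calibrate it.
3. **Compatibility selection.** The final module set must be *compatible*:
   no two modules overlap on any protein, and modules shared by two or more
   proteins appear in the same left-to-right order on all of them. Up to 12
   candidates this maximum-score compatible subset is found exactly by
   exhaustive search (the problem is small and determinism matters more
   than speed); beyond that a greedy sweep by descending score with
   deterministic tie-breaks takes over. Exact-on-small was chosen over
   pure greedy because greedy can miss the optimum even on instances with
   half a dozen blocks, and reproducibility of the *optimal* set is a
   stronger contract.

Module ids `m1..mN` are assigned by each module's lexicographically
smallest carrier and its segment start there; the whole pass is
deterministic in its inputs.

## Module history: trees, reconciliation, replicates

Gene regions evolve semi-independently of their host gene: a module can be
gained, duplicated, lost, or move between paralogs while the gene tree
stays fixed. Each detected module therefore gets its own tree and is
*reconciled* against the gene tree.

- **Module trees.** Pairwise p-distances between segments,
  Poisson-corrected (`d = -log(1 - p)`, `p` capped at 0.95), then
  neighbor-joining. Module segments are short, so ties in the NJ
  Q-criterion are common; they are broken uniformly at random from a seeded
  stream. This is the pipeline's only stochastic step and deliberately so:
  replicate runs (default 10, seeds `baseSeed + 0..9`) differ exactly where
  the data are ambiguous, and the frequency of each presence call across
  replicates is reported as its support. Two-carrier modules have a unique
  cherry and skip NJ entirely.
- **Rooting.** The NJ tree is midpoint-rooted with deterministic
  tie-breaks, but short segments rarely place the root reliably, and a
  mis-rooted module tree lets cheap transfers drag inferred gains away from
  the true node. `consensusPresence` therefore re-roots each replicate's
  topology at the edge whose reconciliation is cheapest (midpoint winning
  ties) — the same role the gene-tree-guided tree correction plays in
  conventional module-phylogeny workflows. `rootBy = "midpoint"` disables
  this.
- **Reconciliation.** An undated duplication–transfer–loss model maps the
  module tree into the gene tree by dynamic programming over (module node,
  gene node): speciation is free, duplication costs 2, transfer 3, loss 1
  by default (all exposed; transfers cheaper than losses warn). Transfers
  land directly on any gene node neither ancestor nor descendant of the
  donor; time consistency is not enforced. Ties resolve by gene-node
  preorder, then speciation < duplication < transfer, keeping backtracking
  deterministic. A gene node is *present* when it lies on a path covered by
  a module-tree edge; gains sit at the module root's mapping and at every
  transfer landing.
- **Dollo baseline.** `dolloPresence` gives the classical single-gain,
  minimal-loss scenario (gain at the carriers' last common ancestor); it
  coincides with the reconciliation whenever the module tree is congruent
  with the induced gene subtree and transfers are expensive, and serves as
  a fast, assumption-light cross-check.

Majority vote over replicates gives the consensus state (an exact 0.5 tie
resolves to *present*, favouring sensitivity in the downstream signature
step) and the vote fraction is the support.

## Function history

Each binary function evolves on the gene tree under a two-state
continuous-time Markov model with gain rate α and loss rate β; the branch
lengths are the gene tree's (missing lengths default to 1, zero lengths are
clamped to 1e-8 for the likelihood). The likelihood is computed by the
pruning recursion with per-node scaling; unknown leaves contribute a
partial likelihood of 1 in both states, and the root is closed with the
stationary frequencies (π₁ = α/(α+β)). Rates are fitted per function by
bounded optimization on log-rates in [1e-6, 100], multi-started from a
fixed 3×3 grid (rates 0.01, 0.5, 10) so the fit is deterministic; boundary
optima are flagged. Marginal posteriors at every node come from the
standard up–down pass, and a node is called *present* when its posterior is
at least 0.5 — a single binary call per node, with the posterior kept as
support, rather than a set-valued call, because the integration step needs
one state per node. Rates are fitted independently per function; no rate
sharing, no branch-specific rates.

## Integration and signatures

For every item (module or function) and every node, the event is *gain*
when the node is present and its parent absent (presence at the root counts
as a gain — items conserved family-wide gain there), *loss* in the opposite
case, and *none* otherwise. A *signature* row is emitted for every function
gain: the set of modules gained at the same node with support at least
`minSupport` (default 0.5). Co-emergence is strict same-node gain; a
relaxed mode additionally accepting gains at the direct parent exists
behind a flag, off by default. Rows with no co-emerging module are kept and
flagged, and modules merely *retained* (present but gained earlier) at the
function's gain node are reported in a separate column as conservation-
based, weaker candidates — not as signature members.

The output bundle contains the module table (1-based inclusive coordinates;
internally everything is 0-based half-open), the per-node event table with
supports, the signature CSV, iTOL datasets (a `DATASET_BINARY` file with
observed leaf annotations, a `DATASET_DOMAINS` file drawing each module's
span with a deterministic palette, the labelled gene tree) and a manifest
with an md5 for every file. Given identical inputs, configuration and seed
the bundle is byte-identical apart from the timestamp in `run.log`.

## The synthetic-data generator

`simulateYuleTree` (pure-birth, conditioned on the leaf count),
`simulateBinaryCharacter` (stationary root, model transitions per branch)
and `plantModulesAndSequences` make every stage testable with known ground
truth. Planted modules are ancestral segments gained at a chosen node,
inherited by the descendant leaves (loss nodes prune lineages) with a
per-site, per-branch substitution probability, and inserted at recorded
positions into i.i.d. background residues drawn from a standard amino-acid
composition. Two generator properties matter for interpreting tests:
ancestral segments are drawn with no internal repeated 4-mer and no 4-mer
shared between modules (otherwise identical-by-descent plants seed shifted
or cross-module anchors, and single-linkage merges distinct planted
blocks); and the *disjoint-alphabet* mode (plants from {W,Y,F,H},
background from the other 16 letters) is a test-only device that guarantees
plants and background never share seeds. What passing these tests shows is
that the machinery is correct on data matching its model — ungapped blocks,
i.i.d. background, no indels, no domain shuffling, no gene-tree error. Real
families violate all of these to some degree; in particular insertions
within a block will split it, and modules with near-identical segments
(e.g. recent clades) have little tree signal, which surfaces as fractional
support rather than as a wrong confident call.

Two limit behaviours are worth knowing. A module whose segments are all
identical has a completely tied distance matrix; its replicate topologies
are random and only the balanced parts of its history are stable (this is
the intended uncertainty mechanism, visible as support strictly between 0
and 1). And a function annotated on exactly half of a perfectly symmetric
tree has a root posterior of exactly 0.5 — a genuine tie, which the
documented rule calls present.

## Problem sizes and numerical choices

The shipped tests and the acceptance script run on families of 8–32
sequences of 100–180 residues, modules of width 12–24, 10 reconciliation
replicates, and a 200-leaf tree for rate recovery; these sizes keep every
oracle (exhaustive DTL search, 2^n labelings, full enumeration of internal
states) tractable while exercising all code paths. Numerical details that
affect results: NJ Q-ties use a 1e-9 relative tolerance; negative NJ branch
lengths clamp to 0; reconciliation cost comparisons use a 1e-9 relative
tolerance with the deterministic tie-breaks above; likelihood scaling is
per node; p-distances cap at 0.95 before Poisson correction.

## A worked miniature

```{r example}
tr <- geneTreeFromPhylo(ape::read.tree(text =
    "(((P1:1,P2:1):1,(P3:1,P4:1):1):1,((P5:1,P6:1):1,(P7:1,P8:1):1):1);"))
sim <- plantModulesAndSequences(
    tr, list(list(gainNode = "g2", width = 16, rate = 0),
             list(gainNode = "g2", width = 16, rate = 0),
             list(gainNode = "g4", width = 16, rate = 0)),
    backgroundLength = 100, seed = 72, disjointAlphabet = TRUE)
mods <- detectModules(sim$records, detectionParams(minWidth = 8))
vapply(mods, function(m) paste(moduleId(m), ":",
    paste(moduleCarriers(m), collapse = " ")), "")

pm <- consensusPresence(mods[[1]], tr, nRuns = 10, baseSeed = 1)
head(deriveGainLossEvents(pm, tr)[, c("node_id", "state", "event",
                                      "support")])
```

The two modules planted at the `(P1,P2)` cherry and the one at the
`(P5..P8)` clade are recovered at their planted spans; reconciliation puts
their gains at the planted nodes with support 1, and with a function
annotated on `P1`,`P2` the signature table proposes exactly those two
modules — the scenario `scripts/acceptance.R` re-runs end to end.
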