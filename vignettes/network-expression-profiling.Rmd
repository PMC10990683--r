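---
title: "Reaction-network exploration and cell-lineage expression profiling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reaction-network exploration and cell-lineage expression profiling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(netprofiler)
```

## What the package models

netprofiler couples two views of cell biology that are usually explored in
separate tools:

1. **Bioregulatory networks** as bipartite species-reaction graphs parsed
   from Reactome-dialect SBML. Pathway databases ship these as model
   *fragments*: each file covers one curated pathway, species identifiers
   are file-scoped, and kinetic parameterization is absent. The network
   half of the package is about making those fragments analyzable --
   classifying what each molecular species does for the system, pruning to
   a reaction neighbourhood, exporting to GraphViz DOT and SIF for
   visualization, relating fragments through shared species, flagging
   knowledge gaps, and injecting prototype kinetic laws so a model can be
   integrated at all.

2. **Cytohistological expression profiles** from Human Protein Atlas style
   single-cell RNA-seq tables (nTPM per gene, tissue, cell type and
   cluster). The expression half condenses those long tables into a
   lineage-by-gene feature matrix and treats cell-lineage assignment as a
   nearest-neighbour problem under the Manhattan (L1) metric on Min-Max
   normalized features.

The package is organized in the classic R modelling idiom where that fits:
`lineage_profiler()` is the single fitting function of the expression side
and returns a classed object with `print()`, `summary()`, `predict()` and
`plot()` methods -- `predict()` *is* the classifier. The network side is
not a fitted model, so it stays a family of plain functions
(`read_sbml()`, `species_roles()`, `prune_subgraph()`, `to_dot()`,
`find_gap_species()`, ...).

## The network model

A `pathway_model` holds species nodes (id, display name, compartment,
optional SBO term, annotation URIs, optional initial amount) and an ordered
reaction list; every participant reference must resolve, so downstream
analytics never see a dangling edge. Parsing is namespace-agnostic on
local element names: Reactome has shipped several SBML levels and
versions, and the network content we consume (ids, participants,
stoichiometries, SBO terms, annotation resources) is invariant across
them. Absent stoichiometry defaults to 1, absent reversibility to false.

**Species roles.** A species that is consumed (as reactant or modifier)
but never produced is a *system input*; produced but never consumed, a
*system output*; both, a *mediator*; referenced by no reaction,
*isolated*. The four roles partition the species set. Modifiers count as
consumption: a catalyst or regulator is engaged by the system even though
its mass balance is unchanged.

**Pruning.** "Depth" is measured in reaction distance: two reactions are
adjacent when they share at least one participant species (any role,
modifiers included -- a shared regulator is a real coupling), and
`prune_subgraph()` keeps every reaction within the requested BFS hop count
of the focus, plus the participant species of the kept reactions. Depth 0
is the focus reaction alone; any depth at or beyond the component diameter
saturates to the focus's connected component.

**Exports.** DOT output uses one fixed style table (species as ellipses,
reactions as orange filled boxes, every edge labelled with its role) so
golden files stay stable; duplicate display names are disambiguated with
the species id because pathway databases reuse names across compartments.
SIF output is one tab-separated `source relation target` line per
participant edge, oriented the same way (reactants and modifiers into the
reaction, products out of it).

## Cross-model analysis and gap detection

Species ids are model-scoped, so cross-model identity goes through
*extracted identifiers*: the final path segment of each annotation URI
(the identifiers.org / UniProt convention), optionally augmented with gene
symbols through an offline HGNC table. A corpus index maps each
identifier to the models containing it; overlap between two models is
reported as the shared identifier set and its Jaccard index.

A **gap species** is a species that is product-only within its model and
whose identifiers appear in no other model of the corpus: the model
produces it, and nothing anywhere consumes, regulates or transforms it.
That is a candidate hole in the curated knowledge, not proof of one -- the
corpus at hand may simply not include the relevant pathway. Two
conventions matter and are deliberate:

* a modifier appearance in another model disqualifies the gap (regulatory
  engagement is exactly the kind of downstream action whose absence the
  flag is meant to detect);
* species with no annotation URIs are excluded from gap claims entirely
  (no cross-model statement is possible) and their count is reported
  alongside the result.

## Kinetic-law injection and the sanity simulator

Pathway-database models are not kinetically parameterized. The two
injectors attach uniform prototype laws so a model becomes integrable:

* **Mass action**: `v = k_f * prod_i [R_i]^s_i` over the reactants; a
  reaction with no reactants becomes a constant source `v = k_f`.
  Reactions flagged reversible get the net law
  `v = k_f * (prod reactants - prod products)`, so a symmetric isomerism
  relaxes to detailed balance instead of draining one side completely.
* **Michaelis-Menten**: `v = v_max * S / (k_m + S)` with `S` the first
  listed reactant. This is a substrate-first convention -- when the enzyme
  is modelled it appears as a modifier and does not enter the rate.
  Reactions without reactants are skipped and reported.

Modifiers are ignored by both laws; uniform defaults
(`k_f = v_max = k_m = 1`, dimensionless units) are a prototype
parameterization for qualitative dynamics, not biology, and per-reaction
overrides exist for anything better. Laws are serialized into SBML as
`kineticLaw` blocks with genuine MathML and local parameters, with the law
type recorded through the standard rate-law ontology terms (SBO:0000012
mass action, SBO:0000028 Michaelis-Menten) so a round trip recovers it.

`simulate_kinetics()` integrates the resulting ODE system with the
classical fixed-step RK4 scheme (via deSolve) purely as a validation
harness: it checks that injected laws produce finite, conservative,
analytically sane dynamics (unimolecular decay matches `exp(-t)` to 1e-6
at `dt = 1e-3`; closed-chain mass drift stays below 1e-9). It is not a
production solver -- no stiffness control, no events, no stochastic
semantics.

## The expression pipeline

The reader accepts the seven-column HPA dialect (`Gene`, `Gene.name`,
`Tissue`, `Cluster`, `Cell.type`, `Read.count`, `nTPM`), order-insensitive,
rejecting rows with missing, non-numeric or negative nTPM. The lineage key
is the tissue and cell-type strings joined by a single space
(`"Placenta smooth muscle cells"`); in cluster-retaining mode the cluster
is appended as `" c-<cluster>"`.

**Cluster replicates and dispersion.** Rows sharing a gene and lineage are
replicate measurements across phenotypic clusters. `cluster_stats()`
computes mean, median, the *sample* standard deviation (n - 1 denominator
-- the convention is pinned by a test, because the n denominator gives a
visibly different value on skewed three-point groups) and the coefficient
of variation in percent. Singleton groups get NA dispersion; zero-mean
groups get NA CV; corpus summaries exclude the NAs and report how many
were excluded.

**Matrix construction.** Clusters collapse to their median (medians resist
the heavy right skew of expression data; an even-sized list takes the mean
of the two central values). Missing gene-lineage combinations are filled
with 0 nTPM -- absence of reads, not missingness; the classifier needs a
dense vector. Columns with no contrast (all values identical, including
all-zero) are dropped and listed. A retain-mode matrix collapsed by median
reproduces the merge-mode matrix exactly when each cluster contributes one
row per gene, which is a test invariant.

**Normalization and distance.** Feature ranges span orders of magnitude
(hemoglobin genes reach hundreds of thousands of nTPM while most genes sit
near zero), so every column is Min-Max rescaled to [0, 1] and the training
minima/maxima are stored. Lineage-to-lineage distances use the L1 norm by
default (more robust to single-gene excursions than L2; both are
available). Query vectors are aligned to the feature set (absent matrix
genes zero-filled, unknown query genes dropped with a warning), normalized
with the *stored* parameters, and clamped to [0, 1], since new data may
exceed the training range. Ties in the ranking break by lineage key so
results are a deterministic total order.

**Differential profiles.** Per gene, `z = (x - mean) / sd` across
lineages, with default tier thresholds `|z| >= 2` (significant) and
`|z| >= 3` (very significant); both are configurable. A constant gene
yields all-zero z. Because z-scores are relative to the sampled panel, a
gene expressed at trace levels everywhere except an *unsampled* lineage
can still tier as significant -- panel coverage, not the arithmetic, is
the limiting factor.

## What the synthetic generator emulates -- and what it does not

`simulate_expression_table()` draws a hierarchical log-normal model:

| parameter | default | meaning |
|---|---|---|
| `baseline_meanlog`, `baseline_sdlog` | 1, 1 | per-gene baseline nTPM (log-normal) |
| `celltype_sdlog` | 0.4 | genome-wide cell-type effect, shared by lineages of the same cell type |
| `lineage_sdlog` | 0.3 | genome-wide private lineage effect |
| `marker_multiplier` | 8 | fold change of planted markers |
| `markers_per_lineage` / `markers_per_celltype` | 5 / 5 | private and shared marker genes |
| `noise_sigma` | 0.2 | multiplicative log-normal noise between cluster replicates |

The hierarchy is the point: real cell lineages differ across the whole
transcriptome, and cell type explains more of that variance than tissue of
origin, so lineages sharing a cell type (smooth muscle in adipose tissue
and in placenta, say) sit close in the distance matrix while remaining
separable -- the qualitative behaviour the classifier is expected to
expose, and the recovery properties hold across a broad band of these
settings, not at a tuned point. What the generator does *not* emulate:
dropout and zero inflation, mixtures within a cluster, gene-gene
correlation structure, and the long tail of near-zero genes in real HPA
marginals. Passing tests therefore demonstrate that the pipeline recovers
planted structure under realistic dispersion, not that real-data accuracy
will match.

`simulate_sbml_corpus()` builds linear conversion chains (head = input,
tail = output, interior = mediators, with periodic modifier attachments),
plants `n_shared` identifiers between consecutive model pairs via disjoint
donate/reuse pools (so non-consecutive models share nothing), and makes
the first `n_gap_models` chain tails corpus-unique -- the planted gaps.
Tails of the other models deliberately reuse a neighbour's identifier so
they are product-only but *not* gaps, which keeps the detector's false
positive behaviour under test. Both generators run from a single integer
seed on an isolated RNG stream and restore the caller's RNG state.

## Numerical choices and degenerate inputs

* Rate expressions are canonicalized infix (`+ - * / ^`, minimal
  parentheses) and converted to and from MathML by a small recursive
  converter; write-then-read is an identity on the stored text.
* Min-Max normalization refuses constant columns (cleaning must run
  first); the classifier refuses queries with no overlapping genes.
* Search ranking is the declared total order (distinct matched fields
  descending, name length ascending, model id) -- a convention, chosen so
  multi-token queries surface more specific entries and results are
  reproducible, not an optimality claim.
* Histogram bins are right-open except the last; an all-equal vector
  occupies a single bin.
* Median of an even-sized list is the mean of the two central values.
* `write_sbml()` refuses models with unresolved references or an empty
  reaction list rather than emitting structurally dead XML.

Test and example problem sizes (8 lineages x 3 clusters x 300 genes; 6
models x 25 species; 200 classification queries) were chosen so every
planted property is exercised at sub-second cost; all scale linearly if
larger panels are wanted.

## Known limitations

* SBML support targets the Reactome dialect's network content; the writer
  emits a plausible Level 3 subset, not a validator-compliant document,
  and layout/extension blocks are not preserved (a model-level annotation
  block is carried through verbatim).
* Only protein/gene annotation types map across models; small molecules
  surface their raw URIs but join no cross-model claims.
* Kinetic injection is a prototype: uniform constants, modifiers ignored,
  no per-mechanism law selection, no stochastic (propensity) formulation.
* The classifier is instance-based; with a handful of cluster replicates
  per lineage there is no train/validation split to support a supervised
  model, which is precisely the regime nearest-neighbour methods are for.
* z-score significance is relative to the sampled lineage panel (see
  above); absent lineages bias it upward for narrowly expressed genes.
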