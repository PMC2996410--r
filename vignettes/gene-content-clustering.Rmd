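---
title: "Gene-content clustering from phyletic patterns: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gene-content clustering from phyletic patterns: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phyletic)
```

## The method

A gene-content ("phyletic pattern") tree classifies genomes not by the
divergence of any one sequence but by the repertoire of gene families each
genome carries. The pipeline in this package runs the classic recipe:

1. **Homology.** Proteins of two proteomes are homologous when they are
   reciprocal best hits (each is the other's highest-scoring match) and the
   best hit aligns over more than 70 columns with more than 20% identity —
   both inequalities strict. Alignment is exact Smith–Waterman with affine
   gaps rather than a heuristic search: at the scale this package targets,
   exactness is affordable and removes a whole class of seed-and-extend
   artifacts. Significance uses the Karlin–Altschul form
   $E = K\,m\,n\,e^{-\lambda S}$ with the gapped BLOSUM62/11/1 parameters
   $\lambda = 0.267$, $K = 0.041$ as defaults.
2. **Profiling.** Each protein is assigned to a category-labelled reference
   ortholog group (a COG-like database) by its best hit, accepted only when
   $E < 10^{-3}$ (strict). Only groups in the informational categories —
   J (translation), A (RNA processing), K (transcription), L (replication
   and repair), B (chromatin) — plus F (nucleotide metabolism) enter the
   analysis. The phyletic matrix sets cell $(t, g) = 1$ when taxon $t$ has
   at least one protein assigned to group $g$.
3. **Clustering.** Distances between taxa are plain Euclidean distances on
   the 0/1 rows (for binary rows, $\sqrt{\text{Hamming}}$), with no
   weighting or normalization. Agglomerative clustering produces the
   dendrogram; complete linkage is the default, with single, average and
   Ward (squared-distance form) available.
4. **Evaluation.** A labelled clade is *recovered* when one dendrogram
   edge separates exactly its taxa. Against a reference topology the
   package reports Robinson–Foulds distance (symmetric difference of
   non-trivial unrooted bipartitions), both on the full taxon set and at
   the clade level (bipartitions in which every clade is wholly on one
   side, projected onto clade labels).

## The synthetic study system

Real gene-content analyses depend on curated ortholog databases and large
proteome collections. To make every stage testable with a known answer,
the package generates its own study system.

**Tree.** `sample_tree()` draws an ultrametric binary tree of
`n_clades` clades with `leaves_per_clade` leaves each. Within a clade,
leaves coalesce at heights drawn uniformly below `within_clade_depth`,
with the clade root at exactly that depth. Clade roots join along a
random backbone whose merge heights are spaced *evenly* between
`within_clade_depth` and `between_clade_depth` (the root). The even
spacing matters: if all backbone joins sat just under the root, the
backbone would effectively be a star and no method — this one or any
other — could recover the clade topology from finite data. Spreading the
joins through the deep part of the tree keeps the generating topology
identifiable while preserving a clean clade structure.

**Gene content.** Each of `n_families` families evolves independently as
a two-state continuous-time Markov chain with gain rate $\lambda$ and
loss rate $\mu$ (events per family per unit branch length). The closed
form $P(\text{present at } t) = \pi + (s_0 - \pi)e^{-(\lambda+\mu)t}$
with $\pi = \lambda/(\lambda+\mu)$ gives analytic checkpoints for the
tests. Root states are Bernoulli($\pi$) by default, so the process is
stationary. The simulator records every event (branch, type, position),
and a replay of the trace must reproduce the leaf matrix bit for bit —
this invariant is tested.

**Sequences.** Each family has one root sequence (length uniform on
[`root_len_min`, `root_len_max`], residues uniform over the 20 amino
acids). Along a branch of length $t$ every site is independently
replaced with probability $\min(1, \text{sub\_rate} \cdot t)$ by one of
the 19 other residues. There are no indels and no rate heterogeneity;
length variation between families exercises the alignment-length filter
instead. The per-branch divergence has the trivial closed form
$p = \min(1, \text{sub\_rate}\cdot t)$, again used directly by the tests.

**Determinism.** Every (family, branch) pair draws from a stream seeded
by a deterministic mix of the master seed and the two indices, so results
cannot depend on evaluation order, and the whole pipeline is
byte-reproducible given its configuration.

## Default parameters and why

| parameter | default | rationale |
|---|---|---|
| `n_clades` × `leaves_per_clade` | 4 × 4 | four domains of comparable size, 16 taxa |
| `n_families` | 300 | order of the informational-gene universe |
| `gain`, `loss` | 0.3, 0.3 | stationary presence 1/2; deepest splits (patristic ≈ 2 × 3.0) stay below saturation |
| `within_clade_depth` | 0.5 | tight clades: sister taxa share most families |
| `between_clade_depth` | 3.0 | 6× the within depth, well-separated clades |
| `sub_rate` | 0.1 / unit length | ≈10% expected divergence between sister leaves (patristic ≤ 1.0) |
| `root_len_min/max` | 80–150 aa | comfortably above the 70-column homology filter |
| gap open/extend | 11 / 1 | the standard gapped BLOSUM62 penalty pair |
| `evalue_threshold` | $10^{-3}$ | strict, matching the profiling convention |
| linkage | complete | the common default of R's hierarchical clustering |

With these defaults a leaf sits at patristic distance 3.0 from the root,
so a leaf sequence is ≈26% diverged from its family root — far enough to
be non-trivial, close enough that best-hit assignment to the root-derived
reference is essentially error-free. That is intentional: the acceptance
experiments isolate each stage's correctness, not the breakdown point of
alignment under extreme divergence.

## Numerical and tie-break choices

- **"Over 70 / over 20%"** are strict inequalities; alignment length
  counts all columns including gaps, and percent identity uses that
  count as denominator (the tabular-output convention of standard
  search tools).
- **Best-hit ties** break by higher score, then lower E-value, then
  lexicographically smallest subject id. Assignment ties additionally
  prefer the smallest group id.
- **Alignment statistics are orientation-canonical**: the score of a
  local alignment is symmetric in its arguments, but when several
  co-optimal alignments exist a traceback could report different column
  counts for (a, b) and (b, a); the package always tracebacks in a fixed
  lexicographic orientation so reported statistics are symmetric too.
- **Clustering ties** (two cluster pairs at exactly the minimal linkage
  distance) merge the pair whose sorted member-label tuple is
  lexicographically smallest. This makes the dendrogram a pure function
  of the labelled distance matrix, invariant to input order.
- **Newick edge lengths** are parent merge height minus child height
  (leaves at height 0), with no halving; heights print with 6 decimals,
  as do all numeric TSV cells, so output is byte-stable.
- **Degenerate inputs**: empty sequences are a no-hit, not an error; a
  taxon whose families are all absent yields an empty FASTA with a
  warning; an empty category filter result warns rather than errors;
  `gain = loss = 0` without an explicit root probability is an error
  (the stationary distribution is undefined).
- **Ward linkage** uses the squared-distance (ward.D2-style)
  Lance–Williams recursion; on distance matrices that are exactly
  Euclidean this matches the minimum-variance criterion, and the test
  suite cross-checks all four linkages against `stats::hclust` on
  tie-free matrices and against an independently coded naive
  agglomerator under the shared tie-break.

## Problem sizes used by the test and acceptance experiments

Simulation-based checks run at sizes chosen to give clear statistical
margins while staying desk-scale: 10,000 families for the stationarity
check (Monte-Carlo error ±0.005 against a ±0.03 band), 200 sequence pairs
of length ≤ 8 against the exhaustive alignment-enumeration oracle, 100
random distance matrices of up to 8 taxa across all four linkages, one
16-taxon × 300-family world for matrix recovery, and 20 independently
seeded worlds for the clade-recovery experiment (clustering run on the
ground-truth matrices, so the experiment measures the phyletic method
itself rather than alignment noise). Measured over 300 further
replicates, per-replicate full recovery (all clades monophyletic and
clade-level RF = 0) is ≈0.99; the residual failures are wrong backbone
pairings under near-caterpillar geometries, an intrinsic limit of
finite-family resolution at deep, nearly saturated splits.

## What passing these experiments does — and does not — show

The generator emulates: clade-structured taxon samples, stochastic gene
gain/loss with known provenance, sequence divergence proportional to
branch length, and reference databases with category labels. It does
**not** emulate: insertions/deletions, rate variation across sites or
lineages, horizontal transfer, paralogy (one sequence per family per
taxon), compositional bias, or the curation noise of real ortholog
databases. Passing the acceptance experiments therefore demonstrates
that the pipeline's computations are correct and internally consistent,
not that gene-content clustering resolves any particular real dataset;
on real proteomes the homology and assignment stages would face
ambiguities (domain shuffling, fusion proteins, promiscuous families)
that this system deliberately excludes.

## A worked miniature

```{r example, eval = FALSE}
library(phyletic)

tree  <- sample_tree(4, 4, seed = 1)
truth <- evolve_content(tree, gain_loss_params(0.3, 0.3, 300,
                                               master_seed = 1))
prot  <- evolve_proteomes(tree, truth, seq_evol_params(seed = 8))

refdb <- reference_from_roots(prot)
asg   <- lapply(prot$proteomes, assign_to_reference, refdb = refdb)
mat   <- build_matrix(asg, sort(refdb$groups$group_id))

dend  <- agglomerative_cluster(euclidean_distances(mat), "complete")
compare_clades(dend, tree$clades, reference_tree = tree)
```

The same computation, stage by stage with all intermediates on disk, is
available as `run_pipeline(pipeline_config(...))` and as the numbered
scripts under `analysis/`.
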