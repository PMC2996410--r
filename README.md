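# phyletic

Gene-content ("phyletic pattern") phylogenetics in R: an exact,
fully reproducible implementation of the classic pipeline that clusters
genomes — cellular organisms and giant DNA viruses alike — by the
presence/absence profile of their informational gene families, together
with a synthetic genome-evolution generator that gives every stage a
known ground truth.

## The problem

Sequence trees compare one gene at a time; a gene-content tree compares
entire repertoires. Each genome is reduced to a binary vector over a
universe of ortholog groups restricted to information storage and
processing (translation J, RNA processing A, transcription K,
replication/repair L, chromatin B) plus nucleotide metabolism (F).
Genomes with similar repertoires cluster together, which is how giant
nucleocytoplasmic DNA viruses can be placed alongside Eukarya, Bacteria
and Archaea without aligning a single shared marker across all four
groups. This package is aimed at comparative genomicists who want that
analysis as tested, deterministic code rather than a one-off script.

## The method

- **Homology**: reciprocal best hits under exact Smith–Waterman with
  affine gaps (BLOSUM62, gap open 11, extend 1), kept when the best hit
  aligns over >70 columns with >20% identity (both strict). Significance
  via the Karlin–Altschul E-value `E = K·m·n·exp(−λS)` (λ = 0.267,
  K = 0.041 by default). Homolog groups are connected components of the
  BBH graph.
- **Profiling**: best-hit assignment of proteins to a category-labelled
  reference ortholog database, accepted when `E < 1e-3` (strict); the
  phyletic matrix sets cell (taxon, group) = 1 iff the taxon has at
  least one assigned protein.
- **Clustering**: Euclidean distances on the 0/1 rows (√Hamming),
  agglomerative clustering (complete linkage by default; single,
  average and Ward available) with a deterministic lexicographic
  tie-break, Newick export.
- **Evaluation**: per-clade monophyly and Robinson–Foulds distance
  (full and clade-level) against a reference topology.
- **Synthetic evolution**: gene gain/loss as a two-state Markov chain
  (rates λ, μ per family per unit branch length) along a clade-structured
  ultrametric tree, plus per-site sequence divergence — with a replayable
  event trace and full determinism from one master seed.

## Worked example

The numbered scripts under `analysis/` run the full study on a
simulated 4-clade world (16 taxa, 300 gene families, ~10% sister-leaf
sequence divergence):

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_homology.R
Rscript analysis/03_profile.R
Rscript analysis/04_cluster.R
Rscript analysis/05_replicates.R
```

which prints, stage by stage:

```
Simulated 16 taxa in 4 clades; 300 gene families (50% mean presence).
Gain/loss events on the tree: 1192. Outputs under results/run/.

BBH search over 6 cross-clade proteome pairs: 503 reciprocal pairs kept,
  99.6% of them link proteins of the same ground-truth family.
Homolog groups: 186, of which 38 span all four clades
  (the 'common to all domains' gene set of this synthetic world).

Assigned 2401 proteins across 16 taxa to 300 reference groups.
Phyletic matrix: 16 x 300, 2401 presences; 100.00% of cells match ground truth.

Gene-content dendrogram (complete linkage on Euclidean distances):
clade_recovery: 4 of 4 clades monophyletic
  RF distance: 2 (clade-level: 0)

Full recovery (4/4 monophyletic, clade-level RF = 0) in 20 of 20 replicates.
```

Reading the numbers: the reciprocal-best-hit stage recovers essentially
only true orthologs; the inferred presence/absence matrix reproduces the
simulator's ground truth exactly; the dendrogram separates all four
clades, and its clade-level topology matches the generating tree
(RF = 0 at the clade level; the taxon-level RF of 2 reflects one
rearranged shallow split inside a clade, which gene content is not
expected to resolve). The same chain is available programmatically as
`run_pipeline(pipeline_config(...))`, which writes every intermediate,
a resolved configuration and an MD5 manifest, and is byte-reproducible
given the seed.

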