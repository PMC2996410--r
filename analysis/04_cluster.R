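#!/usr/bin/env Rscript
# Stage 4: Euclidean distances on the 0/1 phyletic matrix, complete-
# linkage agglomerative clustering into a dendrogram, Newick export,
# and clade-recovery scoring (monophyly of each clade plus
# Robinson-Foulds distance to the generating tree).

suppressPackageStartupMessages(library(phyletic))

run <- "results/run"
mat <- read_matrix_tsv(file.path(run, "matrix.tsv"))
D <- euclidean_distances(mat)
phyletic:::write_distances_tsv(D, file.path(run, "distances.tsv"))

dend <- agglomerative_cluster(D, "complete")
nwk <- to_newick(dend, precision = 6)
writeLines(nwk, file.path(run, "dendrogram.nwk"))

clades <- read.delim(file.path(run, "clades.tsv"))
labels <- setNames(clades$clade, clades$taxon)
rec <- compare_clades(dend, labels, reference_tree = file.path(run, "tree.nwk"))
phyletic:::write_tsv_lf(
  data.frame(clade = names(rec$monophyletic),
             monophyletic = unname(rec$monophyletic)),
  file.path(run, "recovery.tsv"))

cat("Gene-content dendrogram (complete linkage on Euclidean distances):\n")
print(rec)
cat(sprintf("Newick written to %s.\n", file.path(run, "dendrogram.nwk")))
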