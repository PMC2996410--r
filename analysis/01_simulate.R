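#!/usr/bin/env Rscript
# Stage 1: generate the synthetic study system — a 4-clade, 16-taxon
# ultrametric tree, gene-family presence/absence evolved under a
# gain/loss Markov process, and divergent proteomes with known family
# provenance. Everything downstream (homology search, profiling,
# clustering) is scored against this ground truth.

suppressPackageStartupMessages(library(phyletic))

out <- "results/run"
dir.create(file.path(out, "proteomes"), recursive = TRUE,
           showWarnings = FALSE)
dir.create(file.path(out, "refdb"), showWarnings = FALSE)
seed <- 1L

tree <- sample_tree(n_clades = 4, leaves_per_clade = 4,
                    within_clade_depth = 0.5, between_clade_depth = 3.0,
                    seed = seed)
truth <- evolve_content(tree, gain_loss_params(0.3, 0.3, 300,
                                               master_seed = seed))
prot <- evolve_proteomes(tree, truth,
                         seq_evol_params(sub_rate = 0.1, root_len_min = 80,
                                         root_len_max = 150, seed = seed + 7L))

writeLines(tree$newick, file.path(out, "tree.nwk"))
phyletic:::write_tsv_lf(
  data.frame(taxon = names(tree$clades), clade = unname(tree$clades)),
  file.path(out, "clades.tsv"))
write_matrix_tsv(truth$matrix, file.path(out, "truth_matrix.tsv"))
for (tx in names(prot$proteomes)) {
  seqs <- prot$proteomes[[tx]]
  names(seqs) <- paste(tx, names(seqs), sep = "|")
  write_fasta(seqs, file.path(out, "proteomes", paste0(tx, ".fasta")))
}
refdb <- reference_from_roots(prot)
write_reference_db(refdb, file.path(out, "refdb", "groups.tsv"),
                   file.path(out, "refdb", "members.fasta"))

cat(sprintf("Simulated %d taxa in %d clades; %d gene families (%.0f%% mean presence).\n",
            nrow(truth$matrix), length(unique(tree$clades)),
            ncol(truth$matrix), 100 * mean(truth$matrix)))
cat(sprintf("Gain/loss events on the tree: %d. Outputs under %s/.\n",
            nrow(truth$trace), out))
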