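#!/usr/bin/env Rscript
# Stage 5: the clade-recovery experiment. 20 independently seeded
# worlds (4 clades x 4 leaves, 300 families); for each, the clustering
# stage runs on the ground-truth matrix so that the experiment measures
# the phyletic-pattern method itself, not alignment noise. Reported:
# how often all four clades come out monophyletic with the generating
# clade topology reproduced exactly (clade-level RF = 0).

suppressPackageStartupMessages(library(phyletic))

dir.create("results", showWarnings = FALSE)
rows <- list()
for (seed in 1:20) {
  tr <- sample_tree(4, 4, within_clade_depth = 0.5, between_clade_depth = 3,
                    seed = seed)
  truth <- evolve_content(tr, gain_loss_params(0.3, 0.3, 300,
                                               master_seed = seed))
  dend <- agglomerative_cluster(euclidean_distances(truth$matrix), "complete")
  rec <- compare_clades(dend, tr$clades, reference_tree = tr)
  rows[[seed]] <- data.frame(
    seed = seed,
    clades_monophyletic = rec$n_clades_recovered,
    rf_clade = ifelse(is.na(rec$rf_clade), NA_integer_, rec$rf_clade))
}
tab <- do.call(rbind, rows)
phyletic:::write_tsv_lf(tab, "results/clade_recovery_replicates.tsv")

full <- sum(tab$clades_monophyletic == 4 & !is.na(tab$rf_clade) &
              tab$rf_clade == 0)
cat(sprintf("Full recovery (4/4 monophyletic, clade-level RF = 0) in %d of 20 replicates.\n",
            full))
cat("Per-replicate table written to results/clade_recovery_replicates.tsv\n")
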