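#!/usr/bin/env Rscript
# Simulate the synthetic two-region study: negative-binomial counts for four
# RNA biotypes under a CCI-vs-sham design, with planted DE genes, planted
# miRNA-sponge triplets, disease gene sets, annotation sets and a PPI network.

source("analysis/00_common.R")

study <- simulate_study(out_dir = STUDY_DIR, seed = ANALYSIS_SEED)

cat("Simulated study written to", STUDY_DIR, "\n")
cat(sprintf("  samples:       %d (%d per region-condition cell)\n",
            nrow(study$design), max(study$design$replicate)))
cat(sprintf("  genes:         %d (%s)\n", nrow(study$counts),
            paste(sprintf("%s=%d", names(table(study$counts$biotype)),
                          table(study$counts$biotype)), collapse = ", ")))
cat(sprintf("  planted DE:    %d genes (|log2FC| >= %g)\n",
            nrow(study$truth$de_genes), min(abs(study$truth$de_genes$log2fc))))
cat(sprintf("  planted ceRNA: %d triplets in %s (target r = %g)\n",
            nrow(study$truth$triplets),
            unique(study$truth$triplets$region),
            unique(study$truth$triplets$r)))
cat(sprintf("  target map:    %d interactions over %d miRNAs\n",
            nrow(study$targets), length(unique(study$targets$mirna_id))))
cat(sprintf("  PPI edges:     %d\n", nrow(study$ppi_edges)))
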