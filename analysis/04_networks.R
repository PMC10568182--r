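#!/usr/bin/env Rscript
# Network stages: the DEG-induced PPI subnetwork with degree-ranked hubs, and
# the ceRNA (miRNA-sponge) networks combining the shared-miRNA hypergeometric
# statistic with expression-correlation and direction-concordance filters.

source("analysis/00_common.R")
dir.create(TABLE_DIR, recursive = TRUE, showWarnings = FALSE)

study <- load_study()
d <- derive_de(study)

for (r in names(d$de)) {
  graph <- induce_deg_subgraph(study$ppi_edges, d$de[[r]])
  hubs <- select_hubs(graph, k = 50)
  write_tsv(hubs, file.path(TABLE_DIR, paste0("hubs_", r, ".tsv")),
            meta = list(seed = ANALYSIS_SEED))
  cat(sprintf("\n%s: PPI subnetwork %d nodes / %d edges; top hubs:\n",
              r, nrow(graph$nodes), nrow(graph$edges)))
  print(head(hubs[, c("rank", "gene_id", "degree", "direction", "color")], 5))

  pairs <- call_pairs(d$de[[r]], d$expr, study$design, r, study$targets)
  write_tsv(pairs, file.path(TABLE_DIR, paste0("cerna_pairs_", r, ".tsv")),
            meta = list(seed = ANALYSIS_SEED, hyper_alpha = 0.05,
                        ppc_min = 0.5, ppc_alpha = 0.05))
  net <- build_network(pairs)
  write_tsv(net$nodes, file.path(TABLE_DIR, paste0("cerna_nodes_", r, ".tsv")),
            meta = list(seed = ANALYSIS_SEED))
  cat(sprintf("%s: %d candidate ceRNA pairs, %d passing\n",
              r, nrow(pairs), sum(pairs$passes)))
  if (nrow(net$top_cernas)) {
    cat("  top ceRNAs by network degree:\n")
    print(net$top_cernas)
    cat("  top miRNAs by mediated pairs:\n")
    print(net$top_mirnas)
  }
}
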