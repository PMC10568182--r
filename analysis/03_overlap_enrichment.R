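#!/usr/bin/env Rscript
# Disease-category mapping of the significant DEGs (counts, percentages and
# multi-category intersections) and hypergeometric over-representation
# against the annotation gene sets.

source("analysis/00_common.R")
dir.create(TABLE_DIR, recursive = TRUE, showWarnings = FALSE)

study <- load_study()
d <- derive_de(study)

tuples <- list(c("pain", "anxiety", "depression"),
               c("pain", "apoptosis", "inflammation", "immunity"))
background <- intersect(d$expr$gene_id,
                        unique(unlist(study$annotation_sets)))

for (r in names(d$de)) {
  cats <- map_to_categories(d$de[[r]], study$disease_sets, tuples = tuples)
  write_tsv(cats$categories,
            file.path(TABLE_DIR, paste0("category_overlap_", r, ".tsv")),
            meta = list(seed = ANALYSIS_SEED))
  write_tsv(cats$tuples,
            file.path(TABLE_DIR, paste0("category_tuples_", r, ".tsv")),
            meta = list(seed = ANALYSIS_SEED))
  cat(sprintf("\n%s: disease-category coverage of %d significant DEGs\n",
              r, cats$categories$n_deg[1]))
  print(transform(cats$categories, percent = round(percent, 2)))
  print(cats$tuples)

  query <- intersect(d$de[[r]]$gene_id[d$de[[r]]$significant &
                                         d$de[[r]]$biotype == "mRNA"],
                     background)
  enr <- enrich(query, background, study$annotation_sets)
  write_tsv(enr, file.path(TABLE_DIR, paste0("enrichment_", r, ".tsv")),
            meta = list(seed = ANALYSIS_SEED))
  cat(sprintf("\n%s: top annotation terms (-log10 p):\n", r))
  print(head(enr[, c("set_name", "k", "K", "p_value", "neg_log10_p")], 5))
}
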