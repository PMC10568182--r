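#!/usr/bin/env Rscript
# RPKM normalisation and per-region differential expression with the study's
# joint filter (p <= 0.05, fold change >= 2), then cross-region Venn
# accounting of co-regulated genes.

source("analysis/00_common.R")
dir.create(TABLE_DIR, recursive = TRUE, showWarnings = FALSE)

study <- load_study()
d <- derive_de(study)

write_tsv(d$expr, file.path(TABLE_DIR, "rpkm.tsv"),
          meta = list(seed = ANALYSIS_SEED))

cat("Significant genes per region and biotype (p <= 0.05, FC >= 2):\n")
for (r in names(d$de)) {
  write_tsv(d$de[[r]], file.path(TABLE_DIR, paste0("de_", r, ".tsv")),
            meta = list(seed = ANALYSIS_SEED, alpha = 0.05, fc_cutoff = 2))
  print(de_counts(d$de[[r]]))
}

ov <- co_expression_overlap(d$de$TG, d$de$Sp5C)
write_tsv(ov, file.path(TABLE_DIR, "co_expression_overlap.tsv"),
          meta = list(seed = ANALYSIS_SEED))
cat("\nCo-regulated genes across TG and Sp5C:\n")
print(ov[, c("biotype", "direction", "co_expressed", "a_only", "b_only")])
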