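# Shared constants for the analysis scripts: one seed drives the whole
# workflow, and every script reads/writes under results/.

suppressPackageStartupMessages(library(cernaflow))

ANALYSIS_SEED <- 1007L
STUDY_DIR <- "results/study"
TABLE_DIR <- "results/tables"

load_study <- function() {
  list(
    design = read_design_tsv(file.path(STUDY_DIR, "design.tsv")),
    counts = read_counts_tsv(file.path(STUDY_DIR, "counts.tsv")),
    targets = read_target_map_tsv(file.path(STUDY_DIR, "target_map.tsv")),
    ppi_edges = read_tsv(file.path(STUDY_DIR, "ppi_edges.tsv")),
    disease_sets = read_gmt(file.path(STUDY_DIR, "disease_sets.gmt")),
    annotation_sets = read_gmt(file.path(STUDY_DIR, "annotation_sets.gmt")),
    truth = list(
      de_genes = read_tsv(file.path(STUDY_DIR, "truth_de_genes.tsv")),
      triplets = read_tsv(file.path(STUDY_DIR, "truth_triplets.tsv"))
    )
  )
}

# DE tables are recomputed (deterministically) where needed rather than
# serialised with their attributes
derive_de <- function(study) {
  expr <- compute_rpkm(study$counts)
  list(expr = expr,
       de = setNames(lapply(c("TG", "Sp5C"), function(r)
         call_de(expr, study$design, r)), c("TG", "Sp5C")))
}
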