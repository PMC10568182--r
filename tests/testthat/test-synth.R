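test_that("design arithmetic, validation and determinism", {
  d <- generate_design(3)
  expect_equal(nrow(d), 12)
  expect_equal(unname(table(paste(d$region, d$condition))),
               as.integer(rep(3, 4)), ignore_attr = TRUE)
  expect_false(anyDuplicated(d$sample_id) > 0)
  # replicate numbering dense from 1 within each cell
  for (cell in split(d, paste(d$region, d$condition))) {
    expect_equal(sort(cell$replicate), seq_len(3))
  }
  expect_equal(nrow(generate_design(1)), 4)
  expect_identical(generate_design(3, 7), generate_design(3, 7))
  expect_error(generate_design(0), "positive")
})

test_that("count generator is seed-deterministic and honours planted nulls", {
  d <- generate_design(3)
  g1 <- generate_counts(d, n_per_biotype = c(mRNA = 50, lncRNA = 10),
                        n_de = 0, seed = 42)
  g2 <- generate_counts(d, n_per_biotype = c(mRNA = 50, lncRNA = 10),
                        n_de = 0, seed = 42)
  expect_identical(g1, g2)
  expect_equal(nrow(g1$truth$de_genes), 0)
  g3 <- generate_counts(d, n_per_biotype = c(mRNA = 50, lncRNA = 10),
                        n_de = 0, seed = 43)
  expect_false(identical(g1$counts, g3$counts))
  expect_error(
    generate_counts(d, n_per_biotype = c(mRNA = 5), n_de = 10),
    "exceeds"
  )
})

test_that("with no planted effects the observed log2FC shrinks with replicates", {
  gmean_lfc <- function(reps, seed) {
    d <- generate_design(reps)
    g <- generate_counts(d, n_per_biotype = c(mRNA = 300), n_de = 0,
                         seed = seed)
    e <- compute_rpkm(g$counts)
    de <- call_de(e, d, "TG")
    mean(abs(de$log2fc))
  }
  expect_lt(gmean_lfc(9, 1), gmean_lfc(2, 1))
})

test_that("planted fold change is realised in the group means", {
  # Monte-Carlo check of the generator against its own parameters: ratio of
  # condition means for a gene planted at log2FC = 2 stays within a factor
  # of 2 of the nominal 4 at 9 replicates per cell
  d <- generate_design(9)
  for (s in 1:5) {
    g <- generate_counts(d, n_per_biotype = c(mRNA = 60), n_de = 10,
                         de_log2fc = 2, seed = s)
    counts <- g$counts
    m <- as.matrix(counts[, grep("^TG|^Sp5C", names(counts))])
    rownames(m) <- counts$gene_id
    for (i in seq_len(nrow(g$truth$de_genes))) {
      gene <- g$truth$de_genes$gene_id[i]
      r <- g$truth$de_genes$region[i]
      case <- mean(m[gene, paste0(r, "_CCI_", 1:9)])
      ctrl <- mean(m[gene, paste0(r, "_sham_", 1:9)])
      ratio <- (case + 0.5) / (ctrl + 0.5)
      if (g$truth$de_genes$log2fc[i] < 0) ratio <- 1 / ratio
      expect_gt(ratio, 2)
      expect_lt(ratio, 8)
    }
  }
})

test_that("target map plants triplets and controls its size", {
  trip <- data.frame(mirna_id = "miR-t1", cerna_id = "lnc1",
                     mrna_id = "m1", stringsAsFactors = FALSE)
  map <- generate_target_map(universe = c("lnc1", "m1", "m2"),
                             n_mirna = 0, targets_per_mirna = 0,
                             triplets = trip, seed = 1)
  expect_equal(nrow(map), 2)
  sh <- shared_mirnas(map, "lnc1", "m1")
  expect_gte(sh$k_shared, 1)

  map2 <- generate_target_map(universe = sprintf("g%02d", 1:40),
                              n_mirna = 10, targets_per_mirna = 5, seed = 9)
  expect_equal(nrow(map2), 50)
  expect_identical(map2,
                   generate_target_map(universe = sprintf("g%02d", 1:40),
                                       n_mirna = 10, targets_per_mirna = 5,
                                       seed = 9))
  # triplet members excluded from background sampling by default
  map3 <- generate_target_map(universe = c("lnc1", "m1", "m2", "m3"),
                              n_mirna = 5, targets_per_mirna = 2,
                              triplets = trip, seed = 2)
  bg <- map3[!map3$mirna_id %in% "miR-t1", ]
  expect_false(any(bg$target_id %in% c("lnc1", "m1")))
})

test_that("gene set generator hits sizes and pairwise overlaps exactly", {
  u <- sprintf("g%03d", 1:200)
  sets <- generate_gene_sets(u, c(A = 10, B = 10), list("A|B" = 4), seed = 1)
  expect_equal(lengths(sets), c(A = 10L, B = 10L))
  expect_equal(length(intersect(sets$A, sets$B)), 4)

  expect_warning(
    s0 <- generate_gene_sets(u, c(A = 5, Z = 0), seed = 1),
    "size 0"
  )
  expect_equal(length(s0$Z), 0)

  expect_error(
    generate_gene_sets(u, c(A = 10, B = 10), list("A|B" = 11), seed = 1),
    "exceeds the smaller set size"
  )

  # unspecified pairs come out disjoint; specified ones exact, on many seeds
  for (s in 1:3) {
    sets <- generate_gene_sets(u, c(A = 30, B = 25, C = 20),
                               list("A|B" = 7, "B|C" = 5), seed = s)
    expect_equal(length(intersect(sets$A, sets$B)), 7)
    expect_equal(length(intersect(sets$B, sets$C)), 5)
    expect_equal(length(intersect(sets$A, sets$C)), 0)
  }
})

test_that("ground truth is resolvable against the generated study", {
  study <- simulate_study(seed = 21)
  expect_true(all(study$truth$de_genes$gene_id %in% study$counts$gene_id))
  expect_true(all(abs(study$truth$de_genes$log2fc) >= 1))
  trips <- study$truth$triplets
  expect_true(all(c(trips$cerna_id, trips$mrna_id, trips$mirna_id) %in%
                    study$counts$gene_id))
  # every planted triplet is wired into the target map
  for (i in seq_len(nrow(trips))) {
    sh <- shared_mirnas(study$targets, trips$cerna_id[i], trips$mrna_id[i])
    expect_true(trips$mirna_id[i] %in% sh$mirnas)
  }
  expect_true(all(unlist(study$disease_sets) %in% study$counts$gene_id))
})

test_that("written study inputs round-trip and are byte-stable", {
  dir1 <- withr::local_tempdir()
  dir2 <- withr::local_tempdir()
  simulate_study(seed = 5, out_dir = dir1,
                 n_per_biotype = c(mRNA = 80, lncRNA = 30, circRNA = 30,
                                   miRNA = 40),
                 n_de = 30, n_triplets = 2, n_mirna_background = 20,
                 n_ppi_edges = 50)
  simulate_study(seed = 5, out_dir = dir2,
                 n_per_biotype = c(mRNA = 80, lncRNA = 30, circRNA = 30,
                                   miRNA = 40),
                 n_de = 30, n_triplets = 2, n_mirna_background = 20,
                 n_ppi_edges = 50)
  for (f in list.files(dir1)) {
    expect_identical(readLines(file.path(dir1, f)),
                     readLines(file.path(dir2, f)), label = f)
  }
  counts <- read_counts_tsv(file.path(dir1, "counts.tsv"))
  expect_equal(nrow(counts), 180)
  sets <- read_gmt(file.path(dir1, "disease_sets.gmt"))
  expect_equal(length(sets), 6)
})
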