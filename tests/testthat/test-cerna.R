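test_that("shared miRNA extraction matches the pairwise intersection oracle", {
  map <- data.frame(mirna_id = c("miR-1", "miR-1", "miR-2"),
                    target_id = c("L1", "M1", "L1"),
                    stringsAsFactors = FALSE)
  sh <- shared_mirnas(map, "L1", "M1")
  expect_equal(sh$mirnas, "miR-1")
  expect_equal(sh$k_shared, 1)
  expect_equal(shared_mirnas(map, "M1", "L1")$k_shared, 1)

  set.seed(51)
  genes <- sprintf("t%02d", 1:30)
  map_r <- unique(data.frame(
    mirna_id = sample(sprintf("miR-%02d", 1:50), 400, TRUE),
    target_id = sample(genes, 400, TRUE), stringsAsFactors = FALSE))
  for (i in 1:15) {
    pair <- sample(genes, 2)
    sh <- shared_mirnas(map_r, pair[1], pair[2])
    oracle <- intersect(map_r$mirna_id[map_r$target_id == pair[1]],
                        map_r$mirna_id[map_r$target_id == pair[2]])
    expect_setequal(sh$mirnas, oracle)
    expect_equal(sh$k_shared, length(oracle))
  }
})

test_that("pearson_with_p matches closed forms and the cor.test oracle", {
  x <- 1:10
  res <- pearson_with_p(x, 2 * x + 1)
  expect_equal(res$r, 1)
  expect_equal(res$p_value, 0)
  expect_equal(pearson_with_p(x, -x)$r, -1)

  x <- c(1, 2, 3, 4, 5); y <- c(2, 1, 4, 3, 6)
  res <- pearson_with_p(x, y)
  mx <- mean(x); my <- mean(y)
  r_oracle <- sum((x - mx) * (y - my)) /
    sqrt(sum((x - mx)^2) * sum((y - my)^2))
  expect_equal(res$r, r_oracle, tolerance = 1e-12)
  ct <- stats::cor.test(x, y)
  expect_equal(res$r, unname(ct$estimate), tolerance = 1e-12)
  expect_equal(res$p_value, ct$p.value, tolerance = 1e-12)

  set.seed(53)
  for (i in 1:20) {
    n <- sample(4:20, 1)
    a <- rnorm(n); b <- rnorm(n) + 0.5 * a
    ct <- stats::cor.test(a, b)
    res <- pearson_with_p(a, b)
    expect_equal(res$r, unname(ct$estimate), tolerance = 1e-12)
    expect_equal(res$p_value, ct$p.value, tolerance = 1e-12)
  }
  expect_error(pearson_with_p(c(1, 1, 1), c(1, 2, 3)), "zero variance")
  expect_error(pearson_with_p(1:2, 1:2), "at least 3")
})

test_that("call_pairs applies all four pass rules", {
  fix <- generate_cerna_fixture(n_null_cerna = 10, n_null_mrna = 10,
                                n_triplets = 4, n_mirna = 20,
                                targets_per_mirna = 4, seed = 61)
  pairs <- call_pairs(fix$de, fix$expr, fix$design, "TG", fix$targets)
  expect_s3_class(pairs, "cerna_pairs")
  expect_true(all(pairs$k_shared >= 1))
  # pass flag is exactly the conjunction of the four rules
  expect_equal(pairs$passes,
               pairs$hypergeom_p <= 0.05 & pairs$concordant &
                 !is.na(pairs$ppc) & pairs$ppc >= 0.5 & pairs$ppc_p <= 0.05)
  # its hypergeometric p agrees with the scalar statistic exactly
  for (i in seq_len(min(nrow(pairs), 20))) {
    expect_equal(pairs$hypergeom_p[i],
                 hypergeom_tail(pairs$k_shared[i], pairs$K[i], pairs$n[i],
                                pairs$M[i]), tolerance = 1e-15)
  }
  expect_error(call_pairs(fix$de, fix$expr, fix$design, "TG",
                          fix$targets[0, ]), "empty")
})

test_that("anti-correlated or discordant planted pairs never pass", {
  fix <- generate_cerna_fixture(n_null_cerna = 5, n_null_mrna = 5,
                                n_triplets = 6, triplet_r = -0.9, seed = 63)
  pairs <- call_pairs(fix$de, fix$expr, fix$design, "TG", fix$targets)
  planted <- paste(pairs$cerna_id, pairs$mrna_id) %in%
    paste(fix$truth$cerna_id, fix$truth$mrna_id)
  expect_true(all(!pairs$passes[planted]))

  # discordant directions fail regardless of correlation
  fix2 <- generate_cerna_fixture(n_null_cerna = 5, n_null_mrna = 5,
                                 n_triplets = 6, triplet_r = 0.95, seed = 64)
  de2 <- fix2$de
  for (i in seq_len(nrow(fix2$truth))) {
    g <- fix2$truth$mrna_id[i]
    de2$direction[de2$gene_id == g] <-
      ifelse(de2$direction[de2$gene_id == g] == "up", "down", "up")
  }
  pairs2 <- call_pairs(de2, fix2$expr, fix2$design, "TG", fix2$targets)
  planted2 <- paste(pairs2$cerna_id, pairs2$mrna_id) %in%
    paste(fix2$truth$cerna_id, fix2$truth$mrna_id)
  expect_true(any(planted2))
  expect_true(all(!pairs2$concordant[planted2]))
  expect_true(all(!pairs2$passes[planted2]))
})

test_that("tightening any threshold never adds a passing pair", {
  fix <- generate_cerna_fixture(n_null_cerna = 40, n_null_mrna = 60,
                                n_triplets = 8, seed = 65)
  base <- call_pairs(fix$de, fix$expr, fix$design, "TG", fix$targets)
  key <- function(p) paste(p$cerna_id, p$mrna_id)[p$passes]
  for (args in list(list(hyper_alpha = 0.01), list(ppc_min = 0.7),
                    list(ppc_alpha = 0.01),
                    list(hyper_alpha = 0.005, ppc_min = 0.9))) {
    tight <- do.call(call_pairs,
                     c(list(fix$de, fix$expr, fix$design, "TG", fix$targets),
                       args))
    expect_true(all(key(tight) %in% key(base)))
  }
})

test_that("fewer than three samples triggers the hypergeometric-only branch", {
  fix <- generate_cerna_fixture(replicates_per_cell = 1, n_null_cerna = 5,
                                n_null_mrna = 5, n_triplets = 3, seed = 67)
  pairs <- call_pairs(fix$de, fix$expr, fix$design, "TG", fix$targets)
  expect_true(attr(pairs, "degenerate"))
  expect_true(all(is.na(pairs$ppc)))
  expect_equal(pairs$passes, pairs$hypergeom_p <= 0.05 & pairs$concordant)
})

test_that("network degrees equal incidence counts and top lists follow the tie rule", {
  # one passing pair with one shared miRNA: 3 nodes, all degree 1
  one <- data.frame(
    cerna_id = "L1", cerna_biotype = "lncRNA", mrna_id = "M1",
    k_shared = 1L, K = 1L, n = 1L, M = 10L, hypergeom_p = 0.1,
    ppc = 0.9, ppc_p = 0.001, cerna_direction = "up", mrna_direction = "up",
    concordant = TRUE, passes = TRUE, shared_mirnas = "miR-1",
    stringsAsFactors = FALSE
  )
  net <- build_network(one)
  expect_equal(nrow(net$nodes), 3)
  expect_true(all(net$nodes$degree == 1))

  fix <- generate_cerna_fixture(n_null_cerna = 40, n_null_mrna = 60,
                                n_triplets = 10, seed = 69)
  pairs <- call_pairs(fix$de, fix$expr, fix$design, "TG", fix$targets)
  net <- build_network(pairs, top_cerna = 5, top_mirna = 3)
  pass <- pairs[pairs$passes, ]
  for (i in seq_len(nrow(net$nodes))) {
    id <- net$nodes$id[i]
    expected <- switch(net$nodes$type[i],
      ceRNA = length(unique(pass$mrna_id[pass$cerna_id == id])),
      mRNA = length(unique(pass$cerna_id[pass$mrna_id == id])),
      miRNA = sum(vapply(strsplit(pass$shared_mirnas, ";"),
                         function(s) id %in% s, logical(1))))
    expect_equal(net$nodes$degree[i], expected)
  }
  # total ceRNA-side degree = total mRNA-side degree = number of passing pairs
  expect_equal(sum(net$nodes$degree[net$nodes$type == "ceRNA"]), nrow(pass))
  expect_equal(sum(net$nodes$degree[net$nodes$type == "mRNA"]), nrow(pass))
  expect_lte(nrow(net$top_cernas), 5)
  expect_true(all(diff(net$top_cernas$degree) <= 0))

  # permutation invariance in input order
  net2 <- build_network(pairs[sample(nrow(pairs)), ], top_cerna = 5,
                        top_mirna = 3)
  expect_equal(net$nodes, net2$nodes)
  expect_equal(net$top_cernas, net2$top_cernas)
})
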