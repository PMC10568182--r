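test_that("induced subgraph keeps only fully significant edges", {
  de <- make_de_table(c("a", "b", "c"), c(2, -2, 2))
  edges <- data.frame(gene_a = c("a", "b"), gene_b = c("b", "c"),
                      stringsAsFactors = FALSE)
  de$significant <- de$gene_id %in% c("a", "b")
  g <- induce_deg_subgraph(edges, de)
  expect_equal(nrow(g$edges), 1)
  expect_equal(g$edges$gene_a, "a")
  expect_equal(g$nodes$direction, c("up", "down"))

  de$significant <- FALSE
  g0 <- induce_deg_subgraph(edges, de)
  expect_equal(nrow(g0$edges), 0)
  expect_equal(nrow(select_hubs(g0, 5)), 0)
})

test_that("random edge fixtures match the brute-force filter and degree identities", {
  set.seed(41)
  ids <- sprintf("g%02d", 1:30)
  de <- make_de_table(ids, sample(c(2, -2, 0.2), 30, TRUE))
  edges <- data.frame(gene_a = sample(ids, 100, TRUE),
                      gene_b = sample(ids, 100, TRUE),
                      stringsAsFactors = FALSE)
  g <- induce_deg_subgraph(edges, de)
  sig <- de$gene_id[de$significant]
  oracle <- edges[edges$gene_a %in% sig & edges$gene_b %in% sig &
                    edges$gene_a != edges$gene_b, ]
  oracle_keys <- unique(paste(pmin(oracle$gene_a, oracle$gene_b),
                              pmax(oracle$gene_a, oracle$gene_b)))
  expect_setequal(paste(g$edges$gene_a, g$edges$gene_b), oracle_keys)
  # sum of degrees = 2 * |edges|
  expect_equal(sum(g$nodes$degree), 2 * nrow(g$edges))
  # degree equals incident-edge count, node by node
  for (i in seq_len(nrow(g$nodes))) {
    n <- g$nodes$gene_id[i]
    expect_equal(g$nodes$degree[i],
                 sum(g$edges$gene_a == n) + sum(g$edges$gene_b == n))
  }
})

test_that("hub ranking is stable under edge order and orientation", {
  set.seed(43)
  ids <- sprintf("g%02d", 1:20)
  de <- make_de_table(ids, runif(20, 1.5, 4) * sample(c(-1, 1), 20, TRUE))
  edges <- data.frame(gene_a = sample(ids, 60, TRUE),
                      gene_b = sample(ids, 60, TRUE),
                      stringsAsFactors = FALSE)
  hubs <- select_hubs(induce_deg_subgraph(edges, de), k = 10)
  shuffled <- edges[sample(nrow(edges)), ]
  flipped <- data.frame(gene_a = shuffled$gene_b, gene_b = shuffled$gene_a,
                        stringsAsFactors = FALSE)
  hubs2 <- select_hubs(induce_deg_subgraph(flipped, de), k = 10)
  expect_equal(hubs, hubs2)
  expect_true(all(diff(hubs$degree) <= 0))
  expect_equal(hubs$color, ifelse(hubs$direction == "up", "red", "blue"))
})

test_that("star graphs and documented tie-breaks order hubs deterministically", {
  de <- make_de_table(c("c", "l1", "l2", "l3", "l4", "l5"),
                      c(2, 2, 2, 2, 2, 2))
  star <- data.frame(gene_a = "c", gene_b = paste0("l", 1:5),
                     stringsAsFactors = FALSE)
  hubs <- select_hubs(induce_deg_subgraph(star, de), k = 3)
  expect_equal(hubs$gene_id[1], "c")
  expect_equal(hubs$degree[1], 5)

  # degree tie -> larger |log2fc| first, then gene id
  de2 <- make_de_table(c("a", "b", "x"), c(2, 3, 2))
  tri <- data.frame(gene_a = c("a", "b", "a"), gene_b = c("x", "x", "b"),
                    stringsAsFactors = FALSE)
  hubs2 <- select_hubs(induce_deg_subgraph(tri, de2), k = 3)
  expect_equal(hubs2$gene_id, c("b", "a", "x"))

  # min_score column filter
  scored <- data.frame(gene_a = c("a", "b"), gene_b = c("x", "x"),
                       score = c(900, 150), stringsAsFactors = FALSE)
  g <- induce_deg_subgraph(scored, de2, min_score = 400)
  expect_equal(nrow(g$edges), 1)
})
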