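test_that("co-expression overlap counts match explicit set arithmetic", {
  de_a <- make_de_table(c("g1", "g2", "g3"), c(2, 2, -2), region = "TG")
  de_b <- make_de_table(c("g2", "g3", "g4"), c(2, 2, -2), region = "Sp5C")
  ov <- co_expression_overlap(de_a, de_b)
  up <- ov[ov$direction == "up" & ov$biotype == "mRNA", ]
  expect_equal(up$co_expressed, 1)  # g2
  expect_equal(up$a_only, 1)        # g1
  expect_equal(up$b_only, 1)        # g3 is up in B, down in A

  # disjoint tables
  de_c <- make_de_table(c("x1", "x2"), c(2, -2), region = "Sp5C")
  ov2 <- co_expression_overlap(de_a, de_c)
  expect_true(all(ov2$co_expressed == 0))

  # randomised fixture against a brute-force oracle, incl. partition sums
  set.seed(77)
  for (rep in 1:3) {
    ids <- sprintf("g%03d", 1:200)
    a <- make_de_table(ids, sample(c(-2, 2, 0.5), 200, TRUE),
                       p = sample(c(0.01, 0.5), 200, TRUE),
                       biotype = sample(c("mRNA", "lncRNA", "circRNA"),
                                        200, TRUE))
    b <- make_de_table(ids, sample(c(-2, 2, 0.5), 200, TRUE),
                       p = sample(c(0.01, 0.5), 200, TRUE),
                       biotype = a$biotype, region = "Sp5C")
    ov <- co_expression_overlap(a, b)
    for (i in seq_len(nrow(ov))) {
      getset <- function(tab, dir, bt) {
        tab$gene_id[tab$significant & tab$direction == dir & tab$biotype == bt]
      }
      A <- getset(a, ov$direction[i], ov$biotype[i])
      B <- getset(b, ov$direction[i], ov$biotype[i])
      expect_equal(ov$co_expressed[i], length(intersect(A, B)))
      expect_equal(ov$a_only[i], length(setdiff(A, B)))
      expect_equal(ov$b_only[i], length(setdiff(B, A)))
      expect_equal(ov$co_expressed[i] + ov$a_only[i] + ov$b_only[i],
                   length(union(A, B)))
    }
  }
})

test_that("category mapping computes counts, percents and tuple intersections", {
  de <- make_de_table(c("a", "b", "c", "d"), c(2, 2, -2, -2))
  cats <- list(pain = c("a", "b"), anxiety = c("b", "c"), depression = c("b"))
  res <- map_to_categories(de, cats,
                           tuples = list(c("pain", "anxiety", "depression")))
  pain <- res$categories[res$categories$category == "pain", ]
  expect_equal(pain$n_overlap, 2)
  expect_equal(pain$percent, 50)
  expect_equal(res$tuples$n_intersection, 1)  # {b}

  expect_error(map_to_categories(de, cats, tuples = list(c("pain", "mood"))),
               "available")

  # exhaustive enumeration over all 2- and 3-way tuples of a random fixture
  set.seed(5)
  ids <- sprintf("g%02d", 1:60)
  de_r <- make_de_table(ids, rep(c(2, -2), 30))
  sets <- lapply(1:6, function(i) sample(ids, 20))
  names(sets) <- paste0("c", 1:6)
  combos <- c(utils::combn(names(sets), 2, simplify = FALSE),
              utils::combn(names(sets), 3, simplify = FALSE))
  res <- map_to_categories(de_r, sets, tuples = combos)
  for (i in seq_along(combos)) {
    expected <- Reduce(intersect, sets[combos[[i]]], ids)
    expect_equal(res$tuples$n_intersection[i], length(expected))
  }
})

test_that("adding an uncategorised DEG dilutes every percent but no count", {
  de <- make_de_table(c("a", "b", "c"), c(2, 2, -2))
  cats <- list(pain = c("a"), anxiety = c("a", "b"))
  before <- map_to_categories(de, cats)$categories
  de2 <- make_de_table(c("a", "b", "c", "zz"), c(2, 2, -2, 2))
  after <- map_to_categories(de2, cats)$categories
  expect_equal(after$n_overlap, before$n_overlap)
  expect_true(all(after$percent < before$percent))
})

test_that("top-k class table ranks by |log2fc| with the documented tie rule", {
  de <- make_de_table(
    c("a", "b", "c", "d", "e", "f"),
    c(3, 2.5, 2.5, -4, -1.5, 0.1),
    p = c(0.01, 0.02, 0.01, 0.01, 0.01, 0.01)
  )
  top <- top_k_by_class(de, class_set = c("a", "b", "c", "d", "e"), k = 15)
  ups <- top[top$direction == "up", ]
  expect_equal(ups$gene_id, c("a", "c", "b"))  # tie 2.5/2.5 broken by p
  downs <- top[top$direction == "down", ]
  expect_equal(downs$gene_id, c("d", "e"))
  expect_true(all(attr(top, "short")))  # fewer than 15 in both directions

  # lexicographic fallback when |lfc| and p both tie
  de_tie <- make_de_table(c("zz", "aa"), c(2, 2), p = 0.01)
  top_tie <- top_k_by_class(de_tie, c("zz", "aa"), k = 2)
  expect_equal(top_tie$gene_id, c("aa", "zz"))

  # random fixture equals an independent sort
  set.seed(13)
  ids <- sprintf("g%02d", 1:40)
  de_r <- make_de_table(ids, runif(40, -5, 5),
                        p = round(runif(40, 0, 0.04), 3))
  k <- 5
  top_r <- top_k_by_class(de_r, ids, k = k)
  for (dir in c("up", "down")) {
    sub <- de_r[de_r$significant & de_r$direction == dir, ]
    ord <- sub[order(-abs(sub$log2fc), sub$p_value, sub$gene_id), "gene_id"]
    expect_equal(top_r$gene_id[top_r$direction == dir], head(ord, k))
  }
})
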