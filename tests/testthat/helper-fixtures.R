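# Small fixtures shared across test files; everything is built in code.

tiny_counts <- function() {
  data.frame(
    gene_id = c("g1", "g2", "g3"),
    biotype = c("mRNA", "lncRNA", "mRNA"),
    length_bp = c(1000L, 500L, 2000L),
    s1 = c(10L, 0L, 90L),
    s2 = c(5L, 5L, 40L),
    stringsAsFactors = FALSE
  )
}

# hand-built DE table (bypasses call_de) for set/graph/ceRNA unit tests
make_de_table <- function(gene_id, lfc, p = 0.01, biotype = "mRNA",
                          region = "TG", alpha = 0.05, fc_cutoff = 2) {
  out <- data.frame(
    gene_id = gene_id,
    biotype = rep_len(biotype, length(gene_id)),
    region = region,
    mean_case = NA_real_, mean_ctrl = NA_real_,
    log2fc = lfc,
    p_value = rep_len(p, length(gene_id)),
    q_value = rep_len(p, length(gene_id)),
    direction = ifelse(lfc > 0, "up", "down"),
    significant = rep_len(p, length(gene_id)) <= alpha &
      abs(lfc) >= log2(fc_cutoff),
    stringsAsFactors = FALSE
  )
  attr(out, "region") <- region
  attr(out, "alpha") <- alpha
  attr(out, "fc_cutoff") <- fc_cutoff
  class(out) <- c("de_table", "data.frame")
  out
}

# enumeration oracle for the hypergeometric upper tail: counts, over all
# C(M, n) draws from a universe where genes 1..K are marked, the fraction
# with overlap >= k
hyper_tail_enum <- function(k, K, n, M) {
  if (k == 0) return(1)
  draws <- utils::combn(M, n)
  overlaps <- colSums(draws <= K)
  mean(overlaps >= k)
}

# independent step-up BH oracle
bh_oracle <- function(p) {
  m <- length(p)
  ord <- order(p)
  q_sorted <- rev(cummin(rev(p[ord] * m / seq_len(m))))
  q <- numeric(m)
  q[ord] <- pmin(q_sorted, 1)
  q
}
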