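# Hypergeometric over-representation analysis with BH correction.

#' Upper-tail hypergeometric probability
#'
#' `P(X >= k)` for `X ~ Hypergeometric(M, K, n)`: drawing `n` genes from a
#' background of `M` of which `K` belong to the set, the probability of
#' seeing `k` or more set members. This single statistic backs both the
#' annotation over-representation analysis and the shared-miRNA test of the
#' ceRNA module. By total probability, `P(X >= 0) = 1`.
#'
#' @param k Observed overlap (count).
#' @param K Set size within the background.
#' @param n Query size.
#' @param M Background size.
#' @return The upper-tail p-value.
#' @examples
#' hypergeom_tail(4, 5, 4, 10)  # 5/210
#' @export
hypergeom_tail <- function(k, K, n, M) {
  for (arg in list(k = k, K = K, n = n, M = M)) {
    if (!is_scalar_count(arg)) {
      stop_invalid("k, K, n, M must all be non-negative integers")
    }
  }
  if (K > M) stop_invalid("constraint violated: K <= M (K = ", K, ", M = ", M, ")")
  if (n > M) stop_invalid("constraint violated: n <= M (n = ", n, ", M = ", M, ")")
  if (k > min(n, K)) {
    stop_invalid("constraint violated: k <= min(n, K) (k = ", k, ")")
  }
  if (k == 0) return(1)
  phyper(k - 1, K, M - K, n, lower.tail = FALSE)
}

# vectorised internal form used by call_pairs; same quadrature as the scalar
hyper_tail_vec <- function(k, K, n, M) {
  p <- phyper(k - 1, K, M - K, n, lower.tail = FALSE)
  p[k == 0] <- 1
  p
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment with monotone enforcement; the
#' input order is preserved. Thin, validated wrapper around
#' [stats::p.adjust()].
#'
#' @param p_values Numeric vector of p-values in `[0, 1]` (`NA` passed
#'   through).
#' @return q-values in the input order.
#' @export
bh_adjust <- function(p_values) {
  if (!is.numeric(p_values)) stop_invalid("`p_values` must be numeric")
  bad <- !is.na(p_values) & (p_values < 0 | p_values > 1)
  if (any(bad)) {
    stop_invalid("p-values out of [0, 1]: ",
                 paste(head(p_values[bad], 5), collapse = ", "))
  }
  p.adjust(p_values, method = "BH")
}

#' Over-representation analysis of a gene list against a set collection
#'
#' For every set: the overlap `k` with the query, the set size `K` within the
#' background, and the upper-tail hypergeometric p-value of observing at
#' least `k` set members among `n` query genes drawn from `M` background
#' genes. Query genes outside the background are dropped (with a message
#' reporting how many). Results are sorted by p ascending; at most `top`
#' significant sets are flagged for display, matching the bar-chart
#' convention of showing up to ten terms at `p <= alpha` with
#' `-log10(p)` as the axis.
#'
#' @param query Character vector of genes of interest (e.g. significant DEGs).
#' @param background Character vector, the gene universe.
#' @param sets Named list of character vectors.
#' @param alpha Significance cutoff on the raw p-value.
#' @param top Maximum number of sets flagged `displayed`.
#' @return Data frame with columns `set_name`, `k`, `K`, `n`, `M`,
#'   `p_value`, `q_value`, `neg_log10_p`, `significant`, `displayed`.
#' @export
enrich <- function(query, background, sets, alpha = 0.05, top = 10) {
  if (length(background) == 0) stop_invalid("`background` is empty")
  if (is.null(names(sets))) stop_invalid("`sets` must be a named list")
  assert_scalar_prob(alpha, "alpha")
  background <- unique(background)
  query0 <- unique(query)
  query <- intersect(query0, background)
  dropped <- length(query0) - length(query)
  if (dropped > 0) {
    message(dropped, " query gene(s) outside the background were dropped")
  }
  M <- length(background)
  n <- length(query)
  res <- data.frame(
    set_name = names(sets),
    k = vapply(sets, function(s) length(intersect(query, s)), integer(1)),
    K = vapply(sets, function(s) length(intersect(background, s)), integer(1)),
    n = n, M = M,
    stringsAsFactors = FALSE, row.names = NULL
  )
  res$p_value <- hyper_tail_vec(res$k, res$K, res$n, res$M)
  res$q_value <- bh_adjust(res$p_value)
  res$neg_log10_p <- -log10(res$p_value)
  res <- res[order(res$p_value, res$set_name), , drop = FALSE]
  res$significant <- res$p_value <= alpha
  res$displayed <- res$significant & seq_len(nrow(res)) <= top
  rownames(res) <- NULL
  res
}
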