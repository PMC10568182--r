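# Differential expression by threshold filtering: fold change on group means
# of RPKM, Welch's unequal-variance t-test on log2(RPKM + pseudocount).

# Vectorised row-wise Welch t-test. `case`/`ctrl` are matrices with one row
# per gene (already log-transformed). Conventions for degenerate rows:
#   - fewer than 2 replicates in either group        -> p = NA
#   - both groups constant with equal means          -> p = 1
#   - both groups constant with different means      -> p = 0
row_welch_p <- function(case, ctrl) {
  n1 <- ncol(case); n2 <- ncol(ctrl)
  if (n1 < 2 || n2 < 2) return(rep(NA_real_, nrow(case)))
  m1 <- rowMeans(case); m2 <- rowMeans(ctrl)
  v1 <- rowSums((case - m1)^2) / (n1 - 1)
  v2 <- rowSums((ctrl - m2)^2) / (n2 - 1)
  se2 <- v1 / n1 + v2 / n2
  tt <- (m1 - m2) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  p <- 2 * pt(abs(tt), df, lower.tail = FALSE)
  zero <- se2 == 0
  p[zero] <- ifelse(m1[zero] == m2[zero], 1, 0)
  p
}

#' Fold change and Welch p-value for a single gene
#'
#' The workhorse statistic behind [call_de()]: the log2 fold change is taken
#' on pseudocounted group means of expression, and the p-value from Welch's
#' unequal-variance two-sample t-test on `log2(x + pseudocount)`.
#'
#' @param case_values,ctrl_values Numeric expression vectors (e.g. RPKM) for
#'   the injury and sham groups; at least one value each for the fold change,
#'   at least two each for a p-value (otherwise `p_value` is `NA`).
#' @param pseudocount Positive stabiliser added before ratios and logs.
#' @return List with `log2fc` and `p_value`.
#' @examples
#' test_gene(c(10, 12, 11), c(2, 2.5, 1.8))
#' @export
test_gene <- function(case_values, ctrl_values, pseudocount = 1) {
  if (!is.numeric(case_values) || !is.numeric(ctrl_values) ||
      length(case_values) < 1 || length(ctrl_values) < 1) {
    stop_invalid("both groups need at least one numeric value")
  }
  if (!is.numeric(pseudocount) || pseudocount <= 0) {
    stop_invalid("`pseudocount` must be positive")
  }
  log2fc <- log2((mean(case_values) + pseudocount) /
                 (mean(ctrl_values) + pseudocount))
  p <- row_welch_p(matrix(log2(case_values + pseudocount), 1),
                   matrix(log2(ctrl_values + pseudocount), 1))
  list(log2fc = log2fc, p_value = p[1])
}

#' Call differentially expressed genes in one region
#'
#' Applies the study's joint filter — `p <= alpha` and fold change
#' `>= fc_cutoff` in either direction (`|log2fc| >= log2(fc_cutoff)`) — to
#' every gene of an expression matrix, comparing injury (`CCI`) against
#' `sham` samples of one region. No multiple-testing correction enters the
#' filter itself (mirroring the raw-p convention of threshold DE pipelines);
#' Benjamini-Hochberg q-values are reported as an extra column.
#'
#' @param expr Expression table from [compute_rpkm()].
#' @param design Sample design; must contain both conditions in `region`.
#' @param region Region to test (`"TG"` or `"Sp5C"` in the standard design).
#' @param alpha P-value cutoff of the significance filter.
#' @param fc_cutoff Fold-change cutoff (on the natural scale; 2 means
#'   `|log2fc| >= 1`).
#' @param pseudocount Passed to the per-gene statistic.
#' @return A `de_table`: data frame with one row per gene (`gene_id`,
#'   `biotype`, `region`, `mean_case`, `mean_ctrl`, `log2fc`, `p_value`,
#'   `q_value`, `direction`, `significant`), thresholds recorded as
#'   attributes. Genes with fewer than two replicates per group get `NA`
#'   p-values and are never flagged significant.
#' @export
call_de <- function(expr, design, region, alpha = 0.05, fc_cutoff = 2,
                    pseudocount = 1) {
  validate_design(design)
  assert_scalar_prob(alpha, "alpha")
  if (!is.numeric(fc_cutoff) || fc_cutoff < 1) {
    stop_invalid("`fc_cutoff` must be >= 1")
  }
  if (!region %in% design$region) {
    stop_invalid("region `", region, "` not present in the design")
  }
  sub <- design[design$region == region, , drop = FALSE]
  case_ids <- sub$sample_id[sub$condition == "CCI"]
  ctrl_ids <- sub$sample_id[sub$condition == "sham"]
  if (length(case_ids) == 0 || length(ctrl_ids) == 0) {
    stop_invalid("region `", region, "` lacks one of the conditions CCI/sham")
  }
  missing_cols <- setdiff(c(case_ids, ctrl_ids), names(expr))
  if (length(missing_cols)) {
    stop_invalid("expression table lacks sample column(s): ",
                 paste(missing_cols, collapse = ", "))
  }
  m <- expr_values(expr)
  case <- m[, case_ids, drop = FALSE]
  ctrl <- m[, ctrl_ids, drop = FALSE]

  mean_case <- rowMeans(case)
  mean_ctrl <- rowMeans(ctrl)
  log2fc <- log2((mean_case + pseudocount) / (mean_ctrl + pseudocount))
  p <- row_welch_p(log2(case + pseudocount), log2(ctrl + pseudocount))
  q <- p.adjust(p, method = "BH")

  out <- data.frame(
    gene_id = expr$gene_id,
    biotype = if ("biotype" %in% names(expr)) expr$biotype else NA_character_,
    region = region,
    mean_case = mean_case,
    mean_ctrl = mean_ctrl,
    log2fc = log2fc,
    p_value = p,
    q_value = q,
    direction = ifelse(log2fc > 0, "up", "down"),
    significant = !is.na(p) & p <= alpha & abs(log2fc) >= log2(fc_cutoff),
    stringsAsFactors = FALSE,
    row.names = NULL
  )
  attr(out, "region") <- region
  attr(out, "alpha") <- alpha
  attr(out, "fc_cutoff") <- fc_cutoff
  attr(out, "pseudocount") <- pseudocount
  class(out) <- c("de_table", "data.frame")
  out
}

#' Summarise a DE table by biotype and direction
#'
#' @param de A `de_table` from [call_de()].
#' @return Data frame with significant gene counts per biotype, split by
#'   direction.
#' @export
de_counts <- function(de) {
  sig <- de[de$significant, , drop = FALSE]
  bts <- unique(de$biotype)
  data.frame(
    region = attr(de, "region") %||% unique(de$region),
    biotype = bts,
    up = vapply(bts, function(b)
      sum(sig$biotype == b & sig$direction == "up"), integer(1)),
    down = vapply(bts, function(b)
      sum(sig$biotype == b & sig$direction == "down"), integer(1)),
    total = vapply(bts, function(b) sum(sig$biotype == b), integer(1)),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
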