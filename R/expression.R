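#' RPKM normalisation
#'
#' Converts a gene-level count table to reads per kilobase of transcript per
#' million mapped reads:
#' \deqn{RPKM(g, s) = 10^9 \, C(g,s) / (N_s \, L_g)}
#' where `C(g,s)` is the count, `N_s` the per-sample total (column sum of the
#' supplied matrix) and `L_g` the gene length in bases. Using the column sum
#' as `N_s` makes the computation self-contained: the original aligner's
#' mapped-read total is not needed and row order is irrelevant.
#'
#' With `by_biotype = TRUE` the library size `N_s` is computed within each
#' biotype panel instead of globally. miRNA genes are length-normalised like
#' every other row; this is biologically meaningless for such short species
#' but keeps the transform uniform, and is documented rather than
#' special-cased.
#'
#' @param counts Count table (`gene_id`, `biotype`, `length_bp`, one column
#'   per sample).
#' @param by_biotype Compute per-sample totals within biotype panels.
#' @return A data frame of the same shape with counts replaced by RPKM.
#'   `rpkm == 0` exactly where `count == 0`.
#' @examples
#' d <- data.frame(gene_id = c("a", "b"), biotype = "mRNA",
#'                 length_bp = c(1000L, 500L), s1 = c(10L, 90L))
#' compute_rpkm(d)
#' @export
compute_rpkm <- function(counts, by_biotype = FALSE) {
  validate_counts(counts)
  m <- expr_values(counts)
  rpkm <- matrix(0, nrow(m), ncol(m), dimnames = dimnames(m))
  groups <- if (by_biotype) split(seq_len(nrow(m)), counts$biotype) else
    list(all = seq_len(nrow(m)))
  for (rows in groups) {
    n_s <- colSums(m[rows, , drop = FALSE])
    if (any(n_s == 0)) {
      stop_invalid("zero total count in sample(s): ",
                   paste(colnames(m)[n_s == 0], collapse = ", "))
    }
    rpkm[rows, ] <- 1e9 * m[rows, , drop = FALSE] /
      outer(counts$length_bp[rows], n_s)
  }
  out <- counts
  out[, sample_columns(counts)] <- rpkm
  out
}

#' qPCR relative expression ratio (2^-ddCt)
#'
#' Computes the relative expression ratio of a target transcript between a
#' case and a control group from quantitation-cycle (Ct) values, normalising
#' both to a housekeeping reference (e.g. GAPDH):
#' \deqn{2^{-[(Ct_{t,case} - Ct_{r,case}) - (Ct_{t,ctrl} - Ct_{r,ctrl})]}}
#'
#' @param ct_target_case,ct_ref_case Ct of the target and reference gene in
#'   the case sample.
#' @param ct_target_ctrl,ct_ref_ctrl Ct of the target and reference gene in
#'   the control sample.
#' @return The fold-change ratio (positive real); vectorised over its inputs.
#' @examples
#' ddct_ratio(20, 18, 22, 18)  # 4: two cycles earlier relative to control
#' @export
ddct_ratio <- function(ct_target_case, ct_ref_case,
                       ct_target_ctrl, ct_ref_ctrl) {
  vals <- cbind(ct_target_case, ct_ref_case, ct_target_ctrl, ct_ref_ctrl)
  if (!is.numeric(vals) || any(!is.finite(vals))) {
    stop_invalid("all Ct values must be finite numbers")
  }
  ddct <- (ct_target_case - ct_ref_case) - (ct_target_ctrl - ct_ref_ctrl)
  2^(-ddct)
}
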