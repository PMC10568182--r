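# ceRNA (miRNA-sponge) inference: shared-miRNA hypergeometric statistic,
# expression correlation, direction concordance, and tripartite networks.

target_sets <- function(targets) {
  if (!is.data.frame(targets) ||
      !all(c("mirna_id", "target_id") %in% names(targets))) {
    stop_invalid("`targets` must have columns mirna_id, target_id")
  }
  split(targets$mirna_id, targets$target_id)
}

#' miRNAs shared by a candidate ceRNA/mRNA pair
#'
#' @param targets Target map data frame (`mirna_id`, `target_id`, ...).
#' @param cerna_id,mrna_id The two transcripts.
#' @return List with `mirnas` (sorted ids targeting both) and `k_shared`.
#' @export
shared_mirnas <- function(targets, cerna_id, mrna_id) {
  sets <- target_sets(targets)
  shared <- sort(intersect(sets[[cerna_id]], sets[[mrna_id]]))
  list(mirnas = shared, k_shared = length(shared))
}

#' Pearson correlation with a t-based p-value
#'
#' Sample Pearson product-moment correlation between two expression profiles
#' and the two-sided p-value of \eqn{t = r \sqrt{(n-2)/(1-r^2)}} against the
#' t distribution with `n - 2` degrees of freedom. Perfectly collinear input
#' returns `p = 0`.
#'
#' @param x,y Numeric vectors of equal length `>= 3` with non-zero variance.
#' @return List with `r` and `p_value`.
#' @examples
#' pearson_with_p(1:5, c(2, 1, 4, 3, 6))
#' @export
pearson_with_p <- function(x, y) {
  if (length(x) != length(y)) stop_invalid("`x` and `y` must have equal length")
  n <- length(x)
  if (n < 3) stop_invalid("need at least 3 paired observations")
  if (any(!is.finite(x)) || any(!is.finite(y))) {
    stop_invalid("inputs must be finite")
  }
  dx <- x - mean(x)
  dy <- y - mean(y)
  sxx <- sum(dx^2); syy <- sum(dy^2)
  if (sxx == 0 || syy == 0) {
    stop_invalid("zero variance: correlation undefined")
  }
  r <- sum(dx * dy) / sqrt(sxx * syy)
  r <- max(-1, min(1, r))
  p <- if (abs(r) >= 1 - 1e-15) {
    0
  } else {
    tt <- r * sqrt((n - 2) / (1 - r^2))
    2 * pt(abs(tt), n - 2, lower.tail = FALSE)
  }
  list(r = r, p_value = p)
}

# vectorised two-sided p for a matrix of correlations
cor_p_vec <- function(r, n) {
  p <- rep(0, length(r))
  ok <- abs(r) < 1 - 1e-15
  tt <- r[ok] * sqrt((n - 2) / (1 - r[ok]^2))
  p[ok] <- 2 * pt(abs(tt), n - 2, lower.tail = FALSE)
  p
}

#' Call candidate ceRNA pairs in one region
#'
#' For every pair of a significant ceRNA (lncRNA or circRNA) and a
#' significant mRNA that share at least one miRNA in the target map, computes:
#'
#' * `k_shared`, the number of shared miRNAs, with the upper-tail
#'   hypergeometric p-value of that overlap, where `K` miRNAs target the
#'   ceRNA, `n` target the mRNA, and the population `M` is the number of
#'   distinct miRNAs in the map (overridable via `mirna_universe`);
#' * the Pearson correlation (`ppc`) of `log2(expression + pseudocount)`
#'   across all samples of the region, conditions pooled, with its t-based
#'   p-value;
#' * direction concordance (both transcripts regulated the same way).
#'
#' A pair passes when `hypergeom_p <= hyper_alpha`, `ppc >= ppc_min`,
#' `ppc_p <= ppc_alpha` and the directions are concordant. When the region
#' has fewer than 3 samples no correlation can be estimated; the workflow
#' degrades to the hypergeometric-plus-concordance rule and `ppc` is `NA`
#' (the two-group-without-replicates branch). Candidate genes whose
#' expression has zero variance are skipped with a message.
#'
#' @param de The region's `de_table`.
#' @param expr Expression table covering the region's samples.
#' @param design Sample design.
#' @param region Region whose samples are used for the correlation.
#' @param targets Target map (`mirna_id`, `target_id`, ...).
#' @param hyper_alpha,ppc_min,ppc_alpha Pass thresholds.
#' @param pseudocount Added before the log transform of expression.
#' @param cerna_biotypes Biotypes eligible as sponges.
#' @param de_mirnas Optional character vector restricting the map to
#'   differentially expressed miRNAs before pairing (the small-RNA
#'   measurement is often unavailable, so this filter is opt-in).
#' @param mirna_universe Optional integer overriding the hypergeometric
#'   population size `M` (must be at least the number of distinct miRNAs in
#'   the map).
#' @return A `cerna_pairs` data frame, one row per candidate pair, sorted by
#'   (`cerna_id`, `mrna_id`): ids, biotype, `k_shared`, `K`, `n`, `M`,
#'   `hypergeom_p`, `ppc`, `ppc_p`, directions, `concordant`, `passes`,
#'   `shared_mirnas` (semicolon-joined). Thresholds and the degenerate-mode
#'   flag are attributes.
#' @export
call_pairs <- function(de, expr, design, region, targets,
                       hyper_alpha = 0.05, ppc_min = 0.5, ppc_alpha = 0.05,
                       pseudocount = 1,
                       cerna_biotypes = c("lncRNA", "circRNA"),
                       de_mirnas = NULL, mirna_universe = NULL) {
  if (!is.data.frame(targets) || nrow(targets) == 0) {
    stop_invalid("`targets` is empty: no miRNA-target interactions to test")
  }
  assert_scalar_prob(hyper_alpha, "hyper_alpha")
  assert_scalar_prob(ppc_alpha, "ppc_alpha")
  validate_design(design)
  if (!is.null(de_mirnas)) {
    targets <- targets[targets$mirna_id %in% de_mirnas, , drop = FALSE]
  }
  mirnas <- sort(unique(targets$mirna_id))
  M <- if (is.null(mirna_universe)) length(mirnas) else mirna_universe
  if (M < length(mirnas)) {
    stop_invalid("`mirna_universe` smaller than the number of distinct miRNAs")
  }

  sig <- de[de$significant, , drop = FALSE]
  targeted <- unique(targets$target_id)
  cernas <- sort(sig$gene_id[sig$biotype %in% cerna_biotypes &
                               sig$gene_id %in% targeted])
  mrnas <- sort(sig$gene_id[sig$biotype == "mRNA" & sig$gene_id %in% targeted])

  empty <- data.frame(
    cerna_id = character(), cerna_biotype = character(),
    mrna_id = character(), k_shared = integer(), K = integer(),
    n = integer(), M = integer(), hypergeom_p = numeric(), ppc = numeric(),
    ppc_p = numeric(), cerna_direction = character(),
    mrna_direction = character(), concordant = logical(),
    passes = logical(), shared_mirnas = character(),
    stringsAsFactors = FALSE
  )
  finish <- function(out, degenerate) {
    attr(out, "region") <- region
    attr(out, "thresholds") <- list(hyper_alpha = hyper_alpha,
                                    ppc_min = ppc_min, ppc_alpha = ppc_alpha)
    attr(out, "degenerate") <- degenerate
    class(out) <- c("cerna_pairs", "data.frame")
    out
  }
  if (length(cernas) == 0 || length(mrnas) == 0 || length(mirnas) == 0) {
    return(finish(empty, FALSE))
  }

  genes <- c(cernas, mrnas)
  A <- matrix(0L, length(genes), length(mirnas),
              dimnames = list(genes, mirnas))
  hit <- targets[targets$target_id %in% genes, , drop = FALSE]
  A[cbind(match(hit$target_id, genes), match(hit$mirna_id, mirnas))] <- 1L
  Ac <- A[cernas, , drop = FALSE]
  Am <- A[mrnas, , drop = FALSE]
  k_mat <- Ac %*% t(Am)
  Kv <- rowSums(Ac)
  nv <- rowSums(Am)

  idx <- which(k_mat >= 1, arr.ind = TRUE)
  if (nrow(idx) == 0) return(finish(empty, FALSE))
  ci <- idx[, 1]; mi <- idx[, 2]

  samples <- design$sample_id[design$region == region]
  samples <- intersect(samples, names(expr))
  degenerate <- length(samples) < 3

  X <- log2(expr_values(expr)[, samples, drop = FALSE] + pseudocount)
  missing_genes <- setdiff(genes, rownames(X))
  if (length(missing_genes)) {
    stop_invalid("expression table lacks candidate gene(s): ",
                 paste(head(missing_genes, 5), collapse = ", "))
  }

  ppc <- rep(NA_real_, nrow(idx))
  ppc_p <- rep(NA_real_, nrow(idx))
  drop_pair <- rep(FALSE, nrow(idx))
  if (!degenerate) {
    ns <- length(samples)
    sds <- apply(X[genes, , drop = FALSE], 1, function(v) sd(v))
    flat <- names(sds)[sds == 0]
    if (length(flat)) {
      drop_pair <- cernas[ci] %in% flat | mrnas[mi] %in% flat
      message(sum(drop_pair), " candidate pair(s) skipped: ",
              "zero expression variance in ", length(flat), " gene(s)")
    }
    Z <- X[genes, , drop = FALSE]
    Z <- (Z - rowMeans(Z)) / ifelse(sds == 0, 1, sds)
    R <- tcrossprod(Z[cernas, , drop = FALSE],
                    Z[mrnas, , drop = FALSE]) / (ns - 1)
    R <- pmax(pmin(R, 1), -1)
    ppc <- R[cbind(ci, mi)]
    ppc_p <- cor_p_vec(ppc, ns)
  }

  dir_of <- setNames(sig$direction, sig$gene_id)
  bt_of <- setNames(sig$biotype, sig$gene_id)
  kv <- k_mat[cbind(ci, mi)]
  shared_str <- vapply(seq_along(ci), function(i) {
    paste(mirnas[Ac[ci[i], ] == 1L & Am[mi[i], ] == 1L], collapse = ";")
  }, character(1))

  out <- data.frame(
    cerna_id = cernas[ci],
    cerna_biotype = unname(bt_of[cernas[ci]]),
    mrna_id = mrnas[mi],
    k_shared = as.integer(kv),
    K = as.integer(Kv[ci]),
    n = as.integer(nv[mi]),
    M = as.integer(M),
    hypergeom_p = hyper_tail_vec(kv, Kv[ci], nv[mi], M),
    ppc = ppc,
    ppc_p = ppc_p,
    cerna_direction = unname(dir_of[cernas[ci]]),
    mrna_direction = unname(dir_of[mrnas[mi]]),
    stringsAsFactors = FALSE
  )
  out$concordant <- out$cerna_direction == out$mrna_direction
  corr_ok <- if (degenerate) {
    TRUE
  } else {
    !is.na(out$ppc) & out$ppc >= ppc_min & out$ppc_p <= ppc_alpha
  }
  out$passes <- out$hypergeom_p <= hyper_alpha & out$concordant & corr_ok
  out$shared_mirnas <- shared_str
  out <- out[!drop_pair, , drop = FALSE]
  out <- out[order(out$cerna_id, out$mrna_id), , drop = FALSE]
  rownames(out) <- NULL
  finish(out, degenerate)
}

#' Assemble the ceRNA network from passing pairs
#'
#' Node degrees: a ceRNA's degree is its number of distinct passing mRNA
#' partners (and symmetrically for mRNAs); a miRNA's degree is the number of
#' passing pairs it mediates. Top lists are ranked by degree descending with
#' ties broken by the node's best (smallest) hypergeometric p across its
#' pairs, then by id. Produces the tripartite edge tables (miRNA-ceRNA,
#' miRNA-mRNA, plus the ceRNA-mRNA evidence edges).
#'
#' @param pairs A `cerna_pairs` table (only rows with `passes` are used).
#' @param top_cerna,top_mirna Sizes of the display top lists.
#' @return A `cerna_network`: list with `nodes`, `edges` (list of the three
#'   tables), `top_cernas`, `top_mirnas`.
#' @export
build_network <- function(pairs, top_cerna = 10, top_mirna = 2) {
  pass <- pairs[pairs$passes, , drop = FALSE]
  shared_list <- strsplit(pass$shared_mirnas, ";", fixed = TRUE)

  node_block <- function(ids, type, deg, best_p) {
    data.frame(id = as.character(ids), type = rep_len(type, length(ids)),
               degree = as.integer(deg), best_p = as.numeric(best_p),
               stringsAsFactors = FALSE)
  }
  agg_min <- function(values, by) {
    if (length(values) == 0) return(numeric(0))
    vapply(split(values, by), min, numeric(1))
  }

  cerna_deg <- table(pass$cerna_id)
  mrna_deg <- table(pass$mrna_id)
  cerna_p <- agg_min(pass$hypergeom_p, pass$cerna_id)
  mrna_p <- agg_min(pass$hypergeom_p, pass$mrna_id)
  mir_ids <- as.character(unlist(shared_list))
  mir_pair_p <- rep(pass$hypergeom_p, lengths(shared_list))
  mir_deg <- table(mir_ids)
  mir_p <- agg_min(mir_pair_p, mir_ids)

  nodes <- rbind(
    node_block(names(cerna_deg), "ceRNA", as.vector(cerna_deg),
               cerna_p[names(cerna_deg)]),
    node_block(names(mrna_deg), "mRNA", as.vector(mrna_deg),
               mrna_p[names(mrna_deg)]),
    node_block(names(mir_deg), "miRNA", as.vector(mir_deg),
               mir_p[names(mir_deg)])
  )
  nodes <- nodes[order(nodes$type, nodes$id), , drop = FALSE]
  rownames(nodes) <- NULL

  top_of <- function(type, k) {
    nd <- nodes[nodes$type == type, , drop = FALSE]
    nd <- nd[order(-nd$degree, nd$best_p, nd$id), , drop = FALSE]
    nd <- head(nd, k)
    rownames(nd) <- NULL
    nd
  }

  mir_cerna <- unique(data.frame(
    mirna_id = mir_ids,
    partner_id = rep(pass$cerna_id, lengths(shared_list)),
    stringsAsFactors = FALSE))
  mir_mrna <- unique(data.frame(
    mirna_id = mir_ids,
    partner_id = rep(pass$mrna_id, lengths(shared_list)),
    stringsAsFactors = FALSE))
  sort_edges <- function(e) {
    e <- e[order(e[[1]], e[[2]]), , drop = FALSE]
    rownames(e) <- NULL
    e
  }

  structure(list(
    nodes = nodes,
    edges = list(
      cerna_mrna = pass[, c("cerna_id", "mrna_id", "k_shared", "hypergeom_p",
                            "ppc", "ppc_p")],
      mirna_cerna = sort_edges(mir_cerna),
      mirna_mrna = sort_edges(mir_mrna)
    ),
    top_cernas = top_of("ceRNA", top_cerna),
    top_mirnas = top_of("miRNA", top_mirna)
  ), class = "cerna_network")
}
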