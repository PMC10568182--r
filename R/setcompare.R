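# Cross-region Venn accounting, disease-category mapping, top-k class tables.

sig_ids <- function(de, direction = NULL, biotype = NULL) {
  keep <- de$significant
  if (!is.null(direction)) keep <- keep & de$direction == direction
  if (!is.null(biotype)) keep <- keep & de$biotype %in% biotype
  de$gene_id[keep]
}

#' Cross-region co-expression overlap
#'
#' Venn accounting of significant genes between two regions' DE tables, per
#' biotype and per direction: co-upregulated genes (`up(A)` \eqn{\cap}
#' `up(B)`), co-downregulated genes, and the exclusive counts on either side.
#'
#' @param de_a,de_b `de_table`s for the two regions (shared gene universe).
#' @return Data frame with one row per (biotype, direction): columns
#'   `co_expressed`, `a_only`, `b_only` (partition counts summing to the
#'   union) plus the region labels. The member gene ids of every partition
#'   are attached as attribute `"members"`.
#' @export
co_expression_overlap <- function(de_a, de_b) {
  region_a <- attr(de_a, "region") %||% unique(de_a$region)
  region_b <- attr(de_b, "region") %||% unique(de_b$region)
  bts <- sort(unique(c(de_a$biotype, de_b$biotype)))
  rows <- list()
  members <- list()
  for (bt in bts) {
    for (dir in c("up", "down")) {
      a <- sig_ids(de_a, dir, bt)
      b <- sig_ids(de_b, dir, bt)
      both <- intersect(a, b)
      key <- paste(bt, dir, sep = ".")
      members[[key]] <- list(co_expressed = sort(both),
                             a_only = sort(setdiff(a, b)),
                             b_only = sort(setdiff(b, a)))
      rows[[key]] <- data.frame(
        biotype = bt, direction = dir,
        region_a = region_a, region_b = region_b,
        co_expressed = length(both),
        a_only = length(setdiff(a, b)),
        b_only = length(setdiff(b, a)),
        stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "members") <- members
  out
}

#' Map significant DEGs to disease categories
#'
#' For each named category set: the number of significant DEGs falling in the
#' set and that count as a percentage of all significant DEGs of the table
#' (optionally restricted to one biotype for the denominator and the query).
#' For each requested tuple of categories: the size of the intersection of
#' the DEG set with all the named category sets at once.
#'
#' @param de A `de_table`.
#' @param categories Named list of character vectors (e.g. from
#'   [generate_gene_sets()] or [read_gmt()]).
#' @param tuples Optional list of character vectors, each naming >= 2
#'   categories whose joint intersection with the DEGs is counted.
#' @param biotype Optional biotype restriction (e.g. `"mRNA"`) applied to the
#'   significant set before mapping.
#' @return List with data frames `categories` (`category`, `n_overlap`,
#'   `n_deg`, `percent`) and `tuples` (`tuple`, `n_intersection`); member ids
#'   attached to each as attribute `"members"`.
#' @export
map_to_categories <- function(de, categories, tuples = NULL, biotype = NULL) {
  if (is.null(names(categories))) stop_invalid("`categories` must be named")
  wanted <- unique(c(unlist(tuples), character()))
  unknown <- setdiff(wanted, names(categories))
  if (length(unknown)) {
    stop_invalid("unknown category name(s): ",
                 paste(unknown, collapse = ", "),
                 "; available: ", paste(names(categories), collapse = ", "))
  }
  deg <- unique(sig_ids(de, biotype = biotype))
  n_deg <- length(deg)

  cat_tab <- data.frame(
    category = names(categories),
    n_overlap = vapply(categories, function(s)
      length(intersect(deg, s)), integer(1)),
    n_deg = n_deg,
    stringsAsFactors = FALSE, row.names = NULL
  )
  cat_tab$percent <- if (n_deg > 0) 100 * cat_tab$n_overlap / n_deg else 0
  attr(cat_tab, "members") <- lapply(categories, function(s)
    sort(intersect(deg, s)))

  tup_tab <- data.frame(tuple = character(), n_intersection = integer(),
                        stringsAsFactors = FALSE)
  tup_members <- list()
  for (tp in tuples) {
    inter <- deg
    for (nm in tp) inter <- intersect(inter, categories[[nm]])
    key <- paste(tp, collapse = "+")
    tup_tab <- rbind(tup_tab, data.frame(tuple = key,
                                         n_intersection = length(inter),
                                         stringsAsFactors = FALSE))
    tup_members[[key]] <- sort(inter)
  }
  attr(tup_tab, "members") <- tup_members
  list(categories = cat_tab, tuples = tup_tab)
}

#' Top-k up- and downregulated genes within a gene class
#'
#' Ranks the significant genes of a class (e.g. G-protein-coupled receptors,
#' ion channels, pain genes) by `|log2fc|` descending within each direction
#' and returns up to `k` of each. Ties are broken by smaller p-value, then
#' lexicographic gene id.
#'
#' @param de A `de_table`.
#' @param class_set Character vector of gene ids defining the class.
#' @param k Maximum genes per direction.
#' @return Data frame of ranked rows (`direction`, `rank`, then the DE
#'   columns). If a direction holds fewer than `k` significant class genes,
#'   all are returned and attribute `"short"` flags it.
#' @export
top_k_by_class <- function(de, class_set, k = 15) {
  if (!is_scalar_count(k, positive = TRUE)) {
    stop_invalid("`k` must be a positive integer")
  }
  sig <- de[de$significant & de$gene_id %in% class_set, , drop = FALSE]
  short <- c(up = FALSE, down = FALSE)
  pick <- function(dir) {
    d <- sig[sig$direction == dir, , drop = FALSE]
    d <- d[order(-abs(d$log2fc), d$p_value, d$gene_id), , drop = FALSE]
    short[dir] <<- nrow(d) < k
    d <- head(d, k)
    if (nrow(d)) cbind(data.frame(rank = seq_len(nrow(d))), d) else NULL
  }
  out <- rbind(pick("up"), pick("down"))
  if (is.null(out)) {
    out <- cbind(data.frame(rank = integer()),
                 as.data.frame(de)[0, , drop = FALSE])
  }
  rownames(out) <- NULL
  attr(out, "short") <- short
  out
}
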