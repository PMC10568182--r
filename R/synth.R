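#' Generate a two-region, two-condition sample design
#'
#' Builds the sample sheet for a study with two tissue regions (trigeminal
#' ganglion `TG` and spinal trigeminal subnucleus caudalis `Sp5C`), each
#' profiled under nerve injury (`CCI`) and `sham` surgery with a fixed number
#' of replicate libraries per cell.
#'
#' The design is fully determined by `replicates_per_cell`; `seed` is accepted
#' for interface symmetry with the other generators but no random draws are
#' made.
#'
#' @param replicates_per_cell Number of replicate samples in every
#'   region-by-condition cell (positive integer).
#' @param seed Unused; present so all generators share a `(params, seed)`
#'   calling convention.
#' @return A data frame with columns `sample_id`, `region`, `condition`,
#'   `replicate`; one row per sample, `2 * 2 * replicates_per_cell` rows total.
#' @examples
#' generate_design(3)
#' @export
generate_design <- function(replicates_per_cell, seed = 1L) {
  if (!is_scalar_count(replicates_per_cell, positive = TRUE)) {
    stop_invalid("`replicates_per_cell` must be a positive integer")
  }
  grid <- expand.grid(replicate = seq_len(replicates_per_cell),
                      condition = CONDITIONS,
                      region = REGIONS,
                      stringsAsFactors = FALSE,
                      KEEP.OUT.ATTRS = FALSE)
  data.frame(
    sample_id = sprintf("%s_%s_%d", grid$region, grid$condition, grid$replicate),
    region = grid$region,
    condition = grid$condition,
    replicate = grid$replicate,
    stringsAsFactors = FALSE
  )
}

#' Simulate a gene-level count matrix with planted differential expression
#'
#' Draws negative-binomial counts for a mix of mRNA, lncRNA, circRNA and miRNA
#' genes over the samples of a two-region design. Per-gene baseline means are
#' log-normal; planted differentially expressed (DE) genes have their
#' injury/sham condition means split symmetrically so that the expected
#' condition-mean ratio in the planted region is `2^de_log2fc`. Optionally
#' plants ceRNA triplets (miRNA, ceRNA, mRNA) whose ceRNA and mRNA share a
#' latent log-scale factor scaled to a target Pearson correlation and are
#' concordantly regulated in the triplet's region.
#'
#' Gene lengths are sampled uniformly from `length_range` and recorded; miRNA
#' genes are generated like any other biotype (their counts live in the same
#' matrix even though no small-RNA protocol is being modelled — a provenance
#' gap inherited from the study design this emulates, flagged here rather than
#' hidden).
#'
#' @param design Sample design from [generate_design()].
#' @param n_per_biotype Named integer vector giving the number of genes per
#'   biotype (`mRNA`, `lncRNA`, `circRNA`, `miRNA`).
#' @param n_de Number of planted DE genes (drawn from the non-miRNA biotypes,
#'   split across regions and up/down directions).
#' @param de_log2fc Absolute planted log2 fold change for DE genes (must give
#'   fold change >= 2, i.e. `de_log2fc >= 1`).
#' @param dispersion Negative-binomial dispersion (`size = 1/dispersion`).
#' @param n_triplets Number of planted ceRNA triplets (0 for none). ceRNA
#'   biotypes alternate between lncRNA and circRNA.
#' @param triplet_log2fc Absolute planted log2 fold change for triplet ceRNA
#'   and mRNA genes (concordant within a triplet).
#' @param triplet_r Target Pearson correlation between a triplet's ceRNA and
#'   mRNA log expression (in `[-1, 1]`; sign respected).
#' @param triplet_region Region in which triplets are planted.
#' @param triplet_latent_sd Log2-scale standard deviation of the shared latent
#'   factor driving triplet co-expression.
#' @param length_range Two-element range (bases) for gene length sampling.
#' @param baseline_meanlog,baseline_sdlog Parameters of the log-normal
#'   baseline mean distribution.
#' @param seed Integer seed; fixed seed gives bit-identical output.
#' @return A list with elements `counts` (data frame: `gene_id`, `biotype`,
#'   `length_bp`, then one column per sample) and `truth` (list with
#'   `de_genes` and `triplets` data frames recording the planted ground truth).
#' @export
generate_counts <- function(design,
                            n_per_biotype = c(mRNA = 600, lncRNA = 200,
                                              circRNA = 200, miRNA = 120),
                            n_de = 0,
                            de_log2fc = 2,
                            dispersion = 0.1,
                            n_triplets = 0,
                            triplet_log2fc = 3,
                            triplet_r = 0.8,
                            triplet_region = "TG",
                            triplet_latent_sd = 1.2,
                            length_range = c(200, 10000),
                            baseline_meanlog = log(200),
                            baseline_sdlog = 1,
                            seed = 1L) {
  validate_design(design)
  if (is.null(names(n_per_biotype)) || !all(names(n_per_biotype) %in% BIOTYPES)) {
    stop_invalid("`n_per_biotype` must be named with biotypes among: ",
                 paste(BIOTYPES, collapse = ", "))
  }
  if (!is_scalar_count(n_de)) stop_invalid("`n_de` must be a non-negative integer")
  if (!is.numeric(dispersion) || dispersion <= 0) {
    stop_invalid("`dispersion` must be > 0")
  }
  if (n_de > 0 && abs(de_log2fc) < 1) {
    stop_invalid("planted |log2FC| must be >= 1 (fold change >= 2)")
  }
  if (!is_scalar_count(n_triplets)) stop_invalid("`n_triplets` must be a count")
  if (n_triplets > 0) {
    if (abs(triplet_r) > 1) stop_invalid("`triplet_r` must be in [-1, 1]")
    if (abs(triplet_log2fc) < 1) {
      stop_invalid("planted triplet |log2FC| must be >= 1")
    }
    if (!triplet_region %in% design$region) {
      stop_invalid("`triplet_region` not present in the design")
    }
  }

  gene_tab <- do.call(rbind, lapply(names(n_per_biotype), function(bt) {
    n <- n_per_biotype[[bt]]
    if (n == 0) return(NULL)
    data.frame(gene_id = sprintf("%s_%05d", bt, seq_len(n)),
               biotype = bt, stringsAsFactors = FALSE)
  }))
  n_genes <- nrow(gene_tab)
  non_mirna <- gene_tab$gene_id[gene_tab$biotype != "miRNA"]
  if (n_de > length(non_mirna)) {
    stop_invalid("`n_de` (", n_de, ") exceeds the number of non-miRNA genes (",
                 length(non_mirna), ")")
  }

  with_fixed_seed(substream_seed(seed, 2L), {
    samples <- design$sample_id
    n_samp <- length(samples)

    length_bp <- sample_from(seq(length_range[1], length_range[2]), n_genes)
    base_mu <- rlnorm(n_genes, meanlog = baseline_meanlog, sdlog = baseline_sdlog)
    names(base_mu) <- gene_tab$gene_id

    # --- planted DE genes -------------------------------------------------
    de_ids <- sample_from(non_mirna, n_de)
    de_plan <- data.frame(
      gene_id = de_ids,
      region = rep_len(REGIONS, n_de),
      log2fc = rep_len(c(1, -1), n_de) * abs(de_log2fc),
      stringsAsFactors = FALSE
    )[seq_len(n_de), , drop = FALSE]

    # --- planted ceRNA triplets ------------------------------------------
    triplets <- data.frame(mirna_id = character(), cerna_id = character(),
                           mrna_id = character(), region = character(),
                           r = numeric(), log2fc = numeric(),
                           stringsAsFactors = FALSE)
    if (n_triplets > 0) {
      lnc_pool <- setdiff(gene_tab$gene_id[gene_tab$biotype == "lncRNA"], de_ids)
      circ_pool <- setdiff(gene_tab$gene_id[gene_tab$biotype == "circRNA"], de_ids)
      mrna_pool <- setdiff(gene_tab$gene_id[gene_tab$biotype == "mRNA"], de_ids)
      mirna_pool <- gene_tab$gene_id[gene_tab$biotype == "miRNA"]
      n_lnc <- ceiling(n_triplets / 2)
      n_circ <- n_triplets - n_lnc
      if (length(lnc_pool) < n_lnc || length(circ_pool) < n_circ ||
          length(mrna_pool) < n_triplets || length(mirna_pool) < n_triplets) {
        stop_invalid("not enough free genes to plant ", n_triplets, " triplets")
      }
      cerna_ids <- character(n_triplets)
      cerna_ids[seq_len(n_triplets) %% 2 == 1] <- sample_from(lnc_pool, n_lnc)
      cerna_ids[seq_len(n_triplets) %% 2 == 0] <- sample_from(circ_pool, n_circ)
      triplets <- data.frame(
        mirna_id = sample_from(mirna_pool, n_triplets),
        cerna_id = cerna_ids,
        mrna_id = sample_from(mrna_pool, n_triplets),
        region = triplet_region,
        r = triplet_r,
        log2fc = sample_from(c(1, -1), 1) * rep_len(c(1, -1), n_triplets) *
          abs(triplet_log2fc),
        stringsAsFactors = FALSE
      )
      # triplet genes are DE (concordantly) in their region, on a solid
      # baseline so the sponge axis is not drowned by shot noise
      base_mu[triplets$cerna_id] <- rlnorm(n_triplets, log(500), 0.5)
      base_mu[triplets$mrna_id] <- rlnorm(n_triplets, log(500), 0.5)
      de_plan <- rbind(de_plan,
                       data.frame(gene_id = triplets$cerna_id,
                                  region = triplet_region,
                                  log2fc = triplets$log2fc,
                                  stringsAsFactors = FALSE),
                       data.frame(gene_id = triplets$mrna_id,
                                  region = triplet_region,
                                  log2fc = triplets$log2fc,
                                  stringsAsFactors = FALSE))
    }

    # --- expected log2 means ---------------------------------------------
    log2_mu <- matrix(log2(base_mu), nrow = n_genes, ncol = n_samp,
                      dimnames = list(gene_tab$gene_id, samples))
    if (nrow(de_plan)) {
      for (i in seq_len(nrow(de_plan))) {
        g <- de_plan$gene_id[i]
        in_region <- design$region == de_plan$region[i]
        case <- samples[in_region & design$condition == "CCI"]
        ctrl <- samples[in_region & design$condition == "sham"]
        log2_mu[g, case] <- log2_mu[g, case] + de_plan$log2fc[i] / 2
        log2_mu[g, ctrl] <- log2_mu[g, ctrl] - de_plan$log2fc[i] / 2
      }
    }
    if (nrow(triplets)) {
      reg_samples <- samples[design$region == triplet_region]
      a <- sqrt(abs(triplet_r))
      b <- sqrt(1 - abs(triplet_r))
      for (i in seq_len(nrow(triplets))) {
        z <- rnorm(length(reg_samples))
        e1 <- rnorm(length(reg_samples))
        e2 <- rnorm(length(reg_samples))
        log2_mu[triplets$cerna_id[i], reg_samples] <-
          log2_mu[triplets$cerna_id[i], reg_samples] +
          triplet_latent_sd * (a * z + b * e1)
        log2_mu[triplets$mrna_id[i], reg_samples] <-
          log2_mu[triplets$mrna_id[i], reg_samples] +
          triplet_latent_sd * (sign(triplet_r) * a * z + b * e2)
      }
    }

    m <- matrix(rnbinom(n_genes * n_samp, size = 1 / dispersion,
                        mu = as.vector(2^log2_mu)),
                nrow = n_genes, ncol = n_samp,
                dimnames = list(gene_tab$gene_id, samples))

    counts <- cbind(gene_tab,
                    data.frame(length_bp = length_bp, stringsAsFactors = FALSE),
                    as.data.frame(m))
    rownames(counts) <- NULL
    list(counts = counts,
         truth = list(de_genes = de_plan, triplets = triplets))
  })
}

#' Generate a miRNA-to-target interaction map
#'
#' Produces the miRNA target substrate used for ceRNA inference: `n_mirna`
#' background miRNAs each target `targets_per_mirna` genes sampled uniformly
#' without replacement from `universe`, and every planted triplet contributes
#' the two entries miRNA->ceRNA and miRNA->mRNA.
#'
#' By default (`exclude_triplet_targets = TRUE`) triplet member genes are
#' removed from the background sampling pool, so a planted miRNA targets
#' exactly its own sponge axis. This makes the planted ground truth
#' unambiguous: a planted (ceRNA, mRNA) pair owes its shared miRNA only to the
#' plant, never to background coincidence.
#'
#' @param universe Character vector of candidate target gene ids.
#' @param n_mirna Number of background miRNAs.
#' @param targets_per_mirna Targets sampled for each background miRNA.
#' @param triplets Optional data frame with columns `mirna_id`, `cerna_id`,
#'   `mrna_id` (as produced in `generate_counts()$truth$triplets`).
#' @param mirna_ids Optional ids for the background miRNAs (length `n_mirna`);
#'   synthesised as `miR-0001`... when missing.
#' @param biotypes Optional named character vector mapping gene id to biotype,
#'   used to fill the `target_biotype` column.
#' @param exclude_triplet_targets Keep triplet members out of the background
#'   sampling pool (default `TRUE`; see Details).
#' @param seed Integer seed.
#' @return Data frame with columns `mirna_id`, `target_id`, `target_biotype`;
#'   duplicate (miRNA, target) pairs are collapsed with a warning.
#' @export
generate_target_map <- function(universe, n_mirna, targets_per_mirna,
                                triplets = NULL, mirna_ids = NULL,
                                biotypes = NULL,
                                exclude_triplet_targets = TRUE,
                                seed = 1L) {
  if (!is_scalar_count(n_mirna)) stop_invalid("`n_mirna` must be a count")
  if (!is_scalar_count(targets_per_mirna)) {
    stop_invalid("`targets_per_mirna` must be a count")
  }
  trip_members <- character()
  if (!is.null(triplets) && nrow(triplets)) {
    trip_members <- c(triplets$cerna_id, triplets$mrna_id)
    missing <- setdiff(trip_members, universe)
    if (length(missing)) {
      stop_invalid("triplet members not in `universe`: ",
                   paste(head(missing, 5), collapse = ", "))
    }
  }
  pool <- if (exclude_triplet_targets) setdiff(universe, trip_members) else universe
  if (n_mirna > 0 && targets_per_mirna > length(pool)) {
    stop_invalid("`targets_per_mirna` exceeds the background target pool (",
                 length(pool), ")")
  }
  if (is.null(mirna_ids)) {
    mirna_ids <- sprintf("miR-%04d", seq_len(n_mirna))
  } else if (length(mirna_ids) != n_mirna) {
    stop_invalid("`mirna_ids` must have length `n_mirna`")
  }

  with_fixed_seed(substream_seed(seed, 3L), {
    bg <- if (n_mirna > 0 && targets_per_mirna > 0) {
      data.frame(
        mirna_id = rep(mirna_ids, each = targets_per_mirna),
        target_id = unlist(lapply(seq_len(n_mirna), function(i) {
          sample_from(pool, targets_per_mirna)
        })),
        stringsAsFactors = FALSE
      )
    } else {
      data.frame(mirna_id = character(), target_id = character(),
                 stringsAsFactors = FALSE)
    }
    map <- bg
    if (!is.null(triplets) && nrow(triplets)) {
      map <- rbind(map,
                   data.frame(mirna_id = rep(triplets$mirna_id, 2),
                              target_id = c(triplets$cerna_id, triplets$mrna_id),
                              stringsAsFactors = FALSE))
    }
    dup <- duplicated(paste(map$mirna_id, map$target_id))
    if (any(dup)) {
      warning(sum(dup), " duplicate (miRNA, target) pair(s) collapsed",
              call. = FALSE)
      map <- map[!dup, , drop = FALSE]
    }
    map$target_biotype <- if (is.null(biotypes)) {
      NA_character_
    } else {
      unname(biotypes[map$target_id])
    }
    map <- map[order(map$mirna_id, map$target_id), , drop = FALSE]
    rownames(map) <- NULL
    map
  })
}

#' Generate gene sets with prescribed sizes and pairwise overlaps
#'
#' Builds a named collection of gene sets (stand-ins for annotation terms or
#' curated disease lists) with exactly the requested sizes and, where a
#' pairwise overlap is specified, exactly that intersection size. Pairs
#' without an entry in `overlap_spec` are constructed disjoint.
#'
#' @param universe Character vector of gene ids to draw from.
#' @param sizes Named integer vector: set name -> set size.
#' @param overlap_spec Named list/vector: `"A|B"` -> required `|A` \eqn{\cap}
#'   `B|`. Infeasible requests raise an error naming the violated constraint.
#' @param seed Integer seed.
#' @return Named list of character vectors (sorted members).
#' @export
generate_gene_sets <- function(universe, sizes, overlap_spec = list(), seed = 1L) {
  if (is.null(names(sizes)) || any(!nzchar(names(sizes)))) {
    stop_invalid("`sizes` must be a named vector of set sizes")
  }
  if (any(sizes > length(universe))) {
    bad <- names(sizes)[sizes > length(universe)][1]
    stop_invalid("set `", bad, "` larger than the universe (",
                 length(universe), ")")
  }
  ov <- list()
  for (key in names(overlap_spec)) {
    pair <- strsplit(key, "|", fixed = TRUE)[[1]]
    if (length(pair) != 2 || !all(pair %in% names(sizes))) {
      stop_invalid("overlap key `", key, "` must name two sets as \"A|B\"")
    }
    m <- overlap_spec[[key]]
    if (m > min(sizes[pair])) {
      stop_invalid("requested overlap ", m, " for `", key,
                   "` exceeds the smaller set size ", min(sizes[pair]))
    }
    ov[[paste(sort(pair), collapse = "|")]] <- m
  }

  with_fixed_seed(substream_seed(seed, 4L), {
    sets <- list()
    for (nm in names(sizes)) {
      size <- sizes[[nm]]
      prev <- names(sets)
      need <- vapply(prev, function(p) {
        key <- paste(sort(c(nm, p)), collapse = "|")
        if (key %in% names(ov)) ov[[key]] else 0L
      }, numeric(1))
      if (sum(need) > size) {
        stop_invalid("set `", nm, "`: required overlaps (", sum(need),
                     ") exceed its size (", size, ")")
      }
      chosen <- character()
      for (p in prev[need > 0]) {
        other_built <- unlist(sets[setdiff(prev, p)], use.names = FALSE)
        pool <- setdiff(sets[[p]], c(chosen, other_built))
        if (length(pool) < need[[p]]) {
          stop_invalid("cannot realise overlap of ", need[[p]], " between `",
                       nm, "` and `", p, "`: only ", length(pool),
                       " exclusive members available")
        }
        chosen <- c(chosen, sample_from(pool, need[[p]]))
      }
      rest_pool <- setdiff(universe, c(chosen, unlist(sets, use.names = FALSE)))
      n_rest <- size - length(chosen)
      if (length(rest_pool) < n_rest) {
        stop_invalid("set `", nm, "`: universe exhausted (need ", n_rest,
                     " more unconstrained members, have ", length(rest_pool), ")")
      }
      if (size == 0) {
        warning("set `", nm, "` has size 0; retained as an empty set",
                call. = FALSE)
      }
      sets[[nm]] <- sort(c(chosen, sample_from(rest_pool, n_rest)))
    }
    sets
  })
}

#' Generate a random protein-protein interaction edge list
#'
#' Samples `n_edges` distinct undirected edges (no self-loops) among `genes`,
#' as a stand-in for a STRING-style interaction export.
#'
#' @param genes Character vector of node ids.
#' @param n_edges Number of edges to draw.
#' @param seed Integer seed.
#' @return Data frame with columns `gene_a`, `gene_b`.
#' @export
generate_ppi_edges <- function(genes, n_edges, seed = 1L) {
  n <- length(genes)
  if (!is_scalar_count(n_edges)) stop_invalid("`n_edges` must be a count")
  if (n_edges > n * (n - 1) / 2) {
    stop_invalid("`n_edges` exceeds the number of possible edges")
  }
  with_fixed_seed(substream_seed(seed, 5L), {
    got <- character(0)
    a <- integer(0); b <- integer(0)
    tries <- 0L
    while (length(a) < n_edges && tries < 100L) {
      tries <- tries + 1L
      need <- n_edges - length(a)
      i <- sample.int(n, 2 * need, replace = TRUE)
      j <- sample.int(n, 2 * need, replace = TRUE)
      keep <- i != j
      lo <- pmin(i[keep], j[keep])
      hi <- pmax(i[keep], j[keep])
      key <- paste(lo, hi)
      fresh <- which(!duplicated(key) & !(key %in% got))
      take <- fresh[seq_len(min(need, length(fresh)))]
      got <- c(got, key[take])
      a <- c(a, lo[take]); b <- c(b, hi[take])
    }
    if (length(a) < n_edges) stop_invalid("failed to sample distinct edges")
    data.frame(gene_a = genes[a], gene_b = genes[b], stringsAsFactors = FALSE)
  })
}

#' Generate a stage-level ceRNA calling fixture with known ground truth
#'
#' Builds the inputs of [call_pairs()] directly — a differential-expression
#' table, an expression matrix and a miRNA target map — with `n_triplets`
#' planted sponge axes whose ceRNA/mRNA log expression is correlated at
#' `triplet_r`, embedded among null DE genes whose expression is drawn
#' independently. Because null genes are *assigned* DE status rather than
#' estimated from condition-shifted counts, their expression carries no shared
#' condition signal: null candidate pairs are genuinely uncorrelated, which is
#' what a false-positive-rate check requires.
#'
#' @param replicates_per_cell Replicates per design cell (the correlation is
#'   computed over `2 * replicates_per_cell` pooled samples of `region`).
#' @param region Region the fixture's DE table describes.
#' @param n_null_cerna,n_null_mrna Numbers of null (non-planted) DE ceRNAs and
#'   mRNAs forming the candidate background.
#' @param n_triplets Planted sponge axes.
#' @param triplet_r Target Pearson correlation of planted pairs.
#' @param n_mirna,targets_per_mirna Background target map density.
#' @param mean_log2,sd_log2 Location and spread of log2 expression.
#' @param seed Integer seed.
#' @return List with `design`, `expr` (RPKM-scale expression table), `de`
#'   (a `de_table` for `region`), `targets`, and `truth` (planted triplets).
#' @export
generate_cerna_fixture <- function(replicates_per_cell = 9, region = "TG",
                                   n_null_cerna = 150, n_null_mrna = 250,
                                   n_triplets = 20, triplet_r = 0.8,
                                   n_mirna = 100, targets_per_mirna = 8,
                                   mean_log2 = 8, sd_log2 = 1.2,
                                   seed = 1L) {
  design <- generate_design(replicates_per_cell)
  samples <- design$sample_id
  n_samp <- length(samples)

  half <- ceiling(n_null_cerna / 2)
  null_tab <- data.frame(
    gene_id = c(sprintf("lnc_%04d", seq_len(half)),
                sprintf("circ_%04d", seq_len(n_null_cerna - half)),
                sprintf("mRNA_%04d", seq_len(n_null_mrna))),
    biotype = c(rep("lncRNA", half), rep("circRNA", n_null_cerna - half),
                rep("mRNA", n_null_mrna)),
    stringsAsFactors = FALSE
  )
  trip_tab <- if (n_triplets > 0) {
    data.frame(
      gene_id = c(sprintf("lncT_%03d", seq_len(ceiling(n_triplets / 2))),
                  sprintf("circT_%03d", seq_len(floor(n_triplets / 2))),
                  sprintf("mRNAT_%03d", seq_len(n_triplets))),
      biotype = c(rep("lncRNA", ceiling(n_triplets / 2)),
                  rep("circRNA", floor(n_triplets / 2)),
                  rep("mRNA", n_triplets)),
      stringsAsFactors = FALSE
    )
  } else {
    null_tab[0, ]
  }
  gene_tab <- rbind(null_tab, trip_tab)

  with_fixed_seed(substream_seed(seed, 6L), {
    g <- matrix(rnorm(nrow(gene_tab) * n_samp, mean_log2, sd_log2),
                nrow = nrow(gene_tab), dimnames = list(gene_tab$gene_id, samples))
    truth <- data.frame(mirna_id = character(), cerna_id = character(),
                        mrna_id = character(), region = character(),
                        r = numeric(), stringsAsFactors = FALSE)
    directions <- setNames(sample(c("up", "down"), nrow(gene_tab),
                                  replace = TRUE),
                           gene_tab$gene_id)
    if (n_triplets > 0) {
      cerna_ids <- trip_tab$gene_id[trip_tab$biotype != "mRNA"]
      mrna_ids <- trip_tab$gene_id[trip_tab$biotype == "mRNA"]
      a <- sqrt(abs(triplet_r)); b <- sqrt(1 - abs(triplet_r))
      for (i in seq_len(n_triplets)) {
        z <- rnorm(n_samp); e1 <- rnorm(n_samp); e2 <- rnorm(n_samp)
        g[cerna_ids[i], ] <- mean_log2 + sd_log2 * (a * z + b * e1)
        g[mrna_ids[i], ] <- mean_log2 +
          sd_log2 * (sign(triplet_r) * a * z + b * e2)
        directions[c(cerna_ids[i], mrna_ids[i])] <-
          sample_from(c("up", "down"), 1)
      }
      truth <- data.frame(mirna_id = sprintf("miR-t%03d", seq_len(n_triplets)),
                          cerna_id = cerna_ids, mrna_id = mrna_ids,
                          region = region, r = triplet_r,
                          stringsAsFactors = FALSE)
    }

    lfc <- ifelse(directions == "up", 1, -1) * runif(nrow(gene_tab), 1, 3)
    de <- data.frame(
      gene_id = gene_tab$gene_id,
      biotype = gene_tab$biotype,
      region = region,
      mean_case = NA_real_, mean_ctrl = NA_real_,
      log2fc = lfc,
      p_value = runif(nrow(gene_tab), 0, 0.01),
      q_value = NA_real_,
      direction = unname(directions[gene_tab$gene_id]),
      significant = TRUE,
      stringsAsFactors = FALSE
    )
    de$q_value <- p.adjust(de$p_value, "BH")
    attr(de, "region") <- region
    attr(de, "alpha") <- 0.05
    attr(de, "fc_cutoff") <- 2
    class(de) <- c("de_table", "data.frame")

    expr <- cbind(gene_tab,
                  data.frame(length_bp = 1000L, stringsAsFactors = FALSE),
                  as.data.frame(2^g))
    rownames(expr) <- NULL

    targets <- generate_target_map(
      universe = gene_tab$gene_id,
      n_mirna = n_mirna, targets_per_mirna = targets_per_mirna,
      triplets = truth,
      biotypes = setNames(gene_tab$biotype, gene_tab$gene_id),
      seed = substream_seed(seed, 7L)
    )
    list(design = design, expr = expr, de = de, targets = targets,
         truth = truth)
  })
}

#' Simulate a complete synthetic study
#'
#' One-call wrapper that generates every input of the workflow coherently: the
#' sample design, a count matrix with planted DE genes and ceRNA triplets, a
#' miRNA target map concentrated on the perturbed genes (so that candidate
#' ceRNA pairs are plentiful), disease-category gene sets with prescribed
#' overlaps, an annotation gene-set collection for enrichment, and a random
#' PPI edge list. All stages derive their substream seeds from the single
#' `seed`, which therefore determines every output byte.
#'
#' @inheritParams generate_counts
#' @param n_mirna_background Background miRNAs in the target map (their ids
#'   are taken from the matrix's miRNA genes; the matrix must contain at least
#'   `n_mirna_background + n_triplets` miRNA genes).
#' @param targets_per_mirna Background targets per miRNA, sampled from the
#'   planted DE genes (triplet members excluded).
#' @param n_ppi_edges Edges in the synthetic PPI network, sampled among the
#'   planted DE genes plus a background sample of mRNAs.
#' @param out_dir Optional directory; when given, all inputs and the ground
#'   truth are written as TSV/GMT files.
#' @param seed Integer seed.
#' @return List with `design`, `counts`, `truth`, `targets`, `disease_sets`,
#'   `annotation_sets`, `ppi_edges`, `seed`.
#' @export
simulate_study <- function(replicates_per_cell = 3,
                           n_per_biotype = c(mRNA = 600, lncRNA = 200,
                                             circRNA = 200, miRNA = 120),
                           n_de = 150,
                           de_log2fc = 2,
                           dispersion = 0.1,
                           n_triplets = 10,
                           triplet_log2fc = 3,
                           triplet_r = 0.8,
                           triplet_region = "TG",
                           n_mirna_background = 100,
                           targets_per_mirna = 4,
                           n_ppi_edges = 400,
                           out_dir = NULL,
                           seed = 1L) {
  design <- generate_design(replicates_per_cell)
  gen <- generate_counts(design, n_per_biotype = n_per_biotype, n_de = n_de,
                         de_log2fc = de_log2fc, dispersion = dispersion,
                         n_triplets = n_triplets,
                         triplet_log2fc = triplet_log2fc,
                         triplet_r = triplet_r,
                         triplet_region = triplet_region,
                         seed = seed)
  counts <- gen$counts
  truth <- gen$truth
  biotype_of <- setNames(counts$biotype, counts$gene_id)

  mirna_ids_all <- counts$gene_id[counts$biotype == "miRNA"]
  mirna_bg <- setdiff(mirna_ids_all, truth$triplets$mirna_id)
  if (length(mirna_bg) < n_mirna_background) {
    stop_invalid("matrix has too few miRNA genes for ", n_mirna_background,
                 " background miRNAs plus ", nrow(truth$triplets), " triplets")
  }
  de_universe <- unique(truth$de_genes$gene_id)
  targets <- generate_target_map(
    universe = union(de_universe, c(truth$triplets$cerna_id,
                                    truth$triplets$mrna_id)),
    n_mirna = n_mirna_background,
    targets_per_mirna = min(targets_per_mirna,
                            max(1, length(setdiff(de_universe,
                                                  c(truth$triplets$cerna_id,
                                                    truth$triplets$mrna_id))))),
    triplets = truth$triplets,
    mirna_ids = mirna_bg[seq_len(n_mirna_background)],
    biotypes = biotype_of,
    seed = seed
  )

  # category sizes scale with the universe so small test matrices stay
  # feasible; proportions chosen to mimic curated disease lists that cover a
  # few percent to ~10% of the measured genes, with substantial pairwise
  # sharing between related conditions
  G <- nrow(counts)
  disease_sizes <- c(pain = max(4, round(0.10 * G)),
                     anxiety = max(3, round(0.08 * G)),
                     depression = max(3, round(0.08 * G)),
                     inflammation = max(3, round(0.08 * G)),
                     apoptosis = max(3, round(0.08 * G)),
                     immunity = max(3, round(0.08 * G)))
  pair_ov <- function(a, b, frac) {
    max(1, round(frac * min(disease_sizes[[a]], disease_sizes[[b]])))
  }
  disease_overlaps <- list(
    "pain|anxiety" = pair_ov("pain", "anxiety", 0.25),
    "pain|depression" = pair_ov("pain", "depression", 0.25),
    "anxiety|depression" = pair_ov("anxiety", "depression", 0.33),
    "pain|inflammation" = pair_ov("pain", "inflammation", 0.2),
    "pain|apoptosis" = pair_ov("pain", "apoptosis", 0.2),
    "pain|immunity" = pair_ov("pain", "immunity", 0.15),
    "inflammation|immunity" = pair_ov("inflammation", "immunity", 0.25))
  disease_sets <- generate_gene_sets(counts$gene_id, disease_sizes,
                                     disease_overlaps, seed = seed)

  annot_names <- c("BP_neurogenesis", "BP_nervous_system_development",
                   "BP_neuron_differentiation", "BP_axon_guidance",
                   "BP_synaptic_transmission",
                   "CC_neuron_projection", "CC_synapse", "CC_membrane",
                   "CC_cell_junction", "CC_dendrite",
                   "MF_binding", "MF_catalytic_activity",
                   "MF_ion_channel_activity", "MF_receptor_activity",
                   "MF_kinase_activity")
  annot_lo <- max(3, floor(G / 60))
  annot_hi <- max(annot_lo + 1, floor(G / 25))
  annot_sizes <- with_fixed_seed(substream_seed(seed, 8L), {
    setNames(sample(annot_lo:annot_hi, length(annot_names), replace = TRUE),
             annot_names)
  })
  annotation_sets <- generate_gene_sets(counts$gene_id, annot_sizes,
                                        seed = substream_seed(seed, 9L))

  ppi_genes <- union(de_universe,
                     with_fixed_seed(substream_seed(seed, 10L), {
                       sample_from(counts$gene_id[counts$biotype == "mRNA"],
                                   min(200, sum(counts$biotype == "mRNA")))
                     }))
  ppi_edges <- generate_ppi_edges(ppi_genes, n_ppi_edges, seed = seed)

  study <- list(design = design, counts = counts, truth = truth,
                targets = targets, disease_sets = disease_sets,
                annotation_sets = annotation_sets, ppi_edges = ppi_edges,
                seed = seed)
  if (!is.null(out_dir)) write_study_inputs(study, out_dir)
  study
}
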