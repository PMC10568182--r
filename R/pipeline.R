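# End-to-end orchestration: synthesis (or file input), RPKM, per-region DE,
# overlap accounting, enrichment, PPI hubs, ceRNA networks, manifest.

#' Default run configuration
#'
#' Every tunable of the workflow in one flat list. `input_dir = NULL` means
#' inputs are synthesised with [simulate_study()] under the configured seed;
#' otherwise `input_dir` must contain the files written by
#' [write_study_inputs()].
#'
#' @return Named list of configuration values.
#' @export
default_run_config <- function() {
  list(
    seed = 1L,
    out_dir = "cernaflow_run",
    input_dir = NULL,
    regions = c("TG", "Sp5C"),
    # synthesis
    replicates_per_cell = 3L,
    n_mrna = 600L, n_lncrna = 200L, n_circrna = 200L, n_mirna = 120L,
    n_de = 150L, de_log2fc = 2, dispersion = 0.1,
    n_triplets = 10L, triplet_log2fc = 3, triplet_r = 0.8,
    triplet_region = "TG",
    n_mirna_background = 100L, targets_per_mirna = 4L, n_ppi_edges = 400L,
    # normalisation / DE
    rpkm_by_biotype = FALSE,
    alpha = 0.05, fc_cutoff = 2, pseudocount = 1,
    # downstream
    category_tuples = list(c("pain", "anxiety", "depression"),
                           c("pain", "apoptosis", "inflammation", "immunity")),
    enrich_alpha = 0.05, enrich_top = 10L,
    top_hubs = 50L, top_k_class = 15L,
    hyper_alpha = 0.05, ppc_min = 0.5, ppc_alpha = 0.05,
    top_cerna = 10L, top_mirna = 2L
  )
}

#' Validate a run configuration
#'
#' Fails fast: unknown keys are errors, thresholds must lie in their valid
#' ranges, and missing keys are filled from [default_run_config()].
#'
#' @param config Named list of overrides.
#' @return The completed, validated configuration.
#' @export
validate_run_config <- function(config = list()) {
  defaults <- default_run_config()
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown)) {
    stop_invalid("unknown config key(s): ", paste(unknown, collapse = ", "))
  }
  full <- defaults
  full[names(config)] <- config
  for (key in c("alpha", "hyper_alpha", "ppc_alpha", "enrich_alpha")) {
    assert_scalar_prob(full[[key]], key)
  }
  if (full$ppc_min < -1 || full$ppc_min > 1) {
    stop_invalid("`ppc_min` must be in [-1, 1]")
  }
  if (full$fc_cutoff < 1) stop_invalid("`fc_cutoff` must be >= 1")
  if (!is_scalar_count(full$seed)) stop_invalid("`seed` must be an integer")
  for (key in c("replicates_per_cell", "top_hubs", "top_k_class",
                "top_cerna", "top_mirna")) {
    if (!is_scalar_count(full[[key]], positive = TRUE)) {
      stop_invalid("`", key, "` must be a positive integer")
    }
  }
  full
}

#' Read a YAML run configuration
#'
#' @param path YAML file whose keys mirror [default_run_config()].
#' @return Validated configuration list.
#' @export
read_run_config <- function(path) {
  validate_run_config(yaml::read_yaml(path))
}

#' Run the complete workflow
#'
#' Synthesises (or loads) the study inputs, then per region: RPKM, DE
#' calling, disease-category mapping, annotation enrichment, PPI hub
#' extraction, and ceRNA pair/network inference; across regions, the
#' co-expression Venn accounting. All tables are written under
#' `config$out_dir` with the seed in their metadata headers, and a JSON
#' manifest records every file with its row count and MD5 checksum together
#' with the full configuration echo — re-running with the same seed
#' reproduces every table byte for byte.
#'
#' @param config Configuration list (see [default_run_config()]); validated
#'   before use.
#' @return Invisibly, a list with `config`, the in-memory `tables`, the
#'   simulated `study` (when synthesised), and the `manifest`.
#' @export
run_pipeline <- function(config = list()) {
  config <- validate_run_config(config)
  out_dir <- config$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_lines <- sprintf("[%s] run started, seed=%d", Sys.time(), config$seed)
  stage <- function(name, code) {
    tryCatch(code, error = function(e) {
      stop_invalid("stage `", name, "` failed: ", conditionMessage(e))
    })
  }

  study <- stage("inputs", {
    if (is.null(config$input_dir)) {
      simulate_study(
        replicates_per_cell = config$replicates_per_cell,
        n_per_biotype = c(mRNA = config$n_mrna, lncRNA = config$n_lncrna,
                          circRNA = config$n_circrna, miRNA = config$n_mirna),
        n_de = config$n_de, de_log2fc = config$de_log2fc,
        dispersion = config$dispersion, n_triplets = config$n_triplets,
        triplet_log2fc = config$triplet_log2fc, triplet_r = config$triplet_r,
        triplet_region = config$triplet_region,
        n_mirna_background = config$n_mirna_background,
        targets_per_mirna = config$targets_per_mirna,
        n_ppi_edges = config$n_ppi_edges,
        out_dir = file.path(out_dir, "inputs"),
        seed = config$seed
      )
    } else {
      list(
        design = read_design_tsv(file.path(config$input_dir, "design.tsv")),
        counts = read_counts_tsv(file.path(config$input_dir, "counts.tsv")),
        targets = read_target_map_tsv(file.path(config$input_dir,
                                                "target_map.tsv")),
        ppi_edges = read_tsv(file.path(config$input_dir, "ppi_edges.tsv")),
        disease_sets = read_gmt(file.path(config$input_dir,
                                          "disease_sets.gmt")),
        annotation_sets = read_gmt(file.path(config$input_dir,
                                             "annotation_sets.gmt")),
        truth = NULL, seed = config$seed
      )
    }
  })

  meta <- list(seed = config$seed, alpha = config$alpha,
               fc_cutoff = config$fc_cutoff,
               hyper_alpha = config$hyper_alpha, ppc_min = config$ppc_min,
               ppc_alpha = config$ppc_alpha)
  tables <- list()
  files <- character()
  emit <- function(x, name) {
    path <- file.path(out_dir, paste0(name, ".tsv"))
    write_tsv(as.data.frame(x), path, meta)
    tables[[name]] <<- x
    files <<- c(files, setNames(path, name))
    x
  }

  expr <- stage("rpkm", compute_rpkm(study$counts,
                                     by_biotype = config$rpkm_by_biotype))
  emit(expr, "rpkm")

  de <- list()
  for (r in config$regions) {
    de[[r]] <- stage(paste0("de_", r), {
      call_de(expr, study$design, r, alpha = config$alpha,
              fc_cutoff = config$fc_cutoff, pseudocount = config$pseudocount)
    })
    emit(de[[r]], paste0("de_", r))
    log_lines <- c(log_lines,
                   sprintf("[%s] region %s: %d significant genes",
                           Sys.time(), r, sum(de[[r]]$significant)))
  }

  if (length(config$regions) == 2) {
    stage("co_expression", {
      emit(co_expression_overlap(de[[config$regions[1]]],
                                 de[[config$regions[2]]]),
           "co_expression_overlap")
    })
  }

  annot_universe <- unique(unlist(study$annotation_sets, use.names = FALSE))
  background <- intersect(expr$gene_id, annot_universe)

  for (r in config$regions) {
    stage(paste0("categories_", r), {
      cats <- map_to_categories(de[[r]], study$disease_sets,
                                tuples = config$category_tuples)
      emit(cats$categories, paste0("category_overlap_", r))
      emit(cats$tuples, paste0("category_tuples_", r))
    })
    stage(paste0("enrichment_", r), {
      query <- intersect(sig_ids(de[[r]], biotype = "mRNA"), background)
      enr <- if (length(background)) {
        enrich(query, background, study$annotation_sets,
               alpha = config$enrich_alpha, top = config$enrich_top)
      } else {
        stop("empty enrichment background")
      }
      emit(enr, paste0("enrichment_", r))
    })
    stage(paste0("hubs_", r), {
      graph <- induce_deg_subgraph(study$ppi_edges, de[[r]])
      emit(select_hubs(graph, k = config$top_hubs), paste0("hubs_", r))
    })
    stage(paste0("cerna_", r), {
      pairs <- call_pairs(de[[r]], expr, study$design, r, study$targets,
                          hyper_alpha = config$hyper_alpha,
                          ppc_min = config$ppc_min,
                          ppc_alpha = config$ppc_alpha,
                          pseudocount = config$pseudocount)
      emit(pairs, paste0("cerna_pairs_", r))
      net <- build_network(pairs, top_cerna = config$top_cerna,
                           top_mirna = config$top_mirna)
      emit(net$nodes, paste0("cerna_nodes_", r))
      edge_block <- function(type, from, to) {
        data.frame(edge_type = rep_len(type, length(from)),
                   from = as.character(from), to = as.character(to),
                   stringsAsFactors = FALSE)
      }
      edge_tab <- rbind(
        edge_block("mirna_cerna", net$edges$mirna_cerna$mirna_id,
                   net$edges$mirna_cerna$partner_id),
        edge_block("mirna_mrna", net$edges$mirna_mrna$mirna_id,
                   net$edges$mirna_mrna$partner_id),
        edge_block("cerna_mrna", net$edges$cerna_mrna$cerna_id,
                   net$edges$cerna_mrna$mrna_id)
      )
      emit(edge_tab, paste0("cerna_edges_", r))
      emit(rbind(net$top_cernas, net$top_mirnas), paste0("cerna_top_", r))
    })
  }

  manifest <- list(
    package = "cernaflow",
    seed = config$seed,
    config = config[setdiff(names(config), "category_tuples")],
    category_tuples = lapply(config$category_tuples, paste, collapse = "+"),
    files = data.frame(
      name = names(files),
      file = basename(unname(files)),
      n_rows = vapply(tables[names(files)], nrow, integer(1)),
      md5 = unname(tools::md5sum(unname(files))),
      stringsAsFactors = FALSE
    )
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       dataframe = "rows")
  log_lines <- c(log_lines, sprintf("[%s] run finished", Sys.time()))
  writeLines(log_lines, file.path(out_dir, "run.log"))

  invisible(list(config = config, study = study, de = de, tables = tables,
                 manifest = manifest, files = files))
}

#' Score a run against its planted ground truth
#'
#' Compares the DE calls and passing ceRNA pairs of a pipeline run (or of
#' directly supplied tables) with the generator's ground truth: per-region DE
#' sensitivity and empirical false-discovery rate, and ceRNA recall,
#' precision and the pass rate among non-planted candidate pairs.
#'
#' @param de Named list of `de_table`s (region -> table).
#' @param pairs Named list of `cerna_pairs` tables (region -> table); may be
#'   `NULL` to score DE only.
#' @param truth Ground-truth list (`de_genes`, `triplets`) from the
#'   generator.
#' @return List with data frames `de` and `cerna`.
#' @export
recover_truth <- function(de, pairs = NULL, truth) {
  if (is.null(truth)) stop_invalid("no ground truth available to score")
  de_rows <- lapply(names(de), function(r) {
    tab <- de[[r]]
    planted <- truth$de_genes$gene_id[truth$de_genes$region == r]
    called <- tab$gene_id[tab$significant]
    data.frame(
      region = r,
      n_planted = length(planted),
      n_called = length(called),
      sensitivity = if (length(planted)) {
        mean(planted %in% called)
      } else {
        NA_real_
      },
      fdr = if (length(called)) {
        mean(!(called %in% planted))
      } else {
        NA_real_
      },
      stringsAsFactors = FALSE
    )
  })
  cerna_rows <- list()
  if (!is.null(pairs)) {
    cerna_rows <- lapply(names(pairs), function(r) {
      tab <- pairs[[r]]
      planted <- truth$triplets[truth$triplets$region == r, , drop = FALSE]
      key <- paste(tab$cerna_id, tab$mrna_id)
      planted_key <- paste(planted$cerna_id, planted$mrna_id)
      is_planted <- key %in% planted_key
      passed <- tab$passes
      data.frame(
        region = r,
        n_planted = nrow(planted),
        n_candidates = nrow(tab),
        recall = if (nrow(planted)) {
          mean(planted_key %in% key[passed])
        } else {
          NA_real_
        },
        precision = if (any(passed)) mean(is_planted[passed]) else NA_real_,
        null_pass_rate = if (any(!is_planted)) {
          mean(passed[!is_planted])
        } else {
          NA_real_
        },
        stringsAsFactors = FALSE
      )
    })
  }
  list(de = do.call(rbind, de_rows),
       cerna = if (length(cerna_rows)) do.call(rbind, cerna_rows) else NULL)
}
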