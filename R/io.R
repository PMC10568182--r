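# Plain-text readers and writers: TSV tables with optional '#' metadata
# headers, and GMT gene-set files.

#' Write a table as TSV with an optional metadata header
#'
#' Metadata (seed, thresholds, ...) is written as `# key=value` comment
#' lines above the header row, so files stay self-describing while remaining
#' readable by any TSV parser that skips comments. No timestamps are ever
#' written: identical inputs give byte-identical files.
#'
#' @param x Data frame.
#' @param path Output path.
#' @param meta Optional named list of scalar metadata values.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(x, path, meta = NULL) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  if (!is.null(meta)) {
    writeLines(sprintf("# %s=%s", names(meta),
                       vapply(meta, function(v) paste(format(v), collapse = ","),
                              character(1))),
               con)
  }
  write.table(x, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a TSV written by [write_tsv()]
#'
#' @param path File path.
#' @return Data frame; any `# key=value` header lines are attached as the
#'   `"meta"` attribute (a named character vector).
#' @export
read_tsv <- function(path) {
  head_lines <- character()
  con <- file(path, open = "rt")
  while (length(l <- readLines(con, n = 1)) && startsWith(l, "# ")) {
    head_lines <- c(head_lines, l)
  }
  close(con)
  x <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                  check.names = FALSE)
  if (length(head_lines)) {
    kv <- sub("^# ", "", head_lines)
    keys <- sub("=.*$", "", kv)
    vals <- sub("^[^=]*=", "", kv)
    attr(x, "meta") <- setNames(vals, keys)
  }
  x
}

#' Read a counts (or expression) table
#'
#' @param path TSV with columns `gene_id`, `biotype`, `length_bp` and one
#'   column per sample.
#' @return Validated counts data frame.
#' @export
read_counts_tsv <- function(path) {
  counts <- read_tsv(path)
  validate_counts(counts)
  counts
}

#' Read a sample design table
#' @param path TSV with columns `sample_id`, `region`, `condition`,
#'   `replicate`.
#' @return Validated design data frame.
#' @export
read_design_tsv <- function(path) {
  design <- read_tsv(path)
  validate_design(design)
  design
}

#' Read a miRNA target map
#'
#' Duplicate (miRNA, target) rows are collapsed with a warning.
#'
#' @param path TSV with columns `mirna_id`, `target_id` and optionally
#'   `target_biotype`.
#' @return Target map data frame.
#' @export
read_target_map_tsv <- function(path) {
  map <- read_tsv(path)
  if (!all(c("mirna_id", "target_id") %in% names(map))) {
    stop_invalid("target map needs columns mirna_id, target_id")
  }
  dup <- duplicated(paste(map$mirna_id, map$target_id))
  if (any(dup)) {
    warning(sum(dup), " duplicate (miRNA, target) pair(s) collapsed",
            call. = FALSE)
    map <- map[!dup, , drop = FALSE]
  }
  map
}

#' Read a GMT gene-set file
#'
#' One set per line: name, description, then tab-separated member ids.
#' Duplicate members within a set are collapsed.
#'
#' @param path GMT file path.
#' @return Named list of character vectors; descriptions in attribute
#'   `"descriptions"`.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- lengths(parts) < 2
  if (any(bad)) stop_invalid("malformed GMT line(s): ", which(bad)[1])
  sets <- lapply(parts, function(p) unique(p[-(1:2)]))
  names(sets) <- vapply(parts, `[[`, character(1), 1)
  attr(sets, "descriptions") <- setNames(
    vapply(parts, `[[`, character(1), 2), names(sets))
  sets
}

#' Write a GMT gene-set file
#'
#' @param sets Named list of character vectors.
#' @param path Output path.
#' @param descriptions Optional named descriptions (defaults to the set name).
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  if (is.null(descriptions)) descriptions <- setNames(names(sets), names(sets))
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, descriptions[[nm]], sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Write every input of a simulated study to disk
#'
#' Emits the counts, design, target map, disease and annotation GMT files,
#' PPI edges and the planted ground truth under `out_dir`, each file headed
#' by the generator seed.
#'
#' @param study List from [simulate_study()].
#' @param out_dir Output directory (created if needed).
#' @return Named character vector of the written paths, invisibly.
#' @export
write_study_inputs <- function(study, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  meta <- list(seed = study$seed)
  paths <- c(
    counts = write_tsv(study$counts, file.path(out_dir, "counts.tsv"), meta),
    design = write_tsv(study$design, file.path(out_dir, "design.tsv"), meta),
    targets = write_tsv(study$targets, file.path(out_dir, "target_map.tsv"),
                        meta),
    ppi = write_tsv(study$ppi_edges, file.path(out_dir, "ppi_edges.tsv"),
                    meta),
    truth_de = write_tsv(study$truth$de_genes,
                         file.path(out_dir, "truth_de_genes.tsv"), meta),
    truth_triplets = write_tsv(study$truth$triplets,
                               file.path(out_dir, "truth_triplets.tsv"), meta),
    disease_sets = write_gmt(study$disease_sets,
                             file.path(out_dir, "disease_sets.gmt")),
    annotation_sets = write_gmt(study$annotation_sets,
                                file.path(out_dir, "annotation_sets.gmt"))
  )
  invisible(paths)
}
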