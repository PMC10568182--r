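# Internal helpers shared across modules. Nothing here is exported.

BIOTYPES <- c("mRNA", "lncRNA", "circRNA", "miRNA")
REGIONS <- c("TG", "Sp5C")
CONDITIONS <- c("CCI", "sham")

# columns of a counts/expression table that are not per-sample values
ANNOT_COLS <- c("gene_id", "biotype", "length_bp")

stop_invalid <- function(...) stop(..., call. = FALSE)

is_scalar_count <- function(x, positive = FALSE) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x == round(x) &&
    x >= if (positive) 1 else 0
}

assert_scalar_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1) {
    stop_invalid("`", name, "` must be a single value in [0, 1], got: ",
                 deparse(x))
  }
  invisible(x)
}

sample_columns <- function(x) setdiff(names(x), ANNOT_COLS)

# numeric matrix of per-sample values, rownames = gene ids
expr_values <- function(x) {
  m <- as.matrix(x[, sample_columns(x), drop = FALSE])
  rownames(m) <- x$gene_id
  storage.mode(m) <- "double"
  m
}

# Evaluate `code` under a fixed, fully specified RNG state, restoring the
# caller's state afterwards. Pinning the RNG kinds keeps seeded outputs
# identical across platforms and R sessions.
with_fixed_seed <- function(seed, code) {
  if (!is_scalar_count(seed)) stop_invalid("`seed` must be a non-negative integer")
  withr::local_preserve_seed()
  set.seed(as.integer(seed %% .Machine$integer.max),
           kind = "Mersenne-Twister", normal.kind = "Inversion",
           sample.kind = "Rejection")
  code
}

# Fan a single user seed out to per-stage substreams so that adding draws to
# one stage never perturbs another. Kept strictly below 2^31.
substream_seed <- function(seed, stage) {
  if (!is_scalar_count(seed)) stop_invalid("`seed` must be a non-negative integer")
  if (!is_scalar_count(stage)) stop_invalid("`stage` must be a non-negative integer")
  as.integer(((seed %% 65011) * 33013 + stage * 7919) %% 2147483587 + 1)
}

# sample() without the length-1 surprise
sample_from <- function(pool, n) pool[sample.int(length(pool), n)]

validate_design <- function(design) {
  req <- c("sample_id", "region", "condition", "replicate")
  if (!is.data.frame(design) || !all(req %in% names(design))) {
    stop_invalid("`design` must be a data frame with columns ",
                 paste(req, collapse = ", "))
  }
  if (anyDuplicated(design$sample_id)) stop_invalid("sample_ids must be unique")
  invisible(design)
}

validate_counts <- function(counts) {
  if (!is.data.frame(counts) || !all(ANNOT_COLS %in% names(counts))) {
    stop_invalid("`counts` must be a data frame with columns ",
                 paste(ANNOT_COLS, collapse = ", "), " plus one column per sample")
  }
  if (anyDuplicated(counts$gene_id)) stop_invalid("gene_ids must be unique")
  if (any(counts$length_bp < 1)) stop_invalid("gene lengths must be >= 1")
  m <- expr_values(counts)
  if (any(m < 0)) stop_invalid("counts must be non-negative")
  invisible(counts)
}
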