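#' Construct an expression table
#'
#' An expression table couples a non-negative FPKM matrix (features in rows,
#' samples in columns) with per-sample metadata. Features may be isoforms or
#' genes; samples are embryo replicates of one species at one developmental
#' stage (stage 2, all-maternal; stage 5, post zygotic-genome activation).
#'
#' @param values Numeric matrix of FPKM, features x samples, with row and
#'   column names. All values must be finite and >= 0.
#' @param samples Data frame with columns `sample_id`, `species`, `stage`
#'   (one of `"stage2"`, `"stage5"`), `replicate` and optionally `sex`.
#'   `sample_id` must match `colnames(values)` (same order after matching).
#' @return An object of class `expression_table`: a list with elements
#'   `values` and `samples`.
#' @export
expression_table <- function(values, samples) {
  stopifnot(is.matrix(values), is.numeric(values))
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("`values` must have feature row names and sample column names")
  }
  if (anyDuplicated(rownames(values))) stop("duplicate feature ids")
  samples <- as.data.frame(samples)
  req <- c("sample_id", "species", "stage", "replicate")
  missing_cols <- setdiff(req, names(samples))
  if (length(missing_cols)) {
    stop("sample sheet is missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (anyDuplicated(samples$sample_id)) stop("duplicate sample_id in sample sheet")
  bad_stage <- setdiff(unique(samples$stage), c("stage2", "stage5"))
  if (length(bad_stage)) stop("unknown stage value(s): ", paste(bad_stage, collapse = ", "))
  unknown <- setdiff(colnames(values), samples$sample_id)
  if (length(unknown)) {
    stop("sample column(s) absent from sample sheet: ", paste(unknown, collapse = ", "))
  }
  samples <- samples[match(colnames(values), samples$sample_id), , drop = FALSE]
  rownames(samples) <- NULL
  bad <- which(!is.finite(values) | values < 0, arr.ind = TRUE)
  if (nrow(bad)) {
    stop(sprintf(
      "negative or non-finite FPKM at feature '%s', sample '%s'",
      rownames(values)[bad[1, 1]], colnames(values)[bad[1, 2]]
    ))
  }
  structure(list(values = values, samples = samples), class = "expression_table")
}

#' @export
print.expression_table <- function(x, ...) {
  cat(sprintf(
    "expression_table: %d features x %d samples (%d species, stages: %s)\n",
    nrow(x$values), ncol(x$values), length(unique(x$samples$species)),
    paste(sort(unique(x$samples$stage)), collapse = ", ")
  ))
  invisible(x)
}

#' Read a sample sheet
#'
#' @param path Tab-separated file with header
#'   `sample_id, species, stage, replicate[, sex]`.
#' @return Data frame of sample metadata.
#' @export
read_sample_sheet <- function(path) {
  samples <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  req <- c("sample_id", "species", "stage", "replicate")
  missing_cols <- setdiff(req, names(samples))
  if (length(missing_cols)) {
    stop("sample sheet ", path, " is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  samples$replicate <- as.integer(samples$replicate)
  samples
}

#' Read a wide FPKM table with its sample sheet
#'
#' The expression file is a tab-separated table whose first column
#' (`feature_id`) holds isoform or gene identifiers and whose remaining
#' columns are samples. Every sample column must be described in the sample
#' sheet; non-numeric or negative FPKM values are rejected with the offending
#' cell named. Cuffnorm-style `<sample>_0` header suffixes are tolerated.
#'
#' @param path Expression TSV.
#' @param sample_sheet Sample-sheet TSV (see [read_sample_sheet()]), or a
#'   data frame already read.
#' @return An [expression_table()].
#' @export
read_expression_table <- function(path, sample_sheet) {
  raw <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE,
                           colClasses = "character")
  if (ncol(raw) < 2) stop("expression file needs a feature_id column plus samples")
  feature_ids <- raw[[1]]
  samples <- if (is.character(sample_sheet)) read_sample_sheet(sample_sheet) else sample_sheet
  mat <- as.matrix(raw[, -1, drop = FALSE])
  cn <- colnames(mat)
  # Cuffnorm appends a replicate suffix such as "_0" to sample names
  cuff <- !cn %in% samples$sample_id & sub("_[0-9]+$", "", cn) %in% samples$sample_id
  cn[cuff] <- sub("_[0-9]+$", "", cn[cuff])
  colnames(mat) <- cn
  vals <- suppressWarnings(matrix(as.numeric(mat), nrow = nrow(mat),
                                  dimnames = list(feature_ids, cn)))
  bad <- which(is.na(vals) & !is.na(mat), arr.ind = TRUE)
  if (nrow(bad)) {
    stop(sprintf("non-numeric FPKM at feature '%s', sample '%s'",
                 feature_ids[bad[1, 1]], cn[bad[1, 2]]))
  }
  expression_table(vals, samples[samples$sample_id %in% cn, , drop = FALSE])
}

#' Read an isoform-to-gene map
#'
#' @param path TSV with columns `isoform_id, gene_id`.
#' @return Named character vector mapping isoform id to gene id.
#' @export
read_isoform_map <- function(path) {
  m <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("isoform_id", "gene_id") %in% names(m))) {
    stop("isoform map needs columns isoform_id and gene_id")
  }
  if (anyDuplicated(m$isoform_id)) stop("an isoform maps to more than one gene")
  stats::setNames(m$gene_id, m$isoform_id)
}

#' Sum isoform FPKM to gene level
#'
#' Gene FPKM is the total of the FPKM levels of all isoforms of the gene,
#' computed per sample.
#'
#' @param t An isoform-level [expression_table()].
#' @param map Named character vector, isoform id -> gene id.
#' @return A gene-level `expression_table` (one row per gene).
#' @export
aggregate_isoforms_to_genes <- function(t, map) {
  stopifnot(inherits(t, "expression_table"))
  absent <- setdiff(rownames(t$values), names(map))
  if (length(absent)) {
    stop("isoform(s) absent from map: ", paste(utils::head(absent, 5), collapse = ", "))
  }
  genes <- unname(map[rownames(t$values)])
  agg <- rowsum(t$values, group = genes, reorder = TRUE)
  expression_table(agg, t$samples)
}

#' Mean FPKM per species-by-stage condition
#'
#' Collapses replicates to the arithmetic mean FPKM for each
#' (species, stage) condition present in the table. Conditions with no
#' samples are absent from the output.
#'
#' @param t An [expression_table()].
#' @return A `condition_matrix`: list with `values` (features x conditions)
#'   and `conditions` (data frame `condition, species, stage`). Condition
#'   names are `<species>.<stage>`.
#' @export
mean_by_condition <- function(t) {
  stopifnot(inherits(t, "expression_table"))
  key <- paste(t$samples$species, t$samples$stage, sep = ".")
  groups <- unique(key)
  vals <- vapply(groups, function(g) {
    rowMeans(t$values[, key == g, drop = FALSE])
  }, numeric(nrow(t$values)))
  vals <- matrix(vals, nrow = nrow(t$values),
                 dimnames = list(rownames(t$values), groups))
  meta <- unique(data.frame(condition = key, species = t$samples$species,
                            stage = t$samples$stage, stringsAsFactors = FALSE))
  meta <- meta[match(groups, meta$condition), , drop = FALSE]
  rownames(meta) <- NULL
  structure(list(values = vals, conditions = meta), class = "condition_matrix")
}

#' Number of replicates behind each condition of an expression table
#' @param t An [expression_table()].
#' @return Named integer vector keyed by `<species>.<stage>`.
#' @export
replicates_per_condition <- function(t) {
  key <- paste(t$samples$species, t$samples$stage, sep = ".")
  tab <- table(key)
  stats::setNames(as.integer(tab), names(tab))
}
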