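#' Spearman rank correlation
#'
#' Pearson correlation of average-ranked values. A constant vector has no
#' rank ordering, so the coefficient is undefined and returned as `NA`
#' rather than 0.
#'
#' @param x,y Numeric vectors of equal length >= 2; ties allowed.
#' @return Correlation in [-1, 1], or `NA_real_` when undefined.
#' @export
spearman_rho <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 2)
  if (stats::var(x) == 0 || stats::var(y) == 0) return(NA_real_)
  stats::cor(x, y, method = "spearman")
}

# Internal: map a species' gene-level calls onto ortholog-group rows.
# Returns one row per group with NA category/means where the ortholog is
# blank in that species.
calls_by_group <- function(calls, orthologs, species) {
  ids <- orthologs$groups[[species]]
  if (is.null(ids)) stop("unknown species: ", species)
  idx <- match(ids, calls$feature_id)
  idx[ids == ""] <- NA
  data.frame(
    ref_gene = orthologs$groups$ref_gene,
    category = calls$category[idx],
    s2_mean = calls$s2_mean[idx],
    s5_mean = calls$s5_mean[idx],
    stringsAsFactors = FALSE
  )
}

#' Cross-species correlation of a gene class
#'
#' Correlates per-gene FPKM between two species over ortholog groups
#' restricted to a stage or stage-restricted category. Under mode
#' `shared_in_both` a gene must belong to the class in both species; under
#' `in_either` membership in at least one species suffices. Maternal-only
#' genes are compared on stage-2 means, zygotic-only genes on stage-5
#' means, and the `stage2`/`stage5` classes (all genes present at that
#' stage) on the means of that stage. Groups blank in either species are
#' excluded pairwise.
#'
#' @param a,b Per-group call tables for the two species, as produced by
#'   aligning [classify_expression()] output to ortholog groups (columns
#'   `ref_gene, category, s2_mean, s5_mean`; `NA` rows for blanks).
#' @param category One of `"stage2"`, `"stage5"`, `"maternal_only"`,
#'   `"zygotic_only"`.
#' @param mode `"shared_in_both"` or `"in_either"`.
#' @param cfg A [classifier_config()] (presence threshold for the stage
#'   classes).
#' @param species_a,species_b Labels recorded in the result.
#' @return Data frame
#'   `species_a, species_b, category, mode, rho, n_genes` (one row);
#'   `rho` is `NA` when fewer than two genes qualify.
#' @export
pairwise_category_correlation <- function(a, b,
    category = c("stage2", "stage5", "maternal_only", "zygotic_only"),
    mode = c("shared_in_both", "in_either"),
    cfg = classifier_config(),
    species_a = "a", species_b = "b") {
  category <- match.arg(category)
  mode <- match.arg(mode)
  stopifnot(identical(a$ref_gene, b$ref_gene))
  known <- !is.na(a$category) & !is.na(b$category)
  member <- function(d) {
    switch(category,
      stage2 = !is.na(d$s2_mean) & d$s2_mean >= cfg$presence_threshold,
      stage5 = !is.na(d$s5_mean) & d$s5_mean >= cfg$presence_threshold,
      maternal_only = !is.na(d$category) & d$category == "M",
      zygotic_only = !is.na(d$category) & d$category == "Z")
  }
  sel <- if (mode == "shared_in_both") member(a) & member(b) else member(a) | member(b)
  sel <- sel & known
  col <- if (category %in% c("stage2", "maternal_only")) "s2_mean" else "s5_mean"
  n <- sum(sel)
  rho <- if (n >= 2) spearman_rho(a[[col]][sel], b[[col]][sel]) else NA_real_
  data.frame(species_a = species_a, species_b = species_b,
             category = category, mode = mode, rho = rho, n_genes = n,
             stringsAsFactors = FALSE)
}

#' Spearman correlation matrix over conditions
#'
#' @param values Matrix of per-gene mean FPKM, genes x conditions
#'   (species-by-stage), restricted to shared orthologs.
#' @return Symmetric correlation matrix with unit diagonal.
#' @export
correlation_matrix <- function(values) {
  stopifnot(is.matrix(values), ncol(values) >= 2)
  rho <- stats::cor(values, method = "spearman")
  diag(rho) <- 1
  rho
}

#' Average-linkage clustering of transcriptomes
#'
#' Agglomerative hierarchical clustering of condition transcriptomes on
#' the distance 1 - Spearman rho, with average linkage. Metric and linkage
#' are recorded on the result.
#'
#' @param corr Symmetric Spearman correlation matrix
#'   (see [correlation_matrix()]).
#' @return An [stats::hclust] object (standard two-column merge format)
#'   with attributes `metric` and `linkage`.
#' @export
hierarchical_cluster <- function(corr) {
  stopifnot(is.matrix(corr), nrow(corr) == ncol(corr))
  if (max(abs(corr - t(corr))) > 1e-8) stop("correlation matrix is not symmetric")
  h <- stats::hclust(stats::as.dist(1 - corr), method = "average")
  attr(h, "metric") <- "1 - spearman"
  attr(h, "linkage") <- "average"
  h
}

#' Leaf partition at the top split of a dendrogram
#' @param h An [stats::hclust] object.
#' @return Named integer vector of 1/2 memberships (via [stats::cutree()]).
#' @export
top_split <- function(h) stats::cutree(h, k = 2)

#' Conservation of the ALT state across species
#'
#' Counts, per ortholog group, the species whose ortholog shows
#' stage-specific alternative isoform usage, and reports which groups meet
#' the two-thirds-of-species rule.
#'
#' @param alt_flags Logical matrix, groups x species (`NA` for blank
#'   orthologs).
#' @param min_fraction Fraction of species required (default 2/3; the count
#'   must reach `ceiling(min_fraction * n_species)`).
#' @return Data frame `ref_gene, n_alt, conserved`.
#' @export
alt_conservation_count <- function(alt_flags, min_fraction = 2 / 3) {
  stopifnot(is.matrix(alt_flags))
  n_species <- ncol(alt_flags)
  counts <- rowSums(alt_flags, na.rm = TRUE)
  need <- ceiling(min_fraction * n_species)
  data.frame(ref_gene = rownames(alt_flags),
             n_alt = as.integer(counts),
             conserved = counts >= need,
             stringsAsFactors = FALSE)
}

#' Genes stage-restricted in both species of a pair
#'
#' @param a,b Per-group call tables (see
#'   [pairwise_category_correlation()]).
#' @return Named integer vector with elements `maternal_only` (category M
#'   in both species) and `zygotic_only` (category Z in both).
#' @export
shared_stage_restricted_counts <- function(a, b) {
  stopifnot(identical(a$ref_gene, b$ref_gene))
  both <- function(cat) {
    sum(!is.na(a$category) & !is.na(b$category) &
          a$category == cat & b$category == cat)
  }
  c(maternal_only = both("M"), zygotic_only = both("Z"))
}
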