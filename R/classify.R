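#' Classifier configuration
#'
#' Thresholds for the six-way stage classification. A transcript is
#' "present" at a stage when its mean FPKM is at or above
#' `presence_threshold` (default 1). Predominance at a stage requires the
#' level there to be at least `fold` times the other stage (default 2) with
#' a BH-adjusted q-value below `alpha` (default 0.05). The
#' unique-representation screen uses the stricter `unique_hi_threshold`
#' (default 3, strictly exceeded) in the focal species with all other
#' species strictly below `presence_threshold`.
#'
#' @param presence_threshold FPKM at/above which a feature is present.
#' @param unique_hi_threshold FPKM a uniquely represented gene must exceed.
#' @param fold Fold-change required for predominance.
#' @param alpha Significance level on BH-adjusted q-values.
#' @export
classifier_config <- function(presence_threshold = 1, unique_hi_threshold = 3,
                              fold = 2, alpha = 0.05) {
  stopifnot(presence_threshold > 0, unique_hi_threshold >= presence_threshold,
            fold >= 1, alpha > 0, alpha < 1)
  structure(list(presence_threshold = presence_threshold,
                 unique_hi_threshold = unique_hi_threshold,
                 fold = fold, alpha = alpha),
            class = "classifier_config")
}

#' The six stage categories
#' @export
STAGE_CATEGORIES <- c("M", "PM", "MZ", "PZ", "Z", "N")

#' Presence call at a threshold
#'
#' Present means FPKM greater than or equal to the threshold.
#'
#' @param fpkm Non-negative FPKM value(s).
#' @param threshold Presence threshold.
#' @return Logical vector.
#' @export
is_present <- function(fpkm, threshold = 1) {
  stopifnot(all(fpkm >= 0))
  fpkm >= threshold
}

#' Between-stage significance per feature
#'
#' A replicate-level stand-in for read-level differential tests: a
#' two-sided Welch t-test on log2(FPKM + 1) replicate values per feature,
#' with Benjamini-Hochberg adjustment across all tested features. An exact
#' label-permutation test on the difference of log2 means is available for
#' small replicate counts. Features with fewer than two replicates at
#' either stage get `NA` and can never be called predominant.
#'
#' Degenerate replicate sets (zero variance at both stages) are resolved
#' directly: p = 1 when the stage means coincide, p = 0 when they differ.
#'
#' @param s2 Matrix of stage-2 replicate FPKM, features x replicates.
#' @param s5 Matrix of stage-5 replicate FPKM, same features.
#' @param method `"welch"` (default) or `"permutation"` (exact enumeration
#'   of all replicate-label assignments, feasible for <= 6 per stage).
#' @return Data frame `feature_id, p_value, q_value`.
#' @export
stage_significance <- function(s2, s5, method = c("welch", "permutation")) {
  method <- match.arg(method)
  s2 <- as.matrix(s2); s5 <- as.matrix(s5)
  stopifnot(nrow(s2) == nrow(s5))
  ids <- rownames(s2)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(s2)))
  p <- vapply(seq_len(nrow(s2)), function(i) {
    x <- log2(s2[i, !is.na(s2[i, ])] + 1)
    y <- log2(s5[i, !is.na(s5[i, ])] + 1)
    if (length(x) < 2 || length(y) < 2) return(NA_real_)
    if (stats::var(x) < 1e-20 && stats::var(y) < 1e-20) {
      return(if (abs(mean(x) - mean(y)) < 1e-12) 1 else 0)
    }
    if (method == "welch") {
      stats::t.test(x, y)$p.value
    } else {
      permutation_p(x, y)
    }
  }, numeric(1))
  q <- rep(NA_real_, length(p))
  q[!is.na(p)] <- stats::p.adjust(p[!is.na(p)], method = "BH")
  data.frame(feature_id = ids, p_value = p, q_value = q,
             stringsAsFactors = FALSE)
}

# Exact two-sided permutation p for |mean(x) - mean(y)|, enumerating every
# assignment of the pooled values into groups of the observed sizes.
permutation_p <- function(x, y) {
  pooled <- c(x, y)
  n <- length(pooled)
  k <- length(x)
  if (choose(n, k) > 1e5) stop("too many replicates for exact permutation")
  obs <- abs(mean(x) - mean(y))
  idx <- utils::combn(n, k)
  total <- sum(pooled)
  stat <- apply(idx, 2, function(ii) {
    sx <- sum(pooled[ii])
    abs(sx / k - (total - sx) / (n - k))
  })
  mean(stat >= obs - 1e-12)
}

#' Six-way stage category of a feature
#'
#' N when absent at both stages; M (maternal-only) when present at stage 2
#' only; Z (zygotic-only) when present at stage 5 only. Features present at
#' both stages are PM when significantly at least `fold`-fold higher at
#' stage 2, PZ when significantly at least `fold`-fold higher at stage 5,
#' and MZ otherwise. Vectorised over features.
#'
#' @param s2_mean,s5_mean Mean replicate FPKM at each stage.
#' @param q BH-adjusted q-value(s); `NA` when not testable.
#' @param cfg A [classifier_config()].
#' @return Character vector of categories from [STAGE_CATEGORIES].
#' @export
classify_feature <- function(s2_mean, s5_mean, q = NA_real_,
                             cfg = classifier_config()) {
  stopifnot(all(s2_mean >= 0), all(s5_mean >= 0))
  n <- max(length(s2_mean), length(s5_mean))
  s2_mean <- rep_len(s2_mean, n); s5_mean <- rep_len(s5_mean, n)
  q <- rep_len(q, n)
  p2 <- is_present(s2_mean, cfg$presence_threshold)
  p5 <- is_present(s5_mean, cfg$presence_threshold)
  sig <- !is.na(q) & q < cfg$alpha
  out <- rep("MZ", n)
  out[!p2 & !p5] <- "N"
  out[p2 & !p5] <- "M"
  out[!p2 & p5] <- "Z"
  both <- p2 & p5
  out[both & sig & s2_mean >= cfg$fold * s5_mean] <- "PM"
  out[both & sig & s5_mean >= cfg$fold * s2_mean] <- "PZ"
  out
}

#' Classify every feature of one species
#'
#' Runs the full per-species classification: replicate matrices are split
#' by stage, q-values computed jointly across features
#' ([stage_significance()]), and the six-way rule applied to the stage
#' means.
#'
#' @param t An [expression_table()] holding one species at both stages
#'   (isoform- or gene-level).
#' @param cfg A [classifier_config()].
#' @param level `"isoform"` or `"gene"` (recorded in the output).
#' @param method Significance method, see [stage_significance()].
#' @return Data frame
#'   `feature_id, level, category, s2_mean, s5_mean, q_value`.
#' @export
classify_expression <- function(t, cfg = classifier_config(),
                                level = c("isoform", "gene"),
                                method = "welch") {
  level <- match.arg(level)
  stopifnot(inherits(t, "expression_table"))
  if (length(unique(t$samples$species)) != 1) {
    stop("classify_expression expects a single species")
  }
  i2 <- t$samples$stage == "stage2"
  i5 <- t$samples$stage == "stage5"
  if (!any(i2) || !any(i5)) stop("both stages are required")
  s2 <- t$values[, i2, drop = FALSE]
  s5 <- t$values[, i5, drop = FALSE]
  sig <- stage_significance(s2, s5, method = method)
  s2_mean <- rowMeans(s2); s5_mean <- rowMeans(s5)
  data.frame(
    feature_id = rownames(t$values),
    level = level,
    category = classify_feature(s2_mean, s5_mean, sig$q_value, cfg),
    s2_mean = unname(s2_mean),
    s5_mean = unname(s5_mean),
    q_value = sig$q_value,
    stringsAsFactors = FALSE
  )
}

#' Stage-specific alternative isoform (ALT) call for one gene
#'
#' A gene shows stage-specific isoform usage when at least one isoform is
#' maternal-class (M or PM) and at least one other is zygotic-class
#' (Z or PZ).
#'
#' @param categories Character vector of isoform categories for one gene.
#' @return Logical.
#' @export
detect_alt <- function(categories) {
  stopifnot(length(categories) >= 1)
  any(categories %in% c("M", "PM")) && any(categories %in% c("Z", "PZ"))
}

#' ALT calls for all genes of a species
#'
#' @param isoform_calls Output of [classify_expression()] at isoform level.
#' @param map Named character vector, isoform id -> gene id.
#' @return Data frame `gene_id, alt_flag`.
#' @export
detect_alt_genes <- function(isoform_calls, map) {
  gene <- unname(map[isoform_calls$feature_id])
  if (anyNA(gene)) stop("isoform(s) absent from map")
  flags <- vapply(split(isoform_calls$category, gene), detect_alt, logical(1))
  data.frame(gene_id = names(flags), alt_flag = unname(flags),
             stringsAsFactors = FALSE)
}

#' Uniquely represented ortholog in a single species
#'
#' Returns the species in which a gene is uniquely represented at a stage:
#' its FPKM must strictly exceed `unique_hi_threshold` in exactly one
#' species while every other species with a known ortholog is strictly
#' below `presence_threshold`. Blank orthologs (`NA`) are skipped.
#'
#' @param row Named numeric vector of per-species mean FPKM for one gene at
#'   one stage; `NA` marks a blank ortholog.
#' @param cfg A [classifier_config()].
#' @return The species name, or `NA_character_` when no species qualifies.
#' @export
unique_representation <- function(row, cfg = classifier_config()) {
  known <- row[!is.na(row)]
  hi <- known > cfg$unique_hi_threshold
  if (sum(hi) != 1) return(NA_character_)
  if (any(known[!hi] >= cfg$presence_threshold)) return(NA_character_)
  names(known)[hi]
}

#' Screen all ortholog groups for unique representation
#'
#' @param values Matrix of per-species mean FPKM (groups x species) for one
#'   stage, `NA` for blank orthologs; rows restricted to groups passing
#'   [filter_ortholog_groups()].
#' @param cfg A [classifier_config()].
#' @return Data frame `ref_gene, species` of uniquely represented groups.
#' @export
unique_representation_screen <- function(values, cfg = classifier_config()) {
  hits <- vapply(seq_len(nrow(values)), function(i) {
    unique_representation(values[i, ], cfg)
  }, character(1))
  keep <- !is.na(hits)
  data.frame(ref_gene = rownames(values)[keep], species = hits[keep],
             stringsAsFactors = FALSE)
}

#' Fisher exact enrichment of a category within a gene subset
#'
#' Exact two-sided hypergeometric test on the 2x2 table of subset
#' membership against category membership. The odds ratio is the sample
#' cross-product ratio, with 0.5 added to every cell when any cell is zero
#' (noted in the result).
#'
#' @param subset_flag,category_flag Logical vectors over the same genes, or
#'   `NULL` when `counts` is supplied.
#' @param counts Optional 2x2 matrix of counts
#'   (rows: in/out of subset; columns: in/out of category).
#' @return List with `table`, `odds_ratio`, `p_value`, `continuity`.
#' @export
category_enrichment <- function(subset_flag = NULL, category_flag = NULL,
                                counts = NULL) {
  if (is.null(counts)) {
    stopifnot(length(subset_flag) == length(category_flag))
    counts <- matrix(c(
      sum(subset_flag & category_flag), sum(subset_flag & !category_flag),
      sum(!subset_flag & category_flag), sum(!subset_flag & !category_flag)
    ), nrow = 2, byrow = TRUE,
    dimnames = list(c("subset", "other"), c("category", "not")))
  }
  counts <- as.matrix(counts)
  stopifnot(all(dim(counts) == 2), all(counts >= 0), sum(counts) > 0)
  degenerate <- any(rowSums(counts) == 0) || any(colSums(counts) == 0)
  if (degenerate) {
    warning("a margin of the 2x2 table is empty; p = 1")
    p <- 1
  } else {
    p <- stats::fisher.test(counts)$p.value
  }
  continuity <- any(counts == 0)
  cc <- if (continuity) counts + 0.5 else counts
  or <- (cc[1, 1] * cc[2, 2]) / (cc[1, 2] * cc[2, 1])
  list(table = counts, odds_ratio = unname(or), p_value = p,
       continuity = continuity)
}

#' Gene-structure summaries by stage category
#'
#' Per-category means of exon count, exonic length and intronic length,
#' with two-sided Wilcoxon rank-sum tests comparing the combined
#' maternal-class (M and PM) against the combined zygotic-class (Z and PZ)
#' features for each metric. When either class is absent the comparison is
#' skipped with a message and `NA` p-values.
#'
#' @param records Data frame
#'   `gene_id, exon_count, exonic_length, intronic_length`.
#' @param calls Classification data frame with `feature_id` and `category`
#'   matching `records$gene_id`.
#' @return List with `means` (per category) and `tests`
#'   (metric, p_value, n_maternal, n_zygotic).
#' @export
structure_summary <- function(records, calls) {
  merged <- merge(records, calls[, c("feature_id", "category")],
                  by.x = "gene_id", by.y = "feature_id")
  metrics <- c("exon_count", "exonic_length", "intronic_length")
  means <- do.call(rbind, lapply(split(merged, merged$category), function(d) {
    data.frame(category = d$category[1], n = nrow(d),
               t(colMeans(d[, metrics, drop = FALSE])))
  }))
  rownames(means) <- NULL
  mat <- merged[merged$category %in% c("M", "PM"), , drop = FALSE]
  zyg <- merged[merged$category %in% c("Z", "PZ"), , drop = FALSE]
  if (nrow(mat) == 0 || nrow(zyg) == 0) {
    message("only one stage class present; rank-sum comparison skipped")
    tests <- data.frame(metric = metrics, p_value = NA_real_,
                        n_maternal = nrow(mat), n_zygotic = nrow(zyg))
  } else {
    tests <- do.call(rbind, lapply(metrics, function(m) {
      p <- suppressWarnings(stats::wilcox.test(mat[[m]], zyg[[m]])$p.value)
      if (is.na(p)) p <- 1  # fully tied data carry no signal
      data.frame(metric = m, p_value = p,
                 n_maternal = nrow(mat), n_zygotic = nrow(zyg))
    }))
  }
  list(means = means, tests = tests)
}
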