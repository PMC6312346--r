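test_that("spearman matches the rank formula and handles edge cases", {
  expect_equal(spearman_rho(c(1, 2, 3), c(2, 4, 6)), 1)
  expect_equal(spearman_rho(c(1, 2, 3), c(3, 2, 1)), -1)
  expect_equal(spearman_rho(c(1, 2, 3), c(3, 1, 2)),
               rank_formula_rho(c(1, 2, 3), c(3, 1, 2)))
  expect_equal(spearman_rho(c(1, 2, 3), c(3, 1, 2)), -0.5)
  expect_true(is.na(spearman_rho(c(2, 2, 2), c(1, 5, 3))))
})

test_that("spearman is invariant under strictly increasing transforms", {
  set.seed(33)
  for (r in 1:50) {
    x <- stats::rnorm(20); y <- stats::rnorm(20)
    rho <- spearman_rho(x, y)
    expect_equal(spearman_rho(exp(x), y), rho)
    expect_equal(spearman_rho(x, 3 * y + 7), rho)
    expect_equal(spearman_rho(log(exp(x) + 1), exp(y)), rho)
  }
})

make_aligned <- function(ref, category, s2, s5) {
  data.frame(ref_gene = ref, category = category, s2_mean = s2, s5_mean = s5,
             stringsAsFactors = FALSE)
}

test_that("category correlations respect mode and selection semantics", {
  set.seed(44)
  n <- 60
  ref <- paste0("g", 1:n)
  cat_a <- sample(c("M", "Z", "MZ"), n, TRUE)
  a <- make_aligned(ref, cat_a, stats::rlnorm(n, 2), stats::rlnorm(n, 2))
  # identical species: rho = 1 in every category with enough genes
  for (cat in c("stage2", "maternal_only", "zygotic_only")) {
    r <- pairwise_category_correlation(a, a, category = cat,
                                       mode = "shared_in_both")
    if (r$n_genes >= 2) expect_equal(r$rho, 1)
  }
  # shared_in_both is a subset of in_either
  cat_b <- sample(c("M", "Z", "MZ"), n, TRUE)
  b <- make_aligned(ref, cat_b, stats::rlnorm(n, 2), stats::rlnorm(n, 2))
  rb <- pairwise_category_correlation(a, b, "zygotic_only", "shared_in_both")
  re <- pairwise_category_correlation(a, b, "zygotic_only", "in_either")
  expect_lte(rb$n_genes, re$n_genes)
  # fewer than 2 shared genes: rho absent
  one <- make_aligned(c("g1", "g2"), c("Z", "M"), c(0, 5), c(9, 0))
  r0 <- pairwise_category_correlation(one, one, "zygotic_only", "shared_in_both")
  expect_true(is.na(r0$rho))
  expect_identical(r0$n_genes, 1L)
})

test_that("category-conserved genes correlate better than the mixed set", {
  set.seed(55)
  n <- 300
  ref <- paste0("g", 1:n)
  conserved <- seq_len(150)  # zygotic-only in both, correlated levels
  base <- stats::rlnorm(150, 3, 1)
  s5a <- s5b <- rep(0, n); cat_a <- cat_b <- rep("M", n)
  cat_a[conserved] <- "Z"; cat_b[conserved] <- "Z"
  s5a[conserved] <- base * stats::rlnorm(150, 0, 0.1)
  s5b[conserved] <- base * stats::rlnorm(150, 0, 0.1)
  # the rest is zygotic-only in exactly one species, uncorrelated
  half <- 151:225
  cat_a[half] <- "Z"; s5a[half] <- stats::rlnorm(75, 3, 1)
  s5b[half] <- stats::runif(75, 0, 0.5)
  a <- make_aligned(ref, cat_a, rep(5, n), s5a)
  b <- make_aligned(ref, cat_b, rep(5, n), s5b)
  rb <- pairwise_category_correlation(a, b, "zygotic_only", "shared_in_both")
  re <- pairwise_category_correlation(a, b, "zygotic_only", "in_either")
  expect_gt(rb$rho, re$rho)
})

test_that("correlation matrices are symmetric with unit diagonal and restrict cleanly", {
  set.seed(66)
  vals <- matrix(stats::rlnorm(400, 2, 1), 100, 4,
                 dimnames = list(NULL, paste0("c", 1:4)))
  vals[, 2] <- vals[, 1] * stats::rlnorm(100, 0, 0.05)
  corr <- correlation_matrix(vals)
  expect_equal(corr, t(corr), tolerance = 1e-12)
  expect_equal(unname(diag(corr)), rep(1, 4))
  # identical conditions correlate at 1
  two <- correlation_matrix(cbind(a = vals[, 1], b = vals[, 1]))
  expect_equal(unname(two), matrix(1, 2, 2))
  # restriction to a subset equals recomputation on the subset
  sub <- correlation_matrix(vals[, c(1, 3, 4)])
  expect_equal(corr[c(1, 3, 4), c(1, 3, 4)], sub)
})

test_that("clustering separates blocks and is label-equivariant", {
  set.seed(77)
  n <- 200
  blockA <- stats::rlnorm(n, 3, 1); blockB <- stats::rlnorm(n, 3, 1)
  jitter <- function(v) v * stats::rlnorm(n, 0, 0.05)
  vals <- cbind(a1 = jitter(blockA), a2 = jitter(blockA), a3 = jitter(blockA),
                b1 = jitter(blockB), b2 = jitter(blockB))
  h <- hierarchical_cluster(correlation_matrix(vals))
  split <- top_split(h)
  expect_length(unique(split[c("a1", "a2", "a3")]), 1)
  expect_length(unique(split[c("b1", "b2")]), 1)
  expect_false(split[["a1"]] == split[["b1"]])
  # permuting labels permutes the output only
  perm <- c(4, 2, 5, 1, 3)
  h2 <- hierarchical_cluster(correlation_matrix(vals[, perm]))
  canon <- function(x) match(x, unique(x))  # partition up to label numbering
  expect_identical(canon(top_split(h2)[colnames(vals)]),
                   canon(split[colnames(vals)]))
  expect_equal(sort(h2$height), sort(h$height))
  bad <- correlation_matrix(vals); bad[1, 2] <- 0.1
  expect_error(hierarchical_cluster(bad), "symmetric")
})

test_that("ALT conservation counting applies the two-thirds rule", {
  flags <- matrix(FALSE, 3, 14,
                  dimnames = list(c("g1", "g2", "g3"), paste0("s", 1:14)))
  flags[1, 1:10] <- TRUE
  flags[2, 1:9] <- TRUE
  flags[3, ] <- NA
  res <- alt_conservation_count(flags)
  expect_identical(res$n_alt, c(10L, 9L, 0L))
  expect_identical(res$conserved, c(TRUE, FALSE, FALSE))  # need >= ceiling(28/3) = 10
  # invariant to species order
  res2 <- alt_conservation_count(flags[, sample(14)])
  expect_identical(res2$n_alt, res$n_alt)
})

test_that("shared stage-restricted counts are bounded by each species' counts", {
  set.seed(88)
  ref <- paste0("g", 1:100)
  a <- make_aligned(ref, sample(STAGE_CATEGORIES, 100, TRUE),
                    stats::rlnorm(100), stats::rlnorm(100))
  b <- make_aligned(ref, sample(STAGE_CATEGORIES, 100, TRUE),
                    stats::rlnorm(100), stats::rlnorm(100))
  cnt <- shared_stage_restricted_counts(a, b)
  expect_lte(cnt[["maternal_only"]],
             min(sum(a$category == "M"), sum(b$category == "M")))
  expect_lte(cnt[["zygotic_only"]],
             min(sum(a$category == "Z"), sum(b$category == "Z")))
  same <- shared_stage_restricted_counts(a, a)
  expect_identical(same[["maternal_only"]], sum(a$category == "M"))
  disjoint <- shared_stage_restricted_counts(
    make_aligned(ref[1:4], c("M", "M", "Z", "Z"), 1, 1),
    make_aligned(ref[1:4], c("Z", "Z", "M", "M"), 1, 1))
  expect_identical(unname(disjoint), c(0L, 0L))
})

test_that("interspecific correlation decays with patristic distance", {
  sim <- sim_small()
  sp <- sim$tree$tip.label
  # stage-2 gene-level means per species on all groups (truth-side means)
  m2 <- vapply(sp, function(s) sim$gene_means[[s]][, "s2"],
               numeric(sim$config$n_genes))
  pd <- ape::cophenetic.phylo(sim$tree)
  pairs <- utils::combn(sp, 2)
  rho <- dist <- numeric(ncol(pairs))
  for (k in seq_len(ncol(pairs))) {
    rho[k] <- spearman_rho(m2[, pairs[1, k]], m2[, pairs[2, k]])
    dist[k] <- pd[pairs[1, k], pairs[2, k]]
  }
  expect_lt(stats::cor(rho, dist, method = "spearman"), 0)
})
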