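test_that("presence threshold is inclusive at the boundary", {
  expect_true(is_present(1.0, 1))
  expect_false(is_present(0.99, 1))
  expect_false(is_present(0, 1))
  expect_error(is_present(-0.1, 1))
})

test_that("six-way classification follows the definitional rules", {
  cases <- list(
    # s2, s5, q, expected
    list(5.0, 0.3, NA, "M"),
    list(10.0, 4.0, 0.01, "PM"),   # ratio 2.5, significant
    list(10.0, 6.0, 0.01, "MZ"),   # ratio < 2
    list(3.0, 9.0, 0.2, "MZ"),     # not significant
    list(3.0, 9.0, 0.01, "PZ"),
    list(0.2, 0.4, NA, "N"),
    list(0.0, 2.2, NA, "Z"),
    list(2.0, 1.0, 0.01, "PM"),    # ratio exactly 2 counts
    list(2.0, 1.0, NA, "MZ")       # untestable can never be predominant
  )
  for (cs in cases) {
    expect_identical(classify_feature(cs[[1]], cs[[2]], cs[[3]]), cs[[4]])
  }
})

test_that("classification is total and stage-swap symmetric", {
  set.seed(20)
  n <- 2000
  s2 <- stats::rlnorm(n, 0, 2) * stats::rbinom(n, 1, 0.8)
  s5 <- stats::rlnorm(n, 0, 2) * stats::rbinom(n, 1, 0.8)
  q <- ifelse(stats::runif(n) < 0.3, NA, stats::runif(n))
  fwd <- classify_feature(s2, s5, q)
  expect_true(all(fwd %in% STAGE_CATEGORIES))
  expect_length(fwd, n)
  swapped <- classify_feature(s5, s2, q)
  mapping <- c(M = "Z", Z = "M", PM = "PZ", PZ = "PM", MZ = "MZ", N = "N")
  expect_identical(swapped, unname(mapping[fwd]))
})

test_that("stage significance: strong separation is significant, no signal is not", {
  s2 <- rbind(a = c(100, 110, 90), b = c(5, 5.5, 4.5))
  s5 <- rbind(a = c(1, 1.2, 0.9), b = c(5, 5.5, 4.5))
  res <- stage_significance(s2, s5)
  expect_lt(res$q_value[1], 0.05)
  expect_gt(res$q_value[2], 0.5)
  # identical replicate sets: p = 1
  same <- matrix(c(3, 4, 5), 1)
  expect_equal(stage_significance(same, same)$p_value, 1)
  # fewer than 2 replicates at a stage: q absent
  one <- stage_significance(matrix(c(9, 10), 1), matrix(5, 1))
  expect_true(is.na(one$q_value))
})

test_that("exact permutation test matches enumeration over all assignments", {
  x <- c(100, 110, 90); y <- c(1, 1.2, 0.9)
  res <- stage_significance(matrix(x, 1), matrix(y, 1), method = "permutation")
  expect_equal(res$p_value, enum_permutation_p(x, y))
  expect_equal(res$p_value, 2 / 20)  # complete separation, 20 assignments
  set.seed(31)
  for (r in 1:5) {
    x <- stats::rlnorm(4, 2, 1); y <- stats::rlnorm(3, 2.5, 1)
    got <- stage_significance(matrix(x, 1), matrix(y, 1),
                              method = "permutation")$p_value
    expect_equal(got, enum_permutation_p(x, y), tolerance = 1e-12)
  }
})

test_that("ALT detection requires a maternal-class and a zygotic-class isoform", {
  expect_true(detect_alt(c("M", "Z")))
  expect_true(detect_alt(c("PM", "PZ")))
  expect_true(detect_alt(c("M", "MZ", "PZ")))
  expect_false(detect_alt(c("M", "MZ")))
  expect_false(detect_alt(c("PM", "M")))
  expect_false(detect_alt("Z"))
  # monotone: adding a call never flips true -> false
  set.seed(8)
  for (r in 1:200) {
    calls <- sample(STAGE_CATEGORIES, sample(1:5, 1), replace = TRUE)
    if (detect_alt(calls)) {
      expect_true(detect_alt(c(calls, sample(STAGE_CATEGORIES, 1))))
    }
  }
})

test_that("unique representation needs one high species and silent others", {
  cfg <- classifier_config()
  row <- c(a = 5.0, b = 0.2, c = 0.1, d = 0.4)
  expect_identical(unique_representation(row, cfg), "a")
  expect_true(is.na(unique_representation(c(a = 2, b = .5, c = .1, d = .2), cfg)))
  expect_true(is.na(unique_representation(c(a = 5, b = 1.5, c = .2, d = .1), cfg)))
  expect_identical(unique_representation(c(a = 3.5, b = NA, c = 0.2), cfg), "a")
  # exactly 3 is not "over three times the threshold"
  expect_true(is.na(unique_representation(c(a = 3.0, b = 0.1), cfg)))
  # never returns a species when two or more are present
  set.seed(12)
  for (r in 1:300) {
    row <- stats::rlnorm(6, 0, 2)
    names(row) <- letters[1:6]
    if (sum(row >= cfg$presence_threshold) >= 2) {
      expect_true(is.na(unique_representation(row, cfg)))
    }
  }
})

test_that("Fisher enrichment p matches hypergeometric enumeration", {
  flat <- category_enrichment(counts = matrix(c(10, 10, 10, 10), 2))
  expect_equal(flat$odds_ratio, 1)
  expect_equal(flat$p_value, 1)
  strong <- category_enrichment(counts = matrix(c(12, 2, 3, 13), 2, byrow = TRUE))
  expect_equal(strong$p_value, enum_fisher_p(12, 2, 3, 13), tolerance = 1e-12)
  disjoint <- category_enrichment(counts = matrix(c(0, 10, 10, 0), 2, byrow = TRUE))
  expect_lt(disjoint$p_value, 0.001)
  expect_equal(disjoint$p_value, enum_fisher_p(0, 10, 10, 0), tolerance = 1e-12)
  expect_true(disjoint$continuity)
  # empty margin warns and returns p = 1
  expect_warning(deg <- category_enrichment(counts = matrix(c(0, 0, 5, 5), 2,
                                                            byrow = TRUE)),
                 "margin")
  expect_equal(deg$p_value, 1)
  # vector interface builds the same table
  sub <- c(TRUE, TRUE, FALSE, FALSE, TRUE)
  cat <- c(TRUE, FALSE, TRUE, FALSE, TRUE)
  ce <- category_enrichment(sub, cat)
  expect_identical(unname(ce$table[1, 1]), 2L)
})

test_that("structure summaries separate long maternal from short zygotic genes", {
  rec <- data.frame(gene_id = paste0("g", 1:20),
                    exon_count = c(11:20, 1:10),
                    exonic_length = c(3001:3010, 301:310),
                    intronic_length = c(5001:5010, 101:110))
  calls <- data.frame(feature_id = paste0("g", 1:20),
                      category = c(rep("M", 5), rep("PM", 5),
                                   rep("Z", 5), rep("PZ", 5)))
  s <- structure_summary(rec, calls)
  expect_true(all(s$tests$p_value < 0.01))
  # complete separation at 10 vs 10: exact rank-sum p = 2 / choose(20, 10)
  expect_equal(s$tests$p_value[1], 2 / choose(20, 10), tolerance = 1e-10)
  expect_equal(s$means$exon_count[s$means$category == "M"], mean(11:15))
  # identical records across categories: p in the no-signal region
  rec2 <- rec; rec2$exon_count <- 4L
  rec2$exonic_length <- 1000; rec2$intronic_length <- 500
  s2 <- structure_summary(rec2, calls)
  expect_true(all(s2$tests$p_value == 1))
  # single class present: comparison skipped with a notice
  expect_message(
    s3 <- structure_summary(rec, transform(calls, category = "M")),
    "skipped")
  expect_true(all(is.na(s3$tests$p_value)))
})
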