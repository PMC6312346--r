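test_that("transition probabilities are a proper stochastic matrix", {
  m <- mk_model(0.7, 0.3)
  for (t in c(0, 0.01, 1, 50)) {
    P <- mk_transition(m, t)
    expect_equal(unname(rowSums(P)), c(1, 1))
    expect_true(all(P >= 0))
  }
  expect_equal(unname(mk_transition(m, 0)), diag(2))
  # long-branch limit is the stationary distribution in both rows
  Pinf <- mk_transition(m, 1e6)
  expect_equal(unname(Pinf[1, ]), m$root_prior, tolerance = 1e-12)
  expect_equal(unname(Pinf[2, ]), m$root_prior, tolerance = 1e-12)
})

test_that("pruning likelihood matches brute-force enumeration", {
  set.seed(91)
  tr <- ape::rtree(3)
  tr$tip.label <- c("a", "b", "c")
  for (r in 1:20) {
    mod <- mk_model(stats::runif(1, 0.05, 3), stats::runif(1, 0.05, 3))
    st <- stats::setNames(sample(0:1, 3, TRUE), tr$tip.label)
    b <- brute_marginals(tr, st, mod)
    expect_equal(pruning_likelihood(tr, st, mod), b$loglik, tolerance = 1e-12)
  }
  # degenerate single-branch intuition: all zero-length branches with
  # mixed tip states are impossible data
  tr0 <- quartet_tree()
  tr0$edge.length[] <- 0
  st <- c(a = 1, b = 1, c = 0, d = 0)
  expect_identical(pruning_likelihood(tr0, st, mk_model(1, 1)), -Inf)
  # and with identical tips the likelihood collapses to the root prior
  st1 <- c(a = 1, b = 1, c = 1, d = 1)
  mod <- mk_model(2, 1)
  expect_equal(pruning_likelihood(tr0, st1, mod), log(mod$root_prior[2]))
  expect_error(pruning_likelihood(tr0, c(a = NA, b = NA, c = NA, d = NA), mod),
               "unknown")
})

test_that("marginal posteriors equal enumeration on random instances", {
  set.seed(92)
  worst <- 0
  for (r in 1:100) {
    ntp <- sample(3:6, 1)
    tr <- ape::rtree(ntp)
    tr$tip.label <- paste0("t", seq_len(ntp))
    mod <- mk_model(stats::runif(1, 0.05, 3), stats::runif(1, 0.05, 3))
    st <- sample(c(0, 1, NA), ntp, TRUE, prob = c(0.4, 0.4, 0.2))
    names(st) <- tr$tip.label
    if (all(is.na(st))) st[1] <- 1
    post <- marginal_posteriors(tr, st, mod)
    oracle <- brute_marginals(tr, st, mod)
    worst <- max(worst, max(abs(post$P1 - oracle$post1[post$node])))
    expect_equal(post$P0 + post$P1, rep(1, nrow(post)), tolerance = 1e-12)
  }
  expect_lt(worst, 1e-10)
})

test_that("posterior limits: zero branches fix the tree, long branches forget", {
  tr <- quartet_tree()
  mod <- mk_model(1.2, 0.6)
  tr0 <- tr; tr0$edge.length[] <- 1e-9
  post <- marginal_posteriors(tr0, c(a = 1, b = 1, c = 1, d = 1), mod)
  expect_true(all(post$P1 > 1 - 1e-6))
  trL <- tr; trL$edge.length[] <- 1e4
  postL <- marginal_posteriors(trL, c(a = 1, b = 0, c = 1, d = 0), mod)
  internal <- grepl("^n", postL$node)
  expect_equal(postL$P1[internal], rep(mod$root_prior[2], sum(internal)),
               tolerance = 1e-6)
  # observed tips keep posterior 1 on their state; unknown tips get a marginal
  postU <- marginal_posteriors(tr, c(a = 1, b = NA, c = 0, d = 0), mod)
  expect_equal(postU$P1[postU$node == "a"], 1)
  expect_equal(postU$P1[postU$node == "c"], 0)
  expect_true(postU$P1[postU$node == "b"] > 0 &&
                postU$P1[postU$node == "b"] < 1)
})

test_that("likelihood and posteriors are invariant to rate/length rescaling", {
  set.seed(93)
  tr <- ape::rtree(6)
  tr$tip.label <- paste0("t", 1:6)
  st <- stats::setNames(sample(0:1, 6, TRUE), tr$tip.label)
  mod <- mk_model(0.8, 0.4)
  for (cc in c(0.1, 3, 42)) {
    tr2 <- tr; tr2$edge.length <- tr$edge.length / cc
    mod2 <- mk_model(0.8 * cc, 0.4 * cc)
    expect_equal(pruning_likelihood(tr, st, mod),
                 pruning_likelihood(tr2, st, mod2), tolerance = 1e-12)
    expect_equal(marginal_posteriors(tr, st, mod)$P1,
                 marginal_posteriors(tr2, st, mod2)$P1, tolerance = 1e-12)
  }
})

test_that("rate fitting recovers simulation rates within 20%", {
  sim <- simulate_presence(default_tree(), q01 = 0.5, q10 = 1.0, n = 2000,
                           seed = 94)
  fit <- fit_rates(sim$tip_states, default_tree())
  expect_lt(abs(fit$q01 - 0.5) / 0.5, 0.2)
  expect_lt(abs(fit$q10 - 1.0) / 1.0, 0.2)
  expect_equal(fit$root_prior[2], fit$q01 / (fit$q01 + fit$q10))
  # all-constant characters push the loss rate to the lower bound
  const <- matrix(1, 50, 14,
                  dimnames = list(NULL, default_tree()$tip.label))
  expect_warning(fit0 <- fit_rates(const, default_tree()), "bound")
  expect_lt(fit0$q10, 1e-5)
})

test_that("gain/loss calling follows the 90/90 adjacent-node rule", {
  tr <- quartet_tree()
  ids <- node_ids(tr)
  P1 <- matrix(0.5, 3, length(ids), dimnames = list(paste0("ch", 1:3), ids))
  # ch1: root absent, node n6 (parent of a,b) present -> gain on n5->n6
  P1["ch1", ] <- c(1, 1, 0, 0, 0.05, 0.95, 0.02)
  # ch2: same branch but child below threshold -> no call
  P1["ch2", ] <- c(1, 1, 0, 0, 0.05, 0.85, 0.02)
  # ch3: loss on a terminal branch n7->c
  P1["ch3", ] <- c(1, 1, 0, 1, 0.95, 0.95, 0.93)
  states <- matrix(c(1, 1, 0, 0,
                     1, 1, 0, 0,
                     1, 1, 0, 1), 3, byrow = TRUE,
                   dimnames = list(paste0("ch", 1:3), c("a", "b", "c", "d")))
  ev <- call_transitions(P1, tr, states, threshold = 0.9)
  e1 <- ev[ev$character == "ch1" & ev$parent == "n5" & ev$child == "n6", ]
  expect_identical(e1$direction, "gain")
  expect_false(any(ev$character == "ch2" & ev$parent == "n5" & ev$child == "n6"))
  e3 <- ev[ev$character == "ch3" & ev$child == "c", ]
  expect_identical(e3$direction, "loss")
  # raising the threshold never increases the number of events
  set.seed(95)
  Pr <- matrix(stats::runif(20 * length(ids)), 20,
               dimnames = list(paste0("r", 1:20), ids))
  str <- matrix(sample(0:1, 20 * 4, TRUE), 20,
                dimnames = list(paste0("r", 1:20), c("a", "b", "c", "d")))
  last <- Inf
  for (thr in c(0.5, 0.7, 0.9, 0.99)) {
    n_ev <- nrow(call_transitions(Pr, tr, str, threshold = thr))
    expect_lte(n_ev, last)
    last <- n_ev
  }
  # terminal branches can be excluded
  ev_int <- call_transitions(P1, tr, states, threshold = 0.9,
                             include_terminal = FALSE)
  expect_false(any(ev_int$child %in% c("a", "b", "c", "d")))
})

test_that("Fitch parsimony matches textbook cases and brute force", {
  tr <- quartet_tree()
  expect_identical(fitch_parsimony(tr, c(a = 1, b = 1, c = 1, d = 1))$count, 0L)
  expect_identical(fitch_parsimony(tr, c(a = 1, b = 1, c = 0, d = 0))$count, 1L)
  expect_identical(fitch_parsimony(tr, c(a = 1, b = 0, c = 1, d = 0))$count, 2L)
  set.seed(96)
  tr6 <- ape::rtree(6)
  tr6$tip.label <- paste0("t", 1:6)
  for (r in 1:40) {
    st <- sample(c(0, 1, NA), 6, TRUE, prob = c(0.4, 0.4, 0.2))
    names(st) <- tr6$tip.label
    if (all(is.na(st))) st[1] <- 0
    expect_identical(fitch_parsimony(tr6, st)$count,
                     as.integer(brute_parsimony(tr6, st)))
    expect_identical(mpr_state_sets(tr6, st)$count,
                     as.integer(brute_parsimony(tr6, st)))
  }
})

test_that("MAP states approach Fitch sets in the low-rate limit", {
  set.seed(97)
  tr <- ape::rtree(6)
  tr$tip.label <- paste0("t", 1:6)
  height <- max(ape::node.depth.edgelength(tr))
  rate <- 1e-4 / height
  mod <- mk_model(rate, rate)
  agree <- logical(200)
  for (r in 1:200) {
    st <- stats::setNames(sample(0:1, 6, TRUE), tr$tip.label)
    post <- marginal_posteriors(tr, st, mod)
    mpr <- mpr_state_sets(tr, st)
    unique_nodes <- rowSums(mpr$sets) == 1
    map_state <- as.numeric(post$P1[match(rownames(mpr$sets), post$node)] > 0.5)
    mp_state <- as.numeric(mpr$sets[, "1"])
    agree[r] <- all(map_state[unique_nodes] == mp_state[unique_nodes])
  }
  expect_gte(mean(agree), 0.99)
})

test_that("posterior calls at 0.9 match simulated truth on the study tree", {
  tree <- default_tree()
  sim <- simulate_presence(tree, 0.5, 0.1534, n = 600, seed = 98)
  mod <- fit_rates(sim$tip_states, tree)
  P1 <- marginal_posteriors(tree, sim$tip_states, mod)
  internal <- grepl("^n", colnames(P1))
  truth <- sim$node_states[, colnames(P1)[internal], drop = FALSE]
  Pint <- P1[, internal, drop = FALSE]
  calls <- (Pint >= 0.9 & truth == 1) | ((1 - Pint) >= 0.9 & truth == 0)
  n_called <- sum(Pint >= 0.9) + sum((1 - Pint) >= 0.9)
  expect_gte(sum(calls) / n_called, 0.85)
})

test_that("called transitions recover true branch events with high sensitivity", {
  tree <- default_tree()
  cfg <- simulation_config(n_genes = 1000, seed = 99)
  sim <- simulate_presence(tree, cfg$q01, cfg$q10, n = cfg$n_genes)
  states <- sim$tip_states
  rownames(states) <- sprintf("g%04d|stage2", seq_len(nrow(states)))
  mod <- fit_rates(states, tree)
  P1 <- marginal_posteriors(tree, states, mod)
  ev <- call_transitions(P1, tree, states, threshold = 0.9)
  truth <- true_transitions(
    list(tip_states = list(stage2 = sim$tip_states),
         node_states = list(stage2 = sim$node_states)),
    tree, sprintf("g%04d", seq_len(nrow(states))))
  truth <- truth[grepl("stage2", truth$character), ]
  # restrict to true events whose reconstructed endpoint posteriors are
  # both confident
  ids <- node_ids(tree)
  full_truth <- cbind(sim$tip_states, sim$node_states)[, ids]
  conf <- logical(nrow(truth))
  for (i in seq_len(nrow(truth))) {
    g <- truth$character[i]
    pP <- P1[g, truth$parent[i]]; cP <- P1[g, truth$child[i]]
    conf[i] <- if (truth$direction[i] == "gain") {
      (1 - pP) >= 0.9 && cP >= 0.9
    } else {
      pP >= 0.9 && (1 - cP) >= 0.9
    }
  }
  key <- function(d) paste(d$character, d$parent, d$child, d$direction)
  found <- key(truth[conf, ]) %in% key(ev)
  expect_gte(mean(found), 0.8)
})
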