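# Shared fixture builders and independent oracles for the test suite.
# Oracles are deliberately naive (enumeration / closed formulas) and share
# no code with the implementation paths they check.

make_expr <- function(values, species = "spA",
                      stages = rep(c("stage2", "stage5"),
                                   each = ncol(values) / 2)) {
  ids <- sprintf("%s_%s_r%d", species, stages,
                 stats::ave(seq_along(stages), stages, FUN = seq_along))
  colnames(values) <- ids
  samples <- data.frame(sample_id = ids, species = species, stage = stages,
                        replicate = stats::ave(seq_along(stages), stages,
                                               FUN = seq_along))
  expression_table(values, samples)
}

quartet_tree <- function() {
  validate_tree(ape::read.tree(text = "((a:1,b:1):1,(c:1,d:1):1);"))
}

# Brute-force marginal posteriors and likelihood: sum over every joint
# assignment of states to all nodes.
brute_marginals <- function(tree, states, model) {
  tree <- ape::reorder.phylo(tree, "postorder")
  ntip <- length(tree$tip.label)
  nn <- ntip + tree$Nnode
  states <- states[tree$tip.label]
  P <- lapply(seq_len(nrow(tree$edge)),
              function(e) mk_transition(model, tree$edge.length[e]))
  combos <- as.matrix(expand.grid(rep(list(0:1), nn)))
  lik <- apply(combos, 1, function(a) {
    for (i in seq_len(ntip)) {
      if (!is.na(states[i]) && a[i] != states[i]) return(0)
    }
    p <- model$root_prior[a[ntip + 1] + 1]
    for (e in seq_len(nrow(tree$edge))) {
      p <- p * P[[e]][a[tree$edge[e, 1]] + 1, a[tree$edge[e, 2]] + 1]
    }
    p
  })
  post1 <- vapply(seq_len(nn), function(i) {
    sum(lik[combos[, i] == 1]) / sum(lik)
  }, numeric(1))
  names(post1) <- node_ids(tree)
  list(post1 = post1, loglik = log(sum(lik)))
}

# Exhaustive minimum-change count over all internal-state assignments
# (parsimony oracle); unknown tips may take either state.
brute_parsimony <- function(tree, states) {
  tree <- ape::reorder.phylo(tree, "postorder")
  ntip <- length(tree$tip.label)
  nn <- ntip + tree$Nnode
  states <- states[tree$tip.label]
  free <- which(is.na(states))
  fixed_tips <- states
  combos <- as.matrix(expand.grid(rep(list(0:1), tree$Nnode + length(free))))
  best <- Inf
  for (r in seq_len(nrow(combos))) {
    a <- numeric(nn)
    a[seq_len(ntip)] <- fixed_tips
    if (length(free)) a[free] <- combos[r, tree$Nnode + seq_along(free)]
    a[(ntip + 1):nn] <- combos[r, seq_len(tree$Nnode)]
    changes <- sum(a[tree$edge[, 1]] != a[tree$edge[, 2]])
    best <- min(best, changes)
  }
  best
}

# Two-sided Fisher exact p by explicit enumeration of all tables with the
# observed margins, using binomial coefficients directly.
enum_fisher_p <- function(a, b, c, d) {
  m <- a + b; n <- c + d; k <- a + c
  lo <- max(0, k - n); hi <- min(k, m)
  logp <- function(x) {
    lchoose(m, x) + lchoose(n, k - x) - lchoose(m + n, k)
  }
  probs <- exp(vapply(lo:hi, logp, numeric(1)))
  obs <- exp(logp(a))
  sum(probs[probs <= obs * (1 + 1e-7)])
}

# Spearman via the classical rank formula (no ties):
# rho = 1 - 6 * sum(d^2) / (n (n^2 - 1))
rank_formula_rho <- function(x, y) {
  d <- rank(x) - rank(y)
  n <- length(x)
  1 - 6 * sum(d^2) / (n * (n^2 - 1))
}

# Exact permutation p for |mean diff| of log2(x + 1), enumerating every
# split of the pooled values.
enum_permutation_p <- function(x, y) {
  lx <- log2(x + 1); ly <- log2(y + 1)
  pooled <- c(lx, ly)
  n <- length(pooled); k <- length(lx)
  obs <- abs(mean(lx) - mean(ly))
  idx <- utils::combn(n, k)
  stat <- apply(idx, 2, function(ii) {
    abs(mean(pooled[ii]) - mean(pooled[-ii]))
  })
  mean(stat >= obs - 1e-12)
}

# Small simulated dataset cached per test session (noisy defaults).
sim_small <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- simulate_dataset(simulation_config(n_genes = 250, seed = 101))
    }
    cache
  }
})

strip_species <- function(ids, sp) sub(paste0(sp, "|"), "", ids, fixed = TRUE)
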