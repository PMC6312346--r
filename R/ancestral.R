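#' Two-state Markov model of transcript presence
#'
#' Continuous-time Markov model on states {0 = absent, 1 = present} with
#' gain rate `q01` and loss rate `q10` per unit branch length. The root
#' prior defaults to the stationary distribution of the rates,
#' (q10, q01) / (q01 + q10).
#'
#' @param q01 Rate of 0 -> 1 transitions, > 0.
#' @param q10 Rate of 1 -> 0 transitions, > 0.
#' @param root_prior Optional length-2 probability vector (pi0, pi1).
#' @return Object of class `mk_model`.
#' @export
mk_model <- function(q01, q10, root_prior = NULL) {
  stopifnot(is.finite(q01), is.finite(q10), q01 > 0, q10 > 0)
  if (is.null(root_prior)) {
    root_prior <- c(q10, q01) / (q01 + q10)
  }
  stopifnot(length(root_prior) == 2, all(root_prior >= 0),
            abs(sum(root_prior) - 1) < 1e-9)
  structure(list(q01 = q01, q10 = q10, root_prior = root_prior),
            class = "mk_model")
}

#' @export
print.mk_model <- function(x, ...) {
  cat(sprintf("mk_model: q01 = %.6g, q10 = %.6g, root prior = (%.4f, %.4f)\n",
              x$q01, x$q10, x$root_prior[1], x$root_prior[2]))
  invisible(x)
}

#' Transition probability matrix over a branch
#'
#' Closed form for the 2-state chain: with r = q01 + q10 and
#' e = exp(-r t), P(0->1) = q01 (1 - e) / r and P(1->0) = q10 (1 - e) / r.
#'
#' @param model An [mk_model()].
#' @param t Branch length >= 0.
#' @return 2x2 matrix indexed `[from + 1, to + 1]`.
#' @export
mk_transition <- function(model, t) {
  r <- model$q01 + model$q10
  e <- exp(-r * t)
  p01 <- model$q01 * (1 - e) / r
  p10 <- model$q10 * (1 - e) / r
  matrix(c(1 - p01, p10, p01, 1 - p10), nrow = 2,
         dimnames = list(c("0", "1"), c("0", "1")))
}

# Internal engine shared by the likelihood and marginal computations.
#
# states: n_char x n_tips matrix of 0/1/NA, columns matched to
# tree$tip.label. Runs Felsenstein's pruning (up) pass for all characters
# at once, and optionally the outside (down) pass giving exact marginal
# state posteriors at every node. Partial likelihoods are rescaled per
# node to avoid underflow; the log scaling factors are accumulated into
# the log-likelihood.
mk_engine <- function(tree, states, model, posteriors = FALSE) {
  tree <- ape::reorder.phylo(tree, "postorder")
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  edge <- tree$edge
  elen <- tree$edge.length
  n <- nrow(states)
  if (ncol(states) != ntip) stop("states must have one column per tip")
  ord <- match(tree$tip.label, colnames(states))
  if (anyNA(ord)) stop("tip label(s) missing from states: ",
                       paste(setdiff(tree$tip.label, colnames(states)), collapse = ", "))
  states <- states[, ord, drop = FALSE]
  all_unknown <- rowSums(!is.na(states)) == 0
  if (any(all_unknown)) {
    stop("character(s) with all tips unknown: ",
         paste(utils::head(rownames(states)[all_unknown], 5), collapse = ", "))
  }

  L <- vector("list", nnode)
  logs <- vector("list", nnode)
  for (i in seq_len(ntip)) {
    s <- states[, i]
    Li <- cbind(ifelse(is.na(s), 1, as.numeric(s == 0)),
                ifelse(is.na(s), 1, as.numeric(s == 1)))
    L[[i]] <- Li
    logs[[i]] <- numeric(n)
  }
  for (i in (ntip + 1):nnode) {
    L[[i]] <- matrix(1, n, 2)
    logs[[i]] <- numeric(n)
  }

  P <- lapply(seq_len(nrow(edge)), function(e) mk_transition(model, elen[e]))
  D <- vector("list", nrow(edge))

  for (e in seq_len(nrow(edge))) {
    par <- edge[e, 1]; chi <- edge[e, 2]
    D[[e]] <- L[[chi]] %*% t(P[[e]])
    L[[par]] <- L[[par]] * D[[e]]
    logs[[par]] <- logs[[par]] + logs[[chi]]
    m <- pmax(L[[par]][, 1], L[[par]][, 2])
    ok <- m > 0
    L[[par]][ok, ] <- L[[par]][ok, , drop = FALSE] / m[ok]
    logs[[par]][ok] <- logs[[par]][ok] + log(m[ok])
    logs[[par]][!ok] <- -Inf
  }

  root <- ntip + 1L
  pi <- model$root_prior
  rootsum <- L[[root]] %*% pi
  loglik <- ifelse(rootsum > 0, log(rootsum) + logs[[root]], -Inf)

  out <- list(loglik = as.numeric(loglik), tree = tree, states = states)
  if (posteriors) {
    U <- vector("list", nnode)
    U[[root]] <- matrix(pi, n, 2, byrow = TRUE)
    kids <- split(seq_len(nrow(edge)), edge[, 1])
    for (e in rev(seq_len(nrow(edge)))) {
      par <- edge[e, 1]; chi <- edge[e, 2]
      sib <- matrix(1, n, 2)
      for (e2 in kids[[as.character(par)]]) {
        if (e2 != e) sib <- sib * D[[e2]]
      }
      A <- U[[par]] * sib
      Uc <- A %*% P[[e]]
      m <- pmax(Uc[, 1], Uc[, 2])
      ok <- m > 0
      Uc[ok, ] <- Uc[ok, , drop = FALSE] / m[ok]
      U[[chi]] <- Uc
    }
    P1 <- matrix(NA_real_, n, nnode)
    for (i in seq_len(nnode)) {
      post <- L[[i]] * U[[i]]
      rs <- post[, 1] + post[, 2]
      P1[, i] <- ifelse(rs > 0, post[, 2] / rs, NA_real_)
    }
    rownames(P1) <- rownames(states)
    colnames(P1) <- node_ids(tree)
    out$P1 <- P1
  }
  out
}

#' Deterministic node identifiers
#'
#' Tips keep their labels; internal nodes are numbered `n<k>` following
#' the tree's internal numbering (root = `n<ntip+1>`). Used consistently
#' in posteriors, events and the annotated newick the pipeline writes.
#'
#' @param tree A `phylo` object.
#' @return Character vector of length `ntip + Nnode`.
#' @export
node_ids <- function(tree) {
  ntip <- length(tree$tip.label)
  c(tree$tip.label, paste0("n", (ntip + 1):(ntip + tree$Nnode)))
}

#' Log-likelihood of binary characters on a tree
#'
#' Felsenstein pruning over the 2-state model. Unknown tip states
#' contribute a partial likelihood of (1, 1). Impossible data (e.g.
#' conflicting states across zero-length branches) yield `-Inf`.
#'
#' @param tree Rooted `phylo` with branch lengths.
#' @param char Named 0/1/`NA` vector over tips, or an n x ntip matrix for
#'   many characters.
#' @param model An [mk_model()].
#' @return Log-likelihood (vector when `char` is a matrix).
#' @export
pruning_likelihood <- function(tree, char, model) {
  states <- as_state_matrix(char, tree)
  mk_engine(tree, states, model)$loglik
}

as_state_matrix <- function(char, tree) {
  if (is.matrix(char)) return(char)
  if (is.null(names(char))) {
    if (length(char) != length(tree$tip.label)) stop("unnamed character of wrong length")
    names(char) <- tree$tip.label
  }
  matrix(char[tree$tip.label], nrow = 1,
         dimnames = list("char", tree$tip.label))
}

#' Marginal ancestral state posteriors
#'
#' Exact marginal probability of state 1 at every node (tips included),
#' by the standard up-down (inside-outside) pass. Tips with an observed
#' state get posterior 1 on that state; unknown tips get their marginal
#' given the rest of the data.
#'
#' @inheritParams pruning_likelihood
#' @return For a single character, a data frame `node, P0, P1`
#'   (nodes ordered as [node_ids()]); for a matrix of characters, a
#'   matrix of P1 values, characters x nodes.
#' @export
marginal_posteriors <- function(tree, char, model) {
  single <- !is.matrix(char)
  states <- as_state_matrix(char, tree)
  P1 <- mk_engine(tree, states, model, posteriors = TRUE)$P1
  if (single) {
    data.frame(node = colnames(P1), P0 = 1 - P1[1, ], P1 = P1[1, ],
               row.names = NULL, stringsAsFactors = FALSE)
  } else {
    P1
  }
}

#' Fit gain and loss rates by maximum likelihood
#'
#' Maximises the summed pruning log-likelihood over all characters of a
#' stage, with a single (q01, q10) pair shared across characters
#' (single-character data cannot identify per-character rates). Rates are
#' bounded in [1e-6, 1e3]; hitting a bound raises a warning. The root
#' prior of the returned model is the stationary distribution of the
#' fitted rates (empirical Bayes; no free root parameter).
#'
#' @param m A [character_matrix()] (or plain 0/1/NA matrix, characters x
#'   species).
#' @param tree Rooted `phylo` with branch lengths; tips must match the
#'   matrix columns.
#' @param stage Optional stage filter (`"stage2"` or `"stage5"`) applied
#'   when `m` is a `character_matrix`.
#' @param init Starting rates.
#' @return Fitted [mk_model()] with attributes `loglik`, `convergence`
#'   and `n_characters`.
#' @export
fit_rates <- function(m, tree, stage = NULL, init = c(0.5, 0.5)) {
  states <- if (inherits(m, "character_matrix")) {
    if (!is.null(stage)) m$states[m$stage == stage, , drop = FALSE] else m$states
  } else m
  if (nrow(states) < 2) stop("need at least 2 characters to fit rates")
  # collapse identical site patterns for speed
  key <- apply(states, 1, function(r) paste(ifelse(is.na(r), "?", r), collapse = ""))
  first <- !duplicated(key)
  pat <- states[first, , drop = FALSE]
  w <- as.numeric(table(key)[key[first]])

  lb <- log(1e-6); ub <- log(1e3)
  nll <- function(par) {
    mod <- mk_model(exp(par[1]), exp(par[2]))
    ll <- mk_engine(tree, pat, mod)$loglik
    if (any(!is.finite(ll))) return(1e10)
    -sum(w * ll)
  }
  fit <- stats::optim(log(init), nll, method = "L-BFGS-B",
                      lower = lb, upper = ub)
  at_bound <- any(abs(fit$par - lb) < 1e-4) || any(abs(fit$par - ub) < 1e-4)
  if (at_bound) warning("rate estimate at optimisation bound")
  model <- mk_model(exp(fit$par[1]), exp(fit$par[2]))
  attr(model, "loglik") <- -fit$value
  attr(model, "convergence") <- fit$convergence
  attr(model, "n_characters") <- nrow(states)
  attr(model, "at_bound") <- at_bound
  model
}

#' Call gains and losses of representation on branches
#'
#' For every parent-to-child branch, a gain is called when the parent is
#' absent (P0 at or above `threshold`) and the child present (P1 at or
#' above `threshold`); a loss is the mirror image. At most one event per
#' branch per character. Observed tips count with posterior 1 on their
#' state; branches ending in an unknown tip are skipped, as are all
#' terminal branches when `include_terminal = FALSE`.
#'
#' @param P1 Posterior matrix from [marginal_posteriors()] (characters x
#'   nodes, columns named as [node_ids()]).
#' @param tree The tree the posteriors were computed on.
#' @param states The tip-state matrix (used to skip unknown-tip branches).
#' @param threshold Posterior probability required at both branch ends
#'   (default 0.90).
#' @param include_terminal Call events on terminal branches (default TRUE).
#' @return Data frame
#'   `character, parent, child, direction, parent_P, child_P`.
#' @export
call_transitions <- function(P1, tree, states = NULL, threshold = 0.9,
                             include_terminal = TRUE) {
  if (!is.matrix(P1)) stop("P1 must be the characters x nodes posterior matrix")
  ids <- node_ids(tree)
  ntip <- length(tree$tip.label)
  res <- list()
  for (e in seq_len(nrow(tree$edge))) {
    par <- tree$edge[e, 1]; chi <- tree$edge[e, 2]
    is_tip <- chi <= ntip
    if (is_tip && !include_terminal) next
    pP1 <- P1[, par]; cP1 <- P1[, chi]
    skip <- rep(FALSE, nrow(P1))
    if (is_tip && !is.null(states)) {
      skip <- is.na(states[, match(ids[chi], colnames(states))])
    }
    gain <- !skip & (1 - pP1) >= threshold & cP1 >= threshold
    loss <- !skip & pP1 >= threshold & (1 - cP1) >= threshold
    for (dir in c("gain", "loss")) {
      hit <- if (dir == "gain") gain else loss
      hit[is.na(hit)] <- FALSE
      if (any(hit)) {
        res[[length(res) + 1]] <- data.frame(
          character = rownames(P1)[hit],
          parent = ids[par], child = ids[chi], direction = dir,
          parent_P = unname(if (dir == "gain") 1 - pP1[hit] else pP1[hit]),
          child_P = unname(if (dir == "gain") cP1[hit] else 1 - cP1[hit]),
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(res)) {
    return(data.frame(character = character(0), parent = character(0),
                      child = character(0), direction = character(0),
                      parent_P = numeric(0), child_P = numeric(0)))
  }
  out <- do.call(rbind, res)
  out[order(out$character, out$parent, out$child), , drop = FALSE]
}

#' Fitch parsimony for a binary character
#'
#' First-pass Fitch algorithm: state sets are intersected up the tree,
#' with a change counted whenever an intersection is empty. Unknown tips
#' carry the full set {0, 1}.
#'
#' @param tree Rooted `phylo`.
#' @param char Named 0/1/`NA` vector over the tips.
#' @return List with `count` (minimum number of changes) and `sets`
#'   (logical matrix nodes x 2, columns state 0/1, rows ordered as
#'   [node_ids()]).
#' @export
fitch_parsimony <- function(tree, char) {
  states <- as_state_matrix(char, tree)[1, ]
  if (all(is.na(states))) stop("character with all tips unknown")
  tree <- ape::reorder.phylo(tree, "postorder")
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  sets <- matrix(FALSE, nnode, 2, dimnames = list(node_ids(tree), c("0", "1")))
  for (i in seq_len(ntip)) {
    s <- states[tree$tip.label[i]]
    sets[i, ] <- if (is.na(s)) c(TRUE, TRUE) else c(s == 0, s == 1)
  }
  started <- rep(FALSE, nnode)
  count <- 0L
  for (e in seq_len(nrow(tree$edge))) {
    par <- tree$edge[e, 1]; chi <- tree$edge[e, 2]
    if (!started[par]) {
      sets[par, ] <- sets[chi, ]
      started[par] <- TRUE
    } else {
      inter <- sets[par, ] & sets[chi, ]
      if (any(inter)) {
        sets[par, ] <- inter
      } else {
        sets[par, ] <- sets[par, ] | sets[chi, ]
        count <- count + 1L
      }
    }
  }
  list(count = count, sets = sets)
}

#' Most-parsimonious state sets (Sankoff MPR)
#'
#' For each node, the set of states realised by at least one
#' minimum-change reconstruction of the whole tree, computed exactly by
#' the up-down Sankoff recursion with unit change costs. Unlike the
#' first-pass Fitch sets of [fitch_parsimony()], these are the true MPR
#' sets: a state is included iff forcing it at that node still attains
#' the global minimum number of changes.
#'
#' @inheritParams fitch_parsimony
#' @return List with `count` (minimum changes) and `sets` (logical matrix
#'   nodes x 2, rows ordered as [node_ids()]).
#' @export
mpr_state_sets <- function(tree, char) {
  states <- as_state_matrix(char, tree)[1, ]
  if (all(is.na(states))) stop("character with all tips unknown")
  tree <- ape::reorder.phylo(tree, "postorder")
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  up <- matrix(0, nnode, 2)
  for (i in seq_len(ntip)) {
    s <- states[tree$tip.label[i]]
    if (!is.na(s)) up[i, ] <- ifelse(c(0, 1) == s, 0, Inf)
  }
  edge <- tree$edge
  # cost of the child subtree given the parent state
  edge_cost <- function(child_up, s_par) {
    min(child_up[1] + (s_par != 0), child_up[2] + (s_par != 1))
  }
  for (e in seq_len(nrow(edge))) {
    par <- edge[e, 1]; chi <- edge[e, 2]
    up[par, 1] <- up[par, 1] + edge_cost(up[chi, ], 0)
    up[par, 2] <- up[par, 2] + edge_cost(up[chi, ], 1)
  }
  root <- ntip + 1L
  down <- matrix(Inf, nnode, 2)
  down[root, ] <- 0
  kids <- split(seq_len(nrow(edge)), edge[, 1])
  for (e in rev(seq_len(nrow(edge)))) {
    par <- edge[e, 1]; chi <- edge[e, 2]
    for (sc in 0:1) {
      best <- Inf
      for (sp in 0:1) {
        v <- down[par, sp + 1] + (sp != sc)
        for (e2 in kids[[as.character(par)]]) {
          if (e2 != e) v <- v + edge_cost(up[edge[e2, 2], ], sp)
        }
        best <- min(best, v)
      }
      down[chi, sc + 1] <- best
    }
  }
  total <- up + down
  minimum <- min(total[root, ])
  sets <- total <= minimum
  dimnames(sets) <- list(node_ids(tree), c("0", "1"))
  list(count = as.integer(minimum), sets = sets)
}
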