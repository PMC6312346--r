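#' Default 14-tip study tree
#'
#' A synthetic rooted phylogeny mimicking the clade structure of the
#' motivating study: a melanogaster-like subgroup containing two sister
#' pairs, an ananassae-like lone tip, an obscura-like clade of three, a
#' willistoni-like basal tip, and a two-species distant subgenus. Branch
#' lengths are unit-free.
#'
#' @return A `phylo` object with 14 tips.
#' @export
default_tree <- function() {
  txt <- paste0(
    "((((((dmel:0.06,(dsim:0.03,(dsec:0.02,dmau:0.02):0.01):0.03):0.03,",
    "((dyak:0.04,dsan:0.04):0.02,dere:0.06):0.03):0.08,dana:0.17):0.08,",
    "((dpse:0.03,dper:0.03):0.04,dmir:0.07):0.18):0.07,dwil:0.32):0.08,",
    "(dmoj:0.25,dvir:0.25):0.15);")
  validate_tree(ape::read.tree(text = txt))
}

#' Simulation configuration
#'
#' Defaults define the reference study conditions: a 14-tip tree, gain
#' rate 0.5 and loss rate 0.1534 per unit branch length (stationary
#' presence probability 0.765, which combined with the 0.0656 unknown-
#' ortholog rate gives overall state frequencies of about 0.715 present /
#' 0.219 absent / 0.066 unknown), present-state FPKM lognormal with
#' median 20 and log-sd 1 evolving as Brownian motion on the tree
#' (sd 0.3 per unit branch length), 3 replicates with multiplicative
#' lognormal noise at CV 0.2, absent-state FPKM zero-inflated with a 10%
#' chance of a uniform leak below 0.5 FPKM, and 10% of genes carrying
#' stage-specific alternative (ALT) isoforms. Genes present at both
#' stages are predominantly-maternal or predominantly-zygotic with
#' probability 0.15 each (designed fold ratio 3.5-6x), otherwise
#' maternal-zygotic with a designed ratio inside (0.75, 1.33).
#'
#' @param tree Rooted `phylo`; default [default_tree()].
#' @param n_genes Number of ortholog groups.
#' @param q01,q10 Gain / loss rates per unit branch length.
#' @param root_prior Root state prior; default stationary.
#' @param present_meanlog,present_sdlog Lognormal parameters of the
#'   present-state FPKM level at the root.
#' @param bm_sd Brownian log-FPKM divergence per unit branch length.
#' @param replicate_cv Coefficient of variation of replicate noise.
#' @param n_replicates Replicates per species and stage.
#' @param leak_prob,leak_max Absent-state leak probability and upper
#'   bound (FPKM, strictly below the presence threshold).
#' @param missing_rate Probability an ortholog entry is blank (unknown).
#' @param alt_fraction Fraction of genes with stage-specific isoforms.
#' @param iso_probs Distribution of isoform counts (1, 2, 3 isoforms)
#'   for non-ALT genes; ALT genes always carry 2.
#' @param pm_fraction,pz_fraction Subclass probabilities for genes
#'   present at both stages.
#' @param pm_fold_range Designed fold ratio range for PM/PZ genes.
#' @param mz_ratio_range Designed stage-2/stage-5 ratio range for MZ
#'   genes.
#' @param outgroup Name of the distant outgroup species to simulate
#'   (`NULL` to disable).
#' @param outgroup_branch Branch length from the root to the outgroup.
#' @param seed Integer seed; a fixed seed makes output byte-identical.
#' @return Named list of class `simulation_config`.
#' @export
simulation_config <- function(tree = default_tree(),
                              n_genes = 2000,
                              q01 = 0.5,
                              q10 = 0.5 * (1 - 0.76520) / 0.76520,
                              root_prior = NULL,
                              present_meanlog = log(20),
                              present_sdlog = 1,
                              bm_sd = 0.3,
                              replicate_cv = 0.2,
                              n_replicates = 3,
                              leak_prob = 0.1,
                              leak_max = 0.5,
                              missing_rate = 0.0656,
                              alt_fraction = 0.1,
                              iso_probs = c(0.5, 0.3, 0.2),
                              pm_fraction = 0.15,
                              pz_fraction = 0.15,
                              pm_fold_range = c(3.5, 6),
                              mz_ratio_range = c(0.75, 4 / 3),
                              outgroup = "outg",
                              outgroup_branch = 1.0,
                              seed = 1L) {
  stopifnot(n_genes >= 1, q01 > 0, q10 > 0, replicate_cv >= 0,
            n_replicates >= 1, leak_prob >= 0, leak_prob <= 1,
            leak_max < 1, missing_rate >= 0, missing_rate < 1,
            alt_fraction >= 0, alt_fraction <= 1,
            pm_fraction + pz_fraction <= 1)
  structure(list(tree = validate_tree(tree), n_genes = as.integer(n_genes),
                 q01 = q01, q10 = q10, root_prior = root_prior,
                 present_meanlog = present_meanlog,
                 present_sdlog = present_sdlog, bm_sd = bm_sd,
                 replicate_cv = replicate_cv,
                 n_replicates = as.integer(n_replicates),
                 leak_prob = leak_prob, leak_max = leak_max,
                 missing_rate = missing_rate, alt_fraction = alt_fraction,
                 iso_probs = iso_probs, pm_fraction = pm_fraction,
                 pz_fraction = pz_fraction, pm_fold_range = pm_fold_range,
                 mz_ratio_range = mz_ratio_range, outgroup = outgroup,
                 outgroup_branch = outgroup_branch, seed = as.integer(seed)),
            class = "simulation_config")
}

#' Forward-simulate a binary character on a tree
#'
#' Draws the root state from the root prior and evolves it along every
#' branch with the closed-form 2-state transition probabilities, keeping
#' the internal-node states as ground truth. Uses the current RNG stream
#' unless `seed` is given.
#'
#' @param tree Rooted `phylo` with branch lengths.
#' @param q01,q10 Transition rates.
#' @param root_prior Root prior (default stationary).
#' @param n Number of independent characters.
#' @param seed Optional integer seed.
#' @return List with `tip_states` (n x ntip, tip labels as columns) and
#'   `node_states` (n x Nnode, columns `n<k>` as in [node_ids()]).
#' @export
simulate_presence <- function(tree, q01, q10, root_prior = NULL, n = 1,
                              seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  model <- mk_model(q01, q10, root_prior)
  tree <- ape::reorder.phylo(tree, "postorder")
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  states <- matrix(NA_integer_, n, nnode)
  root <- ntip + 1L
  states[, root] <- stats::rbinom(n, 1, model$root_prior[2])
  for (e in rev(seq_len(nrow(tree$edge)))) {
    par <- tree$edge[e, 1]; chi <- tree$edge[e, 2]
    P <- mk_transition(model, tree$edge.length[e])
    p1 <- ifelse(states[, par] == 1, P[2, 2], P[1, 2])
    states[, chi] <- stats::rbinom(n, 1, p1)
  }
  ids <- node_ids(tree)
  list(tip_states = states[, seq_len(ntip), drop = FALSE] |>
         `colnames<-`(ids[seq_len(ntip)]),
       node_states = states[, (ntip + 1):nnode, drop = FALSE] |>
         `colnames<-`(ids[(ntip + 1):nnode]))
}

# Brownian motion of log-FPKM on the tree: returns root draws plus the
# tip values (n_genes x ntip).
bm_on_tree <- function(tree, root, bm_sd) {
  tree <- ape::reorder.phylo(tree, "postorder")
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  n <- length(root)
  z <- matrix(NA_real_, n, nnode)
  z[, ntip + 1L] <- root
  for (e in rev(seq_len(nrow(tree$edge)))) {
    par <- tree$edge[e, 1]; chi <- tree$edge[e, 2]
    z[, chi] <- z[, par] + stats::rnorm(n, 0, bm_sd * sqrt(tree$edge.length[e]))
  }
  tips <- z[, seq_len(ntip), drop = FALSE]
  colnames(tips) <- tree$tip.label
  list(root = root, tips = tips)
}

# lognormal multiplicative noise with unit mean and coefficient of
# variation cv (exactly 1 when cv = 0)
replicate_noise <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  s2 <- log(1 + cv^2)
  stats::rlnorm(n, meanlog = -s2 / 2, sdlog = sqrt(s2))
}

#' Realise isoform-level expression from presence states
#'
#' Converts per-species presence states at the two stages into designed
#' gene- and isoform-level stage means and replicate FPKM tables. Present
#' genes get a lognormal level (floored at twice the presence threshold so
#' presence survives replicate noise); genes present at both stages carry
#' a designed stage ratio by subclass (MZ / PM / PZ); ALT genes carry one
#' maternal and one zygotic isoform; other genes split the gene level
#' across isoforms with stage-constant proportions. Absent stages are 0
#' with an optional sub-threshold uniform leak. Truth categories are the
#' definitional six-way rule applied to the designed means.
#'
#' @param states List with elements `stage2` and `stage5`: 0/1 matrices,
#'   genes x species (identical column sets).
#' @param cfg A [simulation_config()].
#' @param z Optional matrix of per-species log anchor levels (genes x
#'   species); defaults to iid normal draws (no tree structure).
#' @return List with `expression` (named list of isoform-level
#'   [expression_table()] per species), `isoform_map` (named vector),
#'   `gene_means` (list per species: matrix genes x c(s2, s5)),
#'   `truth` (list: `gene_category` genes x species matrix, `alt` logical
#'   matrix, `isoform_category` per-species data frames).
#' @export
simulate_expression <- function(states, cfg, z = NULL) {
  species <- colnames(states$stage2)
  stopifnot(identical(species, colnames(states$stage5)))
  n <- nrow(states$stage2)
  ref <- sprintf("g%04d", seq_len(n))
  if (is.null(z)) {
    z <- matrix(stats::rnorm(n * length(species), cfg$present_meanlog,
                             cfg$present_sdlog),
                n, length(species), dimnames = list(NULL, species))
  }
  thr <- 1  # presence threshold the study conditions fix
  floor_level <- 2 * thr

  # per-gene assignments, shared across species
  alt_gene <- stats::runif(n) < cfg$alt_fraction
  u <- stats::runif(n)
  subclass <- ifelse(u < cfg$pm_fraction, "PM",
                     ifelse(u < cfg$pm_fraction + cfg$pz_fraction, "PZ", "MZ"))
  subclass[alt_gene] <- "MZ"
  fold_r <- stats::runif(n, cfg$pm_fold_range[1], cfg$pm_fold_range[2])
  mz_r <- exp(stats::runif(n, log(cfg$mz_ratio_range[1]),
                           log(cfg$mz_ratio_range[2])))
  n_iso <- ifelse(alt_gene, 2L,
                  sample.int(length(cfg$iso_probs), n, replace = TRUE,
                             prob = cfg$iso_probs))
  shares <- lapply(seq_len(n), function(g) {
    if (alt_gene[g]) return(c(0.5, 0.5))
    w <- stats::rgamma(n_iso[g], shape = 2)
    w / sum(w)
  })

  cat_truth <- matrix(NA_character_, n, length(species),
                      dimnames = list(ref, species))
  alt_truth <- matrix(FALSE, n, length(species), dimnames = list(ref, species))
  expr <- list(); iso_cat <- list(); gene_means <- list()
  iso_map_all <- character(0)

  for (s in species) {
    s2 <- states$stage2[, s]; s5 <- states$stage5[, s]
    L <- pmax(exp(z[, s]), floor_level)
    G2 <- numeric(n); G5 <- numeric(n)
    both <- s2 == 1 & s5 == 1
    G2[s2 == 1 & s5 == 0] <- L[s2 == 1 & s5 == 0]
    G5[s2 == 0 & s5 == 1] <- L[s2 == 0 & s5 == 1]
    i <- both & subclass == "MZ"
    G2[i] <- L[i]; G5[i] <- L[i] / mz_r[i]
    i <- both & subclass == "PM"
    G5[i] <- L[i]; G2[i] <- L[i] * fold_r[i]
    i <- both & subclass == "PZ"
    G2[i] <- L[i]; G5[i] <- L[i] * fold_r[i]
    # sub-threshold leak on absent stages
    leak <- function(absent) {
      out <- numeric(n)
      on <- absent & stats::runif(n) < cfg$leak_prob
      out[on] <- stats::runif(sum(on), 0, cfg$leak_max)
      out
    }
    G2[s2 == 0] <- leak(s2 == 0)[s2 == 0]
    G5[s5 == 0] <- leak(s5 == 0)[s5 == 0]

    q0 <- ifelse(abs(G2 - G5) > 0, 0, 1)
    cat_truth[, s] <- classify_feature(G2, G5, q0)
    alt_truth[, s] <- alt_gene & both
    gene_means[[s]] <- cbind(s2 = G2, s5 = G5)
    rownames(gene_means[[s]]) <- ref

    # isoform-level designed means
    gene_ids <- paste0(s, "|", ref)
    iso_id <- unlist(lapply(seq_len(n), function(g) {
      paste0(gene_ids[g], ".", seq_len(n_iso[g]))
    }))
    iso_gene <- rep(gene_ids, n_iso)
    g_of <- rep(seq_len(n), n_iso)
    iso2 <- numeric(length(iso_id)); iso5 <- numeric(length(iso_id))
    pos <- 1L
    for (g in seq_len(n)) {
      k <- n_iso[g]; idx <- pos:(pos + k - 1L)
      if (alt_gene[g]) {
        iso2[idx] <- c(G2[g], 0)
        iso5[idx] <- c(0, G5[g])
      } else {
        iso2[idx] <- shares[[g]] * G2[g]
        iso5[idx] <- shares[[g]] * G5[g]
      }
      pos <- pos + k
    }
    q0i <- ifelse(abs(iso2 - iso5) > 0, 0, 1)
    iso_cat[[s]] <- data.frame(isoform_id = iso_id, gene_id = iso_gene,
                               category = classify_feature(iso2, iso5, q0i),
                               stringsAsFactors = FALSE)

    # replicate realisation
    reps <- cfg$n_replicates
    mat <- matrix(0, length(iso_id), 2 * reps)
    sample_ids <- c(sprintf("%s_stage2_r%d", s, seq_len(reps)),
                    sprintf("%s_stage5_r%d", s, seq_len(reps)))
    for (j in seq_len(reps)) {
      mat[, j] <- iso2 * replicate_noise(length(iso_id), cfg$replicate_cv)
      mat[, reps + j] <- iso5 * replicate_noise(length(iso_id), cfg$replicate_cv)
    }
    dimnames(mat) <- list(iso_id, sample_ids)
    samples <- data.frame(
      sample_id = sample_ids,
      species = s,
      stage = rep(c("stage2", "stage5"), each = reps),
      replicate = rep(seq_len(reps), 2),
      sex = "unknown",
      stringsAsFactors = FALSE)
    expr[[s]] <- expression_table(mat, samples)
    iso_map_all <- c(iso_map_all, stats::setNames(iso_gene, iso_id))
  }

  list(expression = expr,
       isoform_map = iso_map_all,
       gene_means = gene_means,
       truth = list(gene_category = cat_truth, alt = alt_truth,
                    isoform_category = iso_cat,
                    subclass = subclass, alt_gene = alt_gene))
}

#' Blank ortholog entries at random
#'
#' Each (group, species) entry is blanked independently with probability
#' `missing_rate`; groups falling below any species-count threshold are
#' still emitted (filtering is the pipeline's job).
#'
#' @param orthologs An [ortholog_table()].
#' @param missing_rate Blanking probability in [0, 1).
#' @param seed Optional integer seed.
#' @return The table with blanks injected.
#' @export
inject_missing_orthologs <- function(orthologs, missing_rate, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(missing_rate >= 0, missing_rate < 1)
  g <- orthologs$groups
  for (s in ortholog_species(orthologs)) {
    g[[s]][stats::runif(nrow(g)) < missing_rate] <- ""
  }
  ortholog_table(g, orthologs$annotations)
}

#' Generate a complete ground-truthed dataset
#'
#' Simulates presence characters for both stages on the tree (plus a
#' distant outgroup evolved from the root), tree-structured expression
#' levels, isoform tables with replicate noise, an ortholog table with
#' blanks, and keeps every intermediate truth: tip and internal-node
#' states, designed gene categories, ALT flags and branch transitions.
#'
#' @param cfg A [simulation_config()].
#' @return List with `config`, `tree`, `expression`, `isoform_map`,
#'   `orthologs`, `samples`, `gene_means`, `truth` (tip/node states per
#'   stage, gene categories, ALT flags, isoform categories, outgroup
#'   states, true branch events).
#' @export
simulate_dataset <- function(cfg = simulation_config()) {
  set.seed(cfg$seed)
  tree <- cfg$tree
  species <- tree$tip.label
  n <- cfg$n_genes
  ref <- sprintf("g%04d", seq_len(n))

  pres <- list(
    stage2 = simulate_presence(tree, cfg$q01, cfg$q10, cfg$root_prior, n),
    stage5 = simulate_presence(tree, cfg$q01, cfg$q10, cfg$root_prior, n))
  model <- mk_model(cfg$q01, cfg$q10, cfg$root_prior)
  root_id <- paste0("n", length(species) + 1L)

  tips2 <- pres$stage2$tip_states
  tips5 <- pres$stage5$tip_states
  all_sp <- species
  if (!is.null(cfg$outgroup)) {
    P <- mk_transition(model, cfg$outgroup_branch)
    evolve <- function(root_states) {
      p1 <- ifelse(root_states == 1, P[2, 2], P[1, 2])
      stats::rbinom(n, 1, p1)
    }
    og2 <- evolve(pres$stage2$node_states[, root_id])
    og5 <- evolve(pres$stage5$node_states[, root_id])
    tips2 <- cbind(tips2, og2); colnames(tips2)[ncol(tips2)] <- cfg$outgroup
    tips5 <- cbind(tips5, og5); colnames(tips5)[ncol(tips5)] <- cfg$outgroup
    all_sp <- c(species, cfg$outgroup)
  }

  root_z <- stats::rnorm(n, cfg$present_meanlog, cfg$present_sdlog)
  bm <- bm_on_tree(tree, root_z, cfg$bm_sd)
  z <- bm$tips
  if (!is.null(cfg$outgroup)) {
    zo <- root_z + stats::rnorm(n, 0, cfg$bm_sd * sqrt(cfg$outgroup_branch))
    z <- cbind(z, zo); colnames(z)[ncol(z)] <- cfg$outgroup
  }

  real <- simulate_expression(list(stage2 = tips2, stage5 = tips5), cfg, z = z)

  groups <- data.frame(ref_gene = ref, stringsAsFactors = FALSE)
  for (s in all_sp) groups[[s]] <- paste0(s, "|", ref)
  orthologs <- inject_missing_orthologs(ortholog_table(groups),
                                        cfg$missing_rate)

  samples <- do.call(rbind, lapply(real$expression, function(t) t$samples))
  rownames(samples) <- NULL

  truth <- real$truth
  truth$tip_states <- list(stage2 = pres$stage2$tip_states,
                           stage5 = pres$stage5$tip_states)
  truth$node_states <- list(stage2 = pres$stage2$node_states,
                            stage5 = pres$stage5$node_states)
  if (!is.null(cfg$outgroup)) {
    truth$outgroup_states <- list(stage2 = og2, stage5 = og5)
  }
  truth$events <- true_transitions(truth, tree, ref)

  list(config = cfg, tree = tree, expression = real$expression,
       isoform_map = real$isoform_map, orthologs = orthologs,
       samples = samples, gene_means = real$gene_means, truth = truth)
}

#' True gain/loss events of a simulated dataset
#'
#' Reads the simulated tip and internal-node states and lists every
#' branch on which the character changed, per gene and stage.
#'
#' @param truth The `truth` element of [simulate_dataset()] (needs
#'   `tip_states` and `node_states`).
#' @param tree The simulation tree.
#' @param ref Gene identifiers (rownames of the state matrices).
#' @return Data frame `character, parent, child, direction`.
#' @export
true_transitions <- function(truth, tree, ref) {
  ids <- node_ids(tree)
  res <- list()
  for (st in c("stage2", "stage5")) {
    full <- cbind(truth$tip_states[[st]], truth$node_states[[st]])
    full <- full[, ids, drop = FALSE]
    for (e in seq_len(nrow(tree$edge))) {
      par <- tree$edge[e, 1]; chi <- tree$edge[e, 2]
      ps <- full[, par]; cs <- full[, chi]
      changed <- ps != cs
      if (any(changed)) {
        res[[length(res) + 1]] <- data.frame(
          character = paste(ref[changed], st, sep = "|"),
          parent = ids[par], child = ids[chi],
          direction = ifelse(ps[changed] == 0, "gain", "loss"),
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(res)) {
    return(data.frame(character = character(0), parent = character(0),
                      child = character(0), direction = character(0)))
  }
  out <- do.call(rbind, res)
  out[order(out$character, out$parent), , drop = FALSE]
}

#' Write a simulated dataset to disk
#'
#' Emits one expression TSV per species, a combined sample sheet, the
#' isoform map, the ortholog table, the tree in newick, the truth tables
#' and a YAML manifest recording the configuration and seed. A manifest
#' seed reproduces the fixture byte-identically.
#'
#' @param dir Output directory (created if needed).
#' @param cfg A [simulation_config()].
#' @return Invisibly, the directory path.
#' @export
write_fixture <- function(dir, cfg = simulation_config()) {
  sim <- simulate_dataset(cfg)
  ok <- dir.exists(dir) || dir.create(dir, recursive = TRUE)
  if (!ok || file.access(dir, 2) != 0) stop("cannot write to ", dir)
  wt <- function(d, f) {
    utils::write.table(d, file.path(dir, f), sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  for (s in names(sim$expression)) {
    t <- sim$expression[[s]]
    wt(data.frame(feature_id = rownames(t$values), t$values,
                  check.names = FALSE), paste0("expression_", s, ".tsv"))
  }
  wt(sim$samples, "samples.tsv")
  wt(data.frame(isoform_id = names(sim$isoform_map),
                gene_id = unname(sim$isoform_map)), "isoform_map.tsv")
  write_ortholog_table(sim$orthologs, file.path(dir, "orthologs.tsv"))
  write_tree(sim$tree, file.path(dir, "tree.nwk"))
  truth_cat <- data.frame(ref_gene = rownames(sim$truth$gene_category),
                          sim$truth$gene_category, check.names = FALSE)
  wt(truth_cat, "truth_gene_category.tsv")
  wt(data.frame(ref_gene = rownames(sim$truth$alt), sim$truth$alt,
                check.names = FALSE), "truth_alt.tsv")
  for (st in c("stage2", "stage5")) {
    wt(data.frame(ref_gene = rownames(sim$truth$gene_category),
                  sim$truth$tip_states[[st]],
                  sim$truth$node_states[[st]], check.names = FALSE),
       paste0("truth_states_", st, ".tsv"))
  }
  wt(sim$truth$events, "truth_events.tsv")
  manifest <- list(
    package = "mztevol",
    seed = cfg$seed,
    n_genes = cfg$n_genes,
    config = cfg[setdiff(names(cfg), "tree")],
    tree = ape::write.tree(sim$tree))
  yaml::write_yaml(manifest, file.path(dir, "manifest.yaml"))
  invisible(dir)
}
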