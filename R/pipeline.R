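#' Pipeline run configuration
#'
#' A run either consumes a fixture directory written by [write_fixture()]
#' (or real data in the same layout) or simulates its input in memory
#' from a [simulation_config()].
#'
#' @param out_dir Output directory for all stage outputs and the manifest.
#' @param input_dir Fixture directory (`NULL` when `sim` is given).
#' @param sim A [simulation_config()] (`NULL` when `input_dir` is given).
#' @param classifier A [classifier_config()].
#' @param roles A [species_roles()], or `NULL` to skip conservation.
#' @param min_species Ortholog-group species-count filter (default 12).
#' @param posterior_threshold Gain/loss posterior threshold (default 0.9).
#' @param include_terminal Call events on terminal branches.
#' @param seed Seed recorded in the manifest and used for simulation.
#' @param verbose Log stage timings to stderr.
#' @return List of class `run_config`.
#' @export
run_config <- function(out_dir, input_dir = NULL, sim = NULL,
                       classifier = classifier_config(), roles = NULL,
                       min_species = 12, posterior_threshold = 0.9,
                       include_terminal = TRUE, seed = 1L, verbose = TRUE) {
  if (is.null(input_dir) && is.null(sim)) stop("need input_dir or sim")
  structure(list(out_dir = out_dir, input_dir = input_dir, sim = sim,
                 classifier = classifier, roles = roles,
                 min_species = min_species,
                 posterior_threshold = posterior_threshold,
                 include_terminal = include_terminal,
                 seed = as.integer(seed), verbose = verbose),
            class = "run_config")
}

#' Read a fixture directory into pipeline inputs
#'
#' @param dir Directory holding `samples.tsv`, `expression_<species>.tsv`,
#'   `isoform_map.tsv`, `orthologs.tsv` and `tree.nwk`.
#' @return List with `expression`, `samples`, `isoform_map`, `orthologs`,
#'   `tree`.
#' @export
read_fixture <- function(dir) {
  need <- function(f) {
    p <- file.path(dir, f)
    if (!file.exists(p)) stop("missing input file: ", p)
    p
  }
  samples <- read_sample_sheet(need("samples.tsv"))
  expr <- lapply(split(samples, samples$species), function(d) {
    read_expression_table(need(paste0("expression_", d$species[1], ".tsv")), d)
  })
  list(expression = expr,
       samples = samples,
       isoform_map = read_isoform_map(need("isoform_map.tsv")),
       orthologs = read_ortholog_table(need("orthologs.tsv")),
       tree = read_tree(need("tree.nwk")))
}

# md5 of the canonical YAML serialisation of a list (written to a
# temporary file; tools::md5sum is file-based)
config_hash <- function(x) {
  f <- tempfile(fileext = ".yaml")
  on.exit(unlink(f))
  yaml::write_yaml(x, f)
  unname(tools::md5sum(f))
}

#' Run the full analysis pipeline
#'
#' Chains the stages: (simulate or load) -> per-species six-way
#' classification and ALT detection -> cross-species correlations and
#' average-linkage clustering -> character encoding, rate fitting,
#' marginal ancestral reconstruction and gain/loss calling ->
#' conservation sets. All stage outputs are written as TSV under
#' `cfg$out_dir` together with a YAML manifest carrying the configuration
#' hash and seed; a rerun with identical inputs and seed reproduces the
#' same configuration hash.
#'
#' @param cfg A [run_config()].
#' @return Invisibly, a list with every in-memory stage result and
#'   `out_dir`.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  t0 <- Sys.time()
  timings <- list()
  tick <- function(stage, start) {
    dt <- round(as.numeric(difftime(Sys.time(), start, units = "secs")), 2)
    if (cfg$verbose) message(sprintf("[%s] %.2fs", stage, dt))
    timings[[stage]] <<- dt
  }
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  wt <- function(d, f) {
    utils::write.table(d, file.path(cfg$out_dir, f), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }

  # -- inputs ----------------------------------------------------------
  s <- Sys.time()
  if (!is.null(cfg$sim)) {
    sim_cfg <- cfg$sim
    sim_cfg$seed <- cfg$seed
    data <- simulate_dataset(sim_cfg)
  } else {
    data <- read_fixture(cfg$input_dir)
    missing_sp <- setdiff(data$tree$tip.label, unique(data$samples$species))
    if (length(missing_sp)) {
      stop("tree tip(s) without expression data: ",
           paste(missing_sp, collapse = ", "))
    }
  }
  species <- data$tree$tip.label
  tick("inputs", s)

  # -- classification --------------------------------------------------
  s <- Sys.time()
  iso_calls <- list(); gene_calls <- list(); alt <- list()
  for (sp in names(data$expression)) {
    it <- data$expression[[sp]]
    ic <- classify_expression(it, cfg$classifier, level = "isoform")
    gt <- aggregate_isoforms_to_genes(it, data$isoform_map)
    gc <- classify_expression(gt, cfg$classifier, level = "gene")
    af <- detect_alt_genes(ic, data$isoform_map)
    gc$alt_flag <- af$alt_flag[match(gc$feature_id, af$gene_id)]
    ic$alt_flag <- af$alt_flag[match(data$isoform_map[ic$feature_id], af$gene_id)]
    iso_calls[[sp]] <- ic; gene_calls[[sp]] <- gc; alt[[sp]] <- af
    wt(rbind(ic, gc), paste0("classification_", sp, ".tsv"))
  }
  tick("classify", s)

  # -- comparative -----------------------------------------------------
  s <- Sys.time()
  # the species-count filter applies to the ingroup species only
  orth_in <- filter_ortholog_groups(
    ortholog_table(
      data$orthologs$groups[, c("ref_gene",
                                intersect(names(data$orthologs$groups),
                                          species))],
      data$orthologs$annotations),
    cfg$min_species)
  aligned <- lapply(stats::setNames(species, species), function(sp) {
    calls_by_group(gene_calls[[sp]], orth_in, sp)
  })
  shared <- Reduce(`&`, lapply(aligned, function(a) !is.na(a$category)))
  condmat <- do.call(cbind, lapply(species, function(sp) {
    m <- cbind(aligned[[sp]]$s2_mean, aligned[[sp]]$s5_mean)
    colnames(m) <- paste(sp, c("stage2", "stage5"), sep = ".")
    m
  }))[shared, , drop = FALSE]
  rownames(condmat) <- orth_in$groups$ref_gene[shared]
  corr <- correlation_matrix(condmat)
  clust <- hierarchical_cluster(corr)
  pairs <- utils::combn(species, 2)
  corr_rows <- list()
  for (k in seq_len(ncol(pairs))) {
    a <- pairs[1, k]; b <- pairs[2, k]
    for (cat in c("stage2", "stage5", "maternal_only", "zygotic_only")) {
      corr_rows[[length(corr_rows) + 1]] <- pairwise_category_correlation(
        aligned[[a]], aligned[[b]], category = cat, mode = "shared_in_both",
        cfg = cfg$classifier, species_a = a, species_b = b)
    }
  }
  correlations <- do.call(rbind, corr_rows)
  wt(correlations, "correlations.tsv")
  wt(data.frame(merge1 = clust$merge[, 1], merge2 = clust$merge[, 2],
                height = clust$height), "linkage.tsv")
  alt_mat <- do.call(cbind, lapply(species, function(sp) {
    ids <- orth_in$groups[[sp]]
    f <- alt[[sp]]$alt_flag[match(ids, alt[[sp]]$gene_id)]
    f[ids == ""] <- NA
    f
  }))
  dimnames(alt_mat) <- list(orth_in$groups$ref_gene, species)
  alt_cons <- alt_conservation_count(alt_mat)
  wt(alt_cons, "alt_conservation.tsv")
  # unique representation at each stage
  uniq <- list()
  for (st in c("stage2", "stage5")) {
    vals <- do.call(cbind, lapply(species, function(sp) {
      aligned[[sp]][[if (st == "stage2") "s2_mean" else "s5_mean"]]
    }))
    dimnames(vals) <- list(orth_in$groups$ref_gene, species)
    u <- unique_representation_screen(vals, cfg$classifier)
    if (nrow(u)) u$stage <- st
    uniq[[st]] <- u
  }
  unique_rep <- do.call(rbind, uniq[vapply(uniq, nrow, 1L) > 0])
  if (is.null(unique_rep)) unique_rep <- data.frame(ref_gene = character(0),
                                                    species = character(0),
                                                    stage = character(0))
  wt(unique_rep, "unique_representation.tsv")
  tick("comparative", s)

  # -- ancestral reconstruction ----------------------------------------
  s <- Sys.time()
  cond_list <- lapply(data$expression, function(t) {
    mean_by_condition(aggregate_isoforms_to_genes(t, data$isoform_map))
  })
  chars <- encode_characters(cond_list[species], orth_in,
                             threshold = cfg$classifier$presence_threshold)
  freqs <- character_frequencies(chars)
  models <- list(); P1 <- list(); events <- list()
  for (st in c("stage2", "stage5")) {
    keep <- chars$stage == st
    states <- chars$states[keep, , drop = FALSE]
    models[[st]] <- fit_rates(chars, data$tree, stage = st)
    P1[[st]] <- marginal_posteriors(data$tree, states, models[[st]])
    events[[st]] <- call_transitions(P1[[st]], data$tree, states,
                                     threshold = cfg$posterior_threshold,
                                     include_terminal = cfg$include_terminal)
    if (nrow(events[[st]])) events[[st]]$stage <- st
  }
  rates <- do.call(rbind, lapply(names(models), function(st) {
    data.frame(stage = st, q01 = models[[st]]$q01, q10 = models[[st]]$q10,
               pi1 = models[[st]]$root_prior[2],
               loglik = attr(models[[st]], "loglik"))
  }))
  wt(rates, "rates.tsv")
  all_events <- do.call(rbind, events[vapply(events, nrow, 1L) > 0])
  if (is.null(all_events)) {
    all_events <- data.frame(character = character(0), parent = character(0),
                             child = character(0), direction = character(0),
                             parent_P = numeric(0), child_P = numeric(0),
                             stage = character(0))
  }
  wt(all_events, "events.tsv")
  post_long <- do.call(rbind, lapply(names(P1), function(st) {
    m <- P1[[st]]
    data.frame(character = rep(rownames(m), ncol(m)),
               node = rep(colnames(m), each = nrow(m)),
               P1 = as.vector(m))
  }))
  wt(post_long, "posteriors.tsv")
  labelled <- data$tree
  labelled$node.label <- paste0("n", length(species) + seq_len(data$tree$Nnode))
  write_tree(labelled, file.path(cfg$out_dir, "tree_annotated.nwk"))
  tick("ancestral", s)

  # -- conservation ----------------------------------------------------
  s <- Sys.time()
  conservation <- NULL
  if (!is.null(cfg$roles) || inherits(cfg$sim, "simulation_config")) {
    roles <- cfg$roles
    if (is.null(roles) && !is.null(cfg$sim$outgroup)) {
      roles <- species_roles(outgroup = cfg$sim$outgroup, basal = "dwil",
                             subgenus = c("dmoj", "dvir"), ingroup = species)
    }
    if (!is.null(roles) &&
        is.null(data$orthologs$groups[[roles$outgroup]])) {
      message("outgroup '", roles$outgroup,
              "' absent from the ortholog table; conservation skipped")
      roles <- NULL
    }
    if (!is.null(roles)) {
      all_sp <- c(roles$ingroup, roles$outgroup)
      og_ids <- data$orthologs$groups[[roles$outgroup]][
        match(orth_in$groups$ref_gene, data$orthologs$groups$ref_gene)]
      calls_mat <- do.call(cbind, lapply(all_sp, function(sp) {
        ids <- if (sp == roles$outgroup) og_ids else orth_in$groups[[sp]]
        cc <- gene_calls[[sp]]$category[match(ids, gene_calls[[sp]]$feature_id)]
        cc[ids == ""] <- NA
        cc
      }))
      dimnames(calls_mat) <- list(orth_in$groups$ref_gene, all_sp)
      conservation <- conservation_records(calls_mat, roles, "zygotic_only")
      wt(conservation, "conservation.tsv")
    }
  }
  tick("conservation", s)

  # -- manifest --------------------------------------------------------
  hash_input <- list(
    classifier = unclass(cfg$classifier),
    min_species = cfg$min_species,
    posterior_threshold = cfg$posterior_threshold,
    include_terminal = cfg$include_terminal,
    seed = cfg$seed,
    sim = if (!is.null(cfg$sim)) {
      c(unclass(cfg$sim)[setdiff(names(cfg$sim), "tree")],
        list(tree = ape::write.tree(cfg$sim$tree)))
    },
    input_dir = cfg$input_dir)
  manifest <- list(
    package = "mztevol",
    version = as.character(utils::packageVersion("mztevol")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = cfg$seed,
    config_hash = config_hash(hash_input),
    character_frequencies = as.list(freqs),
    timings = timings)
  yaml::write_yaml(manifest, file.path(cfg$out_dir, "manifest.yaml"))
  if (cfg$verbose) {
    message(sprintf("[total] %.2fs -> %s",
                    as.numeric(difftime(Sys.time(), t0, units = "secs")),
                    cfg$out_dir))
  }
  invisible(list(out_dir = cfg$out_dir, data = data, iso_calls = iso_calls,
                 gene_calls = gene_calls, alt = alt, corr = corr,
                 clust = clust, correlations = correlations,
                 characters = chars, frequencies = freqs, models = models,
                 posteriors = P1, events = all_events,
                 conservation = conservation, manifest = manifest))
}
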