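#' Binary presence/absence character matrix
#'
#' One row per (gene, stage) character, one column per species. States are
#' 1 (transcript present: mean FPKM at or above the threshold), 0 (below
#' the threshold) and `NA` (unknown: no one-to-one ortholog in that
#' species).
#'
#' @param states Integer/numeric matrix of 0/1/`NA`, characters x species.
#' @param gene Character vector of gene (ortholog group) identifiers.
#' @param stage Character vector of stages, parallel to `gene`.
#' @return Object of class `character_matrix`.
#' @export
character_matrix <- function(states, gene, stage) {
  states <- as.matrix(states)
  stopifnot(nrow(states) == length(gene), length(gene) == length(stage))
  vals <- states[!is.na(states)]
  if (length(vals) && !all(vals %in% c(0, 1))) stop("states must be 0, 1 or NA")
  rownames(states) <- paste(gene, stage, sep = "|")
  structure(list(states = states, gene = gene, stage = stage),
            class = "character_matrix")
}

#' @export
print.character_matrix <- function(x, ...) {
  f <- character_frequencies(x)
  cat(sprintf(
    "character_matrix: %d characters x %d species (f1 = %.3f, f0 = %.3f, unknown = %.4f)\n",
    nrow(x$states), ncol(x$states), f["f1"], f["f0"], f["f_unknown"]))
  invisible(x)
}

#' Encode presence/absence characters from condition means
#'
#' For every ortholog group and stage, each species' state is 1 when the
#' mean FPKM of the species' ortholog at that stage is at or above the
#' threshold, 0 when below, and unknown (`NA`) when the ortholog entry is
#' blank.
#'
#' @param cond_list Named list (by species) of `condition_matrix` objects
#'   from [mean_by_condition()], each keyed by species-local gene ids.
#' @param orthologs An [ortholog_table()].
#' @param threshold Presence threshold (FPKM, default 1).
#' @param stages Stages to encode (two characters per gene by default).
#' @return A [character_matrix()] with `2 * n_groups` rows (for the
#'   default two stages), gene = `ref_gene`.
#' @export
encode_characters <- function(cond_list, orthologs, threshold = 1,
                              stages = c("stage2", "stage5")) {
  sp <- ortholog_species(orthologs)
  absent <- setdiff(sp, names(cond_list))
  if (length(absent)) {
    stop("species in ortholog table but absent from expression: ",
         paste(absent, collapse = ", "))
  }
  groups <- orthologs$groups
  ng <- nrow(groups)
  out <- vector("list", length(stages))
  for (k in seq_along(stages)) {
    st <- stages[k]
    states <- matrix(NA_real_, ng, length(sp), dimnames = list(NULL, sp))
    for (s in sp) {
      cond <- cond_list[[s]]
      colname <- paste(s, st, sep = ".")
      if (!colname %in% colnames(cond$values)) {
        stop("condition ", colname, " missing from expression data")
      }
      v <- cond$values[, colname]
      ids <- groups[[s]]
      known <- ids != ""
      hit <- match(ids[known], rownames(cond$values))
      if (anyNA(hit)) {
        stop("ortholog id(s) for species ", s, " absent from its expression table")
      }
      states[known, s] <- as.numeric(v[hit] >= threshold)
    }
    out[[k]] <- states
  }
  character_matrix(do.call(rbind, out),
                   gene = rep(groups$ref_gene, length(stages)),
                   stage = rep(stages, each = ng))
}

#' State frequencies of a character matrix
#'
#' @param m A [character_matrix()] (or plain 0/1/NA matrix).
#' @return Named vector `(f1, f0, f_unknown)`, summing to 1 over all
#'   (character, species) cells.
#' @export
character_frequencies <- function(m) {
  states <- if (inherits(m, "character_matrix")) m$states else as.matrix(m)
  if (!length(states)) stop("empty character matrix")
  total <- length(states)
  c(f1 = sum(states == 1, na.rm = TRUE) / total,
    f0 = sum(states == 0, na.rm = TRUE) / total,
    f_unknown = sum(is.na(states)) / total)
}
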