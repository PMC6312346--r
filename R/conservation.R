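#' Species roles for conservation analysis
#'
#' The core-set criteria distinguish a distant outgroup (a basal Dipteran
#' in the motivating data), the most basally diverging ingroup species,
#' and the members of the other subgenus; the remaining ingroup species
#' supply the "also conserved in N other species" summaries.
#'
#' @param outgroup Outgroup species name.
#' @param basal Required basal ingroup species.
#' @param subgenus Character vector (>= 1) of subgenus species, at least
#'   one of which must share the category.
#' @param ingroup All ingroup species.
#' @return Object of class `species_roles`.
#' @export
species_roles <- function(outgroup, basal, subgenus, ingroup) {
  stopifnot(length(outgroup) == 1, length(basal) == 1, length(subgenus) >= 1)
  if (!basal %in% ingroup) stop("basal species must be in the ingroup")
  if (!all(subgenus %in% ingroup)) stop("subgenus species must be in the ingroup")
  if (outgroup %in% ingroup) stop("outgroup cannot be an ingroup species")
  structure(list(outgroup = outgroup, basal = basal,
                 subgenus = subgenus, ingroup = ingroup),
            class = "species_roles")
}

# category calls as a genes x species character matrix (NA = unknown)
check_calls_matrix <- function(calls, needed) {
  stopifnot(is.matrix(calls))
  absent <- setdiff(needed, colnames(calls))
  if (length(absent)) stop("call matrix missing species: ",
                           paste(absent, collapse = ", "))
  invisible(calls)
}

category_code <- function(category) {
  switch(category, zygotic_only = "Z", maternal_only = "M",
         stop("category must be zygotic_only or maternal_only"))
}

#' Loosely conserved stage-restricted gene set
#'
#' Genes with the category (zygotic-only by default) in the outgroup and
#' in at least one ingroup species.
#'
#' @param calls Character matrix of six-way categories, genes x species
#'   (including the outgroup column); `NA` for unknown orthologs.
#' @param roles A [species_roles()].
#' @param category `"zygotic_only"` or `"maternal_only"`.
#' @return Character vector of gene identifiers (rownames of `calls`).
#' @export
loose_conserved_set <- function(calls, roles, category = "zygotic_only") {
  code <- category_code(category)
  check_calls_matrix(calls, c(roles$outgroup, roles$ingroup))
  og <- !is.na(calls[, roles$outgroup]) & calls[, roles$outgroup] == code
  ing <- calls[, roles$ingroup, drop = FALSE] == code
  rownames(calls)[og & rowSums(ing, na.rm = TRUE) >= 1]
}

#' Core conserved stage-restricted gene set
#'
#' The stringent criterion: the category must hold in the outgroup, in the
#' basal ingroup species, and in at least one member of the subgenus set.
#' Always a subset of [loose_conserved_set()].
#'
#' @inheritParams loose_conserved_set
#' @return Character vector of gene identifiers.
#' @export
core_conserved_set <- function(calls, roles, category = "zygotic_only") {
  code <- category_code(category)
  check_calls_matrix(calls, c(roles$outgroup, roles$basal, roles$subgenus))
  og <- !is.na(calls[, roles$outgroup]) & calls[, roles$outgroup] == code
  bas <- !is.na(calls[, roles$basal]) & calls[, roles$basal] == code
  sub <- calls[, roles$subgenus, drop = FALSE] == code
  rownames(calls)[og & bas & rowSums(sub, na.rm = TRUE) >= 1]
}

#' Mean number of additional ingroup species sharing the category
#'
#' For each gene of a set, counts the ingroup species with the category
#' beyond those used to define membership, and averages over the set.
#' For a core set the basal species and one qualifying subgenus species
#' are excluded from the count; for a loose set one qualifying ingroup
#' species is excluded; the outgroup is never counted. Species with
#' unknown state are excluded from both numerator and denominator.
#'
#' @param gene_set Character vector of gene ids (subset of
#'   `rownames(calls)`).
#' @param calls Category call matrix as in [loose_conserved_set()].
#' @param roles A [species_roles()].
#' @param category `"zygotic_only"` or `"maternal_only"`.
#' @param set_type `"loose"` or `"core"` (controls which defining species
#'   are excluded).
#' @return Mean count (`NA_real_` for an empty set).
#' @export
mean_additional_species <- function(gene_set, calls, roles,
                                    category = "zygotic_only",
                                    set_type = c("loose", "core")) {
  set_type <- match.arg(set_type)
  if (length(gene_set) == 0) return(NA_real_)
  code <- category_code(category)
  ing <- calls[gene_set, roles$ingroup, drop = FALSE] == code
  n_with <- rowSums(ing, na.rm = TRUE)
  n_defining <- if (set_type == "core") 2L else 1L
  mean(pmax(n_with - n_defining, 0))
}

#' Per-gene conservation records
#'
#' @inheritParams loose_conserved_set
#' @return Data frame `gene, n_species, core_flag, loose_flag` where
#'   `n_species` counts ingroup species with the category.
#' @export
conservation_records <- function(calls, roles, category = "zygotic_only") {
  code <- category_code(category)
  check_calls_matrix(calls, c(roles$outgroup, roles$ingroup))
  loose <- loose_conserved_set(calls, roles, category)
  core <- core_conserved_set(calls, roles, category)
  n <- rowSums(calls[, roles$ingroup, drop = FALSE] == code, na.rm = TRUE)
  data.frame(gene = rownames(calls),
             n_species = as.integer(n),
             core_flag = rownames(calls) %in% core,
             loose_flag = rownames(calls) %in% loose,
             stringsAsFactors = FALSE)
}
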