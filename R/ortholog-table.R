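#' Construct a one-to-one ortholog table
#'
#' Rows are ortholog groups keyed by a reference gene name; each species
#' column holds the species' gene identifier or `""` when no one-to-one
#' ortholog exists (missing, or multiple orthologs — both are blank).
#'
#' @param groups Data frame whose first column is `ref_gene` and whose
#'   remaining columns are species.
#' @param annotations Optional data frame
#'   `gene, species, chromosome, muller, unannotated` carrying per-gene
#'   chromosome / Muller-element labels.
#' @return Object of class `ortholog_table`.
#' @export
ortholog_table <- function(groups, annotations = NULL) {
  groups <- as.data.frame(groups)
  if (names(groups)[1] != "ref_gene") stop("first column must be ref_gene")
  if (anyDuplicated(groups$ref_gene)) stop("duplicate ref_gene group keys")
  for (j in seq_along(groups)) groups[[j]][is.na(groups[[j]])] <- ""
  structure(list(groups = groups, annotations = annotations),
            class = "ortholog_table")
}

#' @export
print.ortholog_table <- function(x, ...) {
  cat(sprintf("ortholog_table: %d groups x %d species\n",
              nrow(x$groups), ncol(x$groups) - 1L))
  invisible(x)
}

#' Species covered by an ortholog table
#' @param o An [ortholog_table()].
#' @export
ortholog_species <- function(o) setdiff(names(o$groups), "ref_gene")

#' Read an ortholog table from TSV
#'
#' @param path TSV, first column `ref_gene`, one column per species, empty
#'   string for a blank entry.
#' @param annotations_path Optional companion TSV
#'   `gene, species, chromosome, muller, unannotated`.
#' @return An [ortholog_table()].
#' @export
read_ortholog_table <- function(path, annotations_path = NULL) {
  g <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE,
                         colClasses = "character", na.strings = NULL)
  ann <- if (!is.null(annotations_path)) {
    utils::read.delim(annotations_path, stringsAsFactors = FALSE)
  }
  ortholog_table(g, ann)
}

#' Write an ortholog table to TSV
#' @param o An [ortholog_table()].
#' @param path Output file.
#' @export
write_ortholog_table <- function(o, path) {
  utils::write.table(o$groups, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Count non-blank species per ortholog group
#' @param o An [ortholog_table()].
#' @return Integer vector, one count per group.
#' @export
group_species_counts <- function(o) {
  sp <- ortholog_species(o)
  rowSums(o$groups[, sp, drop = FALSE] != "")
}

#' Keep groups with one-to-one orthologs in enough species
#'
#' The comparative and phylogenetic analyses restrict to groups with
#' one-to-one orthologs in at least `min_species` of the species (default
#' 12 of 14).
#'
#' @param o An [ortholog_table()].
#' @param min_species Minimum number of non-blank species entries.
#' @return Filtered [ortholog_table()].
#' @export
filter_ortholog_groups <- function(o, min_species = 12) {
  sp <- ortholog_species(o)
  if (min_species > length(sp)) {
    stop("min_species exceeds the number of species in the table")
  }
  keep <- group_species_counts(o) >= min_species
  ortholog_table(o$groups[keep, , drop = FALSE], o$annotations)
}

#' Drop ortholog groups with sex-linked members
#'
#' Removes every group in which at least one ortholog lies on a chromosome
#' (or Muller element) named by a removal rule, e.g. Muller A / the X in
#' several species. A group is dropped entirely if any of its members
#' matches any rule.
#'
#' @param o An [ortholog_table()] with chromosome annotations.
#' @param removal_rules Data frame with columns `species` and `label`; a
#'   gene matches when its `chromosome` or `muller` annotation equals
#'   `label` in that species.
#' @return Filtered [ortholog_table()].
#' @export
filter_autosomal <- function(o, removal_rules) {
  removal_rules <- as.data.frame(removal_rules)
  if (nrow(removal_rules) == 0) return(o)
  stopifnot(all(c("species", "label") %in% names(removal_rules)))
  sp <- ortholog_species(o)
  unknown <- setdiff(unique(removal_rules$species), sp)
  if (length(unknown)) {
    stop("removal rule names unknown species: ", paste(unknown, collapse = ", "))
  }
  ann <- o$annotations
  if (is.null(ann)) stop("filter_autosomal needs chromosome annotations")
  flagged <- character(0)
  for (i in seq_len(nrow(removal_rules))) {
    s <- removal_rules$species[i]; lab <- removal_rules$label[i]
    hit <- ann$species == s &
      (ann$chromosome %in% lab | (!is.null(ann$muller) & ann$muller %in% lab))
    flagged <- c(flagged, ann$gene[hit])
  }
  drop <- rep(FALSE, nrow(o$groups))
  for (s in unique(removal_rules$species)) {
    drop <- drop | o$groups[[s]] %in% setdiff(flagged, "")
  }
  ortholog_table(o$groups[!drop, , drop = FALSE], ann)
}
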