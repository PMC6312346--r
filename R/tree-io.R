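#' Read and validate a rooted phylogeny
#'
#' Thin wrapper over [ape::read.tree()] that enforces the contract the
#' downstream reconstruction assumes: a rooted tree, unique tip labels,
#' and non-negative branch lengths on every edge.
#'
#' @param path Newick file.
#' @param species Optional character vector; when given, every tip label
#'   must be one of these species (outgroups included by the caller).
#' @return An [ape::phylo] object.
#' @export
read_tree <- function(path, species = NULL) {
  tree <- ape::read.tree(path)
  if (is.null(tree)) stop("could not parse newick file: ", path)
  validate_tree(tree, species)
}

#' @rdname read_tree
#' @param tree A `phylo` object to validate in memory.
#' @export
validate_tree <- function(tree, species = NULL) {
  stopifnot(inherits(tree, "phylo"))
  if (anyDuplicated(tree$tip.label)) stop("duplicate tip labels in tree")
  if (!ape::is.rooted(tree)) stop("tree must be rooted")
  if (is.null(tree$edge.length)) stop("tree must have branch lengths")
  if (any(!is.finite(tree$edge.length)) || any(tree$edge.length < 0)) {
    stop("branch lengths must be finite and >= 0")
  }
  if (!is.null(species)) {
    extra <- setdiff(tree$tip.label, species)
    if (length(extra)) {
      stop("tip label(s) not in the species list: ", paste(extra, collapse = ", "))
    }
  }
  tree
}

#' Write a tree to newick
#' @param tree A `phylo` object.
#' @param path Output file.
#' @export
write_tree <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}
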