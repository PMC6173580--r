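#' Read and write rooted phylogenies in Newick format
#'
#' Thin wrappers around [ape::read.tree()] / [ape::write.tree()] that enforce
#' the contracts the mapping machinery relies on: the tree is rooted, every
#' tip is labelled and labels are unique, every edge carries a non-negative
#' branch length, and polytomies are resolved into binary nodes with
#' zero-length branches (with a message). Writing uses 10 significant digits
#' so a read/write round trip preserves topology and branch lengths.
#'
#' @param path Newick file.
#' @return `read_newick()` returns an [ape::phylo] object.
#' @export
read_newick <- function(path) {
  tr <- tryCatch(ape::read.tree(path),
                 error = function(e) stop_input("cannot parse Newick '%s': %s",
                                                path, conditionMessage(e)))
  if (is.null(tr)) stop_input("Newick file '%s' contains no tree", path)
  validate_tree(tr)
}

#' @rdname read_newick
#' @param tree A rooted `phylo` tree.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path, digits = 10)
  invisible(path)
}

#' @rdname read_newick
#' @export
validate_tree <- function(tree) {
  if (!inherits(tree, "phylo")) stop_input("not a phylo object")
  if (is.null(tree$tip.label) || any(is.na(tree$tip.label)) ||
      any(!nzchar(tree$tip.label)))
    stop_input("tree has an unlabelled tip")
  if (anyDuplicated(tree$tip.label))
    stop_input("duplicate tip label '%s'",
               tree$tip.label[duplicated(tree$tip.label)][1])
  if (is.null(tree$edge.length))
    stop_input("tree lacks branch lengths")
  if (anyNA(tree$edge.length))
    stop_input("tree has edges without branch lengths")
  if (any(tree$edge.length < 0))
    stop_input("negative branch length in tree")
  if (!ape::is.rooted(tree)) stop_input("tree must be rooted")
  if (!ape::is.binary(tree)) {
    inform("resolving polytomies with zero-length branches")
    tree <- ape::multi2di(tree)
    tree$edge.length[is.na(tree$edge.length)] <- 0
  }
  tree
}
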