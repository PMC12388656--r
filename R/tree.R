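#' Read a rooted, branch-lengthed phylogeny from newick
#'
#' Trees are consumed, not inferred, by this package. Unrooted inputs are
#' midpoint-rooted (loudly). Branch lengths are required because all
#' downstream phylogenetic metrics (betaMNTD, Faith's PD, weighted UniFrac)
#' are in branch-length units.
#'
#' @param path newick file path.
#' @param table optional [community_table()]; tips absent from the table
#'   trigger a warning, and `prune = TRUE` drops them.
#' @param prune drop tips not present in `table`.
#' @return an [ape::read.tree()] `phylo` object, rooted.
#' @export
read_tree <- function(path, table = NULL, prune = FALSE) {
  if (!file.exists(path)) abort(paste0("File not found: ", path))
  tree <- tryCatch(ape::read.tree(path),
                   error = function(e) abort(paste0("Malformed newick: ",
                                                    conditionMessage(e))))
  if (is.null(tree)) abort("Malformed newick: no tree parsed.")
  tree <- validate_tree(tree)
  if (!is.null(table)) {
    extra <- setdiff(tree$tip.label, colnames(table$counts))
    if (length(extra)) {
      warn(sprintf("%d tree tips are absent from the community table.",
                   length(extra)))
      if (prune) tree <- ape::drop.tip(tree, extra)
    }
  }
  tree
}

#' Validate (and if needed midpoint-root) a phylogeny
#' @param tree a `phylo` object.
#' @return the validated, rooted tree.
#' @export
validate_tree <- function(tree) {
  if (is.null(tree$edge.length))
    abort("Tree has no branch lengths; they are required.")
  if (any(tree$edge.length < 0))
    abort("Negative branch lengths.")
  if (anyDuplicated(tree$tip.label))
    abort("Duplicated tip labels.")
  if (!ape::is.rooted(tree)) {
    inform("Input tree is unrooted; midpoint-rooting it.")
    tree <- phangorn::midpoint(tree)
  }
  tree
}

#' Restrict a tree to the taxa of a community table
#' @param tree a `phylo`.
#' @param ct a [community_table()].
#' @return the pruned tree.
#' @export
prune_tree <- function(tree, ct) {
  extra <- setdiff(tree$tip.label, colnames(ct$counts))
  missing <- setdiff(colnames(ct$counts), tree$tip.label)
  if (length(missing))
    abort(paste0("Taxa absent from the tree: ",
                 paste(utils::head(missing, 10), collapse = ", ")))
  if (length(extra)) {
    warn(sprintf("Pruning %d tree tips absent from the table.", length(extra)))
    tree <- ape::drop.tip(tree, extra)
  }
  tree
}

#' Write a tree to newick
#' @param tree a `phylo`.
#' @param path output path.
#' @export
write_tree <- function(tree, path) {
  ape::write.tree(tree, file = path, digits = 12)
  invisible(tree)
}

# Patristic (cophenetic) distances between tips, ordered as `taxa`.
patristic_matrix <- function(tree, taxa = tree$tip.label) {
  missing <- setdiff(taxa, tree$tip.label)
  if (length(missing))
    abort(paste0("Taxa absent from the tree: ",
                 paste(utils::head(missing, 10), collapse = ", ")))
  d <- ape::cophenetic.phylo(tree)
  d[taxa, taxa, drop = FALSE]
}
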