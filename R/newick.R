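#' Read a rooted phylogeny from Newick
#'
#' Thin validating wrapper around [ape::read.tree()].  The tree must be a
#' single rooted tree with unique tip labels and a branch length on every
#' non-root edge; branch lengths must be non-negative.
#'
#' @param path_or_text Path to a Newick file, or a Newick string (detected by
#'   a terminal semicolon).
#' @return An [ape::phylo] object.
#' @export
read_newick <- function(path_or_text) {
  is_text <- grepl(";\\s*$", path_or_text[1L]) && !file.exists(path_or_text[1L])
  tr <- if (is_text) ape::read.tree(text = path_or_text)
        else {
          if (!file.exists(path_or_text)) stop("tree file not found: ", path_or_text)
          ape::read.tree(path_or_text)
        }
  if (is.null(tr)) stop("could not parse Newick input (unbalanced parentheses?)")
  if (inherits(tr, "multiPhylo")) {
    if (length(tr) != 1L) stop("expected a single tree, found ", length(tr))
    tr <- tr[[1L]]
  }
  validate_phylogeny(tr)
}

#' Validate a phylogeny for use in this package
#'
#' @param tree An [ape::phylo] object.
#' @return The tree, invisibly unchanged, or an error.
#' @export
validate_phylogeny <- function(tree) {
  if (!inherits(tree, "phylo")) stop("not a phylo object")
  if (anyDuplicated(tree$tip.label))
    stop("duplicate tip labels: ",
         paste(unique(tree$tip.label[duplicated(tree$tip.label)]), collapse = ", "))
  if (is.null(tree$edge.length))
    stop("tree has no branch lengths")
  if (length(tree$edge.length) != nrow(tree$edge) || anyNA(tree$edge.length))
    stop("missing branch length on a non-root edge")
  if (any(tree$edge.length < 0)) stop("negative branch length")
  tree
}

#' Write a phylogeny to Newick
#'
#' @param tree An [ape::phylo] object.
#' @param path Output path; when `NULL` the Newick string is returned.
#' @return `path` invisibly, or the Newick string when `path` is `NULL`.
#' @export
write_newick <- function(tree, path = NULL) {
  validate_phylogeny(tree)
  txt <- ape::write.tree(tree, digits = 12)
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(path)
}
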