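#' @include AllClasses.R
NULL

#' Read a newick tree, honoring "#1" foreground branch marks
#'
#' Branch-site analyses designate foreground branches by suffixing the label
#' of the node a branch leads to with `#1` (tip or internal). The marks are
#' stripped from the labels and stored as a logical edge attribute.
#'
#' @param file newick file; alternatively give `text`.
#' @param text newick string.
#' @return an `ape::phylo` with attribute `foreground`: logical, one entry
#'   per row of `tree$edge`, `TRUE` for marked branches.
#' @export
readMarkedTree <- function(file = NULL, text = NULL) {
  tr <- if (!is.null(text)) ape::read.tree(text = text) else ape::read.tree(file)
  if (is.null(tr)) stop("could not parse newick input")
  markedTips <- grepl("#\\d+$", tr$tip.label)
  tr$tip.label <- sub("#\\d+$", "", tr$tip.label)
  markedNodes <- rep(FALSE, tr$Nnode)
  if (!is.null(tr$node.label)) {
    markedNodes <- grepl("#\\d+$", tr$node.label)
    tr$node.label <- sub("#\\d+$", "", tr$node.label)
    if (all(tr$node.label == "")) tr$node.label <- NULL
  }
  ntip <- length(tr$tip.label)
  markedNodeIds <- c(which(markedTips), ntip + which(markedNodes))
  fg <- tr$edge[, 2] %in% markedNodeIds
  attr(tr, "foreground") <- fg
  tr
}

#' Write a tree with "#1" foreground marks
#'
#' @param tree `phylo` with optional `foreground` attribute.
#' @param file output path; if `NULL`, the newick string is returned.
#' @export
writeMarkedTree <- function(tree, file = NULL) {
  fg <- foregroundEdges(tree)
  if (any(fg)) {
    ntip <- length(tree$tip.label)
    targets <- tree$edge[fg, 2]
    tipT <- targets[targets <= ntip]
    nodeT <- targets[targets > ntip]
    tree$tip.label[tipT] <- paste0(tree$tip.label[tipT], "#1")
    if (length(nodeT)) {
      if (is.null(tree$node.label)) tree$node.label <- rep("", tree$Nnode)
      tree$node.label[nodeT - ntip] <- paste0(tree$node.label[nodeT - ntip], "#1")
    }
  }
  attr(tree, "foreground") <- NULL
  txt <- ape::write.tree(tree)
  if (is.null(file)) return(txt)
  writeLines(txt, file)
  invisible(file)
}

#' @rdname readMarkedTree
#' @param tree a `phylo`.
#' @export
foregroundEdges <- function(tree) {
  fg <- attr(tree, "foreground")
  if (is.null(fg)) fg <- rep(FALSE, nrow(tree$edge))
  fg
}

#' Mark the branches of a clade as foreground
#'
#' Marks the terminal and internal branches of the smallest clade containing
#' `tips`, plus (optionally) its stem branch.
#'
#' @param tree a `phylo`.
#' @param tips character, tip labels spanning the clade.
#' @param stem include the branch leading into the clade ancestor.
#' @return the tree with its `foreground` attribute set.
#' @export
markForeground <- function(tree, tips, stem = TRUE) {
  stopifnot(all(tips %in% tree$tip.label))
  ids <- match(tips, tree$tip.label)
  if (length(ids) == 1) {
    nodes <- ids
  } else {
    mrca <- ape::getMRCA(tree, ids)
    nodes <- descendantNodes(tree, mrca)  # descendants, mrca excluded
    if (stem) nodes <- c(nodes, mrca)
  }
  attr(tree, "foreground") <- tree$edge[, 2] %in% nodes
  tree
}

# all strict descendant node ids of `node`
descendantNodes <- function(tree, node) {
  out <- integer(0)
  stack <- node
  while (length(stack)) {
    nd <- stack[[1]]; stack <- stack[-1]
    kids <- tree$edge[tree$edge[, 1] == nd, 2]
    out <- c(out, kids)
    stack <- c(stack, kids[kids > length(tree$tip.label)])
  }
  unique(out)
}

# deterministic binary resolution of polytomies (no randomness)
ensureBinary <- function(tree) {
  if (!ape::is.binary(tree)) {
    fg <- attr(tree, "foreground")
    tree2 <- ape::multi2di(tree, random = FALSE)
    if (!is.null(fg)) {
      # zero-length inserted edges are background; original child nodes keep marks
      warning("polytomies resolved deterministically; foreground marks dropped")
      attr(tree2, "foreground") <- rep(FALSE, nrow(tree2$edge))
    }
    tree2
  } else tree
}
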