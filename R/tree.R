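# Phylogeny utilities built on ape. Branches are named after the node (tip or
# internal) at their child end; unlabelled internal nodes get stable synthetic
# labels so event placement is addressable on any tree.

#' Read a rooted phylogeny from Newick
#'
#' Thin wrapper over [ape::read.tree()] that validates tip names, fills in
#' missing internal-node labels (`node_<k>`), and fails with a clear message
#' on malformed input.
#'
#' @param x Path to a Newick file, or a Newick string.
#' @return An [ape::phylo] object with unique tip labels and complete node
#'   labels.
#' @export
read_tree <- function(x) {
  tr <- if (length(x) == 1L && grepl("[(;]", x)) {
    tryCatch(ape::read.tree(text = x),
             error = function(e) stop("Newick parse error: ", conditionMessage(e)))
  } else {
    if (!file.exists(x)) stop("tree file not found: ", x)
    tryCatch(ape::read.tree(x),
             error = function(e) stop("Newick parse error in '", x, "': ",
                                      conditionMessage(e)))
  }
  if (is.null(tr)) stop("Newick parse error: could not read a tree")
  if (anyDuplicated(tr$tip.label))
    stop("duplicate tip labels: ",
         paste(unique(tr$tip.label[duplicated(tr$tip.label)]), collapse = ", "))
  nn <- tr$Nnode
  if (is.null(tr$node.label)) tr$node.label <- character(nn)
  fill <- !nzchar(tr$node.label)
  tr$node.label[fill] <- paste0("node_", which(fill))
  if (anyDuplicated(c(tr$tip.label, tr$node.label)))
    stop("tip and node labels must be unique")
  tr
}

#' Write a phylogeny to Newick
#' @param tree An [ape::phylo].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_tree <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

# label of every node (tips first, as in ape numbering)
node_labels <- function(tree) c(tree$tip.label, tree$node.label)

# name of the branch subtending each non-root node
branch_labels <- function(tree) {
  labs <- node_labels(tree)
  root <- ape::Ntip(tree) + 1L
  labs[setdiff(seq_along(labs), root)]
}

# tips descending from a node (by ape node number)
clade_tips <- function(tree, node) {
  ntip <- ape::Ntip(tree)
  if (node <= ntip) return(tree$tip.label[node])
  kids <- tree$edge[tree$edge[, 1] == node, 2]
  unlist(lapply(kids, clade_tips, tree = tree))
}

# branch labels on the root-to-tip path (excluding the root itself)
path_branches <- function(tree, tip) {
  labs <- node_labels(tree)
  node <- match(tip, labs)
  if (is.na(node)) stop("tip not in tree: ", tip)
  root <- ape::Ntip(tree) + 1L
  out <- character(0)
  while (node != root) {
    out <- c(labs[node], out)
    node <- tree$edge[tree$edge[, 2] == node, 1]
  }
  out
}

# node number for a tip or internal label
node_number <- function(tree, label) {
  i <- match(label, node_labels(tree))
  if (is.na(i)) stop("label not in tree: ", label)
  i
}
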