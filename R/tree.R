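#' Species phylogeny with supergroup labels
#'
#' Wraps a rooted `ape::phylo` tree together with a leaf-to-supergroup map.
#' The root node is the Last Eukaryotic Common Ancestor (LECA) for every
#' ancestral-state query in the package. Multifurcations are allowed; the
#' only structural requirements are that the tree is rooted and that every
#' species scored in any presence matrix appears as exactly one leaf.
#'
#' @param tree a rooted `phylo` object (see [ape::read.tree()]).
#' @param supergroups named character vector mapping every leaf label to a
#'   supergroup label (e.g. "Opisthokonta", "Archaeplastida").
#' @return an object of class `phylogeny`: the `phylo` tree (with internal
#'   node labels filled in, root labelled `"LECA"` when unnamed) plus the
#'   supergroup map and the integer id of the root node.
#' @export
phylogeny <- function(tree, supergroups) {
  if (!inherits(tree, "phylo")) stop_snotrace("tree must be an ape 'phylo' object")
  if (!ape::is.rooted(tree)) stop_snotrace("tree must be rooted")
  ntip <- length(tree$tip.label)
  root <- ntip + 1L
  nnode <- tree$Nnode
  if (is.null(tree$node.label) || !length(tree$node.label)) {
    tree$node.label <- paste0("n", seq_len(nnode))
  }
  empty <- is.na(tree$node.label) | tree$node.label == ""
  tree$node.label[empty] <- paste0("n", which(empty))
  if (tree$node.label[1L] %in% c("", paste0("n", 1L)) &&
      !("LECA" %in% tree$node.label)) {
    tree$node.label[1L] <- "LECA"
  }
  missing_sg <- setdiff(tree$tip.label, names(supergroups))
  if (length(missing_sg)) {
    stop_snotrace("no supergroup label for leaves: %s",
                  paste(missing_sg, collapse = ", "))
  }
  kids <- tabulate(tree$edge[, 1L], nbins = ntip + nnode)
  if (kids[root] < 2L) stop_snotrace("root must have >= 2 children")
  structure(
    list(tree = tree,
         supergroups = supergroups[tree$tip.label],
         root = root),
    class = "phylogeny"
  )
}

#' Read a species tree (Newick) and its supergroup map (TSV)
#'
#' @param newick_file path to a rooted Newick tree; leaf labels are species
#'   ids.
#' @param supergroup_file path to a two-column TSV (`species`, `supergroup`)
#'   with header.
#' @return a [phylogeny] object.
#' @export
read_species_tree <- function(newick_file, supergroup_file) {
  tree <- ape::read.tree(newick_file)
  sg <- utils::read.delim(supergroup_file, stringsAsFactors = FALSE)
  if (!all(c("species", "supergroup") %in% names(sg))) {
    stop_snotrace("supergroup table needs columns 'species' and 'supergroup'")
  }
  phylogeny(tree, stats::setNames(sg$supergroup, sg$species))
}

#' Write a phylogeny back to Newick + supergroup TSV
#' @param phy a [phylogeny] object.
#' @param newick_file,supergroup_file output paths.
#' @return invisibly, the two paths.
#' @export
write_species_tree <- function(phy, newick_file, supergroup_file) {
  ape::write.tree(phy$tree, file = newick_file)
  utils::write.table(
    data.frame(species = names(phy$supergroups),
               supergroup = unname(phy$supergroups)),
    supergroup_file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(newick_file, supergroup_file))
}

#' @export
print.phylogeny <- function(x, ...) {
  cat(sprintf("<phylogeny> %d leaves, %d internal nodes, root = %s\n",
              length(x$tree$tip.label), x$tree$Nnode, node_label(x, x$root)))
  cat("supergroups:",
      paste(sprintf("%s (%d)", names(table(x$supergroups)),
                    as.integer(table(x$supergroups))), collapse = ", "), "\n")
  invisible(x)
}

# ---- internal node arithmetic (integer node ids, ape convention) ----------

n_nodes <- function(phy) length(phy$tree$tip.label) + phy$tree$Nnode

node_label <- function(phy, node) {
  ntip <- length(phy$tree$tip.label)
  c(phy$tree$tip.label, phy$tree$node.label)[node]
}

node_id <- function(phy, label) {
  ntip <- length(phy$tree$tip.label)
  hit <- match(label, c(phy$tree$tip.label, phy$tree$node.label))
  if (anyNA(hit)) {
    stop_snotrace("unknown node label(s): %s",
                  paste(label[is.na(hit)], collapse = ", "))
  }
  hit
}

leaf_ids <- function(phy, species) {
  hit <- match(species, phy$tree$tip.label)
  if (anyNA(hit)) {
    stop_snotrace("unknown taxa: %s", paste(species[is.na(hit)], collapse = ", "))
  }
  hit
}

# parent of every node (0 for the root), children list, postorder node order.
tree_index <- function(phy) {
  e <- phy$tree$edge
  n <- n_nodes(phy)
  parent <- integer(n)
  parent[e[, 2L]] <- e[, 1L]
  children <- vector("list", n)
  for (i in seq_len(nrow(e))) {
    children[[e[i, 1L]]] <- c(children[[e[i, 1L]]], e[i, 2L])
  }
  # postorder: children before parents
  post <- integer(0)
  stack <- phy$root
  seen <- integer(0)
  while (length(stack)) {
    nd <- stack[length(stack)]
    stack <- stack[-length(stack)]
    seen <- c(seen, nd)
    stack <- c(stack, children[[nd]])
  }
  post <- rev(seen)
  list(parent = parent, children = children, postorder = post, edge = e)
}

# leaves (tip ids) under each node, as a list indexed by node id.
leafsets <- function(phy, idx = tree_index(phy)) {
  n <- n_nodes(phy)
  ntip <- length(phy$tree$tip.label)
  ls <- vector("list", n)
  for (nd in idx$postorder) {
    if (nd <= ntip) ls[[nd]] <- nd
    else ls[[nd]] <- sort(unlist(ls[idx$children[[nd]]]))
  }
  ls
}

# MRCA of a set of tip ids (handles a single tip, where ape::getMRCA does not).
mrca_id <- function(phy, tips) {
  tips <- unique(tips)
  if (!length(tips)) stop_snotrace("MRCA of an empty tip set is undefined")
  if (length(tips) == 1L) return(tips)
  ape::getMRCA(phy$tree, tips)
}

# is `anc` an ancestor of (or equal to) `node`?
is_ancestor <- function(phy, anc, node, idx = tree_index(phy)) {
  while (node != 0L) {
    if (node == anc) return(TRUE)
    node <- idx$parent[node]
  }
  FALSE
}
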