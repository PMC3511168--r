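# Dollo-parsimony ancestral-state reconstruction.
#
# Each binary character (a snoRNA family, clan, intron locus or target-site
# locus) is allowed exactly one gain; all homoplasy is explained by losses.
# Under that model the most-parsimonious scenario is fully determined: the
# gain sits at the MRCA of all presence leaves and losses are assigned to the
# highest branches whose subtrees contain only absence leaves.

#' Presence/absence character matrix
#'
#' @param states integer/logical matrix, rows = characters, columns = species;
#'   values strictly 0/1. Row and column names are required.
#' @param kind one of `"family"`, `"clan"`, `"intron_locus"`, `"site_locus"`;
#'   may also be a per-character vector.
#' @return a `presence_matrix`: an integer matrix with a `kind` attribute.
#' @export
presence_matrix <- function(states,
                            kind = c("family", "clan", "intron_locus", "site_locus")) {
  states <- as.matrix(states)
  if (is.null(rownames(states)) || is.null(colnames(states))) {
    stop_snotrace("presence matrix needs character rownames and species colnames")
  }
  mode(states) <- "integer"
  if (!all(states %in% c(0L, 1L))) stop_snotrace("states must be strictly 0/1")
  kinds_ok <- c("family", "clan", "intron_locus", "site_locus")
  if (identical(kind, kinds_ok) || length(kind) == 1L) {
    kind <- match.arg(kind)
  } else if (length(kind) != nrow(states)) {
    stop_snotrace("kind must be length 1 or one per character")
  }
  structure(states, kind = kind, class = c("presence_matrix", "matrix"))
}

#' Read / write a presence matrix as TSV (rows = characters, columns = species)
#' @param file path to a TSV with a `character_id` first column.
#' @param kind character kind, as in [presence_matrix()].
#' @return a `presence_matrix`.
#' @export
read_presence_matrix <- function(file, kind = "family") {
  d <- utils::read.delim(file, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(d[, -1L, drop = FALSE])
  rownames(m) <- d[[1L]]
  presence_matrix(m, kind)
}

#' @rdname read_presence_matrix
#' @param mat a `presence_matrix` to serialise.
#' @export
write_presence_matrix <- function(mat, file) {
  d <- data.frame(character_id = rownames(mat), mat, check.names = FALSE)
  utils::write.table(d, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' Gain node of a character under Dollo parsimony
#'
#' The single origin compatible with Dollo parsimony is the most recent
#' common ancestor of all leaves carrying the character.
#'
#' @param phy a [phylogeny].
#' @param leaf_states named 0/1 vector over (a subset of) the leaves; species
#'   not named are treated as absent.
#' @return the label of the gain node.
#' @export
infer_gain_node <- function(phy, leaf_states) {
  present <- names(leaf_states)[leaf_states == 1L]
  if (!length(present)) stop_snotrace("all-zero character: no gain node exists")
  node_label(phy, mrca_id(phy, leaf_ids(phy, present)))
}

#' Dollo-parsimony reconstruction of a presence matrix
#'
#' For every character the gain is placed at the MRCA of its presence leaves
#' and losses on the maximal all-absent subtrees below the gain; this is the
#' unique minimum-loss single-gain scenario. Species present in the tree but
#' missing from the matrix are scored absent (the conservative default; pass
#' them through `unscored` to mask instead, in which case they constrain
#' neither gains nor losses).
#'
#' @param phy a [phylogeny].
#' @param mat a [presence_matrix] (characters x species).
#' @param unscored optional character vector of species to ignore entirely.
#' @return a `dollo_recon` object: per-character gain node, loss branches
#'   (labelled by the child node of the lost edge), minimum loss count, and a
#'   characters x nodes state matrix.
#' @export
dollo_reconstruct <- function(phy, mat, unscored = NULL) {
  if (!inherits(mat, "presence_matrix")) mat <- presence_matrix(mat)
  taxa <- colnames(mat)
  leaf_ids(phy, taxa)  # errors on unknown taxa
  if (!is.null(unscored)) taxa <- setdiff(taxa, unscored)
  idx <- tree_index(phy)
  n <- n_nodes(phy)
  ntip <- length(phy$tree$tip.label)
  nchar_ <- nrow(mat)

  # leaf presence per character over ALL tree leaves (absent when unlisted,
  # unless the taxon is masked as unscored)
  leafstate <- matrix(0L, nchar_, ntip,
                      dimnames = list(rownames(mat), phy$tree$tip.label))
  leafstate[, taxa] <- mat[, taxa, drop = FALSE]
  scored <- stats::setNames(rep(TRUE, ntip), phy$tree$tip.label)
  if (!is.null(unscored)) scored[intersect(unscored, names(scored))] <- FALSE

  # per-node counts of present and of scored-absent leaves (postorder sweep)
  cnt <- matrix(0L, nchar_, n)
  cnt[, seq_len(ntip)] <- leafstate
  abs_cnt <- matrix(0L, nchar_, n)
  abs_cnt[, seq_len(ntip)] <- (leafstate == 0L) *
    rep(as.integer(scored), each = nchar_)
  for (nd in idx$postorder) {
    if (nd > ntip) {
      ch <- idx$children[[nd]]
      cnt[, nd] <- rowSums(cnt[, ch, drop = FALSE])
      abs_cnt[, nd] <- rowSums(abs_cnt[, ch, drop = FALSE])
    }
  }

  all_labels <- c(phy$tree$tip.label, phy$tree$node.label)
  states <- matrix(0L, nchar_, n, dimnames = list(rownames(mat), all_labels))
  gain <- character(nchar_)
  losses <- vector("list", nchar_)
  minloss <- integer(nchar_)
  e <- idx$edge

  for (k in seq_len(nchar_)) {
    pres <- which(leafstate[k, ] == 1L)
    if (!length(pres)) stop_snotrace("character '%s' is all-absent", rownames(mat)[k])
    g <- mrca_id(phy, pres)
    gain[k] <- node_label(phy, g)
    # under the gain node a node is present iff its subtree retains a carrier
    # (subtrees holding only unscored taxa carry no loss evidence and keep
    # the ancestral state)
    under <- vapply(seq_len(n), function(nd) is_ancestor(phy, g, nd, idx), logical(1))
    states[k, ] <- as.integer(under & (cnt[k, ] > 0L | abs_cnt[k, ] == 0L))
    loss_edges <- which(states[k, e[, 1L]] == 1L & under[e[, 2L]] &
                          cnt[k, e[, 2L]] == 0L & abs_cnt[k, e[, 2L]] > 0L)
    losses[[k]] <- node_label(phy, e[loss_edges, 2L])
    minloss[k] <- length(loss_edges)
  }

  structure(
    list(phy = phy,
         characters = rownames(mat),
         kind = attr(mat, "kind"),
         gain_node = stats::setNames(gain, rownames(mat)),
         loss_branches = stats::setNames(losses, rownames(mat)),
         min_losses = stats::setNames(minloss, rownames(mat)),
         node_states = states),
    class = "dollo_recon"
  )
}

#' @export
print.dollo_recon <- function(x, ...) {
  root_lab <- node_label(x$phy, x$phy$root)
  at_root <- sum(x$node_states[, root_lab] == 1L)
  cat(sprintf("<dollo_recon> %d characters (%s) on %d leaves\n",
              length(x$characters),
              paste(unique(x$kind), collapse = "/"),
              length(x$phy$tree$tip.label)))
  cat(sprintf("  present at root (%s): %d; total losses: %d\n",
              root_lab, at_root, sum(x$min_losses)))
  invisible(x)
}

#' Is a character present at an ancestral node?
#'
#' @param recon a `dollo_recon`.
#' @param character_id character id (row of the reconstructed matrix).
#' @param node node label; defaults to the root (LECA).
#' @return logical scalar.
#' @export
is_in_ancestor <- function(recon, character_id,
                           node = node_label(recon$phy, recon$phy$root)) {
  if (!character_id %in% recon$characters) {
    stop_snotrace("unknown character: %s", character_id)
  }
  node_id(recon$phy, node)  # errors on unknown node
  recon$node_states[character_id, node] == 1L
}

#' Character ids present at a node
#' @param recon a `dollo_recon`.
#' @param node node label (default: root / LECA).
#' @return character vector of character ids with state 1 at `node`.
#' @export
characters_at_node <- function(recon,
                               node = node_label(recon$phy, recon$phy$root)) {
  recon$characters[recon$node_states[, node] == 1L]
}

#' Count characters traceable to a node, by kind and snoRNA class
#'
#' @param recon a `dollo_recon` whose characters are families and/or clans.
#' @param catalog a [family_catalog()].
#' @param node node label (default root).
#' @return a data.frame with one row per (kind, class) combination plus
#'   totals, counting characters with state 1 at `node`.
#' @export
count_traceable <- function(recon, catalog,
                            node = node_label(recon$phy, recon$phy$root)) {
  ids <- characters_at_node(recon, node)
  kind <- if (length(recon$kind) == 1L) {
    rep(recon$kind, length(recon$characters))
  } else recon$kind
  names(kind) <- recon$characters
  cls <- vapply(ids, function(i) catalog_class(catalog, i), character(1))
  if (!length(ids)) {
    return(data.frame(kind = character(0), class = character(0), n = integer(0)))
  }
  out <- as.data.frame(table(kind = kind[ids], class = cls), stringsAsFactors = FALSE)
  names(out)[3L] <- "n"
  out[out$n > 0L, , drop = FALSE]
}

#' Brute-force Dollo oracle: exhaustive enumeration of node-state assignments
#'
#' Enumerates all 2^k assignments of states to the k internal nodes (leaves
#' fixed by `leaf_states`), keeps the assignments with exactly one origin
#' (a presence root, or a single 0 -> 1 edge) and returns the minimum number
#' of 1 -> 0 edges together with the root state realising it. Independent of
#' [dollo_reconstruct()]; intended as a test oracle on small trees.
#'
#' @param phy a [phylogeny] with at most 12 leaves.
#' @param leaf_states named 0/1 vector covering every leaf.
#' @return list with `min_losses` and `root_state`.
#' @export
brute_force_min_losses <- function(phy, leaf_states) {
  ntip <- length(phy$tree$tip.label)
  if (ntip > 12L) stop_snotrace("brute-force oracle limited to <= 12 leaves")
  if (!all(phy$tree$tip.label %in% names(leaf_states))) {
    stop_snotrace("leaf_states must cover every leaf")
  }
  if (sum(leaf_states[phy$tree$tip.label]) == 0L) {
    stop_snotrace("all-zero character: no single-gain scenario exists")
  }
  nint <- phy$tree$Nnode
  n <- ntip + nint
  e <- phy$tree$edge
  a <- as.matrix(expand.grid(rep(list(0:1), nint), KEEP.OUT.ATTRS = FALSE))
  S <- matrix(0L, nrow(a), n)
  S[, seq_len(ntip)] <- matrix(rep(as.integer(leaf_states[phy$tree$tip.label]),
                                   each = nrow(a)), nrow(a))
  S[, ntip + seq_len(nint)] <- a
  P <- S[, e[, 1L], drop = FALSE]
  C <- S[, e[, 2L], drop = FALSE]
  origins <- rowSums(P == 0L & C == 1L) + S[, phy$root]
  losses <- rowSums(P == 1L & C == 0L)
  valid <- origins == 1L
  if (!any(valid)) stop_snotrace("no valid single-gain assignment found")
  mins <- as.integer(min(losses[valid]))
  best <- valid & losses == mins
  roots <- unique(S[best, phy$root])
  if (length(roots) != 1L) {
    stop_snotrace("ambiguous root state among minimal scenarios (unexpected)")
  }
  list(min_losses = mins, root_state = as.integer(roots))
}
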