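quartet <- function() {
  phylogeny(ape::read.tree(text = "((A,B)n2,(C,D)n3)root;"),
            c(A = "U", B = "U", C = "B", D = "B"))
}

states <- function(...) {
  v <- c(...)
  stats::setNames(as.integer(v), names(v))
}

test_that("gain node is the MRCA of presence leaves", {
  phy <- quartet()
  expect_equal(infer_gain_node(phy, states(A = 1, B = 1, C = 1, D = 1)), "root")
  expect_equal(infer_gain_node(phy, states(A = 1, B = 0, C = 0, D = 0)), "A")
  expect_equal(infer_gain_node(phy, states(A = 1, B = 0, C = 1, D = 0)), "root")
  expect_equal(infer_gain_node(phy, states(A = 1, B = 1, C = 0, D = 0)), "n2")
  expect_error(infer_gain_node(phy, states(A = 0, B = 0, C = 0, D = 0)),
               "no gain")
})

test_that("reconstruction places gains and minimal losses on the quartet", {
  phy <- quartet()
  m <- presence_matrix(rbind(x = c(A = 1, B = 0, C = 1, D = 0),
                             y = c(A = 1, B = 1, C = 0, D = 0)))
  r <- dollo_reconstruct(phy, m)
  expect_equal(unname(r$gain_node["x"]), "root")
  expect_setequal(r$loss_branches$x, c("B", "D"))
  expect_equal(unname(r$min_losses["x"]), 2L)
  expect_equal(unname(r$node_states["x", "root"]), 1L)
  expect_equal(unname(r$gain_node["y"]), "n2")
  expect_equal(unname(r$min_losses["y"]), 0L)
  expect_equal(unname(r$node_states["y", "root"]), 0L)
  expect_true(is_in_ancestor(r, "x"))
  expect_false(is_in_ancestor(r, "y"))
  expect_error(dollo_reconstruct(phy, presence_matrix(
    rbind(x = c(A = 1, E = 1)))), "unknown taxa")
})

test_that("cross-supergroup presence traces to the root, confined clades do not", {
  phy <- make_supergroup_tree(4)
  sp <- phy$tree$tip.label
  m <- matrix(0L, 2, length(sp), dimnames = list(c("cross", "local"), sp))
  m["cross", c("uni1", "bik3")] <- 1L
  m["local", c("uni1", "uni2", "uni3")] <- 1L
  r <- dollo_reconstruct(phy, presence_matrix(m))
  expect_true(is_in_ancestor(r, "cross", "LECA"))
  expect_false(is_in_ancestor(r, "local", "LECA"))
})

test_that("reconstruction agrees with the exhaustive assignment oracle", {
  set.seed(101)
  for (rep_ in 1:4) {
    phy <- random_phylogeny(6)
    sp <- phy$tree$tip.label
    pats <- as.matrix(expand.grid(rep(list(0:1), 6)))[-1L, ]
    rownames(pats) <- sprintf("p%03d", seq_len(nrow(pats)))
    colnames(pats) <- sp
    r <- dollo_reconstruct(phy, presence_matrix(pats))
    root_lab <- snotrace:::node_label(phy, phy$root)
    for (k in seq_len(nrow(pats))) {
      bf <- brute_force_min_losses(phy, stats::setNames(pats[k, ], sp))
      expect_identical(unname(r$min_losses[k]), bf$min_losses)
      expect_identical(unname(r$node_states[k, root_lab]), bf$root_state)
    }
  }
})

test_that("is_in_ancestor matches a path-walk over gain and loss branches", {
  set.seed(7)
  phy <- random_phylogeny(7)
  sp <- phy$tree$tip.label
  pats <- matrix(rbinom(20 * 7, 1, 0.5), 20, 7,
                 dimnames = list(sprintf("c%02d", 1:20), sp))
  pats <- pats[rowSums(pats) > 0, , drop = FALSE]
  r <- dollo_reconstruct(phy, presence_matrix(pats))
  idx <- snotrace:::tree_index(phy)
  all_labels <- c(sp, phy$tree$node.label)
  for (k in rownames(pats)) {
    g <- snotrace:::node_id(phy, r$gain_node[[k]])
    loss_ids <- snotrace:::node_id(phy, r$loss_branches[[k]])
    for (nd in seq_along(all_labels)) {
      walk <- snotrace:::is_ancestor(phy, g, nd, idx) &&
        !any(vapply(loss_ids, function(l) {
          snotrace:::is_ancestor(phy, l, nd, idx)
        }, logical(1)))
      expect_identical(is_in_ancestor(r, k, all_labels[nd]), walk)
    }
  }
})

test_that("adding a presence leaf never moves the gain node tipward", {
  set.seed(13)
  phy <- random_phylogeny(8)
  sp <- phy$tree$tip.label
  idx <- snotrace:::tree_index(phy)
  for (rep_ in 1:25) {
    pres <- sample(sp, sample(1:7, 1))
    extra <- sample(setdiff(sp, pres), 1)
    v1 <- stats::setNames(as.integer(sp %in% pres), sp)
    v2 <- stats::setNames(as.integer(sp %in% c(pres, extra)), sp)
    g1 <- snotrace:::node_id(phy, infer_gain_node(phy, v1))
    g2 <- snotrace:::node_id(phy, infer_gain_node(phy, v2))
    expect_true(snotrace:::is_ancestor(phy, g2, g1, idx))
  }
})

test_that("count_traceable tallies planted root-spanning families by class", {
  phy <- quartet()
  cat <- family_catalog(data.frame(
    family_id = c("f1", "f2", "f3", "h1"), clan_id = c("", "", "", ""),
    class = c("CD", "CD", "CD", "HACA"),
    fun = rep("modification_guide", 4)))
  m <- matrix(0L, 4, 4, dimnames = list(c("f1", "f2", "f3", "h1"),
                                        c("A", "B", "C", "D")))
  m[c("f1", "f2", "f3"), ] <- 1L          # three CD families span the root
  m["h1", "A"] <- 1L                       # singleton H/ACA
  r <- dollo_reconstruct(phy, presence_matrix(m, "family"))
  counts <- count_traceable(r, cat)
  expect_equal(counts$n[counts$class == "CD"], 3L)
  expect_false("HACA" %in% counts$class)
})

test_that("taxa absent from the matrix count as absence, unscored taxa are masked", {
  phy <- quartet()
  m <- presence_matrix(rbind(x = c(A = 1, C = 1)))   # B, D unlisted
  r <- dollo_reconstruct(phy, m)
  expect_equal(unname(r$min_losses["x"]), 2L)        # B and D scored absent
  r2 <- dollo_reconstruct(phy, presence_matrix(
    rbind(x = c(A = 1, B = 0, C = 1, D = 0))), unscored = c("B", "D"))
  expect_equal(unname(r2$min_losses["x"]), 0L)       # masked taxa force no loss
  expect_equal(unname(r2$node_states["x", "root"]), 1L)
})
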