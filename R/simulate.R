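# Synthetic-data generator with full ground truth.
#
# Emulates the statistical structure the comparative pipeline assumes:
# single-origin snoRNA family gain with branch-wise loss on a two-supergroup
# (unikont/bikont) tree, intragenomic mobility among host introns, guide
# sequences exactly complementary to planted rRNA windows, independent gains
# of unrelated families into orthologous introns, and broader expression for
# host genes. Every stochastic draw flows from one seeded RNG; the truth
# tables record gain nodes, loss branches, planted site columns, mobility
# events and expected verdicts so that every pipeline stage can be checked
# against construction.

#' Simulation parameters
#'
#' Defaults define the package's reference study conditions: 2 supergroups x
#' 6 taxa, 50 ancestral families with per-branch loss probability 0.15, five
#' mobility events, 30 planted guide target sites of 10-14 nt on 1.8-kb
#' SSU/LSU rRNAs, 30 species-specific decoy snoRNAs, and a 0.5-nat expression
#' entropy gap across 37 tissues.
#'
#' @param taxa_per_supergroup leaves per supergroup.
#' @param supergroups supergroup labels (first = unikont side, second =
#'   bikont side of the root).
#' @param n_anc_families families born at the root (LECA).
#' @param n_new_families additional families born on uniformly drawn branches.
#' @param q_loss per-branch, per-family loss probability.
#' @param n_mobility planted copy-and-relocate events.
#' @param source_retain_prob probability the source copy is retained after a
#'   mobility event (retrotransposition keeps the template).
#' @param n_independent_pairs planted independent-gain pairs: two unrelated
#'   families homed at the same orthologous intron locus on opposite sides of
#'   the root (first pair different classes, second same class).
#' @param n_host_genes ortholog groups of host genes (present in all taxa).
#' @param introns_per_gene ancestral introns per host gene.
#' @param intron_loss_prob per-branch, per-intron loss probability.
#' @param n_derived_introns intron-gain events on random branches.
#' @param protein_len host protein length (amino acids, alignment columns).
#' @param protein_sub_rate per-branch, per-column substitution probability.
#' @param protein_del_prob per-branch probability of one 1-3-column deletion.
#' @param rrna_len named lengths of the SSU and LSU rRNAs.
#' @param rrna_sub_rate per-branch, per-position substitution probability
#'   (planted windows are kept invariant).
#' @param rrna_del_prob per-branch probability of one short deletion outside
#'   the planted windows.
#' @param n_sites planted guide target windows (split across subunits).
#' @param guide_len_range min/max planted guide length (nt).
#' @param sno_len snoRNA sequence length (nt).
#' @param n_decoys species-specific decoy snoRNAs with no planted
#'   complementarity.
#' @param frac_haca fraction of ancestral families of the H/ACA class.
#' @param n_cleavage_only C/D families flagged as cleavage-only (U3/snoU13
#'   style, excluded from target mapping).
#' @param n_clans number of multi-family clans among ancestral C/D families.
#' @param clan_size families per clan.
#' @param n_tissues expression tissues.
#' @param entropy_gap target mean entropy difference (nats) between host and
#'   non-host genes.
#' @param host_alpha symmetric Dirichlet concentration for host profiles.
#' @param n_expr_nonhost filler non-host genes in the expression matrix.
#' @param intergenic_prob probability a family is intergenic (no host).
#' @return a `sim_params` list.
#' @export
sim_params <- function(taxa_per_supergroup = 6L,
                       supergroups = c("Unikonta", "Bikonta"),
                       n_anc_families = 50L,
                       n_new_families = 5L,
                       q_loss = 0.15,
                       n_mobility = 5L,
                       source_retain_prob = 1,
                       n_independent_pairs = 2L,
                       n_host_genes = 14L,
                       introns_per_gene = 5L,
                       intron_loss_prob = 0.05,
                       n_derived_introns = 6L,
                       protein_len = 300L,
                       protein_sub_rate = 0.02,
                       protein_del_prob = 0.2,
                       rrna_len = c(SSU = 1800L, LSU = 1800L),
                       rrna_sub_rate = 0.01,
                       rrna_del_prob = 0.2,
                       n_sites = 30L,
                       guide_len_range = c(10L, 14L),
                       sno_len = 80L,
                       n_decoys = 30L,
                       frac_haca = 0.1,
                       n_cleavage_only = 2L,
                       n_clans = 6L,
                       clan_size = 2L,
                       n_tissues = 37L,
                       entropy_gap = 0.5,
                       host_alpha = 20,
                       n_expr_nonhost = 200L,
                       intergenic_prob = 0.05) {
  p <- as.list(environment())
  stopifnot(p$q_loss >= 0, p$q_loss <= 1, p$intron_loss_prob >= 0,
            p$intron_loss_prob <= 1, p$taxa_per_supergroup >= 1)
  structure(p, class = "sim_params")
}

# ladder newick for a set of labels: (((a,b),c),d)
ladder_newick <- function(labels) {
  s <- labels[1L]
  for (i in seq_along(labels)[-1L]) s <- sprintf("(%s,%s)", s, labels[i])
  s
}

#' Build the default two-supergroup species tree
#'
#' Two ladders (one per supergroup) joined at a root labelled LECA, mirroring
#' the unikont/bikont rooting of the eukaryote tree collapsed to two root
#' subtrees.
#'
#' @param taxa_per_supergroup leaves per side.
#' @param supergroups two supergroup labels.
#' @return a [phylogeny].
#' @export
make_supergroup_tree <- function(taxa_per_supergroup = 6L,
                                 supergroups = c("Unikonta", "Bikonta")) {
  pref <- substr(tolower(supergroups), 1L, 3L)
  left <- paste0(pref[1L], seq_len(taxa_per_supergroup))
  right <- paste0(pref[2L], seq_len(taxa_per_supergroup))
  nwk <- sprintf("(%s,%s)LECA;", ladder_newick(left), ladder_newick(right))
  tree <- ape::read.tree(text = nwk)
  sg <- stats::setNames(rep(supergroups, each = taxa_per_supergroup),
                        c(left, right))
  phylogeny(tree, sg)
}

#' Random rooted phylogeny (for oracle sweeps)
#'
#' Wraps [ape::rtree()] (driven by the current RNG) and splits the leaves
#' into two pseudo-supergroups at the root.
#'
#' @param n number of leaves.
#' @return a [phylogeny].
#' @export
random_phylogeny <- function(n) {
  tree <- ape::rtree(n, rooted = TRUE, br = NULL)
  phy0 <- list(tree = tree, root = n + 1L)
  class(phy0) <- "phylogeny"
  idx <- tree_index(phy0)
  kids <- idx$children[[n + 1L]]
  ls <- leafsets(phy0, idx)
  sg <- stats::setNames(rep("B", n), tree$tip.label)
  sg[tree$tip.label[ls[[kids[1L]]]]] <- "A"
  phylogeny(tree, sg)
}

# preorder node order (parents before children) and root->node path helpers
preorder_nodes <- function(phy, idx = tree_index(phy)) rev(idx$postorder)

root_path <- function(phy, node, idx) {
  path <- integer(0)
  while (node != 0L) { path <- c(node, path); node <- idx$parent[node] }
  path
}

# ---- family evolution ------------------------------------------------------

#' Simulate snoRNA family gain and loss on the tree
#'
#' Ancestral families are born at the root; each extra family at a uniformly
#' drawn non-root node (= its subtending branch). Along every branch each
#' carried family is lost independently with probability `q_loss`. The truth
#' table records the gain node, realised loss branches and the expected LECA
#' status (ancestral AND surviving carriers in both root subtrees).
#'
#' @param phy a [phylogeny].
#' @param params a [sim_params()].
#' @return list: `presence` ([presence_matrix], families x species),
#'   `families` (data.frame incl. clan/class/function assignments) and
#'   `truth` (gain node, loss branches, expected_leca per family).
#' @export
simulate_family_evolution <- function(phy, params = sim_params()) {
  ntip <- length(phy$tree$tip.label)
  if (ntip == 0L) stop_snotrace("tree has no taxa")
  idx <- tree_index(phy)
  ls <- leafsets(phy, idx)
  n_anc <- params$n_anc_families
  n_new <- params$n_new_families
  fam_ids <- sprintf("RF%05d", seq_len(n_anc + n_new))
  origin <- c(rep(phy$root, n_anc),
              sample(setdiff(seq_len(n_nodes(phy)), phy$root), n_new,
                     replace = TRUE))

  # class / function / clan assignment over ancestral families
  fun <- rep("modification_guide", n_anc + n_new)
  cls <- rep("CD", n_anc + n_new)
  if (params$n_cleavage_only > 0L) {
    fun[seq_len(min(params$n_cleavage_only, n_anc))] <- "cleavage_only"
  }
  n_haca <- round(params$frac_haca * n_anc)
  if (n_haca > 0L) {
    haca_pool <- which(fun == "modification_guide" & seq_along(fun) <= n_anc)
    cls[utils::tail(haca_pool, n_haca)] <- "HACA"
  }
  clan <- rep("", n_anc + n_new)
  cd_guides <- which(cls == "CD" & fun == "modification_guide" &
                       seq_along(cls) <= n_anc)
  nc <- min(params$n_clans, length(cd_guides) %/% params$clan_size)
  for (ci in seq_len(nc)) {
    members <- cd_guides[(ci - 1L) * params$clan_size + seq_len(params$clan_size)]
    clan[members] <- sprintf("CL%05d", ci)
  }

  # gain/loss sweep (preorder); presence state per node, losses recorded
  nfam <- length(fam_ids)
  state <- matrix(FALSE, nfam, n_nodes(phy))
  losses <- vector("list", nfam)
  for (nd in preorder_nodes(phy, idx)) {
    if (nd == phy$root) {
      state[, nd] <- origin == phy$root
      next
    }
    par <- idx$parent[nd]
    carried <- state[, par]
    lost <- carried & stats::runif(nfam) < params$q_loss
    state[, nd] <- (carried & !lost) | (origin == nd)
    for (k in which(lost)) {
      losses[[k]] <- c(losses[[k]], node_label(phy, nd))
    }
  }
  presence <- state[, seq_len(ntip), drop = FALSE] * 1L
  dimnames(presence) <- list(fam_ids, phy$tree$tip.label)

  kids <- idx$children[[phy$root]]
  in_subtree <- function(k, child) any(presence[k, ls[[child]]] == 1L)
  expected_leca <- vapply(seq_len(nfam), function(k) {
    origin[k] == phy$root && all(vapply(kids, function(ch) in_subtree(k, ch),
                                        logical(1)))
  }, logical(1))

  families <- data.frame(
    family_id = fam_ids, clan_id = clan, class = cls, fun = fun,
    gain_node = node_label(phy, origin), ancestral = origin == phy$root,
    stringsAsFactors = FALSE)
  truth <- data.frame(
    family_id = fam_ids, gain_node = families$gain_node,
    n_losses = lengths(losses),
    loss_branches = vapply(losses, function(x) paste(sort(x %||% character(0)),
                                                     collapse = ","), character(1)),
    expected_leca = expected_leca, n_carriers = rowSums(presence),
    stringsAsFactors = FALSE)
  list(presence = presence_matrix(presence, "family"),
       families = families, truth = truth)
}

# ---- sequence-level machinery ---------------------------------------------

# qualifying antisense windows of a snoRNA against an rRNA: all length
# 10..19 windows at >= min_id identity between revcomp(sno) and the rRNA
# (any longer qualifying window necessarily contains one of these). Used by
# the generator to certify absence of unplanted complementarity; kept
# independent of the search implementation in guides.R.
antisense_windows_brute <- function(sno, rrna, min_len = 10L, min_id = 0.9,
                                    max_len = 19L, seed_w = NULL) {
  qc <- revcomp(sno)
  nq <- nchar(qc); nr <- nchar(rrna)
  if (nq < min_len || nr < min_len) {
    return(data.frame(sno_start = integer(0), sno_end = integer(0),
                      r_start = integer(0), r_end = integer(0),
                      len = integer(0), identity = numeric(0)))
  }
  qch <- seq_chars(qc); rch <- seq_chars(rrna)
  diag_set <- (-nq + min_len):(nr - min_len)
  if (!is.null(seed_w)) {
    # any <= 1-mismatch-per-10 window holds an exact run >= 5; restricting to
    # diagonals sharing a seed_w-mer is lossless for min_id >= 0.9
    qw <- substring(qc, seq_len(nq - seed_w + 1L),
                    seq_len(nq - seed_w + 1L) + seed_w - 1L)
    rw <- substring(rrna, seq_len(nr - seed_w + 1L),
                    seq_len(nr - seed_w + 1L) + seed_w - 1L)
    rind <- split(seq_along(rw) - 1L, rw)
    dd <- integer(0)
    for (j0 in seq_along(qw)) {
      is <- rind[[qw[j0]]]
      if (!is.null(is)) dd <- c(dd, is - (j0 - 1L))
    }
    diag_set <- intersect(diag_set, sort(unique(dd)))
  }
  out <- NULL
  for (d in diag_set) {
    lo <- max(0L, -d); hi <- min(nq, nr - d)
    L <- hi - lo
    if (L < min_len) next
    jj <- lo:(hi - 1L)
    m <- qch[jj + 1L] == rch[jj + d + 1L]
    cs <- c(0L, cumsum(m))
    for (len in min_len:min(max_len, L)) {
      starts <- seq_len(L - len + 1L)
      ident <- (cs[starts + len] - cs[starts]) / len
      ok <- which(ident >= min_id)
      for (s in ok) {
        j0 <- lo + s - 1L
        out <- rbind(out, data.frame(
          sno_start = nq - (j0 + len), sno_end = nq - j0,
          r_start = j0 + d, r_end = j0 + d + len, len = len,
          identity = ident[s]))
      }
    }
  }
  out %||% data.frame(sno_start = integer(0), sno_end = integer(0),
                      r_start = integer(0), r_end = integer(0),
                      len = integer(0), identity = numeric(0))
}

# intervals [start, end) that may not be disturbed on the rRNA
overlaps_any <- function(start, end, iv_start, iv_end) {
  if (!length(iv_start)) return(rep(FALSE, length(start)))
  vapply(seq_along(start), function(i) {
    any(start[i] < iv_end & end[i] > iv_start)
  }, logical(1))
}

# mutate one base of a string at 0-based position `pos` to a different base
mutate_base <- function(seq, pos) {
  ch <- seq_chars(seq)
  ch[pos + 1L] <- sample(setdiff(c("A", "C", "G", "T"), ch[pos + 1L]), 1L)
  paste(ch, collapse = "")
}

# positions (0-based) where an antisense window actually matches: returns a
# data.frame of aligned (sno_pos, r_pos) pairs with equal bases
window_match_positions <- function(sno, rrna, w) {
  qc <- seq_chars(revcomp(sno))
  rch <- seq_chars(rrna)
  nq <- length(qc)
  j0 <- nq - w$sno_end          # qc-space start of the window
  k <- seq_len(w$len) - 1L
  eq <- qc[j0 + k + 1L] == rch[w$r_start + k + 1L]
  data.frame(sno_pos = nq - 1L - (j0 + k[eq]), r_pos = w$r_start + k[eq])
}

# remove every qualifying antisense window of `sno` against `rrna` whose
# rRNA footprint lies outside `allowed` (matrix start,end of permitted
# regions), by mutating sno bases outside `protect` (0-based sno interval).
scrub_sno <- function(sno, rrna, allowed = NULL, protect = NULL,
                      min_id = 0.9, max_iter = 400L) {
  for (it in seq_len(max_iter)) {
    w <- antisense_windows_brute(sno, rrna, min_id = min_id,
                                 seed_w = if (min_id >= 0.9) 5L else 3L)
    if (nrow(w) && !is.null(allowed)) {
      # only windows fully contained in an allowed region are exempt:
      # flank-extended matches past the planted window must be destroyed or
      # they would shift the reported hit center
      contained <- vapply(seq_len(nrow(w)), function(i) {
        any(w$r_start[i] >= allowed[, 1L] & w$r_end[i] <= allowed[, 2L])
      }, logical(1))
      w <- w[!contained, , drop = FALSE]
    }
    if (!nrow(w)) return(sno)
    mp <- window_match_positions(sno, rrna, w[1L, ])
    pos <- mp$sno_pos
    if (!is.null(protect)) pos <- setdiff(pos, seq.int(protect[1L], protect[2L] - 1L))
    if (!length(pos)) return(sno)  # window indistinguishable from the guide
    at <- if (length(pos) == 1L) pos else sample(pos, 1L)
    sno <- mutate_base(sno, at)
  }
  stop_snotrace("failed to scrub snoRNA of unplanted complementarity")
}

# scrub a snoRNA against several rRNAs to a joint fixed point: a mutation
# fixing one subunit may open a window on another, so passes repeat until a
# full sweep leaves the sequence unchanged.
scrub_sno_multi <- function(sno, rrnas, allowed_list = NULL, protect = NULL,
                            min_id = 0.9, max_pass = 50L) {
  for (pass in seq_len(max_pass)) {
    before <- sno
    for (nm in names(rrnas)) {
      sno <- scrub_sno(sno, rrnas[[nm]],
                       allowed = allowed_list[[nm]], protect = protect,
                       min_id = min_id)
    }
    if (identical(sno, before)) return(sno)
  }
  stop_snotrace("failed to jointly scrub snoRNA across rRNAs")
}

# remove qualifying matches of `pattern` (plain, same-orientation) inside
# `seq`, never touching `keep` intervals; used to keep planted windows unique
# on the rRNA.
scrub_rrna_against <- function(rrna, guide_rc, keep, min_id = 0.8,
                               max_iter = 400L) {
  for (it in seq_len(max_iter)) {
    w <- antisense_windows_brute(revcomp(guide_rc), rrna, min_id = min_id,
                                 seed_w = if (min_id >= 0.9) 5L else 3L)
    if (nrow(w)) {
      bad <- !overlaps_any(w$r_start, w$r_end, keep[, 1L], keep[, 2L])
      w <- w[bad, , drop = FALSE]
    }
    if (!nrow(w)) return(rrna)
    mid <- (w$r_start[1L] + w$r_end[1L]) %/% 2L
    mp <- window_match_positions(revcomp(guide_rc), rrna, w[1L, ])
    cand <- setdiff(mp$r_pos,
                    unlist(lapply(seq_len(nrow(keep)), function(i) {
                      seq.int(keep[i, 1L], keep[i, 2L] - 1L)
                    })))
    if (!length(cand)) return(rrna)
    pos <- cand[which.min(abs(cand - mid))]
    rrna <- mutate_base(rrna, pos)
  }
  stop_snotrace("failed to scrub rRNA of duplicate guide targets")
}

# evolve a root sequence down the tree: per-branch substitutions (sub_rate
# per column) and optional short deletions, both restricted to columns
# outside `frozen` (sorted unique 0-based columns). Returns per-leaf list of
# list(chars, del) in root-column space.
evolve_sequence <- function(phy, root_chars, sub_rate, del_prob, frozen,
                            alphabet, del_guard = integer(0)) {
  idx <- tree_index(phy)
  n <- length(root_chars)
  mutable <- setdiff(seq_len(n) - 1L, frozen)
  delable <- setdiff(mutable, del_guard)
  states <- vector("list", n_nodes(phy))
  states[[phy$root]] <- list(chars = root_chars, del = rep(FALSE, n))
  for (nd in preorder_nodes(phy, idx)) {
    if (nd == phy$root) next
    st <- states[[idx$parent[nd]]]
    alive <- which(!st$del) - 1L
    subs <- intersect(alive, mutable)
    hit <- subs[stats::runif(length(subs)) < sub_rate]
    for (p in hit) {
      st$chars[p + 1L] <- sample(setdiff(alphabet, st$chars[p + 1L]), 1L)
    }
    if (stats::runif(1L) < del_prob) {
      len <- sample(1:3, 1L)
      avail <- intersect(alive, delable)
      # anchor positions where the whole block stays inside deletable space
      ok <- avail[vapply(avail, function(a) {
        all((a + seq_len(len) - 1L) %in% avail)
      }, logical(1))]
      if (length(ok)) {
        at <- if (length(ok) == 1L) ok else sample(ok, 1L)
        st$del[at + seq_len(len)] <- TRUE  # 1-based index of cols at..at+len-1
      }
    }
    states[[nd]] <- st
  }
  ntip <- length(phy$tree$tip.label)
  stats::setNames(states[seq_len(ntip)], phy$tree$tip.label)
}

# aligned row from an evolved state (root-column space)
state_to_row <- function(st) {
  ch <- st$chars
  ch[st$del] <- "-"
  paste(ch, collapse = "")
}

# ---- genome-level simulation ------------------------------------------------

# gene model in local coordinates then flipped for minus-strand genes.
# coding cuts (intron positions in coding-nt space) must be multiples of 3.
build_gene_model <- function(tx_id, strand, seqid, coding_len, intron_cpos,
                             intron_lens, gstart, utr5 = 50L, utr3 = 50L) {
  o <- order(intron_cpos)
  intron_cpos <- intron_cpos[o]
  intron_lens <- intron_lens[o]
  tx_len <- utr5 + coding_len + utr3
  bounds <- c(0L, utr5 + intron_cpos, tx_len)          # tx-space exon bounds
  nex <- length(bounds) - 1L
  exons <- matrix(0L, nex, 2L)
  pos <- 0L
  offsets <- integer(nex)                              # local genomic - tx
  for (i in seq_len(nex)) {
    elen <- bounds[i + 1L] - bounds[i]
    offsets[i] <- pos - bounds[i]
    exons[i, ] <- c(pos, pos + elen)
    pos <- pos + elen
    if (i < nex) pos <- pos + intron_lens[i]
  }
  span <- pos
  cds <- NULL
  cs <- utr5; ce <- utr5 + coding_len                  # coding range, tx space
  for (i in seq_len(nex)) {
    a <- max(bounds[i], cs); b <- min(bounds[i + 1L], ce)
    if (a < b) cds <- rbind(cds, c(a + offsets[i], b + offsets[i]))
  }
  if (strand == "-") {
    flip <- function(m) cbind(span - m[, 2L], span - m[, 1L])
    exons <- flip(exons)
    cds <- flip(cds)
  }
  transcript(tx_id, strand, exons + gstart, cds = cds + gstart, seqid = seqid)
}

# per-species amino-acid position of an intron planted at root column `a`,
# given the species' retained (non-deleted) root columns.
species_aa <- function(retained, a) sum(retained < a)

#' Simulate genomes, alignments, rRNA targets and snoRNA placements
#'
#' Given a simulated family history, emits per-species genome annotations
#' (host genes with exon/intron structure and intronic snoRNAs), gap-consistent
#' protein and rRNA alignments evolved from root sequences, planted guide
#' target windows with exactly complementary guides in the carriers' C/D
#' snoRNAs, decoy snoRNAs certified free of unplanted complementarity,
#' mobility and independent-gain events, a known-site table for three
#' reference species, and the corresponding truth tables.
#'
#' @param phy a [phylogeny].
#' @param fam a result of [simulate_family_evolution()].
#' @param params a [sim_params()].
#' @return a large list (annotations, alignments, catalog, orthologs,
#'   known_sites, snoRNA sequences, truth).
#' @export
simulate_genomes <- function(phy, fam, params = sim_params()) {
  idx <- tree_index(phy)
  ls <- leafsets(phy, idx)
  species <- phy$tree$tip.label
  nsp <- length(species)
  kids <- idx$children[[phy$root]]

  ## ---- host genes and introns ----
  genes <- data.frame(
    gene_id = sprintf("G%02d", seq_len(params$n_host_genes)),
    strand = rep(c("+", "-"), length.out = params$n_host_genes),
    stringsAsFactors = FALSE)
  slot_grid <- seq(20L, params$protein_len - 20L, by = 15L)
  introns <- NULL
  free_slots <- list()
  for (gi in seq_len(nrow(genes))) {
    sl <- sort(sample(slot_grid, params$introns_per_gene))
    free_slots[[genes$gene_id[gi]]] <- setdiff(slot_grid, sl)
    introns <- rbind(introns, data.frame(
      intron_id = sprintf("%s.i%02d", genes$gene_id[gi], seq_along(sl)),
      gene_id = genes$gene_id[gi], root_aa = sl, type = "ancestral",
      origin = node_label(phy, phy$root), stringsAsFactors = FALSE))
  }
  # derived intron gains on random branches
  nonroot <- setdiff(seq_len(n_nodes(phy)), phy$root)
  for (k in seq_len(params$n_derived_introns)) {
    gid <- sample(genes$gene_id, 1L)
    if (!length(free_slots[[gid]])) next
    sl <- if (length(free_slots[[gid]]) == 1L) free_slots[[gid]] else
      sample(free_slots[[gid]], 1L)
    free_slots[[gid]] <- setdiff(free_slots[[gid]], sl)
    nd <- if (length(nonroot) == 1L) nonroot else sample(nonroot, 1L)
    introns <- rbind(introns, data.frame(
      intron_id = sprintf("%s.d%02d", gid, k), gene_id = gid, root_aa = sl,
      type = "derived", origin = node_label(phy, nd), stringsAsFactors = FALSE))
  }
  introns$length <- sample(150:400, nrow(introns), replace = TRUE)

  # intron presence sweep (origin node, then branch-wise loss below it)
  nin <- nrow(introns)
  istate <- matrix(FALSE, nin, n_nodes(phy))
  origin_id <- node_id(phy, introns$origin)
  for (nd in preorder_nodes(phy, idx)) {
    if (nd == phy$root) { istate[, nd] <- origin_id == nd; next }
    par <- idx$parent[nd]
    carried <- istate[, par]
    lost <- carried & stats::runif(nin) < params$intron_loss_prob
    istate[, nd] <- (carried & !lost) | (origin_id == nd)
  }
  intron_presence <- istate[, seq_len(nsp), drop = FALSE] * 1L
  dimnames(intron_presence) <- list(introns$intron_id, species)

  ## ---- family homes, independent pairs, mobility ----
  families <- fam$families
  fam_truth <- fam$truth
  presence <- fam$presence
  anc_introns <- introns$intron_id[introns$type == "ancestral"]
  intergenic <- stats::runif(nrow(families)) < params$intergenic_prob
  need <- sum(!intergenic)
  reserve <- params$n_mobility + params$n_independent_pairs
  if (need + reserve > length(anc_introns)) {
    stop_snotrace("not enough host introns (%d) for %d families + %d reserved",
                  length(anc_introns), need, reserve)
  }
  shuffled <- sample(anc_introns)
  home <- rep(NA_character_, nrow(families))
  home[!intergenic] <- shuffled[seq_len(need)]
  free_pool <- shuffled[-seq_len(need)]
  families$home_intron <- home

  # independent-gain pairs: two unrelated families, one per root subtree,
  # homed at the same (otherwise unused) ancestral intron locus
  pair_truth <- NULL
  side_node <- function(child) {
    tips <- ls[[child]]
    mrca_id(phy, tips[seq_len(min(2L, length(tips)))])
  }
  for (pi in seq_len(params$n_independent_pairs)) {
    # the pair's shared locus must stay observable on both sides of the
    # root: home it in an intron no lineage has lost
    full <- free_pool[rowSums(intron_presence[free_pool, , drop = FALSE]) == nsp]
    locus <- if (length(full)) full[1L] else free_pool[1L]
    free_pool <- setdiff(free_pool, locus)
    cls2 <- if (pi %% 2L == 1L) c("CD", "HACA") else c("CD", "CD")
    ids <- sprintf("RF9%02d%02d", pi, 1:2)
    onodes <- c(side_node(kids[1L]), side_node(kids[2L]))
    for (j in 1:2) {
      families <- rbind(families, data.frame(
        family_id = ids[j], clan_id = "", class = cls2[j],
        fun = "modification_guide", gain_node = node_label(phy, onodes[j]),
        ancestral = FALSE, home_intron = locus, stringsAsFactors = FALSE))
      # present in the whole clade under the origin node (no loss)
      newrow <- matrix(0L, 1L, nsp, dimnames = list(ids[j], species))
      newrow[1L, intersect(ls[[onodes[j]]], seq_len(nsp))] <- 1L
      presence <- presence_matrix(rbind(unclass(presence), newrow), "family")
      fam_truth <- rbind(fam_truth, data.frame(
        family_id = ids[j], gain_node = node_label(phy, onodes[j]),
        n_losses = 0L, loss_branches = "", expected_leca = FALSE,
        n_carriers = sum(newrow), stringsAsFactors = FALSE))
    }
    pair_truth <- rbind(pair_truth, data.frame(
      pair = pi, intron_id = locus, family_1 = ids[1L], family_2 = ids[2L],
      class_1 = cls2[1L], class_2 = cls2[2L],
      expected_verdict = if (cls2[1L] != cls2[2L]) "unrelated_classes"
                         else "same_class_no_evidence",
      stringsAsFactors = FALSE))
  }

  # mobility events: copy-and-relocate a family into a fresh ancestral intron
  mob <- NULL
  eligible <- families$family_id[families$ancestral & !is.na(families$home_intron)]
  eligible <- eligible[rowSums(unclass(presence)[eligible, , drop = FALSE]) >= 2L]
  for (ev in seq_len(params$n_mobility)) {
    if (!length(free_pool) || !length(eligible)) break
    f <- if (length(eligible) == 1L) eligible else sample(eligible, 1L)
    fi <- match(f, families$family_id)
    # a branch where the family is present: uniform over nodes below its gain
    cand <- nonroot[vapply(nonroot, function(nd) {
      any(presence[f, species[ls[[nd]]]] == 1L)
    }, logical(1))]
    nd <- if (length(cand) == 1L) cand else sample(cand, 1L)
    dest <- free_pool[1L]; free_pool <- free_pool[-1L]
    mob <- rbind(mob, data.frame(
      event = ev, family_id = f, node = node_label(phy, nd),
      source_intron = families$home_intron[fi], dest_intron = dest,
      retain = stats::runif(1L) < params$source_retain_prob,
      stringsAsFactors = FALSE))
  }

  # per-species family locations by root->leaf replay of mobility events
  locations <- list()  # locations[[species]][[family]] = character vector of introns
  for (si in seq_len(nsp)) {
    sp <- species[si]
    path <- root_path(phy, si, idx)
    lsp <- list()
    for (f in rownames(presence)) {
      if (presence[f, sp] != 1L) next
      fi <- match(f, families$family_id)
      locs <- if (is.na(families$home_intron[fi])) character(0) else
        families$home_intron[fi]
      if (!is.null(mob)) {
        for (m in which(mob$family_id == f)) {
          if (node_id(phy, mob$node[m]) %in% path) {
            locs <- if (mob$retain[m]) union(locs, mob$dest_intron[m]) else
              union(setdiff(locs, mob$source_intron[m]), mob$dest_intron[m])
          }
        }
      }
      lsp[[f]] <- locs
    }
    locations[[sp]] <- lsp
  }

  # realised mobility truth: carriers actually holding the destination copy
  if (!is.null(mob)) {
    mob$realized_species <- vapply(seq_len(nrow(mob)), function(m) {
      sp <- species[vapply(seq_len(nsp), function(si) {
        f <- mob$family_id[m]
        !is.null(locations[[species[si]]][[f]]) &&
          mob$dest_intron[m] %in% locations[[species[si]]][[f]] &&
          intron_presence[mob$dest_intron[m], species[si]] == 1L
      }, logical(1))]
      paste(sp, collapse = ",")
    }, character(1))
    mob$expected_node <- vapply(seq_len(nrow(mob)), function(m) {
      sp <- strsplit(mob$realized_species[m], ",", fixed = TRUE)[[1L]]
      sp <- sp[nzchar(sp)]
      if (!length(sp)) return(NA_character_)
      node_label(phy, mrca_id(phy, leaf_ids(phy, sp)))
    }, character(1))
  }

  ## ---- protein alignments and per-species gene models ----
  aa_alpha <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1L]]
  protein_alignments <- list()
  protein_states <- list()
  for (gi in seq_len(nrow(genes))) {
    gid <- genes$gene_id[gi]
    root_chars <- sample(aa_alpha, params$protein_len, replace = TRUE)
    slots <- introns$root_aa[introns$gene_id == gid]
    guard <- unique(unlist(lapply(slots, function(s) (s - 2L):(s + 6L))))
    st <- evolve_sequence(phy, root_chars, params$protein_sub_rate,
                          params$protein_del_prob, frozen = integer(0),
                          alphabet = aa_alpha, del_guard = guard)
    protein_states[[gid]] <- st
    protein_alignments[[gid]] <- multiple_alignment(
      vapply(st, state_to_row, character(1)), "protein")
  }

  ## ---- rRNA roots, planted windows, evolution ----
  subunits <- names(params$rrna_len)
  rrna_root <- lapply(params$rrna_len, function(L) {
    sample(c("A", "C", "G", "T"), L, replace = TRUE)
  })
  guide_fams <- families$family_id[families$class == "CD" &
                                     families$fun == "modification_guide" &
                                     families$ancestral]
  n_sites <- min(params$n_sites, length(guide_fams))
  site_subunit <- rep(subunits, length.out = n_sites)
  sites <- NULL
  win_by_subunit <- stats::setNames(vector("list", length(subunits)), subunits)
  for (s in seq_len(n_sites)) {
    su <- site_subunit[s]
    used <- win_by_subunit[[su]]
    L <- params$rrna_len[[su]]
    glen <- sample(seq(params$guide_len_range[1L], params$guide_len_range[2L]), 1L)
    cand <- seq(60L, L - 80L, by = 30L)
    if (!is.null(used)) {
      cand <- cand[!overlaps_any(cand, cand + glen, used[, 1L] - 8L, used[, 2L] + 8L)]
    }
    start <- if (length(cand) == 1L) cand else sample(cand, 1L)
    win_by_subunit[[su]] <- rbind(used, c(start, start + glen))
    sites <- rbind(sites, data.frame(
      site_id = sprintf("S%02d", s), subunit = su, start = start,
      len = glen, center_col = (start + start + glen - 1L) %/% 2L,
      family_id = guide_fams[s], stringsAsFactors = FALSE))
  }
  # clan-expansion fixtures: the first clan's two families share one target
  # (artefactual split); the second clan's families keep distinct targets
  clans <- unique(families$clan_id[families$clan_id != ""])
  fam_site <- stats::setNames(sites$site_id, sites$family_id)
  if (length(clans) >= 1L) {
    m1 <- clan_members(family_catalog(families[, c("family_id", "clan_id",
                                                   "class", "fun")]), clans[1L])
    m1 <- intersect(m1, names(fam_site))
    if (length(m1) >= 2L) {
      shared <- fam_site[[m1[1L]]]
      for (f in m1[-1L]) {
        sites$family_id[sites$site_id == fam_site[[f]]] <- NA_character_
        fam_site[[f]] <- shared
      }
    }
  }
  sites <- sites[!is.na(sites$family_id), , drop = FALSE]  # freed windows unused
  # make window contents mutually dissimilar, then unique on both rRNA roots
  for (i in seq_len(nrow(sites))) {
    su <- sites$subunit[i]
    w <- sites[i, ]
    for (try in 1:20) {
      wseq <- paste(rrna_root[[su]][(w$start + 1L):(w$start + w$len)], collapse = "")
      conflict <- FALSE
      for (j in seq_len(i - 1L)) {
        other <- sites[j, ]
        oseq <- paste(rrna_root[[other$subunit]][(other$start + 1L):(other$start + other$len)],
                      collapse = "")
        hits <- antisense_windows_brute(revcomp(wseq), oseq, min_id = 0.8)
        if (nrow(hits)) { conflict <- TRUE; break }
      }
      if (!conflict) break
      rrna_root[[su]][(w$start + 1L):(w$start + w$len)] <-
        sample(c("A", "C", "G", "T"), w$len, replace = TRUE)
    }
  }
  keep_by_su <- lapply(subunits, function(su) {
    s <- sites[sites$subunit == su, , drop = FALSE]
    if (!nrow(s)) matrix(integer(0), 0, 2) else cbind(s$start, s$start + s$len)
  })
  names(keep_by_su) <- subunits
  for (i in seq_len(nrow(sites))) {
    su <- sites$subunit[i]
    wseq <- paste(rrna_root[[su]][(sites$start[i] + 1L):(sites$start[i] + sites$len[i])],
                  collapse = "")
    for (su2 in subunits) {
      keep <- keep_by_su[[su2]]
      root_str <- paste(rrna_root[[su2]], collapse = "")
      root_str <- scrub_rrna_against(root_str, revcomp(wseq), keep, min_id = 0.8)
      rrna_root[[su2]] <- seq_chars(root_str)
    }
  }
  # evolve rRNAs with planted windows frozen
  rrna_states <- list()
  rrna_alignments <- list()
  for (su in subunits) {
    keep <- keep_by_su[[su]]
    frozen <- if (nrow(keep)) {
      unique(unlist(lapply(seq_len(nrow(keep)), function(i) {
        seq.int(keep[i, 1L] - 3L, keep[i, 2L] + 2L)
      })))
    } else integer(0)
    frozen <- frozen[frozen >= 0L & frozen < params$rrna_len[[su]]]
    st <- evolve_sequence(phy, rrna_root[[su]], params$rrna_sub_rate,
                          params$rrna_del_prob, frozen = frozen,
                          alphabet = c("A", "C", "G", "T"))
    rrna_states[[su]] <- st
  }
  # final per-species sweep: no species rRNA region outside the planted
  # windows may reach hit-level similarity to any planted guide target
  window_seqs <- vapply(seq_len(nrow(sites)), function(i) {
    su <- sites$subunit[i]
    paste(rrna_root[[su]][(sites$start[i] + 1L):(sites$start[i] + sites$len[i])],
          collapse = "")
  }, character(1))
  for (su in subunits) {
    keep <- keep_by_su[[su]]
    for (sp in species) {
      st <- rrna_states[[su]][[sp]]
      for (rep_ in 1:20) {
        retained <- which(!st$del) - 1L
        rseq <- paste(st$chars[!st$del], collapse = "")
        dirty <- FALSE
        for (wi in seq_along(window_seqs)) {
          w <- antisense_windows_brute(revcomp(window_seqs[wi]), rseq,
                                       min_id = 0.9, seed_w = 5L)
          if (!nrow(w)) next
          # map ungapped coords back to root columns, drop planted regions
          wcol_s <- retained[w$r_start + 1L]
          wcol_e <- retained[w$r_end] + 1L
          bad <- !overlaps_any(wcol_s, wcol_e,
                               if (nrow(keep)) keep[, 1L] else integer(0),
                               if (nrow(keep)) keep[, 2L] else integer(0))
          if (!any(bad)) next
          k <- which(bad)[1L]
          mp <- window_match_positions(revcomp(window_seqs[wi]), rseq, w[k, ])
          cols <- retained[mp$r_pos + 1L]
          cols <- cols[!overlaps_any(cols, cols + 1L,
                                     if (nrow(keep)) keep[, 1L] else integer(0),
                                     if (nrow(keep)) keep[, 2L] else integer(0))]
          if (!length(cols)) next
          p <- cols[ceiling(length(cols) / 2)]
          st$chars[p + 1L] <- sample(setdiff(c("A", "C", "G", "T"),
                                             st$chars[p + 1L]), 1L)
          dirty <- TRUE
        }
        if (!dirty) break
      }
      rrna_states[[su]][[sp]] <- st
    }
    rrna_alignments[[su]] <- multiple_alignment(
      vapply(rrna_states[[su]], state_to_row, character(1)),
      if (su == "SSU") "rRNA_SSU" else "rRNA_LSU")
  }

  ## ---- snoRNA sequences and genomic placement ----
  guide_of <- stats::setNames(rep(NA_character_, nrow(families)),
                              families$family_id)
  for (f in names(fam_site)) {
    si <- match(fam_site[[f]], sites$site_id)
    if (!is.na(si)) guide_of[[f]] <- window_seqs[si]
  }
  site_of_family <- stats::setNames(rep(NA_character_, nrow(families)),
                                    families$family_id)
  for (f in names(fam_site)) {
    if (fam_site[[f]] %in% sites$site_id) site_of_family[[f]] <- fam_site[[f]]
  }

  annotations <- list()
  sno_seqs <- list()
  chrU_pos <- stats::setNames(rep(0L, nsp), species)
  sp_rseq <- lapply(subunits, function(su) {
    vapply(species, function(sp) {
      st <- rrna_states[[su]][[sp]]
      paste(st$chars[!st$del], collapse = "")
    }, character(1))
  })
  names(sp_rseq) <- subunits
  allowed_for <- function(f, sp) {
    # rRNA region a planted guide is allowed to match: its own window
    sid <- site_of_family[[f]]
    if (is.na(sid)) return(NULL)
    si <- match(sid, sites$site_id)
    su <- sites$subunit[si]
    st <- rrna_states[[su]][[sp]]
    retained <- which(!st$del) - 1L
    a <- sum(retained < sites$start[si])
    list(subunit = su, iv = matrix(c(a - 2L, a + sites$len[si] + 2L), 1L))
  }

  sn_rows <- list()
  for (sp in species) {
    ann_genes <- list()
    # gene models for this species
    gstart <- 0L
    txs <- list()
    for (gi in seq_len(nrow(genes))) {
      gid <- genes$gene_id[gi]
      st <- protein_states[[gid]][[sp]]
      retained <- which(!st$del) - 1L
      coding_len <- 3L * length(retained)
      pin <- introns[introns$gene_id == gid, , drop = FALSE]
      pin <- pin[intron_presence[pin$intron_id, sp] == 1L, , drop = FALSE]
      pin <- pin[order(pin$root_aa), , drop = FALSE]
      cpos <- vapply(pin$root_aa, function(a) 3L * species_aa(retained, a),
                     integer(1))
      tx_id <- sprintf("%s_%s.t1", gid, sp)
      tx <- build_gene_model(tx_id, genes$strand[gi], "chr1", coding_len,
                             cpos, pin$length, gstart)
      span <- max(tx$exons[, 2L]) - min(tx$exons[, 1L])
      gstart <- gstart + span + 1000L
      gid_sp <- sprintf("%s_%s", gid, sp)
      txl <- list(); txl[[tx_id]] <- tx
      ann_genes[[gid_sp]] <- list(id = gid_sp, seqid = "chr1",
                                  strand = genes$strand[gi], transcripts = txl)
      txs[[gid]] <- list(tx = tx, intron_ids = pin$intron_id)
    }
    # snoRNAs
    sp_sno <- character(0)
    rows <- NULL
    copy_n <- stats::setNames(rep(0L, nrow(families)), families$family_id)
    for (f in names(locations[[sp]])) {
      fi <- match(f, families$family_id)
      locs <- locations[[sp]][[f]]
      if (!length(locs)) locs <- NA_character_  # intergenic family
      for (loc in locs) {
        # a copy whose host intron was lost in this lineage survives
        # intergenically (location drifts; the family does not vanish)
        placed <- !is.na(loc) && intron_presence[loc, sp] == 1L
        copy_n[[f]] <- copy_n[[f]] + 1L
        sid <- sprintf("%s_%s_c%d", f, sp, copy_n[[f]])
        seqv <- random_dna(params$sno_len)
        protect <- NULL
        if (families$class[fi] == "CD" && !is.na(guide_of[[f]])) {
          g <- revcomp(guide_of[[f]])
          at <- 20L
          ch <- seq_chars(seqv)
          ch[(at + 1L):(at + nchar(g))] <- seq_chars(g)
          seqv <- paste(ch, collapse = "")
          protect <- c(at, at + nchar(g))
        }
        if (families$class[fi] == "CD") {
          alw <- allowed_for(f, sp)
          allowed_list <- stats::setNames(vector("list", length(subunits)),
                                          subunits)
          if (!is.null(alw)) allowed_list[[alw$subunit]] <- alw$iv
          seqv <- scrub_sno_multi(
            seqv, stats::setNames(lapply(subunits, function(su) {
              sp_rseq[[su]][[sp]]
            }), subunits), allowed_list, protect)
        }
        sp_sno[[sid]] <- seqv
        if (placed) {
          info <- txs[[introns$gene_id[match(loc, introns$intron_id)]]]
          k <- match(loc, info$intron_ids)
          iv <- intron_interval(info$tx, k)
          rows <- rbind(rows, data.frame(
            snorna_id = sid, family_id = f, class = families$class[fi],
            seqid = "chr1", start = iv[["start"]] + 30L,
            end = iv[["start"]] + 30L + params$sno_len,
            strand = info$tx$strand, intron_id = loc, stringsAsFactors = FALSE))
        } else {
          rows <- rbind(rows, data.frame(
            snorna_id = sid, family_id = f, class = families$class[fi],
            seqid = "chrU", start = chrU_pos[[sp]],
            end = chrU_pos[[sp]] + params$sno_len, strand = "+",
            intron_id = NA_character_, stringsAsFactors = FALSE))
          chrU_pos[[sp]] <- chrU_pos[[sp]] + params$sno_len + 100L
        }
      }
    }
    sn_rows[[sp]] <- rows
    sno_seqs[[sp]] <- sp_sno
    annotations[[sp]] <- genome_annotation(
      sp, ann_genes,
      if (is.null(rows)) NULL else
        rows[, c("snorna_id", "family_id", "class", "seqid", "start", "end",
                 "strand")])
  }

  ## ---- decoys: species-specific, certified free of complementarity ----
  decoys <- NULL
  for (k in seq_len(params$n_decoys)) {
    sp <- species[((k - 1L) %% nsp) + 1L]
    f <- sprintf("DFAM%03d", k)
    sid <- sprintf("DEC%03d_%s", k, sp)
    seqv <- random_dna(params$sno_len)
    seqv <- scrub_sno_multi(seqv, stats::setNames(lapply(subunits, function(su) {
      sp_rseq[[su]][[sp]]
    }), subunits))
    sno_seqs[[sp]][[sid]] <- seqv
    families <- rbind(families, data.frame(
      family_id = f, clan_id = "", class = "CD", fun = "modification_guide",
      gain_node = sp, ancestral = FALSE, home_intron = NA_character_,
      stringsAsFactors = FALSE))
    annotations[[sp]]$snornas <- rbind(annotations[[sp]]$snornas, data.frame(
      snorna_id = sid, family_id = f, class = "CD", seqid = "chrU",
      start = chrU_pos[[sp]], end = chrU_pos[[sp]] + params$sno_len,
      strand = "+", stringsAsFactors = FALSE))
    chrU_pos[[sp]] <- chrU_pos[[sp]] + params$sno_len + 100L
    decoys <- rbind(decoys, data.frame(snorna_id = sid, family_id = f,
                                       species = sp, stringsAsFactors = FALSE))
  }

  ## ---- ortholog groups, catalog, known sites, truth ----
  orthologs <- do.call(rbind, lapply(genes$gene_id, function(gid) {
    data.frame(group_id = gid, species = species,
               gene_id = sprintf("%s_%s", gid, species),
               transcript_id = sprintf("%s_%s.t1", gid, species),
               stringsAsFactors = FALSE)
  }))
  catalog <- family_catalog(families[, c("family_id", "clan_id", "class", "fun")])

  uni <- species[ls[[kids[1L]]]]
  bik <- species[ls[[kids[2L]]]]
  refs <- c(hs = uni[1L], sc = uni[min(2L, length(uni))], at = bik[1L])
  known <- NULL
  for (i in seq_len(nrow(sites))) {
    f <- sites$family_id[i]
    fams_here <- names(fam_site)[vapply(names(fam_site), function(x) {
      identical(fam_site[[x]], sites$site_id[i])
    }, logical(1))]
    for (ff in fams_here) {
      for (sp in unique(refs)) {
        if (presence[ff, sp] != 1L) next
        su <- sites$subunit[i]
        st <- rrna_states[[su]][[sp]]
        retained <- which(!st$del) - 1L
        pos <- sum(retained < sites$center_col[i])
        base <- st$chars[[sites$center_col[i] + 1L]]
        known <- rbind(known, data.frame(
          species = sp, subunit = su, site_position = pos,
          modification_type = paste0(base, "m"),
          snorna_id = sprintf("%s_%s_c1", ff, sp), family_id = ff,
          stringsAsFactors = FALSE))
      }
    }
  }

  # per-site truth: carriers and expected LECA status
  site_truth <- NULL
  for (i in seq_len(nrow(sites))) {
    fams_here <- names(fam_site)[vapply(names(fam_site), function(x) {
      identical(fam_site[[x]], sites$site_id[i])
    }, logical(1))]
    carriers <- species[colSums(unclass(presence)[fams_here, , drop = FALSE]) > 0L]
    both <- length(intersect(carriers, uni)) > 0L &&
      length(intersect(carriers, bik)) > 0L
    site_truth <- rbind(site_truth, data.frame(
      site_id = sites$site_id[i], subunit = sites$subunit[i],
      center_col = sites$center_col[i],
      families = paste(sort(fams_here), collapse = ","),
      carriers = paste(sort(carriers), collapse = ","),
      n_carriers = length(carriers),
      expected_locus = length(carriers) >= 2L,
      expected_leca = both, stringsAsFactors = FALSE))
  }

  # intron truth
  intron_truth <- cbind(introns, data.frame(
    n_carriers = rowSums(intron_presence),
    expected_leca = vapply(seq_len(nin), function(i) {
      sum(intron_presence[i, uni]) > 0L && sum(intron_presence[i, bik]) > 0L
    }, logical(1))))

  # occupancy truth: (intron, species, family) triples actually emitted
  occ_truth <- do.call(rbind, lapply(species, function(sp) {
    r <- sn_rows[[sp]]
    if (is.null(r)) return(NULL)
    r <- r[!is.na(r$intron_id), , drop = FALSE]
    if (!nrow(r)) return(NULL)
    data.frame(species = sp, intron_id = r$intron_id, family_id = r$family_id,
               snorna_id = r$snorna_id, stringsAsFactors = FALSE)
  }))

  list(phy = phy, params = params, genes = genes, introns = introns,
       intron_presence = intron_presence, families = families,
       presence = presence, catalog = catalog,
       annotations = annotations, sno_seqs = sno_seqs,
       protein_alignments = protein_alignments,
       rrna_alignments = rrna_alignments, orthologs = orthologs,
       known_sites = known, sites = sites, refs = refs,
       truth = list(families = fam_truth, sites = site_truth,
                    introns = intron_truth, occupancy = occ_truth,
                    mobility = mob, independent_pairs = pair_truth,
                    decoys = decoys))
}

# expected Dirichlet(alpha symmetric, k) entropy: psi(k a + 1) - psi(a + 1)
dirichlet_entropy <- function(alpha, k) digamma(k * alpha + 1) - digamma(alpha + 1)

#' Simulate tissue expression profiles with an entropy gap
#'
#' Host genes draw near-uniform profiles (symmetric Dirichlet, concentration
#' `host_alpha`); non-host genes use a lower concentration solved numerically
#' so the expected entropy difference equals `entropy_gap` nats.
#'
#' @param host_ids,nonhost_ids gene id vectors.
#' @param params a [sim_params()].
#' @return list: `mat` (gene x tissue matrix), `host_ids`, `alpha` used.
#' @export
simulate_expression <- function(host_ids, nonhost_ids, params = sim_params()) {
  k <- params$n_tissues
  if (k < 2L) stop_snotrace("need at least 2 tissues")
  a_h <- params$host_alpha
  target <- dirichlet_entropy(a_h, k) - params$entropy_gap
  a_n <- if (params$entropy_gap == 0) a_h else {
    stats::uniroot(function(a) dirichlet_entropy(a, k) - target,
                   lower = 1e-4, upper = a_h, tol = 1e-9)$root
  }
  draw <- function(alpha) {
    g <- stats::rgamma(k, shape = alpha)
    if (all(g == 0)) g[1L] <- 1
    1000 * g / sum(g)
  }
  mat <- rbind(
    t(vapply(host_ids, function(g) draw(a_h), numeric(k))),
    t(vapply(nonhost_ids, function(g) draw(a_n), numeric(k))))
  colnames(mat) <- sprintf("tissue%02d", seq_len(k))
  rownames(mat) <- c(host_ids, nonhost_ids)
  list(mat = mat, host_ids = host_ids, alpha = c(host = a_h, nonhost = a_n))
}

#' Generate and write a complete synthetic input bundle
#'
#' Runs family evolution, genome simulation and expression simulation under
#' one seed and writes the full input set (Newick + supergroup TSV, catalog
#' TSV, per-species GFF3 and snoRNA FASTA, aligned rRNA and protein FASTA,
#' ortholog TSV, known-site TSV, expression TSV) plus `truth/truth.json`.
#' Regenerating with the same seed yields byte-identical files.
#'
#' @param dir output directory (created).
#' @param params a [sim_params()].
#' @param seed integer seed; all randomness flows from it.
#' @return invisibly, the in-memory bundle (including `$truth` and `$dir`).
#' @export
simulate_bundle <- function(dir, params = sim_params(), seed = 1L) {
  set.seed(seed)
  phy <- make_supergroup_tree(params$taxa_per_supergroup, params$supergroups)
  fam <- simulate_family_evolution(phy, params)
  gen <- simulate_genomes(phy, fam, params)

  # expression: hosts = reference-species genes carrying an intronic snoRNA
  ref <- gen$refs[["hs"]]
  occ <- gen$truth$occupancy
  host_groups <- sort(unique(gen$introns$gene_id[match(
    occ$intron_id[occ$species == ref], gen$introns$intron_id)]))
  nonhost <- c(setdiff(gen$genes$gene_id, host_groups),
               sprintf("N%04d", seq_len(params$n_expr_nonhost)))
  expr <- simulate_expression(host_groups, nonhost, params)

  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "truth"), showWarnings = FALSE)
  dir.create(file.path(dir, "proteins"), showWarnings = FALSE)
  dir.create(file.path(dir, "species"), showWarnings = FALSE)
  write_species_tree(phy, file.path(dir, "tree.nwk"),
                     file.path(dir, "supergroups.tsv"))
  write_family_catalog(gen$catalog, file.path(dir, "catalog.tsv"))
  write_presence_matrix(gen$presence, file.path(dir, "family_presence.tsv"))
  for (sp in phy$tree$tip.label) {
    write_genome_annotation(gen$annotations[[sp]],
                            file.path(dir, "species", paste0(sp, ".gff3")))
    seqs <- gen$sno_seqs[[sp]]
    Biostrings::writeXStringSet(
      Biostrings::DNAStringSet(unlist(seqs)),
      file.path(dir, "species", paste0(sp, "_snorna.fa")), width = 80L)
  }
  for (su in names(gen$rrna_alignments)) {
    write_alignment(gen$rrna_alignments[[su]],
                    file.path(dir, sprintf("rrna_%s.aln.fa", tolower(su))))
  }
  for (gid in names(gen$protein_alignments)) {
    write_alignment(gen$protein_alignments[[gid]],
                    file.path(dir, "proteins", paste0(gid, ".aln.fa")))
  }
  utils::write.table(gen$orthologs, file.path(dir, "orthologs.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(gen$known_sites)) {
    write_known_sites(gen$known_sites, file.path(dir, "known_sites.tsv"))
  }
  write_expression_matrix(expr$mat, file.path(dir, "expression.tsv"))
  truth <- gen$truth
  truth$expression <- list(reference_species = ref, host_genes = host_groups)
  truth$seed <- seed
  jsonlite::write_json(truth, file.path(dir, "truth", "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null")
  out <- gen
  out$expression <- expr
  out$dir <- dir
  out$seed <- seed
  invisible(out)
}
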