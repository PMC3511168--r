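# a plus-strand gene: 50 nt 5'UTR, coding exons split at given coding
# positions, 50 nt 3'UTR; intron length 200
make_coding_tx <- function(strand, coding_len, cuts, utr5 = 50L, utr3 = 50L) {
  snotrace:::build_gene_model("t1", strand, "chr1", coding_len, cuts,
                              rep(200L, length(cuts)), gstart = 0L,
                              utr5 = utr5, utr3 = utr3)
}

test_that("intron position is the count of upstream codons", {
  tx <- make_coding_tx("+", 600L, 300L)
  expect_equal(intron_protein_position(tx, 1L), 100L)   # 300 nt / 3
  txm <- make_coding_tx("-", 600L, 300L)
  expect_equal(intron_protein_position(txm, 1L), 100L)  # strand symmetric
  expect_error(intron_protein_position(tx, 5L), "no intron")
})

test_that("UTR introns are excluded", {
  # intron between two 5'UTR exons: exons [0,30)+[230,...), CDS starts at 280
  tx <- transcript("t", "+", rbind(c(0L, 30L), c(230L, 500L)),
                   cds = rbind(c(280L, 460L)))
  expect_true(is.na(intron_protein_position(tx, 1L)))
  # 3'UTR intron: CDS ends before the intron
  tx2 <- transcript("t", "+", rbind(c(0L, 300L), c(500L, 600L)),
                    cds = rbind(c(50L, 230L)))
  expect_true(is.na(intron_protein_position(tx2, 1L)))
})

test_that("intron positions agree with explicit codon enumeration", {
  set.seed(17)
  for (rep_ in 1:20) {
    ncut <- sample(1:4, 1)
    coding_len <- 3L * sample(60:150, 1)
    cuts <- sort(sample(seq(3L, coding_len - 3L, by = 3L), ncut))
    strand <- sample(c("+", "-"), 1)
    tx <- make_coding_tx(strand, coding_len, cuts)
    # oracle: walk coding genomic positions in transcript order and count
    # complete codons before each intron boundary
    cds_pos <- unlist(lapply(seq_len(nrow(tx$cds)), function(i) {
      tx$cds[i, 1L]:(tx$cds[i, 2L] - 1L)
    }))
    if (strand == "-") cds_pos <- rev(cds_pos)
    for (k in seq_len(n_introns(tx))) {
      iv <- intron_interval(tx, k)
      upstream <- if (strand == "+") sum(cds_pos < iv["start"]) else
        sum(cds_pos >= iv["end"])
      expect_identical(intron_protein_position(tx, k),
                       as.integer(upstream %/% 3L))
    }
  }
})

test_that("intron loci bin within +/- 5 columns and respect input order", {
  phy <- make_supergroup_tree(2)
  ann <- list()
  for (sp in phy$tree$tip.label) {
    tx <- make_coding_tx("+", 600L, c(150L, 300L))
    g <- list(id = paste0("g_", sp), seqid = "chr1", strand = "+",
              transcripts = stats::setNames(list(tx), "t1"))
    ann[[sp]] <- genome_annotation(sp, stats::setNames(list(g), paste0("g_", sp)))
  }
  aln <- multiple_alignment(stats::setNames(
    rep(strrep("M", 200), 4), phy$tree$tip.label), "protein")
  og <- ortholog_group("G1", data.frame(
    species = phy$tree$tip.label, gene_id = paste0("g_", phy$tree$tip.label),
    transcript_id = "t1", stringsAsFactors = FALSE))
  il <- bin_intron_loci(og, ann, aln)
  expect_equal(nrow(il$loci), 2L)                  # two distinct loci
  expect_equal(sort(il$loci$column), c(50L, 100L))
  expect_true(all(il$loci$n_species == 4L))
  # columns 100 and 104 co-bin; 100 and 106 do not
  expect_equal(max(abs(outer(c(100, 104), c(100, 104), "-"))) <= 5, TRUE)
  expect_equal(length(unique(snotrace:::chain_clusters(c(100L, 104L), 5L))), 1L)
  expect_equal(length(unique(snotrace:::chain_clusters(c(100L, 106L), 5L))), 2L)
})

test_that("snoRNA occupancy requires containment and the host strand", {
  phy <- make_supergroup_tree(2)
  sp <- "uni1"
  tx <- make_coding_tx("+", 600L, 300L)    # one intron
  iv <- intron_interval(tx, 1L)
  sn <- data.frame(
    snorna_id = c("in_ok", "span", "anti"),
    family_id = c("f1", "f1", "f2"), class = c("CD", "CD", "HACA"),
    seqid = "chr1",
    start = c(iv["start"] + 10L, iv["start"] - 5L, iv["start"] + 12L),
    end = c(iv["start"] + 90L, iv["start"] + 40L, iv["start"] + 92L),
    strand = c("+", "+", "-"), stringsAsFactors = FALSE)
  g <- list(id = "g1", seqid = "chr1", strand = "+",
            transcripts = list(t1 = tx))
  ann <- list()
  ann[[sp]] <- genome_annotation(sp, list(g1 = g), sn)
  cat <- family_catalog(data.frame(family_id = c("f1", "f2"),
                                   clan_id = c("CL1", ""),
                                   class = c("CD", "HACA"),
                                   fun = "modification_guide"))
  members <- data.frame(species = sp, gene_id = "g1", transcript_id = "t1",
                        intron_index = 1L, aa = 100L, column = 100L,
                        locus_id = "G1_i0100", stringsAsFactors = FALSE)
  res <- assign_snorna_occupancy(members, ann, cat)
  expect_equal(res$occupancy$snorna_id, "in_ok")
  expect_equal(res$occupancy$clan_id, "CL1")
  expect_equal(res$flagged$snorna_id, "span")
  # strand requirement off: the antisense copy is admitted too
  res2 <- assign_snorna_occupancy(members, ann, cat, same_strand = FALSE)
  expect_setequal(res2$occupancy$snorna_id, c("in_ok", "anti"))
})

test_that("cross-supergroup verdicts follow family, clan and class identity", {
  sg <- c(hum = "Opisthokonta", mouse = "Opisthokonta", fly = "Opisthokonta",
          ath = "Archaeplastida", osa = "Archaeplastida")
  occ <- function(...) {
    d <- data.frame(..., stringsAsFactors = FALSE)
    d$locus_id <- "L1"
    d
  }
  # mammal CD + fly HACA + rice CD at one locus: classes clash across groups
  v <- cross_supergroup_homology(occ(
    species = c("hum", "fly", "osa"),
    family_id = c("RF00133", "FBgn1", "OsnoR30"),
    clan_id = c("", "", ""), class = c("CD", "HACA", "CD")), sg)
  expect_equal(v$verdict, "unrelated_classes")
  # same family spanning human and Arabidopsis
  v <- cross_supergroup_homology(occ(
    species = c("hum", "ath"), family_id = c("RF1", "RF1"),
    clan_id = c("", ""), class = c("CD", "CD")), sg)
  expect_equal(v$verdict, "same_family")
  # clan-level identity only
  v <- cross_supergroup_homology(occ(
    species = c("hum", "ath"), family_id = c("RF1", "RF2"),
    clan_id = c("CL9", "CL9"), class = c("CD", "CD")), sg)
  expect_equal(v$verdict, "same_clan")
  # same class, different families/clans
  v <- cross_supergroup_homology(occ(
    species = c("hum", "ath"), family_id = c("RF1", "RF2"),
    clan_id = c("", ""), class = c("CD", "CD")), sg)
  expect_equal(v$verdict, "same_class_no_evidence")
  # confined to one supergroup
  v <- cross_supergroup_homology(occ(
    species = c("hum", "mouse"), family_id = c("RF1", "RF2"),
    clan_id = c("", ""), class = c("CD", "CD")), sg)
  expect_equal(v$verdict, "single_supergroup")
})

test_that("association dating calls recent gains below the host placement", {
  phy <- make_supergroup_tree(3)
  occ <- data.frame(
    locus_id = c("L1", "L1", "L2", "L2", "L2", "L2", "L2", "L2"),
    group_id = "G1",
    species = c("uni1", "uni2", phy$tree$tip.label),
    family_id = c("SNORA58", "SNORA58", rep("RFALL", 6)),
    stringsAsFactors = FALSE)
  d <- date_association(occ, phy, c(G1 = "LECA"))
  gained <- d[d$family_id == "SNORA58", ]
  expect_true(gained$recent_gain)                       # primate-style gain
  expect_equal(gained$assoc_node,
               infer_gain_node(phy, c(uni1 = 1L, uni2 = 1L)))
  everywhere <- d[d$family_id == "RFALL", ]
  expect_equal(everywhere$assoc_node, "LECA")
  expect_false(everywhere$recent_gain)                  # no gain call at root
})
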