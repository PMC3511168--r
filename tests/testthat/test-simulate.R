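test_that("loss-free and loss-saturated regimes behave as designed", {
  phy <- make_supergroup_tree(3)
  set.seed(1)
  p0 <- sim_params(taxa_per_supergroup = 3, n_anc_families = 8,
                   n_new_families = 0, q_loss = 0)
  f0 <- simulate_family_evolution(phy, p0)
  expect_true(all(f0$presence == 1L))
  expect_true(all(f0$truth$expected_leca))
  p1 <- sim_params(taxa_per_supergroup = 3, n_anc_families = 8,
                   n_new_families = 0, q_loss = 1)
  f1 <- simulate_family_evolution(phy, p1)
  expect_true(all(f1$presence == 0L))       # nothing survives any branch
  expect_true(!any(f1$truth$expected_leca))
})

test_that("Dollo reconstruction recovers the generator's expected LECA set", {
  set.seed(77)
  phy <- make_supergroup_tree(5)
  p <- sim_params(taxa_per_supergroup = 5, n_anc_families = 40,
                  n_new_families = 5, q_loss = 0.15)
  f <- simulate_family_evolution(phy, p)
  keep <- rowSums(f$presence) > 0
  recon <- dollo_reconstruct(phy, f$presence[keep, , drop = FALSE])
  leca <- characters_at_node(recon)
  expect_setequal(leca, f$truth$family_id[f$truth$expected_leca])
  # single origin by construction: reconstruction never needs more losses
  # than the generator actually drew
  expect_true(all(recon$min_losses <= f$truth$n_losses[keep]))
})

test_that("regenerating a bundle under the same seed is byte-identical", {
  d1 <- file.path(tempdir(), "rep1"); d2 <- file.path(tempdir(), "rep2")
  p <- sim_params(taxa_per_supergroup = 2, n_anc_families = 6,
                  n_new_families = 1, n_host_genes = 4, n_sites = 4,
                  n_decoys = 2, n_mobility = 1, n_independent_pairs = 1,
                  n_expr_nonhost = 10)
  simulate_bundle(d1, p, seed = 5)
  simulate_bundle(d2, p, seed = 5)
  files <- list.files(d1, recursive = TRUE)
  expect_true(length(files) > 10)
  for (f in files) {
    expect_identical(readLines(file.path(d1, f), warn = FALSE),
                     readLines(file.path(d2, f), warn = FALSE), info = f)
  }
})

test_that("emitted files replay the recorded truth", {
  b <- get_small_bundle()
  # every recorded occupancy corresponds to a snoRNA wholly inside the
  # recorded intron of the emitted annotation
  occ <- b$truth$occupancy
  for (i in sample(seq_len(nrow(occ)), min(25, nrow(occ)))) {
    sp <- occ$species[i]
    ann <- b$annotations[[sp]]
    sn <- ann$snornas[ann$snornas$snorna_id == occ$snorna_id[i], ]
    expect_equal(nrow(sn), 1L)
    gid <- b$introns$gene_id[b$introns$intron_id == occ$intron_id[i]]
    gene <- ann$genes[[sprintf("%s_%s", gid, sp)]]
    tx <- gene$transcripts[[1L]]
    pin <- b$introns[b$introns$gene_id == gid, ]
    pin <- pin[b$intron_presence[pin$intron_id, sp] == 1L, ]
    pin <- pin[order(pin$root_aa), ]
    k <- match(occ$intron_id[i], pin$intron_id)
    iv <- intron_interval(tx, k)
    expect_true(sn$start >= iv["start"] && sn$end <= iv["end"])
    expect_equal(sn$strand, tx$strand)
  }
  # family presence in annotations equals the simulated presence matrix
  fams <- rownames(b$presence)
  for (sp in sample(colnames(b$presence), 3)) {
    seen <- unique(b$annotations[[sp]]$snornas$family_id)
    expect_setequal(intersect(seen, fams), fams[b$presence[, sp] == 1L])
  }
})

test_that("planted guides are perfect complements and decoys are inert", {
  b <- get_small_bundle()
  sites <- b$sites
  for (i in seq_len(nrow(sites))) {
    su <- sites$subunit[i]
    f <- sites$family_id[i]
    carriers <- colnames(b$presence)[b$presence[f, ] == 1L]
    for (sp in carriers[seq_len(min(2, length(carriers)))]) {
      rseq <- snotrace:::ungapped_row(b$rrna_alignments[[su]], sp)
      sid <- sprintf("%s_%s_c1", f, sp)
      sno <- b$sno_seqs[[sp]][[sid]]
      h <- search_guides(list(snorna_id = sid, family_id = f, species_id = sp,
                              class = "CD", sequence = sno), rseq, su)
      # the planted window is recovered at identity 1 at its column
      col <- ungapped_to_column(b$rrna_alignments[[su]], sp, h$center)
      expect_true(any(abs(col - sites$center_col[i]) <= 2 & h$identity == 1))
    }
  }
  # decoys produce no hits at all on either subunit (checked via the
  # independent window oracle for a sample)
  dec <- b$truth$decoys
  for (i in seq_len(min(3, nrow(dec)))) {
    sp <- dec$species[i]
    sno <- b$sno_seqs[[sp]][[dec$snorna_id[i]]]
    for (su in c("SSU", "LSU")) {
      rseq <- snotrace:::ungapped_row(b$rrna_alignments[[su]], sp)
      expect_null(guide_oracle(sno, rseq))
      h <- search_guides(list(snorna_id = "d", family_id = "d", species_id = sp,
                              class = "CD", sequence = sno), rseq, su)
      expect_equal(nrow(h), 0L)
    }
  }
})

test_that("expression simulation hits the designed entropy gap on average", {
  set.seed(99)
  sim <- simulate_expression(sprintf("h%03d", 1:150), sprintf("n%03d", 1:150),
                             sim_params(entropy_gap = 0.5))
  S <- apply(sim$mat, 1, expression_entropy)
  gap <- mean(S[sim$host_ids]) - mean(S[setdiff(rownames(sim$mat), sim$host_ids)])
  expect_equal(gap, 0.5, tolerance = 0.15)
  expect_error(simulate_expression("a", "b", sim_params(n_tissues = 1L)),
               "tissues")
})
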