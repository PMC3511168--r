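two_exon_tx <- function(strand = "+") {
  transcript("tx1", strand, rbind(c(0L, 100L), c(200L, 300L)),
             cds = rbind(c(50L, 100L), c(200L, 250L)))
}

test_that("genomic to cDNA conversion is strand-aware", {
  expect_equal(genomic_to_cdna(two_exon_tx("+"), 200L), 100L)
  expect_equal(genomic_to_cdna(two_exon_tx("-"), 299L), 0L)
  expect_equal(genomic_to_cdna(two_exon_tx("+"), 0L), 0L)
  expect_equal(genomic_to_cdna(two_exon_tx("-"), 0L), 199L)
  expect_error(genomic_to_cdna(two_exon_tx("+"), 150L), "intronic")
  expect_error(genomic_to_cdna(two_exon_tx("+"), 400L), "intronic|outside")
})

test_that("cDNA coordinates agree with explicit splice enumeration", {
  set.seed(5)
  for (rep_ in 1:20) {
    nex <- sample(1:5, 1)
    starts <- sort(sample(0:500, nex))
    lens <- sample(10:50, nex, replace = TRUE)
    ex <- cbind(starts + cumsum(c(0, rep(60, nex - 1))),
                starts + cumsum(c(0, rep(60, nex - 1))) + lens)
    strand <- sample(c("+", "-"), 1)
    tx <- transcript("t", strand, ex)
    # explicit spliced coordinate list, 5' to 3'
    gpos <- unlist(lapply(seq_len(nex), function(i) ex[i, 1L]:(ex[i, 2L] - 1L)))
    if (strand == "-") gpos <- rev(gpos)
    for (p in sample(gpos, 5)) {
      expect_identical(genomic_to_cdna(tx, p), match(p, gpos) - 1L)
      expect_identical(cdna_to_genomic(tx, match(p, gpos) - 1L), p)
    }
  }
})

test_that("GFF3 write/read round-trips genes, transcripts and snoRNAs", {
  ann <- genome_annotation(
    "spX",
    genes = list(g1 = list(id = "g1", seqid = "chr1", strand = "+",
                           transcripts = list(t1 = two_exon_tx("+"))),
                 g2 = list(id = "g2", seqid = "chr1", strand = "-",
                           transcripts = list(t2 = transcript(
                             "t2", "-", rbind(c(500L, 600L), c(700L, 800L)),
                             cds = rbind(c(520L, 600L), c(700L, 780L)))))),
    snornas = data.frame(snorna_id = "sno1", family_id = "RF00001",
                         class = "CD", seqid = "chr1", start = 120L,
                         end = 180L, strand = "+", stringsAsFactors = FALSE))
  # transcript ids must be unique in the file; rebuild g1 with its own id
  f <- tempfile(fileext = ".gff3")
  write_genome_annotation(ann, f)
  back <- read_genome_annotation(f, "spX")
  expect_equal(names(back$genes), c("g1", "g2"))
  tx <- back$genes$g1$transcripts[[1]]
  expect_equal(unname(tx$exons), unname(two_exon_tx()$exons))
  expect_equal(unname(tx$cds), unname(two_exon_tx()$cds))
  expect_equal(back$snornas$start, 120L)
  expect_equal(back$snornas$end, 180L)
  expect_equal(back$snornas$family_id, "RF00001")
  # GFF3 is 1-based closed on disk: the 0-based [0, 100) exon prints as 1..100
  lines <- readLines(f)
  expect_true(any(grepl("\t1\t100\t", lines)))
})

test_that("malformed GFF3 and structurally invalid models are rejected", {
  f <- tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               "chr1\tsrc\tgene\t1\t100"), f)  # 5 fields, not 9
  expect_error(read_genome_annotation(f), "line 2")
  expect_error(transcript("t", "+", rbind(c(0, 100), c(50, 150))), "overlap")
  expect_error(transcript("t", "+", rbind(c(100, 100))), "start < end")
  expect_error(transcript("t", "+", rbind(c(0, 100)),
                          cds = rbind(c(50, 150))), "CDS outside")
  expect_error(genome_annotation("s", genes = list(
    g = list(id = "g", seqid = "c", strand = "+", transcripts = list()))),
    "no transcripts")
})

test_that("full-length locator matches the brute-force Hamming scan", {
  expect_equal(locate_full_length("ACGT", "TTACGTTT", 1L)$position[1], 2L)
  hit <- locate_full_length("ACGA", "TTACGTTT", 1L)
  fwd <- hit[hit$strand == "+", ]
  expect_true(any(fwd$position == 2L & fwd$substitutions == 1L))
  expect_error(locate_full_length("", "ACGT"), "empty")
  expect_error(locate_full_length("ACGTACGT", "ACG"), "longer")
  set.seed(11)
  for (rep_ in 1:10) {
    genome <- random_dna(800)
    query <- if (rep_ %% 2 == 0) {
      substr(genome, 301, 330)           # guaranteed embedded match
    } else random_dna(30)
    for (ms in 0:2) {
      expect_equal(locate_full_length(query, genome, ms),
                   hamming_scan_oracle(query, genome, ms))
    }
  }
})
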