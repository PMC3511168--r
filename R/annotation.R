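# Genome annotations and coordinate arithmetic.
#
# All intervals are 0-based half-open internally; GFF3 (1-based closed) is
# converted at the read/write boundary. GFF3 parsing itself is delegated to
# rtracklayer; this file owns the domain model and its invariants.

#' Transcript model
#'
#' @param id transcript id.
#' @param strand `"+"` or `"-"`.
#' @param exons two-column matrix (start, end), 0-based half-open, genomic;
#'   will be sorted by start. Exons must not overlap.
#' @param cds optional CDS intervals (same convention); must lie within the
#'   exon union.
#' @param seqid chromosome/scaffold name.
#' @return a `transcript` object.
#' @export
transcript <- function(id, strand, exons, cds = NULL, seqid = "chr1") {
  exons <- matrix(as.integer(exons), ncol = 2L,
                  dimnames = list(NULL, c("start", "end")))
  check_interval(exons[, 1L], exons[, 2L], "exon")
  exons <- exons[order(exons[, 1L]), , drop = FALSE]
  if (nrow(exons) > 1L && any(exons[-1L, 1L] < exons[-nrow(exons), 2L])) {
    stop_snotrace("transcript %s: exons overlap", id)
  }
  if (!is.null(cds)) {
    cds <- matrix(as.integer(cds), ncol = 2L,
                  dimnames = list(NULL, c("start", "end")))
    check_interval(cds[, 1L], cds[, 2L], "CDS")
    cds <- cds[order(cds[, 1L]), , drop = FALSE]
    for (i in seq_len(nrow(cds))) {
      inside <- any(cds[i, 1L] >= exons[, 1L] & cds[i, 2L] <= exons[, 2L])
      if (!inside) stop_snotrace("transcript %s: CDS outside exon space", id)
    }
  }
  structure(list(id = id, seqid = seqid, strand = strand,
                 exons = exons, cds = cds),
            class = "transcript")
}

#' Genome annotation container
#'
#' @param species_id species identifier.
#' @param genes named list of genes; each gene is a list with `id`, `seqid`,
#'   `strand` and `transcripts` (named list of [transcript()] objects).
#' @param snornas data.frame with columns `snorna_id`, `family_id`, `class`,
#'   `seqid`, `start`, `end` (0-based half-open), `strand`.
#' @return a `genome_annotation` object.
#' @export
genome_annotation <- function(species_id, genes = list(), snornas = NULL) {
  if (is.null(snornas)) {
    snornas <- data.frame(snorna_id = character(0), family_id = character(0),
                          class = character(0), seqid = character(0),
                          start = integer(0), end = integer(0),
                          strand = character(0))
  }
  for (g in genes) {
    if (!length(g$transcripts)) {
      stop_snotrace("gene %s has no transcripts", g$id)
    }
    for (tx in g$transcripts) {
      if (!nrow(tx$exons)) stop_snotrace("transcript %s has no exons", tx$id)
    }
  }
  if (nrow(snornas)) check_interval(snornas$start, snornas$end, "snoRNA")
  structure(list(species_id = species_id, genes = genes, snornas = snornas),
            class = "genome_annotation")
}

#' @export
print.genome_annotation <- function(x, ...) {
  cat(sprintf("<genome_annotation> %s: %d genes, %d snoRNAs\n",
              x$species_id, length(x$genes), nrow(x$snornas)))
  invisible(x)
}

# pick the transcript with the longest CDS (isoform policy used pipeline-wide)
main_transcript <- function(gene) {
  txs <- gene$transcripts
  if (length(txs) == 1L) return(txs[[1L]])
  cdslen <- vapply(txs, function(tx) {
    if (is.null(tx$cds)) 0L else sum(tx$cds[, 2L] - tx$cds[, 1L])
  }, integer(1))
  txs[[which.max(cdslen)]]
}

# ---- GFF3 I/O --------------------------------------------------------------

#' Read a GFF3 genome annotation
#'
#' Recognised feature types: `gene`, `mRNA`/`transcript`, `exon`, `CDS` and
#' `snoRNA` (top level, with `family_id` and `class` attributes). Coordinates
#' are converted from GFF3 1-based closed to internal 0-based half-open.
#'
#' @param file GFF3 path.
#' @param species_id species id; defaults to the file base name.
#' @return a [genome_annotation()].
#' @export
read_genome_annotation <- function(file,
                                   species_id = sub("\\.gff3?$", "", basename(file))) {
  lines <- readLines(file)
  body <- which(!grepl("^#", lines) & nzchar(lines))
  nf <- lengths(strsplit(lines[body], "\t", fixed = TRUE))
  if (any(nf != 9L)) {
    stop_snotrace("malformed GFF3 line %d in %s (expected 9 tab-separated fields)",
                  body[which(nf != 9L)[1L]], file)
  }
  gr <- rtracklayer::import(file, format = "gff3")
  df <- data.frame(
    seqid = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    type = as.character(gr$type),
    id = if (is.null(gr$ID)) NA_character_ else as.character(gr$ID),
    stringsAsFactors = FALSE)
  parent <- if (is.null(gr$Parent)) rep(NA_character_, length(gr)) else
    vapply(as.list(gr$Parent), function(p) if (length(p)) p[[1L]] else NA_character_,
           character(1))
  df$parent <- parent

  genes <- list()
  gene_rows <- which(df$type == "gene")
  tx_rows <- which(df$type %in% c("mRNA", "transcript"))
  for (gi in gene_rows) {
    gid <- df$id[gi]
    gtx <- list()
    for (ti in tx_rows[df$parent[tx_rows] == gid]) {
      tid <- df$id[ti]
      ex <- df[df$type == "exon" & df$parent == tid, , drop = FALSE]
      if (!nrow(ex)) stop_snotrace("transcript %s has no exons", tid)
      cd <- df[df$type == "CDS" & df$parent == tid, , drop = FALSE]
      gtx[[tid]] <- transcript(
        tid, df$strand[ti], as.matrix(ex[, c("start", "end")]),
        cds = if (nrow(cd)) as.matrix(cd[, c("start", "end")]) else NULL,
        seqid = df$seqid[ti])
    }
    if (!length(gtx)) stop_snotrace("gene %s has no transcripts", gid)
    genes[[gid]] <- list(id = gid, seqid = df$seqid[gi], strand = df$strand[gi],
                         transcripts = gtx)
  }
  sn_rows <- which(df$type == "snoRNA")
  snornas <- data.frame(
    snorna_id = df$id[sn_rows],
    family_id = if (!is.null(gr$family_id)) as.character(gr$family_id)[sn_rows]
                else rep(NA_character_, length(sn_rows)),
    class = if (!is.null(gr$sno_class)) as.character(gr$sno_class)[sn_rows]
            else rep(NA_character_, length(sn_rows)),
    seqid = df$seqid[sn_rows], start = df$start[sn_rows], end = df$end[sn_rows],
    strand = df$strand[sn_rows], stringsAsFactors = FALSE)
  genome_annotation(species_id, genes, snornas)
}

#' Write a genome annotation as GFF3
#' @param ann a [genome_annotation()].
#' @param file output path.
#' @return invisibly, `file`.
#' @export
write_genome_annotation <- function(ann, file) {
  rows <- list()
  add <- function(seqid, start, end, strand, type, id, parent = NA_character_,
                  family_id = NA_character_, sno_class = NA_character_,
                  phase = NA_integer_) {
    rows[[length(rows) + 1L]] <<- data.frame(
      seqid = seqid, start = start, end = end, strand = strand, type = type,
      id = id, parent = parent, family_id = family_id, sno_class = sno_class,
      phase = phase, stringsAsFactors = FALSE)
  }
  for (g in ann$genes) {
    spans <- do.call(rbind, lapply(g$transcripts, function(tx) {
      c(min(tx$exons[, 1L]), max(tx$exons[, 2L]))
    }))
    add(g$seqid, min(spans[, 1L]), max(spans[, 2L]), g$strand, "gene", g$id)
    for (tx in g$transcripts) {
      add(tx$seqid, min(tx$exons[, 1L]), max(tx$exons[, 2L]), tx$strand,
          "mRNA", tx$id, g$id)
      for (i in seq_len(nrow(tx$exons))) {
        add(tx$seqid, tx$exons[i, 1L], tx$exons[i, 2L], tx$strand, "exon",
            sprintf("%s.exon%d", tx$id, i), tx$id)
      }
      if (!is.null(tx$cds)) {
        # GFF3 phase: bases to skip to reach the next codon boundary
        ord <- if (tx$strand == "+") seq_len(nrow(tx$cds)) else
          rev(seq_len(nrow(tx$cds)))
        cum <- 0L
        phases <- integer(nrow(tx$cds))
        for (i in ord) {
          phases[i] <- (3L - cum %% 3L) %% 3L
          cum <- cum + tx$cds[i, 2L] - tx$cds[i, 1L]
        }
        for (i in seq_len(nrow(tx$cds))) {
          add(tx$seqid, tx$cds[i, 1L], tx$cds[i, 2L], tx$strand, "CDS",
              sprintf("%s.cds%d", tx$id, i), tx$id, phase = phases[i])
        }
      }
    }
  }
  sn <- ann$snornas
  for (i in seq_len(nrow(sn))) {
    add(sn$seqid[i], sn$start[i], sn$end[i], sn$strand[i], "snoRNA",
        sn$snorna_id[i], family_id = sn$family_id[i], sno_class = sn$class[i])
  }
  d <- do.call(rbind, rows)
  gr <- GenomicRanges::GRanges(
    seqnames = d$seqid,
    ranges = IRanges::IRanges(start = d$start + 1L, end = d$end),
    strand = d$strand)
  gr$type <- d$type
  gr$ID <- d$id
  gr$Parent <- ifelse(is.na(d$parent), "", d$parent)
  gr$Parent <- S4Vectors::unname(IRanges::CharacterList(
    lapply(gr$Parent, function(p) if (nzchar(p)) p else character(0))))
  gr$family_id <- d$family_id
  gr$sno_class <- d$sno_class
  gr$phase <- d$phase
  rtracklayer::export(gr, file, format = "gff3")
  invisible(file)
}

# ---- coordinate conversions ------------------------------------------------

#' Genomic position to spliced (cDNA) coordinate
#'
#' @param tx a [transcript()].
#' @param genomic_pos 0-based genomic position; must fall in an exon.
#' @return 0-based offset within the spliced transcript, counted from the
#'   transcript 5' end (strand-aware).
#' @export
genomic_to_cdna <- function(tx, genomic_pos) {
  ex <- tx$exons
  hit <- which(genomic_pos >= ex[, 1L] & genomic_pos < ex[, 2L])
  if (!length(hit)) {
    stop_snotrace("position %d is intronic or outside transcript %s",
                  genomic_pos, tx$id)
  }
  if (tx$strand == "+") {
    before <- if (hit > 1L) sum(ex[seq_len(hit - 1L), 2L] - ex[seq_len(hit - 1L), 1L]) else 0L
    as.integer(before + (genomic_pos - unname(ex[hit, 1L])))
  } else {
    n <- nrow(ex)
    after <- if (hit < n) sum(ex[(hit + 1L):n, 2L] - ex[(hit + 1L):n, 1L]) else 0L
    as.integer(after + (unname(ex[hit, 2L]) - 1L - genomic_pos))
  }
}

#' Spliced (cDNA) coordinate back to genomic position
#' @param tx a [transcript()].
#' @param cdna_pos 0-based spliced offset from the transcript 5' end.
#' @return 0-based genomic position.
#' @export
cdna_to_genomic <- function(tx, cdna_pos) {
  ex <- tx$exons
  lens <- ex[, 2L] - ex[, 1L]
  total <- sum(lens)
  if (cdna_pos < 0L || cdna_pos >= total) {
    stop_snotrace("cDNA position %d outside transcript %s (length %d)",
                  cdna_pos, tx$id, total)
  }
  if (tx$strand == "+") {
    cum <- cumsum(lens)
    hit <- which(cdna_pos < cum)[1L]
    prev <- if (hit > 1L) cum[hit - 1L] else 0L
    as.integer(unname(ex[hit, 1L]) + (cdna_pos - prev))
  } else {
    cum <- cumsum(rev(lens))
    hitr <- which(cdna_pos < cum)[1L]
    prev <- if (hitr > 1L) cum[hitr - 1L] else 0L
    hit <- nrow(ex) - hitr + 1L
    as.integer(unname(ex[hit, 2L]) - 1L - (cdna_pos - prev))
  }
}

#' Locate all near-exact full-length placements of a query on a genome
#'
#' Every placement on either strand where the Hamming distance between the
#' query and the genome window is at most `max_subst` (no indels), mirroring a
#' strict full-length BLAT-style locator for snoRNA sequences.
#'
#' @param query nucleotide string (non-empty).
#' @param genome nucleotide string, at least as long as `query`.
#' @param max_subst maximum substitutions (default 1, i.e. "fewer than 2").
#' @return data.frame with `position` (0-based window start on the genome
#'   forward strand), `strand`, `substitutions`, sorted by position.
#' @export
locate_full_length <- function(query, genome, max_subst = 1L) {
  if (!nzchar(query)) stop_snotrace("empty query")
  if (nchar(query) > nchar(genome)) stop_snotrace("query longer than genome")
  subj <- Biostrings::DNAString(genome)
  one_strand <- function(q, strand) {
    m <- Biostrings::matchPattern(Biostrings::DNAString(q), subj,
                                  max.mismatch = max_subst, with.indels = FALSE)
    if (!length(m)) return(NULL)
    st <- Biostrings::start(m)
    ed <- Biostrings::neditStartingAt(Biostrings::DNAString(q), subj,
                                      starting.at = st)
    data.frame(position = st - 1L, strand = strand,
               substitutions = as.integer(ed), stringsAsFactors = FALSE)
  }
  out <- rbind(one_strand(query, "+"), one_strand(revcomp(query), "-"))
  if (is.null(out)) {
    return(data.frame(position = integer(0), strand = character(0),
                      substitutions = integer(0)))
  }
  out <- out[order(out$position, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}
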