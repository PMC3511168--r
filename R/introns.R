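# Intron positional conservation and snoRNA occupancy.
#
# Intron positions are expressed in amino-acid space of the host protein
# (number of coding bases 5' of the intron, divided by 3), projected onto the
# group's protein alignment, and binned into loci with a +/- 5 column
# tolerance. Occupancy then attaches intronic snoRNAs to loci, and verdicts
# ask whether positionally equivalent snoRNAs across supergroups are
# plausibly homologous.

# exons in transcript (5'->3') order
tx_order_exons <- function(tx) {
  if (tx$strand == "+") tx$exons else tx$exons[rev(seq_len(nrow(tx$exons))), , drop = FALSE]
}

#' Number of introns of a transcript
#' @param tx a [transcript()].
#' @return integer.
#' @export
n_introns <- function(tx) nrow(tx$exons) - 1L

#' Genomic interval of an intron
#' @param tx a [transcript()].
#' @param intron_index 1-based index in transcript (5'->3') order.
#' @return integer vector (start, end), 0-based half-open genomic.
#' @export
intron_interval <- function(tx, intron_index) {
  if (intron_index < 1L || intron_index > n_introns(tx)) {
    stop_snotrace("transcript %s has no intron %d", tx$id, intron_index)
  }
  ex <- tx$exons  # genomic order
  gi <- if (tx$strand == "+") intron_index else nrow(ex) - intron_index
  c(start = unname(ex[gi, 2L]), end = unname(ex[gi + 1L, 1L]))
}

#' Protein-space position of an intron
#'
#' The amino-acid index is the number of coding bases 5' of the intron
#' divided by 3 (floor), i.e. the count of complete codons upstream of the
#' exon boundary adjacent to the intron. Introns lying in UTRs (no coding
#' sequence upstream, or none downstream) are excluded and return `NA`.
#'
#' @param tx a [transcript()] carrying CDS intervals.
#' @param intron_index 1-based index in transcript order.
#' @return 0-based amino-acid index, or `NA_integer_` for UTR introns.
#' @export
intron_protein_position <- function(tx, intron_index) {
  if (is.null(tx$cds)) stop_snotrace("transcript %s has no CDS", tx$id)
  iv <- intron_interval(tx, intron_index)
  cds <- tx$cds
  total <- sum(cds[, 2L] - cds[, 1L])
  if (tx$strand == "+") {
    upstream <- sum(pmax(0L, pmin(cds[, 2L], iv["start"]) - cds[, 1L]))
  } else {
    upstream <- sum(pmax(0L, cds[, 2L] - pmax(cds[, 1L], iv["end"])))
  }
  if (upstream == 0L || upstream == total) return(NA_integer_)  # UTR intron
  as.integer(upstream %/% 3L)
}

#' Ortholog group
#'
#' @param group_id group identifier (by convention the seed gene id).
#' @param members data.frame with columns `species`, `gene_id`,
#'   `transcript_id`; one member per species.
#' @return an `ortholog_group`.
#' @export
ortholog_group <- function(group_id, members) {
  need <- c("species", "gene_id", "transcript_id")
  if (!all(need %in% names(members))) {
    stop_snotrace("ortholog group needs columns: %s", paste(need, collapse = ", "))
  }
  if (anyDuplicated(members$species)) {
    stop_snotrace("group %s: one member per species", group_id)
  }
  structure(list(group_id = group_id,
                 members = members[order(members$species), , drop = FALSE]),
            class = "ortholog_group")
}

# all (species, intron_index, aa) positions of a group, UTR introns dropped
group_intron_positions <- function(group, annotations) {
  rows <- NULL
  for (i in seq_len(nrow(group$members))) {
    sp <- group$members$species[i]
    ann <- annotations[[sp]]
    if (is.null(ann)) stop_snotrace("no annotation for species %s", sp)
    gene <- ann$genes[[group$members$gene_id[i]]]
    if (is.null(gene)) stop_snotrace("species %s lacks gene %s", sp,
                                     group$members$gene_id[i])
    tx <- gene$transcripts[[group$members$transcript_id[i]]] %||% main_transcript(gene)
    for (k in seq_len(max(0L, n_introns(tx)))) {
      aa <- intron_protein_position(tx, k)
      if (!is.na(aa)) {
        rows <- rbind(rows, data.frame(species = sp, gene_id = gene$id,
                                       transcript_id = tx$id, intron_index = k,
                                       aa = aa, stringsAsFactors = FALSE))
      }
    }
  }
  rows %||% data.frame(species = character(0), gene_id = character(0),
                       transcript_id = character(0), intron_index = integer(0),
                       aa = integer(0))
}

#' Bin a group's intron positions into positional loci
#'
#' Positions are projected to protein-alignment columns through the species'
#' row and clustered by single linkage with link distance `tol` (5 columns).
#' Deterministic and invariant to input order.
#'
#' @param group an [ortholog_group()].
#' @param annotations named list of [genome_annotation()]s by species.
#' @param alignment the group's protein [multiple_alignment()].
#' @param params a [locus_binning_params()].
#' @return an `intron_loci` object: `$loci` (locus_id, group_id, column,
#'   n_species) and `$members` (per species intron memberships).
#' @export
bin_intron_loci <- function(group, annotations, alignment,
                            params = locus_binning_params()) {
  pos <- group_intron_positions(group, annotations)
  if (!nrow(pos)) {
    return(structure(list(
      loci = data.frame(locus_id = character(0), group_id = character(0),
                        column = integer(0), n_species = integer(0)),
      members = cbind(pos, data.frame(column = integer(0), locus_id = character(0)))),
      class = "intron_loci"))
  }
  pos$column <- vapply(seq_len(nrow(pos)), function(i) {
    ungapped_to_column(alignment, pos$species[i], pos$aa[i])
  }, integer(1))
  cl <- chain_clusters(pos$column, params$intron_tol)
  loci <- NULL
  members <- NULL
  for (c0 in sort(unique(cl))) {
    pp <- pos[cl == c0, , drop = FALSE]
    col <- as.integer(round(stats::median(pp$column)))
    lid <- sprintf("%s_i%04d", group$group_id, col)
    pp$locus_id <- lid
    members <- rbind(members, pp)
    loci <- rbind(loci, data.frame(locus_id = lid, group_id = group$group_id,
                                   column = col,
                                   n_species = length(unique(pp$species)),
                                   stringsAsFactors = FALSE))
  }
  o <- order(loci$column)
  loci <- loci[o, , drop = FALSE]
  rownames(loci) <- NULL
  members <- members[order(members$column, members$species, members$intron_index), ,
                     drop = FALSE]
  rownames(members) <- NULL
  structure(list(loci = loci, members = members), class = "intron_loci")
}

#' @export
print.intron_loci <- function(x, ...) {
  cat(sprintf("<intron_loci> %d loci, %d intron memberships\n",
              nrow(x$loci), nrow(x$members)))
  invisible(x)
}

#' Intron loci traceable to the root (LECA)
#'
#' @param members combined `$members` rows from one or more
#'   [bin_intron_loci()] results.
#' @param phy a [phylogeny].
#' @return character vector of locus ids with Dollo root state 1.
#' @export
reconstruct_intron_ancestry <- function(members, phy) {
  if (!nrow(members)) return(character(0))
  mat <- locus_presence_matrix(members$locus_id, members$species, phy,
                               kind = "intron_locus")
  recon <- dollo_reconstruct(phy, mat)
  sort(characters_at_node(recon))
}

#' Attach intronic snoRNA occupancy to intron loci
#'
#' A snoRNA occupies a locus for a species iff its genomic interval is fully
#' contained in that species' intron at the locus and (by default) lies on
#' the host strand. snoRNAs overlapping an exon/intron boundary are flagged
#' and not assigned.
#'
#' @param members `$members` rows from [bin_intron_loci()].
#' @param annotations named list of [genome_annotation()]s by species.
#' @param catalog a [family_catalog()].
#' @param same_strand require snoRNA on the host strand (default TRUE).
#' @return list with `$occupancy` (locus_id, species, snorna_id, family_id,
#'   clan_id, class) and `$flagged` (boundary-spanning snoRNAs).
#' @export
assign_snorna_occupancy <- function(members, annotations, catalog,
                                    same_strand = TRUE) {
  occ <- NULL
  flagged <- NULL
  for (i in seq_len(nrow(members))) {
    sp <- members$species[i]
    ann <- annotations[[sp]]
    gene <- ann$genes[[members$gene_id[i]]]
    tx <- gene$transcripts[[members$transcript_id[i]]]
    iv <- intron_interval(tx, members$intron_index[i])
    sn <- ann$snornas
    if (!nrow(sn)) next
    same_chr <- sn$seqid == tx$seqid
    inside <- same_chr & sn$start >= iv["start"] & sn$end <= iv["end"]
    spanning <- same_chr & !inside & sn$start < iv["end"] & sn$end > iv["start"]
    if (same_strand) inside <- inside & sn$strand == tx$strand
    if (any(spanning)) {
      flagged <- rbind(flagged, cbind(
        sn[spanning, c("snorna_id", "family_id", "class"), drop = FALSE],
        data.frame(locus_id = members$locus_id[i], species = sp,
                   stringsAsFactors = FALSE)))
    }
    if (any(inside)) {
      hit <- sn[inside, , drop = FALSE]
      occ <- rbind(occ, data.frame(
        locus_id = members$locus_id[i], group_id = members$gene_id[i],
        species = sp, snorna_id = hit$snorna_id, family_id = hit$family_id,
        clan_id = vapply(hit$family_id, function(f) {
          if (is.na(f)) "" else family_clan(catalog, f)
        }, character(1)),
        class = hit$class, stringsAsFactors = FALSE))
    }
  }
  empty_occ <- data.frame(locus_id = character(0), group_id = character(0),
                          species = character(0), snorna_id = character(0),
                          family_id = character(0), clan_id = character(0),
                          class = character(0))
  occ <- occ %||% empty_occ
  occ <- unique(occ)
  occ <- occ[order(occ$locus_id, occ$species, occ$snorna_id), , drop = FALSE]
  rownames(occ) <- NULL
  list(occupancy = occ, flagged = flagged %||% empty_occ[, c(
    "snorna_id", "family_id", "class", "locus_id", "species")])
}

#' Cross-supergroup homology verdict for an occupied intron locus
#'
#' @param occ occupancy rows (one locus) from [assign_snorna_occupancy()].
#' @param supergroups named character vector species -> supergroup.
#' @return a one-row data.frame: `locus_id`, `verdict` (one of
#'   `same_family`, `same_clan`, `same_class_no_evidence`, `unrelated_classes`,
#'   `single_supergroup`) and the supporting family/supergroup constituency.
#' @export
cross_supergroup_homology <- function(occ, supergroups) {
  if (!nrow(occ)) stop_snotrace("locus has no occupancy")
  occ$supergroup <- unname(supergroups[occ$species])
  if (anyNA(occ$supergroup)) {
    stop_snotrace("species without supergroup label: %s",
                  paste(unique(occ$species[is.na(occ$supergroup)]), collapse = ", "))
  }
  n_sg <- length(unique(occ$supergroup))
  fam_span <- vapply(split(occ$supergroup, occ$family_id),
                     function(s) length(unique(s)), integer(1))
  clan_occ <- occ[occ$clan_id != "", , drop = FALSE]
  clan_span <- if (nrow(clan_occ)) {
    vapply(split(clan_occ$supergroup, clan_occ$clan_id),
           function(s) length(unique(s)), integer(1))
  } else integer(0)
  classes_by_sg <- split(occ$class, occ$supergroup)
  verdict <- if (n_sg < 2L) {
    "single_supergroup"
  } else if (any(fam_span >= 2L)) {
    "same_family"
  } else if (length(clan_span) && any(clan_span >= 2L)) {
    "same_clan"
  } else if (length(unique(occ$class)) > 1L) {
    "unrelated_classes"
  } else {
    "same_class_no_evidence"
  }
  data.frame(locus_id = occ$locus_id[1L], verdict = verdict,
             n_supergroups = n_sg,
             families = paste(sort(unique(occ$family_id)), collapse = ","),
             classes = paste(sort(unique(occ$class)), collapse = ","),
             stringsAsFactors = FALSE)
}

#' Date a (family, locus) association and call recent gains
#'
#' For every family x intron-locus association, reports the MRCA of the
#' species sharing it, alongside the Dollo placement of the host gene's
#' presence; a recent gain is called when the association MRCA is strictly
#' shallower than the host-gene placement (the snoRNA moved into an older
#' gene).
#'
#' @param occ occupancy data.frame from [assign_snorna_occupancy()].
#' @param phy a [phylogeny].
#' @param host_gain named character vector: locus_id (or group_id) -> label of
#'   the node where the host gene is placed; when named by group the locus'
#'   group is used.
#' @return data.frame with one row per (family_id, locus_id): `assoc_node`,
#'   `host_node`, `recent_gain`.
#' @export
date_association <- function(occ, phy, host_gain) {
  if (!nrow(occ)) {
    return(data.frame(family_id = character(0), locus_id = character(0),
                      assoc_node = character(0), host_node = character(0),
                      recent_gain = logical(0)))
  }
  idx <- tree_index(phy)
  keys <- unique(occ[, c("family_id", "locus_id", "group_id")])
  out <- NULL
  for (i in seq_len(nrow(keys))) {
    rows <- occ$family_id == keys$family_id[i] & occ$locus_id == keys$locus_id[i]
    sp <- unique(occ$species[rows])
    anode <- mrca_id(phy, leaf_ids(phy, sp))
    hlab <- unname(host_gain[keys$locus_id[i]])
    if (is.na(hlab)) hlab <- unname(host_gain[keys$group_id[i]])
    if (is.na(hlab)) hlab <- node_label(phy, phy$root)
    hnode <- node_id(phy, hlab)
    recent <- is_ancestor(phy, hnode, anode, idx) && hnode != anode
    out <- rbind(out, data.frame(
      family_id = keys$family_id[i], locus_id = keys$locus_id[i],
      assoc_node = node_label(phy, anode), host_node = hlab,
      recent_gain = recent, stringsAsFactors = FALSE))
  }
  out <- out[order(out$family_id, out$locus_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
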