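# End-to-end orchestration: read an input bundle, run every stage in order,
# write deterministic TSV/JSON reports.

#' Pipeline configuration
#'
#' @param input_dir directory holding the input bundle (layout as written by
#'   [simulate_bundle()]: `tree.nwk`, `supergroups.tsv`, `catalog.tsv`,
#'   `species/<sp>.gff3` + `species/<sp>_snorna.fa`, `rrna_ssu.aln.fa`,
#'   `rrna_lsu.aln.fa`, `proteins/<group>.aln.fa`, `orthologs.tsv`,
#'   `known_sites.tsv`, `expression.tsv`).
#' @param out_dir report directory (created by [run_pipeline()]).
#' @param search a [guide_search_params()].
#' @param binning a [locus_binning_params()].
#' @param reference_species species whose expression matrix is analysed;
#'   defaults to the first leaf of the first root subtree.
#' @param same_strand require intronic snoRNAs on the host strand.
#' @param seed seed recorded in every report (the pipeline itself is
#'   deterministic given its inputs).
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(input_dir, out_dir,
                            search = guide_search_params(),
                            binning = locus_binning_params(),
                            reference_species = NULL,
                            same_strand = TRUE,
                            seed = 1L) {
  cfg <- list(input_dir = input_dir, out_dir = out_dir, search = search,
              binning = binning, reference_species = reference_species,
              same_strand = same_strand, seed = as.integer(seed))
  class(cfg) <- "pipeline_config"
  cfg
}

check_config <- function(cfg) {
  need <- c("tree.nwk", "supergroups.tsv", "catalog.tsv", "orthologs.tsv",
            "expression.tsv")
  for (f in need) {
    p <- file.path(cfg$input_dir, f)
    if (!file.exists(p)) stop_snotrace("missing input file: %s", p)
  }
  invisible(TRUE)
}

read_bundle <- function(cfg) {
  check_config(cfg)
  dir <- cfg$input_dir
  phy <- read_species_tree(file.path(dir, "tree.nwk"),
                           file.path(dir, "supergroups.tsv"))
  catalog <- read_family_catalog(file.path(dir, "catalog.tsv"))
  species <- phy$tree$tip.label
  annotations <- list()
  sno_seqs <- list()
  for (sp in species) {
    annotations[[sp]] <- read_genome_annotation(
      file.path(dir, "species", paste0(sp, ".gff3")), species_id = sp)
    fa <- file.path(dir, "species", paste0(sp, "_snorna.fa"))
    sno_seqs[[sp]] <- if (file.exists(fa)) {
      ss <- Biostrings::readDNAStringSet(fa)
      stats::setNames(as.character(ss), names(ss))
    } else character(0)
  }
  alns <- list()
  for (su in c("SSU", "LSU")) {
    p <- file.path(dir, sprintf("rrna_%s.aln.fa", tolower(su)))
    if (file.exists(p)) {
      alns[[su]] <- read_alignment(p, kind = paste0("rRNA_", su))
    }
  }
  prot_files <- sort(list.files(file.path(dir, "proteins"),
                                pattern = "\\.aln\\.fa$", full.names = TRUE))
  proteins <- lapply(prot_files, read_alignment, kind = "protein")
  names(proteins) <- sub("\\.aln\\.fa$", "", basename(prot_files))
  orthologs <- utils::read.delim(file.path(dir, "orthologs.tsv"),
                                 stringsAsFactors = FALSE)
  known <- NULL
  if (file.exists(file.path(dir, "known_sites.tsv"))) {
    known <- read_known_sites(file.path(dir, "known_sites.tsv"))
  }
  expr <- read_expression_matrix(file.path(dir, "expression.tsv"))
  list(phy = phy, catalog = catalog, annotations = annotations,
       sno_seqs = sno_seqs, rrna = alns, proteins = proteins,
       orthologs = orthologs, known = known, expression = expr)
}

# family and clan presence characters from annotated snoRNAs
annotation_presence <- function(annotations, catalog, phy) {
  species <- phy$tree$tip.label
  fams <- sort(unique(unlist(lapply(annotations, function(a) a$snornas$family_id))))
  fams <- fams[!is.na(fams)]
  m <- matrix(0L, length(fams), length(species), dimnames = list(fams, species))
  for (sp in species) {
    seen <- unique(annotations[[sp]]$snornas$family_id)
    m[intersect(fams, seen), sp] <- 1L
  }
  clans <- sort(unique(catalog$families$clan_id[catalog$families$clan_id != ""]))
  cm <- NULL
  for (cl in clans) {
    members <- intersect(clan_members(catalog, cl), fams)
    if (!length(members)) next
    row <- as.integer(colSums(m[members, , drop = FALSE]) > 0L)
    cm <- rbind(cm, matrix(row, 1L, dimnames = list(cl, species)))
  }
  list(families = presence_matrix(m, "family"),
       clans = if (!is.null(cm)) presence_matrix(cm, "clan") else NULL)
}

#' Run the full comparative pipeline on an input bundle
#'
#' Stages, in order: annotation load, family/clan presence and Dollo
#' placement, guide mapping and site-locus binning, LECA site inference and
#' known-site recovery, intron atlas with occupancy / homology verdicts /
#' association dating, expression-breadth comparison, and the total-evidence
#' intersection. All reports are written to `cfg$out_dir` as TSV/JSON;
#' rerunning on identical inputs yields byte-identical files.
#'
#' @param cfg a [pipeline_config()].
#' @return invisibly, the report bundle (a list).
#' @export
run_pipeline <- function(cfg) {
  b <- read_bundle(cfg)
  phy <- b$phy
  catalog <- b$catalog
  species <- phy$tree$tip.label
  idx <- tree_index(phy)
  ls <- leafsets(phy, idx)
  kids <- idx$children[[phy$root]]
  uni <- species[ls[[kids[1L]]]]
  bik <- species[ls[[kids[2L]]]]
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)

  ## stage 1: family/clan placement
  pres <- annotation_presence(b$annotations, catalog, phy)
  recon_f <- dollo_reconstruct(phy, pres$families)
  leca_families <- sort(characters_at_node(recon_f))
  leca_clans <- character(0)
  if (!is.null(pres$clans)) {
    recon_c <- dollo_reconstruct(phy, pres$clans)
    leca_clans <- sort(characters_at_node(recon_c))
  }
  write_presence_matrix(pres$families,
                        file.path(cfg$out_dir, "family_presence.tsv"))

  ## stage 2: guide mapping
  hits <- NULL
  for (sp in species) {
    sn <- b$annotations[[sp]]$snornas
    sn <- sn[!is.na(sn$class) & sn$class == "CD", , drop = FALSE]
    for (i in seq_len(nrow(sn))) {
      seqv <- b$sno_seqs[[sp]][[sn$snorna_id[i]]]
      if (is.null(seqv)) next
      rec <- list(snorna_id = sn$snorna_id[i], family_id = sn$family_id[i],
                  species_id = sp, class = "CD", sequence = seqv)
      for (su in names(b$rrna)) {
        rseq <- ungapped_row(b$rrna[[su]], sp)
        h <- search_guides(rec, rseq, su, cfg$search)
        if (nrow(h)) hits <- rbind(hits, h)
      }
    }
  }
  if (!is.null(hits)) hits <- project_hits(hits, b$rrna)
  sites <- bin_sites(hits %||% cbind(empty_hit_frame(), data.frame(
    snorna_id = character(0), family_id = character(0),
    species_id = character(0), subunit = character(0),
    center_column = integer(0))), cfg$binning)
  leca_site_ids <- infer_leca_sites(sites, phy)
  utils::write.table(sites$loci, file.path(cfg$out_dir, "site_loci.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(sites$members, file.path(cfg$out_dir, "site_members.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  ## stage 3: known-site recovery
  recovery <- NULL
  if (!is.null(b$known) && nrow(b$known)) {
    recovery <- compare_to_known(sites, b$known, b$rrna,
                                 tol = cfg$binning$site_tol)
    utils::write.table(recovery$rows,
                       file.path(cfg$out_dir, "known_site_recovery.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  ## stage 4: intron atlas
  groups <- split(b$orthologs, b$orthologs$group_id)
  all_members <- NULL
  for (gid in sort(names(groups))) {
    if (is.null(b$proteins[[gid]])) next
    og <- ortholog_group(gid, groups[[gid]])
    il <- bin_intron_loci(og, b$annotations, b$proteins[[gid]], cfg$binning)
    if (nrow(il$members)) all_members <- rbind(all_members, il$members)
  }
  leca_introns <- if (!is.null(all_members)) {
    reconstruct_intron_ancestry(all_members, phy)
  } else character(0)
  occ_res <- assign_snorna_occupancy(
    all_members %||% data.frame(species = character(0), gene_id = character(0),
                                transcript_id = character(0),
                                intron_index = integer(0), aa = integer(0),
                                column = integer(0), locus_id = character(0)),
    b$annotations, catalog, same_strand = cfg$same_strand)
  occ <- occ_res$occupancy
  # map per-species gene ids back to group ids for reporting
  occ$group_id <- b$orthologs$group_id[match(occ$group_id, b$orthologs$gene_id)]
  utils::write.table(occ, file.path(cfg$out_dir, "occupancy.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  # homology verdicts for occupied LECA intron loci
  verdicts <- NULL
  for (lid in sort(unique(occ$locus_id))) {
    if (!lid %in% leca_introns) next
    verdicts <- rbind(verdicts,
                      cross_supergroup_homology(occ[occ$locus_id == lid, ,
                                                    drop = FALSE],
                                                phy$supergroups))
  }
  # association dating: host genes are present in every species here, so the
  # host placement is the Dollo gain of the gene's presence pattern
  gene_presence <- do.call(rbind, lapply(sort(unique(b$orthologs$group_id)),
    function(gid) {
      sp_with <- b$orthologs$species[b$orthologs$group_id == gid]
      row <- as.integer(species %in% sp_with)
      matrix(row, 1L, dimnames = list(gid, species))
    }))
  recon_g <- dollo_reconstruct(phy, presence_matrix(gene_presence, "family"))
  host_gain <- recon_g$gain_node
  dating <- date_association(occ, phy, host_gain)
  if (!is.null(verdicts)) {
    utils::write.table(verdicts, file.path(cfg$out_dir, "homology_verdicts.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  utils::write.table(dating, file.path(cfg$out_dir, "association_dating.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  ## stage 5: expression breadth
  ref <- cfg$reference_species %||% uni[1L]
  host_groups <- sort(unique(occ$group_id[occ$species == ref]))
  host_groups <- intersect(host_groups, rownames(b$expression))
  expr_cmp <- if (length(host_groups)) {
    compare_host_vs_nonhost(b$expression, host_groups)
  } else NULL

  ## stage 6: evidence sets and total evidence
  set_A <- leca_families
  for (cl in leca_clans) set_A <- union(set_A, clan_members(catalog, cl))
  set_A <- sort(set_A)
  leca_loci_members <- sites$members[sites$members$locus_id %in% leca_site_ids, ,
                                     drop = FALSE]
  set_B <- sort(unique(leca_loci_members$family_id))
  set_C <- character(0)
  if (!is.null(b$known) && nrow(b$known)) {
    for (f in sort(unique(b$known$family_id))) {
      sp_f <- unique(b$known$species[b$known$family_id == f])
      if (length(intersect(sp_f, uni)) && length(intersect(sp_f, bik))) {
        set_C <- c(set_C, f)
      }
    }
  }
  evidence <- total_evidence(set_A, set_B, set_C, catalog)

  # clan expansion checks over clans with >= 2 LECA member families
  family_loci <- split(leca_loci_members$locus_id, leca_loci_members$family_id)
  family_loci <- lapply(family_loci, function(x) sort(unique(x)))
  clan_checks <- NULL
  for (cl in sort(unique(catalog$families$clan_id[catalog$families$clan_id != ""]))) {
    chk <- clan_expansion_check(cl, leca_families, family_loci, catalog)
    clan_checks <- rbind(clan_checks, chk)
  }

  report <- list(
    seed = cfg$seed,
    reference_species = ref,
    leca_families = leca_families,
    leca_clans = leca_clans,
    n_leca_families = length(leca_families),
    n_leca_clans = length(leca_clans),
    site_loci = sites$loci,
    leca_site_loci = leca_site_ids,
    n_leca_site_loci = length(leca_site_ids),
    known_recovery = if (!is.null(recovery)) {
      as.list(recovery$totals)
    } else NULL,
    n_intron_loci = length(unique(all_members$locus_id %||% character(0))),
    leca_introns = leca_introns,
    n_leca_introns = length(leca_introns),
    occupied_leca_introns = sort(unique(occ$locus_id[occ$locus_id %in% leca_introns])),
    verdicts = verdicts,
    dating = dating,
    expression = if (!is.null(expr_cmp)) {
      list(p_value = expr_cmp$test$p_value, U = expr_cmp$test$U,
           medians = as.list(expr_cmp$medians),
           n_host = length(expr_cmp$host_entropy),
           n_nonhost = length(expr_cmp$nonhost_entropy))
    } else NULL,
    evidence = list(sizes = as.list(evidence$sizes),
                    intersection = evidence$intersection,
                    exclusions = evidence$exclusions),
    clan_checks = clan_checks)
  jsonlite::write_json(report, file.path(cfg$out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null")
  invisible(c(report, list(sites = sites, occupancy = occ,
                           expression_cmp = expr_cmp,
                           recovery = recovery)))
}
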