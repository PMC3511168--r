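# Total-evidence intersection and clan-expansion checks.

#' Total-evidence intersection of the three lines of evidence
#'
#' A: families placed at LECA by presence/absence of annotated snoRNAs
#' (directly or through their clan); B: families supporting at least one
#' LECA guide-mapped site locus; C: families with at least one independently
#' reported modification site whose species distribution spans the root.
#' H/ACA and cleavage-only families cannot take part in guide mapping and
#' are listed as exclusions rather than silently dropped.
#'
#' @param A,B,C character vectors of family ids.
#' @param catalog a [family_catalog()].
#' @return an `evidence_report`: per-set and pairwise/triple cardinalities,
#'   the intersection itself, and the exclusion table.
#' @export
total_evidence <- function(A, B, C, catalog) {
  for (f in unique(c(A, B, C))) catalog_lookup(catalog, f)  # errors if unknown
  excl <- NULL
  for (f in sort(unique(A))) {
    cls <- catalog_class(catalog, f)
    if (cls != "CD") {
      excl <- rbind(excl, data.frame(family_id = f, reason = "non_CD_class",
                                     stringsAsFactors = FALSE))
    } else if (is_cleavage_only(catalog, f)) {
      excl <- rbind(excl, data.frame(family_id = f, reason = "cleavage_only",
                                     stringsAsFactors = FALSE))
    }
  }
  excluded_ids <- excl$family_id %||% character(0)
  A_use <- setdiff(A, excluded_ids)
  B_use <- setdiff(B, excluded_ids)
  C_use <- setdiff(C, excluded_ids)
  inter <- sort(Reduce(intersect, list(A_use, B_use, C_use)))
  res <- list(
    A = sort(unique(A)), B = sort(unique(B)), C = sort(unique(C)),
    intersection = inter,
    sizes = c(A = length(unique(A)), B = length(unique(B)),
              C = length(unique(C)),
              AB = length(intersect(A_use, B_use)),
              AC = length(intersect(A_use, C_use)),
              BC = length(intersect(B_use, C_use)),
              ABC = length(inter)),
    exclusions = excl %||% data.frame(family_id = character(0),
                                      reason = character(0)))
  class(res) <- "evidence_report"
  res
}

#' @export
print.evidence_report <- function(x, ...) {
  s <- x$sizes
  cat(sprintf(
    "<evidence_report> |A|=%d |B|=%d |C|=%d; pairwise AB=%d AC=%d BC=%d; total evidence |ABC|=%d (%d excluded)\n",
    s["A"], s["B"], s["C"], s["AB"], s["AC"], s["BC"], s["ABC"],
    nrow(x$exclusions)))
  invisible(x)
}

#' Clan expansion check: pre-LECA duplication vs artefactual split
#'
#' For a clan with two or more families independently placed at LECA, asks
#' whether those families guide modifications at distinct LECA site loci
#' (consistent with duplication and divergence before the root) or share a
#' target (consistent with an artefactual split of one orthologous group
#' during family model building).
#'
#' @param clan_id clan id.
#' @param leca_families family ids placed at LECA.
#' @param family_loci named list: family id -> character vector of LECA site
#'   locus ids it supports.
#' @param catalog a [family_catalog()].
#' @return one-row data.frame with the `verdict`: `"duplication"`,
#'   `"artefactual_split_or_orthologous"`, or `"not_applicable"` (fewer than
#'   two LECA families in the clan).
#' @export
clan_expansion_check <- function(clan_id, leca_families, family_loci, catalog) {
  members <- intersect(clan_members(catalog, clan_id), leca_families)
  if (length(members) < 2L) {
    return(data.frame(clan_id = clan_id, verdict = "not_applicable",
                      n_leca_families = length(members),
                      stringsAsFactors = FALSE))
  }
  loci <- lapply(members, function(f) family_loci[[f]] %||% character(0))
  names(loci) <- members
  mapped <- members[lengths(loci) > 0L]
  verdict <- "artefactual_split_or_orthologous"
  if (length(mapped) >= 2L) {
    for (i in seq_along(mapped)[-length(mapped)]) {
      for (j in (i + 1L):length(mapped)) {
        if (!length(intersect(loci[[mapped[i]]], loci[[mapped[j]]]))) {
          verdict <- "duplication"
        }
      }
    }
  }
  data.frame(clan_id = clan_id, verdict = verdict,
             n_leca_families = length(members), stringsAsFactors = FALSE)
}
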