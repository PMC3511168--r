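# Rfam-style family catalog plus the small TSV tables shared across stages
# (known modification sites, expression matrices).

#' Family catalog (families, clans, classes, function flags)
#'
#' @param df data.frame with columns `family_id`, `clan_id` (empty/NA for
#'   families outside any clan), `class` (`"CD"` or `"HACA"`) and `fun`
#'   (`"modification_guide"` or `"cleavage_only"`; the latter houses the
#'   U3/snoU13-style exclusion from target mapping).
#' @return a `family_catalog` object.
#' @export
family_catalog <- function(df) {
  need <- c("family_id", "clan_id", "class", "fun")
  if (!all(need %in% names(df))) {
    stop_snotrace("catalog needs columns: %s", paste(need, collapse = ", "))
  }
  df$clan_id[is.na(df$clan_id)] <- ""
  if (anyDuplicated(df$family_id)) {
    stop_snotrace("each family may appear once (and hence in at most one clan)")
  }
  if (!all(df$class %in% c("CD", "HACA"))) {
    stop_snotrace("class must be 'CD' or 'HACA'")
  }
  if (!all(df$fun %in% c("modification_guide", "cleavage_only"))) {
    stop_snotrace("fun must be 'modification_guide' or 'cleavage_only'")
  }
  structure(list(families = df[order(df$family_id), , drop = FALSE]),
            class = "family_catalog")
}

#' @rdname family_catalog
#' @param file TSV path with the four catalog columns.
#' @export
read_family_catalog <- function(file) {
  family_catalog(utils::read.delim(file, stringsAsFactors = FALSE,
                                   na.strings = c("NA", "")))
}

#' @rdname family_catalog
#' @param catalog a `family_catalog`.
#' @export
write_family_catalog <- function(catalog, file) {
  utils::write.table(catalog$families, file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(file)
}

#' @export
print.family_catalog <- function(x, ...) {
  f <- x$families
  cat(sprintf("<family_catalog> %d families, %d clans (%d CD, %d HACA, %d cleavage-only)\n",
              nrow(f), length(unique(f$clan_id[f$clan_id != ""])),
              sum(f$class == "CD"), sum(f$class == "HACA"),
              sum(f$fun == "cleavage_only")))
  invisible(x)
}

catalog_lookup <- function(catalog, family_id) {
  i <- match(family_id, catalog$families$family_id)
  if (is.na(i)) stop_snotrace("unknown family: %s", family_id)
  catalog$families[i, , drop = FALSE]
}

#' Clan of a family ("" when the family sits outside any clan)
#' @param catalog a [family_catalog()].
#' @param family_id family id.
#' @return the clan id, or `""`.
#' @export
family_clan <- function(catalog, family_id) {
  catalog_lookup(catalog, family_id)$clan_id
}

#' Member families of a clan
#' @param catalog a [family_catalog()].
#' @param clan_id clan id.
#' @return character vector of family ids.
#' @export
clan_members <- function(catalog, clan_id) {
  catalog$families$family_id[catalog$families$clan_id == clan_id]
}

# class for a family OR a clan id (clan class = class of its members; "mixed"
# if members disagree, which the simulator never produces).
catalog_class <- function(catalog, id) {
  f <- catalog$families
  i <- match(id, f$family_id)
  if (!is.na(i)) return(f$class[i])
  cls <- unique(f$class[f$clan_id == id & f$clan_id != ""])
  if (!length(cls)) stop_snotrace("unknown family or clan: %s", id)
  if (length(cls) > 1L) "mixed" else cls
}

is_cleavage_only <- function(catalog, family_id) {
  catalog_lookup(catalog, family_id)$fun == "cleavage_only"
}

#' Read / write a known-modification-site table
#'
#' Columns: `species`, `subunit` (SSU/LSU), `site_position` (1-based position
#' on that species' ungapped rRNA, converted to the internal 0-based
#' convention on read), `modification_type` (e.g. "Am"), `snorna_id`,
#' `family_id`.
#'
#' @param file TSV path.
#' @return data.frame with `site_position` 0-based.
#' @export
read_known_sites <- function(file) {
  d <- utils::read.delim(file, stringsAsFactors = FALSE)
  need <- c("species", "subunit", "site_position", "modification_type",
            "snorna_id", "family_id")
  if (!all(need %in% names(d))) {
    stop_snotrace("known-site table needs columns: %s", paste(need, collapse = ", "))
  }
  d$site_position <- as.integer(d$site_position) - 1L
  d
}

#' @rdname read_known_sites
#' @param sites data.frame as returned by [read_known_sites()] (0-based).
#' @export
write_known_sites <- function(sites, file) {
  sites$site_position <- as.integer(sites$site_position) + 1L
  utils::write.table(sites, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' Read / write a gene x tissue expression matrix (TSV, header row)
#' @param file TSV path; first column `gene_id`.
#' @return numeric matrix, rows = genes, columns = tissues.
#' @export
read_expression_matrix <- function(file) {
  d <- utils::read.delim(file, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(d[, -1L, drop = FALSE])
  rownames(m) <- d[[1L]]
  storage.mode(m) <- "double"
  m
}

#' @rdname read_expression_matrix
#' @param mat numeric matrix with gene rownames and tissue colnames.
#' @export
write_expression_matrix <- function(mat, file) {
  d <- data.frame(gene_id = rownames(mat), mat, check.names = FALSE)
  utils::write.table(d, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}
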