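# Multiple alignments and ungapped <-> column coordinate maps. Both '-' and
# '.' are gaps (SILVA-style alignments use dots). Columns are 0-based,
# matching every other coordinate in the package.

#' Multiple alignment container
#'
#' @param rows named character vector: species id -> gapped sequence; all
#'   rows must be equal length.
#' @param kind one of `"rRNA_SSU"`, `"rRNA_LSU"`, `"protein"`.
#' @return a `multiple_alignment` with a precomputed per-row map from
#'   ungapped positions to alignment columns.
#' @export
multiple_alignment <- function(rows, kind = c("protein", "rRNA_SSU", "rRNA_LSU")) {
  kind <- match.arg(kind)
  if (is.null(names(rows)) || any(!nzchar(names(rows)))) {
    stop_snotrace("alignment rows must be named by species id")
  }
  w <- unique(nchar(rows))
  if (length(w) != 1L) stop_snotrace("alignment rows differ in length")
  maps <- lapply(rows, function(r) {
    ch <- seq_chars(r)
    which(!(ch %in% GAP_CHARS)) - 1L   # 0-based columns of non-gap chars
  })
  structure(list(rows = rows, kind = kind, ncol = w, maps = maps),
            class = "multiple_alignment")
}

#' Read / write an aligned FASTA file
#' @param file aligned FASTA path; record names are species ids.
#' @param kind alignment kind, as in [multiple_alignment()].
#' @return a `multiple_alignment`.
#' @export
read_alignment <- function(file, kind = "protein") {
  ss <- Biostrings::readBStringSet(file)
  multiple_alignment(stats::setNames(as.character(ss), names(ss)), kind)
}

#' @rdname read_alignment
#' @param aln a `multiple_alignment`.
#' @export
write_alignment <- function(aln, file) {
  Biostrings::writeXStringSet(Biostrings::BStringSet(aln$rows), file, width = 80L)
  invisible(file)
}

#' @export
print.multiple_alignment <- function(x, ...) {
  cat(sprintf("<multiple_alignment> %s: %d rows x %d columns\n",
              x$kind, length(x$rows), x$ncol))
  invisible(x)
}

aln_row <- function(aln, species) {
  if (!species %in% names(aln$rows)) {
    stop_snotrace("species %s has no row in the %s alignment", species, aln$kind)
  }
  species
}

#' Ungapped sequence position to alignment column
#'
#' @param aln a [multiple_alignment()].
#' @param species row name.
#' @param seq_pos 0-based position(s) in the ungapped row sequence.
#' @return 0-based alignment column(s) holding those residues.
#' @export
ungapped_to_column <- function(aln, species, seq_pos) {
  map <- aln$maps[[aln_row(aln, species)]]
  if (any(seq_pos < 0L) || any(seq_pos >= length(map))) {
    stop_snotrace("seq_pos out of range for %s (ungapped length %d)",
                  species, length(map))
  }
  map[seq_pos + 1L]
}

#' Alignment column back to ungapped position (non-gap columns only)
#' @param aln a [multiple_alignment()].
#' @param species row name.
#' @param column 0-based alignment column(s); must be non-gap in that row.
#' @return 0-based ungapped position(s).
#' @export
column_to_ungapped <- function(aln, species, column) {
  map <- aln$maps[[aln_row(aln, species)]]
  hit <- match(column, map)
  if (anyNA(hit)) {
    stop_snotrace("column %d is a gap (or out of range) in row %s",
                  column[which(is.na(hit))[1L]], species)
  }
  hit - 1L
}

#' Nearest non-gap column projection for a species
#'
#' Projects an ungapped position of one species to a column, then finds the
#' closest non-gap position of another species' row to that column. Used when
#' comparing per-species site coordinates across rows with private indels.
#'
#' @param aln a [multiple_alignment()].
#' @param species row name.
#' @param column 0-based alignment column.
#' @return 0-based ungapped position in `species` nearest to `column`.
#' @export
nearest_ungapped <- function(aln, species, column) {
  map <- aln$maps[[aln_row(aln, species)]]
  which.min(abs(map - column)) - 1L
}

# degap a row back to its plain sequence
ungapped_row <- function(aln, species) {
  gsub("[-.]", "", aln$rows[[aln_row(aln, species)]])
}
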