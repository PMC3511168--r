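# C/D snoRNA guide -> rRNA target mapping.
#
# The search is a deterministic, ungapped seed-and-extend: exact word seeds
# (W = 5) between the reverse complement of the snoRNA and the rRNA are
# extended in both directions under an X-dropoff, trimmed to the maximal
# scoring extent, and filtered on length and identity. Gaps are disallowed
# outright (the classic G = 50 / E = 50 setting forbids them at guide scale),
# so length/identity thresholds replace E-value statistics.

#' Guide search parameters
#'
#' Defaults are chosen so that a canonical 10-21 nt C/D guide with at most
#' one mismatch passes while isolated random word seeds do not.
#'
#' @param word_size exact seed length W (>= 4).
#' @param match,mismatch ungapped scoring (+1 / -2).
#' @param min_len minimum reported hit length (>= word_size).
#' @param min_identity minimum fraction of matching bases.
#' @param dropoff X-dropoff: extension stops once the running score falls this
#'   far below its maximum.
#' @return a `guide_search_params` list.
#' @export
guide_search_params <- function(word_size = 5L, match = 1L, mismatch = -2L,
                                min_len = 10L, min_identity = 0.9,
                                dropoff = 4L) {
  if (word_size < 4L) stop_snotrace("word_size must be >= 4")
  if (min_len < word_size) stop_snotrace("min_len must be >= word_size")
  structure(list(word_size = as.integer(word_size), match = as.integer(match),
                 mismatch = as.integer(mismatch), min_len = as.integer(min_len),
                 min_identity = min_identity, dropoff = as.integer(dropoff)),
            class = "guide_search_params")
}

#' Locus binning tolerances
#' @param site_tol alignment-column tolerance for modification-site loci
#'   (+/- 2 nucleotides).
#' @param intron_tol alignment-column tolerance for intron loci (+/- 5 amino
#'   acids).
#' @return a `locus_binning_params` list.
#' @export
locus_binning_params <- function(site_tol = 2L, intron_tol = 5L) {
  if (site_tol < 0L || intron_tol < 0L) stop_snotrace("tolerances must be >= 0")
  list(site_tol = as.integer(site_tol), intron_tol = as.integer(intron_tol))
}

# X-dropoff extension span around a seed run [a, b) (0-based half-open in
# the diagonal's comparison vector m): extend while the running score stays
# within `dropoff` of its maximum; the span bounds the windows considered.
extend_span <- function(m, a, b, params) {
  sc_m <- params$match; sc_x <- params$mismatch; drop <- params$dropoff
  best <- 0L; run <- 0L
  j <- b
  while (j < length(m)) {
    run <- run + (if (m[j + 1L]) sc_m else sc_x)
    if (run > best) best <- run
    if (run <= best - drop) break
    j <- j + 1L
  }
  right <- j
  best <- 0L; run <- 0L
  i <- a
  while (i > 0L) {
    run <- run + (if (m[i]) sc_m else sc_x)
    if (run > best) best <- run
    if (run <= best - drop) break
    i <- i - 1L
  }
  c(i, right)
}

# all qualifying windows within a span of a diagonal's match vector:
# length >= min_len, identity >= min_identity, containing an exact word run.
span_windows <- function(m, sa, sb, params) {
  W <- params$word_size
  L <- sb - sa
  if (L < params$min_len) return(NULL)
  mm <- m[(sa + 1L):sb]
  cs <- c(0L, cumsum(mm))
  # seedable[i]: positions i-W+1 .. i (1-based, span-local) all match
  rl <- integer(L)
  r <- 0L
  for (i in seq_len(L)) { r <- if (mm[i]) r + 1L else 0L; rl[i] <- r }
  seedable <- c(0L, cumsum(rl >= W))
  out <- NULL
  for (len in params$min_len:L) {
    starts <- seq_len(L - len + 1L)               # span-local, 1-based
    matches <- cs[starts + len] - cs[starts]
    ident <- matches / len
    seeded <- (seedable[starts + len] - seedable[starts + W - 1L]) > 0L
    ok <- which(ident >= params$min_identity & seeded)
    if (length(ok)) {
      out <- rbind(out, data.frame(
        a = sa + ok - 1L, b = sa + ok - 1L + len,
        matches = matches[ok], stringsAsFactors = FALSE))
    }
  }
  out
}

# greedy dedup: keep the best hit of every overlapping set on the rRNA
# interval. Deterministic order: score desc, length asc (trim to the
# tightest extent), start asc, sno_start asc.
dedup_hits <- function(h) {
  if (!nrow(h)) return(h)
  h <- h[order(-h$score, h$end - h$start, h$start, h$sno_start), , drop = FALSE]
  keep <- logical(nrow(h))
  for (i in seq_len(nrow(h))) {
    ov <- keep & h$start < h$end[i] & h$end > h$start[i]
    if (!any(ov)) keep[i] <- TRUE
  }
  h <- h[keep, , drop = FALSE]
  h <- h[order(h$start, h$end), , drop = FALSE]
  rownames(h) <- NULL
  h
}

# core ungapped antisense search of one snoRNA sequence against one rRNA.
antisense_hits <- function(sno_seq, rrna_seq, params = guide_search_params()) {
  W <- params$word_size
  qc <- revcomp(sno_seq)
  nq <- nchar(qc); nr <- nchar(rrna_seq)
  if (nq < W || nr < W) return(empty_hit_frame())
  qch <- seq_chars(qc); rch <- seq_chars(rrna_seq)
  qw <- substring(qc, seq_len(nq - W + 1L), seq_len(nq - W + 1L) + W - 1L)
  rw <- substring(rrna_seq, seq_len(nr - W + 1L), seq_len(nr - W + 1L) + W - 1L)
  rindex <- split(seq_along(rw) - 1L, rw)
  diags <- integer(0)
  for (j0 in seq_along(qw)) {
    is <- rindex[[qw[j0]]]
    if (!is.null(is)) diags <- c(diags, is - (j0 - 1L))
  }
  diags <- sort(unique(diags))
  out <- list()
  for (d in diags) {
    lo <- max(0L, -d); hi <- min(nq, nr - d)
    if (hi - lo < W) next
    jj <- lo:(hi - 1L)
    m <- qch[jj + 1L] == rch[jj + d + 1L]
    r <- rle(m)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    runs <- which(r$values & r$lengths >= W)
    if (!length(runs)) next
    # X-dropoff spans around each seed run, merged when overlapping
    spans <- t(vapply(runs, function(k) {
      extend_span(m, starts[k] - 1L, ends[k], params)
    }, integer(2)))
    spans <- spans[order(spans[, 1L]), , drop = FALSE]
    merged <- spans[1L, , drop = FALSE]
    for (k in seq_len(nrow(spans))[-1L]) {
      last <- nrow(merged)
      if (spans[k, 1L] <= merged[last, 2L]) {
        merged[last, 2L] <- max(merged[last, 2L], spans[k, 2L])
      } else merged <- rbind(merged, spans[k, , drop = FALSE])
    }
    for (k in seq_len(nrow(merged))) {
      win <- span_windows(m, merged[k, 1L], merged[k, 2L], params)
      if (is.null(win)) next
      ja <- lo + win$a; jb <- lo + win$b   # window in qc coordinates
      out[[length(out) + 1L]] <- data.frame(
        start = ja + d, end = jb + d,
        sno_start = nq - jb, sno_end = nq - ja,
        length = win$b - win$a, matches = win$matches,
        score = win$matches * params$match +
          (win$b - win$a - win$matches) * params$mismatch,
        identity = win$matches / (win$b - win$a), stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) return(empty_hit_frame())
  h <- unique(do.call(rbind, out))
  h$center <- (h$start + h$end - 1L) %/% 2L
  dedup_hits(h)
}

empty_hit_frame <- function() {
  data.frame(start = integer(0), end = integer(0), sno_start = integer(0),
             sno_end = integer(0), length = integer(0), matches = integer(0),
             score = integer(0), identity = numeric(0), center = integer(0))
}

#' Search a C/D snoRNA's guide complementarity against an rRNA
#'
#' @param snorna a list/row with `snorna_id`, `family_id`, `species_id`,
#'   `class` (`"CD"`; H/ACA records are rejected, their bipartite guides are
#'   out of scope) and `sequence`.
#' @param rrna ungapped rRNA sequence (character scalar).
#' @param subunit `"SSU"` or `"LSU"`.
#' @param params a [guide_search_params()].
#' @return data.frame of guide hits; `start`/`end`/`center` are 0-based on
#'   the ungapped rRNA, `center_column` is `NA` until [project_hits()].
#' @export
search_guides <- function(snorna, rrna, subunit, params = guide_search_params()) {
  if (!identical(snorna$class, "CD")) {
    stop_snotrace("guide search is defined for C/D snoRNAs only (got %s)",
                  snorna$class %||% "NA")
  }
  h <- antisense_hits(snorna$sequence, rrna, params)
  if (!nrow(h)) {
    h <- cbind(empty_hit_frame(),
               data.frame(snorna_id = character(0), family_id = character(0),
                          species_id = character(0), subunit = character(0),
                          center_column = integer(0)))
    return(h)
  }
  h$snorna_id <- snorna$snorna_id
  h$family_id <- snorna$family_id
  h$species_id <- snorna$species_id
  h$subunit <- subunit
  h$center_column <- NA_integer_
  h
}

#' Project guide hits into rRNA alignment columns
#'
#' Fills `center_column` via [ungapped_to_column()] on the species' row of
#' the matching subunit alignment, making per-species rRNA coordinates
#' comparable across the tree.
#'
#' @param hits data.frame from [search_guides()] (possibly rbind-ed).
#' @param alignments named list: `SSU` and/or `LSU` [multiple_alignment()]s.
#' @return `hits` with `center_column` filled.
#' @export
project_hits <- function(hits, alignments) {
  if (!nrow(hits)) return(hits)
  for (i in seq_len(nrow(hits))) {
    aln <- alignments[[hits$subunit[i]]]
    if (is.null(aln)) stop_snotrace("no alignment for subunit %s", hits$subunit[i])
    hits$center_column[i] <- ungapped_to_column(aln, hits$species_id[i],
                                                hits$center[i])
  }
  hits
}

# single-linkage 1-D clustering of integer positions: returns cluster id per
# input value; clusters split where consecutive sorted values differ by more
# than `tol`.
chain_clusters <- function(values, tol) {
  o <- order(values)
  v <- values[o]
  brk <- c(0L, cumsum(diff(v) > tol))
  cl <- integer(length(values))
  cl[o] <- brk + 1L
  cl
}

#' Bin projected guide hits into cross-species site loci
#'
#' Single-linkage clustering on `center_column` with link distance
#' `tol` (+/- 2 columns by default); loci supported by fewer than two
#' distinct species are discarded. Output is independent of input order.
#'
#' @param hits projected hits (one subunit per locus is enforced by
#'   clustering within subunit).
#' @param params a [locus_binning_params()].
#' @return a `site_loci` object: `$loci` (locus_id, subunit, column = rounded
#'   median member column, n_species, families) and `$members` (hits plus
#'   locus_id).
#' @export
bin_sites <- function(hits, params = locus_binning_params()) {
  if (nrow(hits) && anyNA(hits$center_column)) {
    stop_snotrace("bin_sites needs projected hits (center_column filled)")
  }
  members <- NULL
  loci <- NULL
  for (su in sort(unique(hits$subunit))) {
    h <- hits[hits$subunit == su, , drop = FALSE]
    cl <- chain_clusters(h$center_column, params$site_tol)
    for (c0 in sort(unique(cl))) {
      hh <- h[cl == c0, , drop = FALSE]
      if (length(unique(hh$species_id)) < 2L) next
      col <- as.integer(round(stats::median(hh$center_column)))
      lid <- sprintf("%s_c%04d", su, col)
      hh$locus_id <- lid
      members <- rbind(members, hh)
      loci <- rbind(loci, data.frame(
        locus_id = lid, subunit = su, column = col,
        n_species = length(unique(hh$species_id)),
        families = paste(sort(unique(hh$family_id)), collapse = ","),
        stringsAsFactors = FALSE))
    }
  }
  if (is.null(loci)) {
    loci <- data.frame(locus_id = character(0), subunit = character(0),
                       column = integer(0), n_species = integer(0),
                       families = character(0))
  } else {
    o <- order(loci$subunit, loci$column)
    loci <- loci[o, , drop = FALSE]
    rownames(loci) <- NULL
    members <- members[order(members$subunit, members$center_column,
                             members$species_id, members$snorna_id), , drop = FALSE]
    rownames(members) <- NULL
  }
  structure(list(loci = loci, members = members %||% cbind(
    empty_hit_frame(), data.frame(snorna_id = character(0),
                                  family_id = character(0),
                                  species_id = character(0),
                                  subunit = character(0),
                                  center_column = integer(0),
                                  locus_id = character(0)))),
    class = "site_loci")
}

#' @export
print.site_loci <- function(x, ...) {
  cat(sprintf("<site_loci> %d loci (%d SSU, %d LSU) from %d member hits\n",
              nrow(x$loci), sum(x$loci$subunit == "SSU"),
              sum(x$loci$subunit == "LSU"), nrow(x$members)))
  invisible(x)
}

#' Site loci whose phylogenetic distribution is compatible with LECA
#'
#' Builds a locus x species presence matrix and runs the Dollo engine; a
#' locus is returned iff its reconstructed state at the root (LECA) is 1,
#' i.e. carriers occur in both root subtrees.
#'
#' @param sites a `site_loci` object from [bin_sites()].
#' @param phy a [phylogeny].
#' @return character vector of LECA locus ids.
#' @export
infer_leca_sites <- function(sites, phy) {
  if (!nrow(sites$loci)) return(character(0))
  mat <- locus_presence_matrix(sites$members$locus_id, sites$members$species_id,
                               phy, kind = "site_locus")
  recon <- dollo_reconstruct(phy, mat)
  sort(characters_at_node(recon))
}

# locus x species presence matrix from membership pairs
locus_presence_matrix <- function(locus_id, species_id, phy, kind) {
  leaf_ids(phy, unique(species_id))  # errors on unknown taxa
  loci <- sort(unique(locus_id))
  sp <- phy$tree$tip.label
  m <- matrix(0L, length(loci), length(sp), dimnames = list(loci, sp))
  m[cbind(match(locus_id, loci), match(species_id, sp))] <- 1L
  presence_matrix(m, kind)
}

#' Compare binned site loci against a known-site table
#'
#' A known site is recovered for a species iff some locus contains a hit from
#' that species whose `center_column` lies within `tol` columns of the known
#' position projected through the alignment. Sites are grouped by
#' (subunit, family); a site counts as fully recovered when every species
#' row reporting it is recovered.
#'
#' @param sites a `site_loci` object.
#' @param known data.frame from [read_known_sites()] (0-based positions).
#' @param alignments named list of rRNA alignments (`SSU`, `LSU`).
#' @param tol column tolerance (defaults to the site binning tolerance, 2).
#' @return list with `$rows` (per species-record flags), `$sites` (per-site
#'   verdicts) and `$totals` (n_sites, n_recovered).
#' @export
compare_to_known <- function(sites, known, alignments, tol = 2L) {
  known$known_column <- NA_integer_
  known$recovered <- FALSE
  mem <- sites$members
  for (i in seq_len(nrow(known))) {
    aln <- alignments[[known$subunit[i]]]
    if (is.null(aln)) stop_snotrace("no alignment for subunit %s", known$subunit[i])
    col <- ungapped_to_column(aln, known$species[i], known$site_position[i])
    known$known_column[i] <- col
    hit <- mem$species_id == known$species[i] &
      mem$subunit == known$subunit[i] &
      abs(mem$center_column - col) <= tol
    known$recovered[i] <- any(hit)
  }
  key <- paste(known$subunit, known$family_id, sep = ":")
  per_site <- vapply(split(known$recovered, key), all, logical(1))
  sites_df <- data.frame(site = names(per_site), recovered = unname(per_site),
                         stringsAsFactors = FALSE)
  sites_df <- sites_df[order(sites_df$site), , drop = FALSE]
  rownames(sites_df) <- NULL
  list(rows = known, sites = sites_df,
       totals = c(n_sites = nrow(sites_df),
                  n_recovered = sum(sites_df$recovered)))
}
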