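# Independent oracles used across the suite. These re-derive expected
# results by direct enumeration, deliberately avoiding the package's
# algorithmic code paths.

# reverse complement, written from scratch
rc_oracle <- function(x) {
  paste(rev(strsplit(chartr("ACGT", "TGCA", x), "")[[1L]]), collapse = "")
}

# exhaustive Hamming scan of query against genome, both strands
hamming_scan_oracle <- function(query, genome, max_subst) {
  q <- strsplit(query, "")[[1L]]
  g <- strsplit(genome, "")[[1L]]
  n <- length(g) - length(q) + 1L
  res <- NULL
  for (strand in c("+", "-")) {
    qq <- if (strand == "+") q else strsplit(rc_oracle(query), "")[[1L]]
    for (i in seq_len(n)) {
      d <- sum(qq != g[i:(i + length(q) - 1L)])
      if (d <= max_subst) {
        res <- rbind(res, data.frame(position = i - 1L, strand = strand,
                                     substitutions = d))
      }
    }
  }
  if (is.null(res)) {
    return(data.frame(position = integer(0), strand = character(0),
                      substitutions = integer(0)))
  }
  res <- res[order(res$position, res$strand), , drop = FALSE]
  rownames(res) <- NULL
  res
}

# transitive closure of the |x - y| <= tol relation, by fixed-point expansion
components_oracle <- function(values, tol) {
  n <- length(values)
  comp <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (abs(values[i] - values[j]) <= tol && comp[j] != comp[i]) {
          new <- min(comp[i], comp[j])
          comp[comp == comp[i] | comp == comp[j]] <- new
          changed <- TRUE
        }
      }
    }
    if (!changed) break
  }
  match(comp, unique(comp))
}

# full window-enumeration oracle for the antisense guide search: every
# ungapped window (any diagonal) of length >= min_len at identity >=
# min_identity containing word_size consecutive matches, then the same
# greedy overlap dedup (best score; ties: shortest, leftmost).
guide_oracle <- function(sno, rrna, params = guide_search_params()) {
  W <- params$word_size
  qc <- strsplit(rc_oracle(sno), "")[[1L]]
  r <- strsplit(rrna, "")[[1L]]
  nq <- length(qc); nr <- length(r)
  cand <- NULL
  for (d in (-nq + params$min_len):(nr - params$min_len)) {
    lo <- max(0L, -d); hi <- min(nq, nr - d)
    L <- hi - lo
    if (L < params$min_len) next
    jj <- lo:(hi - 1L)
    m <- qc[jj + 1L] == r[jj + d + 1L]
    rr <- rle(m)
    if (!any(rr$values & rr$lengths >= W)) next
    rl <- sequence(rr$lengths)
    rl[!rep(rr$values, rr$lengths)] <- 0L
    cs <- c(0L, cumsum(m))
    sd <- c(0L, cumsum(rl >= W))
    for (len in params$min_len:L) {
      starts <- seq_len(L - len + 1L)
      matches <- cs[starts + len] - cs[starts]
      seeded <- (sd[starts + len] - sd[starts + W - 1L]) > 0L
      ok <- which(matches / len >= params$min_identity & seeded)
      for (s in ok) {
        a <- lo + s - 1L
        cand <- rbind(cand, data.frame(
          start = a + d, end = a + d + len, sno_start = nq - (a + len),
          sno_end = nq - a, length = len, matches = matches[s],
          score = matches[s] * params$match +
            (len - matches[s]) * params$mismatch,
          identity = matches[s] / len))
      }
    }
  }
  if (is.null(cand)) return(cand)
  cand <- cand[order(-cand$score, cand$length, cand$start, cand$sno_start), ,
               drop = FALSE]
  keep <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    ov <- keep & cand$start < cand$end[i] & cand$end > cand$start[i]
    if (!any(ov)) keep[i] <- TRUE
  }
  cand <- cand[keep, , drop = FALSE]
  cand <- cand[order(cand$start, cand$end), , drop = FALSE]
  rownames(cand) <- NULL
  cand
}

# exhaustive rank-sum enumeration over all choose(n1+n2, n1) group labellings
ranksum_enum_oracle <- function(a, b, sided = "two.sided") {
  n1 <- length(a); n2 <- length(b)
  r <- rank(c(a, b))
  w_obs <- sum(r[seq_len(n1)])
  combs <- utils::combn(n1 + n2, n1)
  ws <- apply(combs, 2L, function(ix) sum(r[ix]))
  eps <- 1e-9
  p_ge <- mean(ws >= w_obs - eps)
  p_le <- mean(ws <= w_obs + eps)
  switch(sided,
         greater = p_ge, less = p_le,
         two.sided = min(1, 2 * min(p_ge, p_le)))
}

# cached small synthetic bundle shared by intron/pipeline tests
.fixture_env <- new.env(parent = emptyenv())

small_sim_params <- function(...) {
  sim_params(taxa_per_supergroup = 3L, n_anc_families = 10L,
             n_new_families = 2L, n_host_genes = 6L, n_sites = 6L,
             n_decoys = 4L, n_mobility = 2L, n_expr_nonhost = 30L,
             n_derived_introns = 4L, ...)
}

get_small_bundle <- function() {
  if (is.null(.fixture_env$bundle)) {
    dir <- file.path(tempdir(), "snotrace_fixture")
    .fixture_env$bundle <- simulate_bundle(dir, small_sim_params(), seed = 20260920L)
  }
  .fixture_env$bundle
}

get_small_report <- function() {
  if (is.null(.fixture_env$report)) {
    b <- get_small_bundle()
    out <- file.path(tempdir(), "snotrace_fixture_out")
    .fixture_env$report <- run_pipeline(pipeline_config(b$dir, out, seed = 20260920L))
  }
  .fixture_env$report
}

# 6-species fixture with 30 planted guides and 30 decoys (guide-mapper scale)
get_guide_bundle <- function() {
  if (is.null(.fixture_env$guide_bundle)) {
    p <- sim_params(taxa_per_supergroup = 3L, n_anc_families = 40L,
                    n_new_families = 3L, n_sites = 30L, n_decoys = 30L,
                    n_mobility = 2L, n_independent_pairs = 1L,
                    n_expr_nonhost = 30L)
    dir <- file.path(tempdir(), "snotrace_guide_fixture")
    .fixture_env$guide_bundle <- simulate_bundle(dir, p, seed = 31L)
  }
  .fixture_env$guide_bundle
}

# reference study conditions: 12 taxa, 50 ancestral families, q = 0.15,
# 5 mobility events (the sim_params defaults)
get_full_bundle <- function() {
  if (is.null(.fixture_env$full_bundle)) {
    dir <- file.path(tempdir(), "snotrace_full_fixture")
    .fixture_env$full_bundle <- simulate_bundle(dir, sim_params(), seed = 12L)
  }
  .fixture_env$full_bundle
}

get_full_report <- function() {
  if (is.null(.fixture_env$full_report)) {
    b <- get_full_bundle()
    out <- file.path(tempdir(), "snotrace_full_out")
    .fixture_env$full_report <- run_pipeline(pipeline_config(b$dir, out, seed = 12L))
  }
  .fixture_env$full_report
}
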