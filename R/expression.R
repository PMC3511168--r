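# Expression breadth (Shannon entropy over tissue proportions, in nats) and
# the host-vs-non-host rank-sum comparison.

#' Shannon entropy of a tissue expression profile
#'
#' S = -sum(P_i * ln(P_i)) with P_i = E_i / T and the limit convention
#' 0 * ln(0) = 0; reported in nats, so S is bounded by ln(number of tissues).
#'
#' @param signals nonnegative per-tissue signal vector with positive total.
#' @return entropy S in nats.
#' @export
expression_entropy <- function(signals) {
  if (any(signals < 0)) stop_snotrace("negative expression signal")
  total <- sum(signals)
  if (total == 0) stop_snotrace("all-zero profile: entropy undefined")
  p <- signals[signals > 0] / total
  -sum(p * log(p))
}

#' Median array signal with duplicate-tissue collapsing
#'
#' Tissues in the same duplicate group (e.g. brain subsamples) are averaged
#' before taking the median over groups.
#'
#' @param signals named or unnamed per-tissue signal vector.
#' @param duplicate_map character vector (same length/order as `signals`)
#'   assigning each tissue to a group; identity (all distinct) by default.
#' @return median over collapsed groups.
#' @export
median_signal <- function(signals, duplicate_map = NULL) {
  if (!length(signals)) stop_snotrace("empty profile")
  if (is.null(duplicate_map)) duplicate_map <- as.character(seq_along(signals))
  if (length(duplicate_map) != length(signals)) {
    stop_snotrace("duplicate_map must cover all tissues")
  }
  stats::median(vapply(split(signals, duplicate_map), mean, numeric(1)))
}

# exact permutation distribution of the rank-sum via a subset-sum DP over
# doubled midranks: counts[k+1, s+1] = number of k-subsets with doubled-rank
# sum s. Identical to exhaustive enumeration, feasible for moderate n.
ranksum_exact_p <- function(r2, n1, w2_obs) {
  n <- length(r2)
  maxs <- sum(sort(r2, decreasing = TRUE)[seq_len(n1)])
  counts <- matrix(0, n1 + 1L, maxs + 1L)
  counts[1L, 1L] <- 1
  for (v in r2) {
    kmax <- n1
    for (k in kmax:1L) {
      nz <- which(counts[k, ] > 0)
      if (length(nz)) {
        tgt <- nz - 1L + v
        ok <- tgt <= maxs
        counts[k + 1L, tgt[ok] + 1L] <- counts[k + 1L, tgt[ok] + 1L] + counts[k, nz[ok]]
      }
    }
  }
  dist <- counts[n1 + 1L, ]
  total <- sum(dist)
  sums <- seq_along(dist) - 1L
  list(p_ge = sum(dist[sums >= w2_obs]) / total,
       p_le = sum(dist[sums <= w2_obs]) / total)
}

#' Mann-Whitney / Wilcoxon rank-sum test
#'
#' U is computed with midranks. The p-value comes from the exact permutation
#' distribution (computed by a tie-aware subset-sum recursion, equivalent to
#' exhaustive enumeration of all group assignments) when `n1 * n2 <= 400`,
#' and otherwise from the normal approximation with tie-corrected variance
#' and continuity correction.
#'
#' @param a,b numeric vectors (both nonempty).
#' @param sided `"greater"` (a tends larger), `"less"`, or `"two.sided"`.
#' @return a `rank_sum_result`: `U` (for group `a`), `z` (NA for exact),
#'   `p_value`, `n1`, `n2`, `method`, `sided`.
#' @export
rank_sum_test <- function(a, b, sided = c("two.sided", "greater", "less")) {
  sided <- match.arg(sided)
  n1 <- length(a); n2 <- length(b)
  if (n1 == 0L || n2 == 0L) stop_snotrace("both groups must be nonempty")
  n <- n1 + n2
  r <- rank(c(a, b))            # midranks
  w1 <- sum(r[seq_len(n1)])
  U <- w1 - n1 * (n1 + 1) / 2   # U statistic for group a
  if (n1 * n2 <= 400L) {
    ex <- ranksum_exact_p(as.integer(round(2 * r)), n1, as.integer(round(2 * w1)))
    p <- switch(sided,
                greater = ex$p_ge,
                less = ex$p_le,
                two.sided = min(1, 2 * min(ex$p_ge, ex$p_le)))
    res <- list(U = U, z = NA_real_, p_value = p, n1 = n1, n2 = n2,
                method = "exact", sided = sided)
  } else {
    mu <- n1 * n2 / 2
    ties <- table(r)
    tie_term <- sum(ties^3 - ties) / (n * (n - 1))
    sigma2 <- n1 * n2 / 12 * ((n + 1) - tie_term)
    sigma <- sqrt(sigma2)
    cc <- 0.5
    z_g <- (U - mu - cc) / sigma
    z_l <- (U - mu + cc) / sigma
    p <- switch(sided,
                greater = stats::pnorm(z_g, lower.tail = FALSE),
                less = stats::pnorm(z_l),
                two.sided = min(1, 2 * min(stats::pnorm(z_g, lower.tail = FALSE),
                                           stats::pnorm(z_l))))
    res <- list(U = U, z = if (sided == "less") z_l else z_g, p_value = p,
                n1 = n1, n2 = n2, method = "normal_approx", sided = sided)
  }
  structure(res, class = "rank_sum_result")
}

#' @export
print.rank_sum_result <- function(x, ...) {
  cat(sprintf("Rank-sum test (%s, %s): U = %.1f, n = %d + %d, p = %.4g\n",
              x$method, x$sided, x$U, x$n1, x$n2, x$p_value))
  invisible(x)
}

#' Compare expression breadth of host vs non-host genes
#'
#' Computes per-gene expression entropies and tests (one-sided by default,
#' host > non-host, matching the directional claim that snoRNA host genes
#' are more broadly expressed).
#'
#' @param mat gene x tissue expression matrix.
#' @param host_genes character vector of host gene ids (subset of rownames).
#' @param sided test sidedness (default `"greater"`).
#' @return list with the `rank_sum_result` (`$test`), per-group entropy
#'   vectors and group medians.
#' @export
compare_host_vs_nonhost <- function(mat, host_genes, sided = "greater") {
  if (!length(host_genes)) stop_snotrace("empty host gene set")
  unknown <- setdiff(host_genes, rownames(mat))
  if (length(unknown)) {
    stop_snotrace("host genes missing from matrix: %s",
                  paste(utils::head(unknown, 5L), collapse = ", "))
  }
  S <- apply(mat, 1L, expression_entropy)
  host <- S[rownames(mat) %in% host_genes]
  nonhost <- S[!rownames(mat) %in% host_genes]
  if (!length(nonhost)) stop_snotrace("no non-host genes in matrix")
  list(test = rank_sum_test(host, nonhost, sided = sided),
       host_entropy = host, nonhost_entropy = nonhost,
       medians = c(host = stats::median(host),
                   nonhost = stats::median(nonhost)))
}
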