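test_that("entropy closed forms: uniform, degenerate, direct evaluation", {
  expect_equal(expression_entropy(rep(2, 3)), log(3), tolerance = 1e-12)
  expect_equal(expression_entropy(c(0, 7, 0)), 0)
  # (2,1,1): -(1/2 ln 1/2 + 2 * 1/4 ln 1/4)
  expect_equal(expression_entropy(c(2, 1, 1)),
               -(0.5 * log(0.5) + 0.5 * log(0.25)), tolerance = 1e-12)
  expect_error(expression_entropy(c(0, 0)), "all-zero")
  expect_error(expression_entropy(c(-1, 2)), "negative")
})

test_that("entropy is bounded by ln k and invariant to scale", {
  set.seed(2)
  for (rep_ in 1:20) {
    k <- sample(2:40, 1)
    e <- stats::rexp(k)
    s <- expression_entropy(e)
    expect_gte(s, 0)
    expect_lte(s, log(k) + 1e-12)
    for (cc in c(0.1, 1, 10)) {
      expect_equal(expression_entropy(cc * e), s, tolerance = 1e-9)
    }
  }
})

test_that("median signal collapses duplicate tissue groups by mean", {
  expect_equal(median_signal(c(1, 2, 3)), 2)
  # two brain subsamples (4,6) -> 5; groups (5, 1, 9) -> median 5
  expect_equal(median_signal(c(4, 6, 1, 9), c("br", "br", "liv", "hrt")), 5)
  x <- c(3, 1, 4)
  expect_equal(median_signal(x, as.character(seq_along(x))), median(x))
  expect_error(median_signal(numeric(0)), "empty")
  expect_error(median_signal(c(1, 2), "a"), "cover")
})

test_that("rank-sum identities: symmetric data and tiny worked example", {
  r <- rank_sum_test(c(1, 2, 3), c(1, 2, 3), sided = "two.sided")
  expect_equal(r$U, 4.5)                    # n1 n2 / 2
  expect_equal(r$p_value, 1)
  r2 <- rank_sum_test(c(1, 2), c(3, 4), sided = "less")
  expect_equal(r2$U, 0)
  expect_equal(r2$p_value, 1 / 6)           # 1 of 6 arrangements as extreme
  expect_error(rank_sum_test(numeric(0), 1:3), "nonempty")
})

test_that("exact p equals exhaustive enumeration for all n1, n2 <= 6", {
  set.seed(8)
  for (n1 in 2:6) {
    for (n2 in 2:6) {
      a <- sample(1:8, n1, replace = TRUE)   # ties likely
      b <- sample(1:8, n2, replace = TRUE)
      for (sided in c("greater", "less", "two.sided")) {
        expect_equal(rank_sum_test(a, b, sided)$p_value,
                     ranksum_enum_oracle(a, b, sided), tolerance = 1e-12,
                     info = sprintf("n1=%d n2=%d %s", n1, n2, sided))
      }
    }
  }
})

test_that("exact path agrees with wilcox.test on untied data", {
  set.seed(9)
  for (rep_ in 1:10) {
    a <- stats::rnorm(7)
    b <- stats::rnorm(9)
    w <- stats::wilcox.test(a, b, exact = TRUE, alternative = "greater")
    expect_equal(rank_sum_test(a, b, "greater")$p_value, w$p.value,
                 tolerance = 1e-12)
  }
})

test_that("normal approximation tracks the exact p for moderate samples", {
  set.seed(10)
  a <- stats::rnorm(15); b <- stats::rnorm(15, 0.3)
  exact <- rank_sum_test(a, b, "greater")
  expect_equal(exact$method, "exact")       # 225 <= 400
  # recompute the tie-corrected normal approximation by hand
  n <- 30; r <- rank(c(a, b)); U <- sum(r[1:15]) - 15 * 16 / 2
  ties <- table(r)
  s2 <- 15 * 15 / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
  papprox <- stats::pnorm((U - 112.5 - 0.5) / sqrt(s2), lower.tail = FALSE)
  expect_lt(abs(papprox - exact$p_value), 0.01)
  # large samples switch to the approximation
  big <- rank_sum_test(stats::rnorm(25), stats::rnorm(25), "two.sided")
  expect_equal(big$method, "normal_approx")
  expect_true(big$p_value > 0 && big$p_value <= 1)
})

test_that("host vs non-host comparison detects and bounds separation", {
  k <- 5
  mat <- rbind(matrix(rep(1, 10 * k), 10, k),                 # uniform hosts
               t(vapply(1:40, function(i) {
                 v <- rep(0, k); v[(i %% k) + 1] <- 1; v
               }, numeric(k))))                                # single-tissue
  rownames(mat) <- c(sprintf("h%02d", 1:10), sprintf("n%02d", 1:40))
  colnames(mat) <- paste0("t", 1:k)
  res <- compare_host_vs_nonhost(mat, sprintf("h%02d", 1:10))
  expect_equal(unname(res$medians), c(log(k), 0))
  expect_lt(res$test$p_value, 1e-3)
  # identical profiles: one-sided p = 1 under enumeration
  same <- matrix(rep(c(1, 2, 3), each = 20), 20, 3,
                 dimnames = list(sprintf("g%02d", 1:20), paste0("t", 1:3)))
  res2 <- compare_host_vs_nonhost(same, sprintf("g%02d", 1:5))
  expect_equal(res2$test$p_value, 1)
  expect_error(compare_host_vs_nonhost(mat, character(0)), "empty")
  expect_error(compare_host_vs_nonhost(mat, "nope"), "missing")
})

test_that("a planted 0.5-nat entropy gap at 200+200 genes rejects at 0.005", {
  set.seed(424242)
  sim <- simulate_expression(sprintf("h%03d", 1:200), sprintf("n%03d", 1:200),
                             sim_params(entropy_gap = 0.5))
  res <- compare_host_vs_nonhost(sim$mat, sim$host_ids)
  expect_lt(res$test$p_value, 0.005)
  # and the realised mean gap is near the 0.5-nat design value
  gap <- mean(res$host_entropy) - mean(res$nonhost_entropy)
  expect_gt(gap, 0.3)
  expect_lt(gap, 0.7)
})

test_that("with no planted gap the one-sided test is not systematically significant", {
  set.seed(5151)
  rejections <- 0L
  for (rep_ in 1:20) {
    sim <- simulate_expression(sprintf("h%02d", 1:30), sprintf("n%02d", 1:30),
                               sim_params(entropy_gap = 0))
    p <- compare_host_vs_nonhost(sim$mat, sim$host_ids)$test$p_value
    rejections <- rejections + (p < 0.05)
  }
  expect_lte(rejections, 4L)   # ~binomial(20, 0.05) upper tail
})
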