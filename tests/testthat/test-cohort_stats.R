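test_that("rank-sum exact p matches enumeration on worked cases", {
  r <- rank_sum_test(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 0.1) # 2 of the 20 labelings are this extreme
  expect_equal(r$mode_used, "exact")

  same <- rank_sum_test(c(2, 5, 9), c(9, 2, 5), mode = "exact")
  expect_equal(same$p_value, 1)

  expect_error(rank_sum_test(numeric(0), 1:3), class = "empty_group")
})

test_that("exact rank-sum p equals brute-force permutation p, ties included", {
  set.seed(31)
  cases <- list(
    list(x = c(1.2, 3.4), y = c(0.5, 2.2, 7.7)),
    list(x = c(1, 1, 2), y = c(2, 3, 3)),
    list(x = c(5, 5, 5, 1), y = c(5, 2, 2)),
    list(x = rnorm(4), y = rnorm(4))
  )
  for (cs in cases) {
    got <- rank_sum_test(cs$x, cs$y, mode = "exact")$p_value
    expect_equal(got, brute_force_rank_sum_p(cs$x, cs$y))
  }
})

test_that("normal-approximation p agrees with the base-R rank-sum route", {
  set.seed(13)
  x <- rnorm(25)
  y <- rnorm(30, 0.4)
  ours <- rank_sum_test(x, y, mode = "normal_approx")
  ref <- suppressWarnings(stats::wilcox.test(x, y, exact = FALSE,
                                             correct = TRUE))
  expect_equal(ours$statistic, unname(ref$statistic))
  expect_equal(ours$p_value, unname(ref$p.value), tolerance = 1e-10)

  # with heavy ties the tie-corrected variance must match too
  xt <- c(1, 1, 2, 2, 2, 3, 4, 4, 4, 4)
  yt <- c(2, 2, 3, 3, 4, 4, 5, 5, 1, 3, 3)
  ours_t <- rank_sum_test(xt, yt, mode = "normal_approx")
  ref_t <- suppressWarnings(stats::wilcox.test(xt, yt, exact = FALSE,
                                               correct = TRUE))
  expect_equal(ours_t$p_value, unname(ref_t$p.value), tolerance = 1e-10)
})

test_that("Kruskal-Wallis reproduces the worked H and degenerate cases", {
  res <- kruskal_wallis(list(c(1, 2), c(3, 4), c(5, 6)))
  expect_equal(res$statistic, 32 / 7, tolerance = 1e-12)
  expect_equal(res$df, 2L)
  expect_equal(res$p_value, stats::pchisq(32 / 7, 2, lower.tail = FALSE))

  tied <- kruskal_wallis(list(c(3, 3), c(3, 3, 3)))
  expect_equal(tied$statistic, 0)
  expect_equal(tied$p_value, 1)

  expect_error(kruskal_wallis(list(1:3)), class = "validation_error")
  expect_error(kruskal_wallis(list(1:3, numeric(0))), class = "empty_group")
})

test_that("two-group Kruskal-Wallis tracks the rank-sum normal approximation", {
  set.seed(41)
  for (i in 1:5) {
    x <- rnorm(20)
    y <- rnorm(20, 0.5)
    p_kw <- kruskal_wallis(list(x, y))$p_value
    p_rs <- rank_sum_test(x, y, mode = "normal_approx")$p_value
    # same statistic family; they differ only in the continuity correction
    expect_lt(abs(p_kw - p_rs), 0.02)
  }
})

test_that("H is invariant under strictly monotone transforms", {
  set.seed(17)
  groups <- list(rnorm(8), rnorm(6, 1), rnorm(7, -0.5))
  h0 <- kruskal_wallis(groups)$statistic
  expect_equal(kruskal_wallis(lapply(groups, exp))$statistic, h0)
  expect_equal(kruskal_wallis(lapply(groups, function(g) 3 * g - 100))$statistic,
               h0)
})

test_that("BH adjustment matches hand-computed step-up values", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(rep(0.05, 4)), rep(0.05, 4))
  expect_equal(bh_fdr(0.2), 0.2)
  # order restored to input order
  p <- c(0.9, 0.001, 0.5, 0.03)
  adj <- bh_fdr(p)
  expect_equal(adj, c(0.9, 0.004, 0.6666667, 0.06), tolerance = 1e-6)
  expect_error(bh_fdr(c(0.5, 1.2)), class = "validation_error")
})

test_that("BH adjustment is monotone, capped, and matches the step-up oracle", {
  # oracle: adj(i) = min over j with p(j) >= p(i) of p(j) * m / rank(j)
  bh_oracle <- function(p) {
    m <- length(p)
    ord <- order(p)
    raw <- p[ord] * m / seq_len(m)
    adj <- rev(cummin(rev(raw)))
    pmin(1, adj)[order(ord)]
  }
  set.seed(29)
  for (i in 1:10) {
    p <- runif(sample(2:12, 1))
    adj <- bh_fdr(p)
    expect_equal(adj, bh_oracle(p), tolerance = 1e-12)
    expect_true(all(adj >= p - 1e-12))
    expect_true(all(adj <= 1))
    # monotone in the order statistics of the input
    expect_true(all(diff(adj[order(p)]) >= -1e-12))
  }
})

test_that("bin comparisons run the configured scheme with exclusions", {
  set.seed(23)
  tab <- data.frame(
    mapi = c(rnorm(10, -5), rnorm(10, -4.5), rnorm(10, -4), rnorm(3, 0)),
    phenotype = c(rep("healthy", 10), rep("mild", 10), rep("diseased", 10),
                  rep("unknown", 3))
  )
  om <- suppressMessages(compare_by_bins(tab, "phenotype", "omnibus"))
  expect_equal(om$method, "kruskal_wallis")
  expect_equal(om$df, 2L)
  expect_equal(om$n_a, 30) # unknowns excluded

  tab5 <- data.frame(
    mapi = rnorm(50),
    age_bin = rep(c("0-10", "11-20", "21-30", "31-40", "41-50"), each = 10)
  )
  pw <- compare_by_bins(tab5, "age_bin", "pairwise_fdr")
  expect_equal(nrow(pw), choose(5, 2))
  expect_true(all(!is.na(pw$p_adjusted)))
  expect_true(all(pw$p_adjusted >= pw$p_value - 1e-12))

  thin <- data.frame(mapi = c(1, 2, 3), phenotype = c("a", "a", "b"))
  expect_error(suppressMessages(compare_by_bins(thin, "phenotype")),
               class = "insufficient_bins")
})

test_that("group summaries report n, mean, SD, quartiles and exclusions", {
  tab <- data.frame(mapi = c(-5, -6, -4, NA), phenotype = c("h", "h", "m", "m"))
  gs <- group_summary(tab, "phenotype")
  h <- gs[gs$group == "h", ]
  expect_equal(h$mean, -5.5)
  expect_equal(h$sd, abs(-5 - -6) / sqrt(2))
  m <- gs[gs$group == "m", ]
  expect_equal(m$n, 1L)
  expect_true(is.na(m$sd))
  expect_equal(m$n_excluded, 1L)
  expect_error(group_summary(tab[0, ], "phenotype"), class = "empty_input")
})

test_that("ages map into demographic decade bins", {
  expect_equal(age_bin(c(0, 10, 11, 35, 60.5, 61, 80, 81, 99, NA)),
               c("0-10", "0-10", "11-20", "31-40", "61-70", "61-70",
                 "71-80", "81+", "81+", NA))
})
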