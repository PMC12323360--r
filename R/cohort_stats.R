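#' Two-group rank-sum test (Mann-Whitney U)
#'
#' Computes the Mann-Whitney U statistic with midranks for ties. In
#' \code{auto} mode the two-sided p-value is exact — full enumeration of
#' all group labelings — when the combined sample size is at most 12 and
#' there are no ties; otherwise the normal approximation with tie
#' correction and continuity correction is used. \code{exact} forces
#' enumeration (midranks make it valid under ties too); \code{normal_approx}
#' forces the approximation. The exact two-sided p-value is the probability,
#' over all equally likely labelings of the pooled data, of a U at least as
#' far from its null mean as the observed U.
#'
#' The unpaired rank-sum test is used for all two-group comparisons here,
#' including cross-sectional gender contrasts, where no pairing exists that
#' would support a signed-rank test.
#'
#' @param x,y Numeric vectors, both non-empty.
#' @param mode \code{"auto"}, \code{"exact"} or \code{"normal_approx"}.
#' @return A one-row \code{test_result} data frame: \code{method},
#'   \code{group_a}, \code{group_b}, \code{n_a}, \code{n_b},
#'   \code{statistic} (U of the first group), \code{p_value},
#'   \code{p_adjusted} (NA), \code{mode_used}.
#' @examples
#' rank_sum_test(c(1, 2, 3), c(4, 5, 6))$p_value # 0.1
#' @export
rank_sum_test <- function(x, y, mode = c("auto", "exact", "normal_approx")) {
  mode <- match.arg(mode)
  if (length(x) == 0L || length(y) == 0L) {
    gi_error("rank-sum test needs two non-empty groups", "empty_group")
  }
  stopifnot(is.numeric(x), is.numeric(y), !anyNA(x), !anyNA(y))
  n1 <- length(x)
  n2 <- length(y)
  pooled <- c(x, y)
  r <- rank(pooled) # midranks
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- anyDuplicated(pooled) > 0L
  use_exact <- switch(mode,
    exact = TRUE,
    normal_approx = FALSE,
    auto = (n1 + n2) <= 12L && !ties
  )
  if (use_exact) {
    p <- rank_sum_exact_p(r, n1)
    mode_used <- "exact"
  } else {
    p <- rank_sum_normal_p(r, n1, u)
    mode_used <- "normal_approx"
  }
  test_result("rank_sum", "x", "y", n1, n2, u, p, mode_used)
}

# Exact two-sided p by enumeration of all C(n, n1) labelings of the pooled
# midranks: p = P(|U - n1*n2/2| >= |u_obs - n1*n2/2|).
rank_sum_exact_p <- function(r, n1) {
  n <- length(r)
  n2 <- n - n1
  mu <- n1 * n2 / 2
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  dev <- abs(u_obs - mu)
  combos <- utils::combn(n, n1)
  us <- colSums(matrix(r[combos], nrow = n1)) - n1 * (n1 + 1) / 2
  mean(abs(us - mu) >= dev - 1e-12)
}

# Normal approximation with tie-corrected variance and continuity correction.
rank_sum_normal_p <- function(r, n1, u) {
  n <- length(r)
  n2 <- n - n1
  mu <- n1 * n2 / 2
  tie_counts <- table(r)
  tie_term <- sum(tie_counts^3 - tie_counts)
  sigma2 <- n1 * n2 / 12 * ((n + 1) - tie_term / (n * (n - 1)))
  if (sigma2 <= 0) return(1) # all observations tied
  z <- (abs(u - mu) - 0.5) / sqrt(sigma2)
  z <- max(z, 0)
  min(1, 2 * stats::pnorm(-z))
}

#' Kruskal-Wallis omnibus test
#'
#' Rank-based k-group omnibus test with midranks and tie correction:
#' H = 12 / (N (N + 1)) * sum(R_j^2 / n_j) - 3 (N + 1), corrected for ties,
#' with the p-value from the chi-square distribution on k - 1 degrees of
#' freedom (via \code{stats::kruskal.test}).
#'
#' @param groups List of at least two non-empty numeric vectors
#'   (total n >= 3).
#' @return A one-row \code{test_result} data frame; \code{statistic} is H,
#'   \code{df} holds the degrees of freedom.
#' @examples
#' kruskal_wallis(list(c(1, 2), c(3, 4), c(5, 6)))$statistic # 32/7
#' @export
kruskal_wallis <- function(groups) {
  if (!is.list(groups) || length(groups) < 2L) {
    gi_error("Kruskal-Wallis needs at least 2 groups", "validation_error")
  }
  sizes <- lengths(groups)
  if (any(sizes == 0L)) {
    gi_error("Kruskal-Wallis groups must be non-empty", "empty_group")
  }
  if (sum(sizes) < 3L) {
    gi_error("Kruskal-Wallis needs total n >= 3", "validation_error")
  }
  values <- unlist(groups, use.names = FALSE)
  g <- factor(rep(seq_along(groups), sizes))
  if (length(unique(values)) == 1L) {
    # total tie: no evidence against the null
    res <- test_result("kruskal_wallis",
                       paste(seq_along(groups), collapse = ","), NA,
                       sum(sizes), NA, 0, 1, "chi_square")
    res$df <- length(groups) - 1L
    return(res)
  }
  kt <- stats::kruskal.test(values, g)
  res <- test_result("kruskal_wallis",
                     paste(seq_along(groups), collapse = ","), NA,
                     sum(sizes), NA,
                     unname(kt$statistic), unname(kt$p.value), "chi_square")
  res$df <- unname(kt$parameter)
  res
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values, capped at 1, returned in the input order
#' (via \code{stats::p.adjust}). Values outside [0, 1] are a validation
#' error.
#'
#' @param p_values Numeric vector of raw p-values.
#' @return Adjusted p-values, same length and order.
#' @export
bh_fdr <- function(p_values) {
  stopifnot(is.numeric(p_values))
  if (anyNA(p_values) || any(p_values < 0 | p_values > 1)) {
    gi_error("p-values must lie in [0, 1]", "validation_error")
  }
  stats::p.adjust(p_values, method = "BH")
}

test_result <- function(method, group_a, group_b, n_a, n_b, statistic,
                        p_value, mode_used) {
  res <- data.frame(
    method = method,
    group_a = as.character(group_a),
    group_b = as.character(group_b),
    n_a = n_a,
    n_b = n_b,
    statistic = statistic,
    p_value = p_value,
    p_adjusted = NA_real_,
    mode_used = mode_used,
    stringsAsFactors = FALSE
  )
  class(res) <- c("test_result", "data.frame")
  res
}

#' Compare a score across bins of a grouping field
#'
#' Reproduces the two comparison schemes used for cohort contrasts:
#' \code{pairwise_fdr} runs the rank-sum test on every pair of bins and
#' BH-adjusts the p-values (age-bin style comparisons); \code{omnibus} runs
#' one Kruskal-Wallis test across all bins (phenotype style). Samples with
#' missing scores, and bins labelled \code{"unknown"} or \code{NA}, are
#' excluded; bins left with fewer than 2 samples are dropped (reported via
#' message).
#'
#' @param score_table Data frame with the score column and the bin field.
#' @param bin_field Name of the grouping column (e.g. \code{"phenotype"},
#'   \code{"age_bin"}, \code{"gender"}).
#' @param scheme \code{"omnibus"} or \code{"pairwise_fdr"}.
#' @param value Name of the score column (default \code{"mapi"}).
#' @param quiet Suppress exclusion messages.
#' @return A data frame of test results (one row per pair, or a single
#'   omnibus row).
#' @export
compare_by_bins <- function(score_table, bin_field = "phenotype",
                            scheme = c("omnibus", "pairwise_fdr"),
                            value = "mapi", quiet = FALSE) {
  scheme <- match.arg(scheme)
  if (!bin_field %in% names(score_table) || !value %in% names(score_table)) {
    gi_error(sprintf("score table lacks column %s",
                     if (!bin_field %in% names(score_table)) bin_field
                     else value), "validation_error")
  }
  bins <- as.character(score_table[[bin_field]])
  v <- score_table[[value]]
  keep <- !is.na(v) & !is.na(bins) & bins != "unknown"
  n_excluded <- sum(!keep)
  bins <- bins[keep]
  v <- v[keep]
  counts <- table(bins)
  usable <- names(counts)[counts >= 2L]
  dropped <- setdiff(names(counts), usable)
  if (!quiet && (n_excluded > 0L || length(dropped))) {
    message(sprintf("compare_by_bins: excluded %d samples; dropped bins: %s",
                    n_excluded,
                    if (length(dropped)) paste(dropped, collapse = ", ")
                    else "none"))
  }
  if (length(usable) < 2L) {
    gi_error(sprintf("need >= 2 usable bins, have: %s",
                     paste(usable, collapse = ", ")), "insufficient_bins")
  }
  groups <- split(v, bins)[usable]
  if (scheme == "omnibus") {
    res <- kruskal_wallis(groups)
    res$group_a <- paste(usable, collapse = ",")
    return(res)
  }
  pairs <- utils::combn(usable, 2L)
  rows <- lapply(seq_len(ncol(pairs)), function(k) {
    a <- pairs[1L, k]
    b <- pairs[2L, k]
    r <- rank_sum_test(groups[[a]], groups[[b]])
    r$group_a <- a
    r$group_b <- b
    r
  })
  out <- do.call(rbind, rows)
  out$p_adjusted <- bh_fdr(out$p_value)
  rownames(out) <- NULL
  out
}

#' Per-bin summary statistics
#'
#' Reports n, mean, sample SD (absent for single-member bins), median and
#' quartiles of a score per bin, ignoring samples with missing scores (the
#' exclusion count is reported per bin).
#'
#' @inheritParams compare_by_bins
#' @return Data frame with one row per bin: \code{group}, \code{n},
#'   \code{mean}, \code{sd}, \code{median}, \code{q1}, \code{q3},
#'   \code{n_excluded}.
#' @export
group_summary <- function(score_table, bin_field, value = "mapi") {
  if (nrow(score_table) == 0L) {
    gi_error("empty score table", "empty_input")
  }
  bins <- as.character(score_table[[bin_field]])
  v <- score_table[[value]]
  out <- lapply(split(seq_along(v), bins), function(idx) {
    vals <- v[idx]
    excl <- sum(is.na(vals))
    vals <- vals[!is.na(vals)]
    q <- if (length(vals)) stats::quantile(vals, c(0.25, 0.5, 0.75),
                                           names = FALSE)
         else rep(NA_real_, 3)
    data.frame(
      n = length(vals),
      mean = if (length(vals)) mean(vals) else NA_real_,
      sd = if (length(vals) > 1L) stats::sd(vals) else NA_real_,
      median = q[2],
      q1 = q[1],
      q3 = q[3],
      n_excluded = excl
    )
  })
  res <- do.call(rbind, out)
  res <- cbind(data.frame(group = names(out), stringsAsFactors = FALSE), res)
  rownames(res) <- NULL
  res
}

#' Assign demographic age bins
#'
#' Decade bins 0-10, 11-20, ..., 71-80, with 81+ open-ended, matching the
#' demographic strata used for age comparisons.
#'
#' @param age Numeric vector of ages in years.
#' @return Character vector of bin labels (\code{NA} for missing ages).
#' @export
age_bin <- function(age) {
  labels <- c("0-10", "11-20", "21-30", "31-40", "41-50", "51-60",
              "61-70", "71-80", "81+")
  out <- rep(NA_character_, length(age))
  ok <- !is.na(age) & age >= 0
  idx <- pmin(ceiling(pmax(age[ok], 1) / 10), 9L)
  out[ok] <- labels[idx]
  out
}
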