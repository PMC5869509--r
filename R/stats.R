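# Exact small-sample inference: two-sided Fisher test on 2x2 counts and the
# Wilcoxon signed-rank test, plus the site-to-control pairing scheme.

new_test_result <- function(statistic, p_value, n_effective, method) {
  structure(list(statistic = statistic, p_value = p_value,
                 n_effective = n_effective, method = method),
            class = "provsel_test")
}

#' @export
print.provsel_test <- function(x, ...) {
  cat(x$method, "\n  statistic = ", format(x$statistic),
      ", p = ", format.pval(x$p_value, digits = 4),
      ", n = ", x$n_effective, "\n", sep = "")
  invisible(x)
}

#' Exact two-sided Fisher test on a 2x2 table
#'
#' Exact hypergeometric computation, no chi-square approximation. The
#' two-sided p-value follows the probability-mass ordering ("Count Data"
#' convention): the sum of the probabilities of all tables with the same
#' margins whose probability does not exceed the observed table's, with a
#' 1e-7 relative slack absorbing floating-point ties. The statistic is the
#' sample odds ratio.
#'
#' @param table 2x2 integer matrix (rows: groups, columns: in/out of
#'   feature), or a length-4 vector `(a, b, c, d)` filled by row.
#' @return A `provsel_test` with the odds ratio, p-value and total count.
#' @examples
#' fisher_exact_2x2(matrix(c(3, 1, 1, 3), 2, byrow = TRUE))
#' @export
fisher_exact_2x2 <- function(table) {
  if (!is.matrix(table)) table <- matrix(as.numeric(table), 2L, byrow = TRUE)
  stopifnot(all(dim(table) == 2L))
  x <- as.vector(t(table))  # a, b, c, d
  if (any(x < 0) || any(x != round(x))) {
    stop_bad("table entries must be non-negative integers")
  }
  n <- sum(x)
  if (n == 0) stop_bad("all-zero 2x2 table")
  a <- x[1L]; b <- x[2L]; c_ <- x[3L]; d <- x[4L]
  m <- a + b          # row 1 margin
  k <- a + c_         # column 1 margin
  lo <- max(0, k - (n - m))
  hi <- min(k, m)
  support <- lo:hi
  probs <- stats::dhyper(support, m, n - m, k)
  p_obs <- stats::dhyper(a, m, n - m, k)
  p <- min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
  or <- (a * d) / (b * c_)
  new_test_result(statistic = or, p_value = p, n_effective = n,
                  method = "Fisher's exact test for count data (two-sided)")
}

#' Wilcoxon signed-rank test
#'
#' Two-sided test on paired differences. Zero differences are dropped
#' (Wilcoxon's original treatment); ties among the remaining absolute
#' differences receive average ranks. For `n <= exact_limit` effective
#' pairs the p-value is exact under the 2^n uniform sign-flip law (computed
#' by convolution over the signed-rank generating function, so ties are
#' handled exactly); above that, a normal approximation with tie-corrected
#' variance and continuity correction is used. The statistic is V, the sum
#' of ranks of positive differences.
#'
#' @param differences Numeric vector of paired differences.
#' @param exact_limit Largest n for which the exact distribution is used.
#' @return A `provsel_test`; `n_effective` is the number of non-zero
#'   differences.
#' @examples
#' wilcoxon_signed_rank(c(1, 2, 3, 4, 5))  # p = 2/32
#' @export
wilcoxon_signed_rank <- function(differences, exact_limit = 25L) {
  d <- differences[!is.na(differences)]
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) stop_bad("all differences are zero (or missing)")
  r <- rank(abs(d))
  v <- sum(r[d > 0])
  if (n <= exact_limit) {
    p <- signed_rank_exact_p(r, v)
    method <- "Wilcoxon signed rank test (exact)"
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    z <- v - mu
    z <- (z - sign(z) * 0.5) / sqrt(sigma2)
    p <- min(1, 2 * min(stats::pnorm(z), stats::pnorm(z, lower.tail = FALSE)))
    method <- "Wilcoxon signed rank test (normal approximation)"
  }
  new_test_result(statistic = v, p_value = p, n_effective = n,
                  method = method)
}

# Exact two-sided p under the uniform sign-flip law: distribution of V by
# convolution over doubled ranks (integers even with average-rank ties),
# p = min(1, 2 * min(P(V <= v), P(V >= v))).
signed_rank_exact_p <- function(ranks, v) {
  r2 <- as.integer(round(2 * ranks))
  total <- sum(r2)
  f <- numeric(total + 1L)
  f[1L] <- 1
  for (r in r2) {
    shifted <- c(numeric(r), f[seq_len(total + 1L - r)])
    f <- f + shifted
  }
  f <- f / 2^length(ranks)
  v2 <- as.integer(round(2 * v))
  p_le <- sum(f[seq_len(v2 + 1L)])
  p_ge <- sum(f[(v2 + 1L):(total + 1L)])
  min(1, 2 * min(p_le, p_ge))
}

#' Pair each site with its matched controls
#'
#' Builds the paired structure behind the signed-rank distance comparisons:
#' each integration site against a reduction of its own matched controls.
#' The default reducer is the per-site median of control distances (robust,
#' keeps n = number of sites); `"mean"` averages instead; `"each"` emits
#' one pair per control, which inflates n and is provided for sensitivity
#' analysis only.
#'
#' @param site_distances data.frame with `site_id`/`query_id` and
#'   `distance` (e.g. from [nearest_distance()] on the sites).
#' @param control_distances data.frame with `parent_site_id` and `distance`
#'   per control. If it lacks `parent_site_id` (e.g. raw
#'   [nearest_distance()] output on a control table), pass the control
#'   table's `parent_site_id` alongside via the `parents` argument.
#' @param reducer `"median"`, `"mean"` or `"each"`.
#' @param parents Optional parent site id per control row.
#' @return data.frame with `site_id`, `site_distance`, `control_distance`
#'   (one row per site, or per control for `"each"`).
#' @export
pair_site_controls <- function(site_distances, control_distances,
                               reducer = c("median", "mean", "each"),
                               parents = NULL) {
  reducer <- match.arg(reducer)
  sid <- site_distances$site_id %||% site_distances$query_id
  parent <- parents %||% control_distances$parent_site_id
  if (is.null(parent)) {
    stop_bad("control distances need parent_site_id (or pass `parents`)")
  }
  cd <- control_distances$distance
  missing_ctrl <- setdiff(sid, parent)
  if (length(missing_ctrl) > 0L) {
    stop_bad("site(s) without controls: ",
             paste(utils::head(missing_ctrl, 5L), collapse = ", "))
  }
  if (reducer == "each") {
    keep <- parent %in% sid
    data.frame(site_id = parent[keep],
               site_distance =
                 site_distances$distance[match(parent[keep], sid)],
               control_distance = cd[keep],
               stringsAsFactors = FALSE)
  } else {
    fun <- if (reducer == "median") stats::median else mean
    red <- tapply(cd, parent, fun)
    data.frame(site_id = sid,
               site_distance = site_distances$distance,
               control_distance = as.numeric(red[sid]),
               stringsAsFactors = FALSE)
  }
}

#' Compare targeting frequencies of sites versus controls
#'
#' Builds the 2x2 table (sites in/out of the feature vs controls in/out)
#' and delegates to [fisher_exact_2x2()].
#'
#' @param sites_in,sites_total Counts for the integration sites.
#' @param controls_in,controls_total Counts for the matched controls.
#' @return A `provsel_test`.
#' @examples
#' compare_targeting(40, 46, 55, 138)
#' @export
compare_targeting <- function(sites_in, sites_total, controls_in,
                              controls_total) {
  stopifnot(sites_in <= sites_total, controls_in <= controls_total)
  fisher_exact_2x2(matrix(c(sites_in, sites_total - sites_in,
                            controls_in, controls_total - controls_in),
                          2L, byrow = TRUE))
}

#' Compare site and control distances by signed rank
#'
#' Runs [wilcoxon_signed_rank()] on the paired differences
#' `site_distance - control_distance` from [pair_site_controls()].
#'
#' @param pairs data.frame from [pair_site_controls()].
#' @return A `provsel_test`.
#' @export
compare_distances <- function(pairs) {
  wilcoxon_signed_rank(pairs$site_distance - pairs$control_distance)
}

#' Collect test results into a table
#'
#' Binds `provsel_test` objects into a long results table. Raw p-values are
#' reported by default; `adjust = TRUE` adds a Benjamini-Hochberg adjusted
#' column (off by default — the primary analyses report raw p-values).
#'
#' @param results Named list of `provsel_test` objects; names become the
#'   `comparison` column.
#' @param adjust Add a BH-adjusted `p_adjusted` column.
#' @return data.frame with `comparison`, `method`, `statistic`, `p_value`,
#'   `n_effective` (and `p_adjusted` when requested).
#' @export
test_results_table <- function(results, adjust = FALSE) {
  out <- do.call(rbind, lapply(names(results), function(nm) {
    r <- results[[nm]]
    data.frame(comparison = nm, method = r$method, statistic = r$statistic,
               p_value = r$p_value, n_effective = r$n_effective,
               stringsAsFactors = FALSE)
  }))
  if (adjust) out$p_adjusted <- stats::p.adjust(out$p_value, method = "BH")
  rownames(out) <- NULL
  out
}
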