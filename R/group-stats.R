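#' Tie-corrected Kruskal-Wallis test
#'
#' Rank-based k-sample location test used to compare activity and clinical
#' variables across the severity groups. Mid-ranks are used for ties and the
#' statistic is divided by the tie-correction factor
#' `1 - sum(t^3 - t) / (N^3 - N)`; the p-value is the upper tail of the
#' chi-square distribution with `k - 1` degrees of freedom. The computation
#' is delegated to [stats::kruskal.test()]; the fully tied input (every value
#' equal), where the correction factor degenerates to 0/0, is defined as
#' `H = 0`, `p = 1`.
#'
#' @param values Numeric observations.
#' @param groups Group labels (coerced to factor).
#' @return Object of class `"kw_test"`: list with `statistic` (H), `df`,
#'   `p.value`, `n`, `k`.
#' @export
#' @examples
#' kruskal_wallis(1:9, rep(c("a", "b", "c"), each = 3)) # H = 7.2
kruskal_wallis <- function(values, groups) {
  ok <- !is.na(values) & !is.na(groups)
  values <- values[ok]
  groups <- droplevels(factor(groups[ok]))
  if (nlevels(groups) < 2) stop("need at least 2 groups", call. = FALSE)
  if (any(table(groups) == 0)) stop("every group needs >= 1 observation", call. = FALSE)
  k <- nlevels(groups)
  if (length(unique(values)) == 1) {
    res <- list(statistic = 0, df = k - 1L, p.value = 1,
                n = length(values), k = k)
  } else {
    kw <- stats::kruskal.test(values, groups)
    res <- list(statistic = unname(kw$statistic), df = unname(kw$parameter),
                p.value = kw$p.value, n = length(values), k = k)
  }
  structure(res, class = "kw_test")
}

#' @export
print.kw_test <- function(x, ...) {
  cat(sprintf("Kruskal-Wallis (tie-corrected): H = %.4g, df = %d, p = %.4g (n = %d)\n",
              x$statistic, x$df, x$p.value, x$n))
  invisible(x)
}

#' Dunn's post-hoc pairwise test
#'
#' Pairwise follow-up to [kruskal_wallis()] on the joint-ranking scale. For
#' groups i and j,
#' `z = (meanrank_i - meanrank_j) / sqrt((N(N+1)/12 - T/(12(N-1))) (1/n_i + 1/n_j))`
#' with tie term `T = sum(t^3 - t)`; two-sided p-values from the standard
#' normal. No multiplicity adjustment is applied by default — the choice is
#' surfaced rather than imposed — with Holm and Bonferroni available.
#'
#' @inheritParams kruskal_wallis
#' @param adjust Multiple-comparison adjustment: `"none"` (default),
#'   `"holm"` or `"bonferroni"`.
#' @return Tibble of class `"dunn_test"`: `group1`, `group2`, `z`,
#'   `p.value`, `p.adjusted`, `significant` (adjusted p < 0.05); the
#'   adjustment method is stored in attribute `"adjust"`.
#' @export
dunn_posthoc <- function(values, groups, adjust = c("none", "holm", "bonferroni")) {
  adjust <- match.arg(adjust)
  ok <- !is.na(values) & !is.na(groups)
  values <- values[ok]
  groups <- droplevels(factor(groups[ok]))
  if (nlevels(groups) < 2) stop("need at least 2 groups", call. = FALSE)
  N <- length(values)
  r <- rank(values)  # mid-ranks
  tie_tab <- table(values)
  tie_term <- sum(tie_tab^3 - tie_tab)
  mean_rank <- tapply(r, groups, mean)
  n_g <- table(groups)
  lev <- levels(groups)
  pairs <- utils::combn(lev, 2)
  var_base <- N * (N + 1) / 12 - tie_term / (12 * (N - 1))
  res <- purrr::map_dfr(seq_len(ncol(pairs)), function(p) {
    i <- pairs[1, p]; j <- pairs[2, p]
    se <- sqrt(var_base * (1 / n_g[[i]] + 1 / n_g[[j]]))
    z <- if (se == 0) 0 else (mean_rank[[i]] - mean_rank[[j]]) / se
    tibble::tibble(group1 = i, group2 = j, z = z,
                   p.value = 2 * stats::pnorm(-abs(z)))
  })
  res$p.adjusted <- stats::p.adjust(res$p.value, method = adjust)
  res$significant <- res$p.adjusted < 0.05
  attr(res, "adjust") <- adjust
  class(res) <- c("dunn_test", class(res))
  res
}

#' Compare several variables across groups
#'
#' Runs the Kruskal-Wallis test and Dunn's post-hoc on each named variable,
#' the screening applied to every continuous participant characteristic and
#' activity metric across the four severity groups.
#'
#' @param data Data frame with the variables and a grouping column.
#' @param vars Character vector of variable names to test.
#' @param group Name of the grouping column.
#' @inheritParams dunn_posthoc
#' @return Tibble: one row per variable with `H`, `df`, `p.value` and a
#'   `dunn` list-column holding each variable's [dunn_posthoc()] table.
#' @export
group_compare <- function(data, vars, group,
                          adjust = c("none", "holm", "bonferroni")) {
  adjust <- match.arg(adjust)
  stopifnot(group %in% names(data), all(vars %in% names(data)))
  purrr::map_dfr(vars, function(v) {
    kw <- kruskal_wallis(data[[v]], data[[group]])
    tibble::tibble(
      variable = v, H = kw$statistic, df = kw$df, p.value = kw$p.value,
      n = kw$n,
      dunn = list(dunn_posthoc(data[[v]], data[[group]], adjust = adjust))
    )
  })
}
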