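# Enrichment and group-comparison statistics used by the subgroup / WCA
# characterisation panels: contingency tests with adjusted standardized
# residuals, rank-based group comparisons, and Benjamini-Hochberg
# correction within declared families.

#' Contingency-table association test with standardized residuals
#'
#' Tests association between two categorical variables. In `"auto"` mode a
#' 2x2 table with any expected cell below 5 is tested with Fisher's exact
#' test; all other tables use the chi-squared test (without continuity
#' correction, so that the statistic matches the residual decomposition).
#' Per-cell adjusted standardized residuals
#' \deqn{r_{ij} = (O_{ij} - E_{ij}) / \sqrt{E_{ij} (1 - p_{i\cdot}) (1 - p_{\cdot j})}}
#' indicate the direction and strength of enrichment in each cell.
#'
#' @param x matrix of non-negative integer counts, at least 2x2.
#' @param mode `"auto"`, `"fisher"` (2x2 only) or `"chi2"`.
#' @return object of class `contingency_result`: observed and expected
#'   tables, `chi2`, `p`, `test` used, and `residuals`.
#' @export
contingency_test <- function(x, mode = c("auto", "fisher", "chi2")) {
  mode <- match.arg(mode)
  x <- as.matrix(x)
  stop_if(any(x < 0) || any(x != round(x)), "counts must be non-negative integers")
  stop_if(nrow(x) < 2 || ncol(x) < 2, "table must be at least 2x2")
  stop_if(any(rowSums(x) == 0) || any(colSums(x) == 0),
          "zero-margin row or column")

  n <- sum(x)
  expected <- outer(rowSums(x), colSums(x)) / n
  rowp <- rowSums(x) / n
  colp <- colSums(x) / n
  resid <- (x - expected) /
    sqrt(expected * outer(1 - rowp, 1 - colp))

  chi2 <- sum((x - expected)^2 / expected)
  is2x2 <- nrow(x) == 2 && ncol(x) == 2
  use_fisher <- switch(mode,
    fisher = {
      stop_if(!is2x2, "fisher mode requires a 2x2 table")
      TRUE
    },
    chi2 = FALSE,
    auto = is2x2 && any(expected < 5)
  )
  if (use_fisher) {
    p <- stats::fisher.test(x)$p.value
    test <- "fisher"
  } else {
    p <- stats::pchisq(chi2, df = (nrow(x) - 1) * (ncol(x) - 1),
                       lower.tail = FALSE)
    test <- "chi2"
  }
  structure(
    list(observed = x, expected = expected, chi2 = chi2, p = p,
         test = test, residuals = resid),
    class = "contingency_result"
  )
}

#' @export
print.contingency_result <- function(x, ...) {
  cat(sprintf("Contingency test (%s): chi2 = %.4g, p = %.4g\n",
              x$test, x$chi2, x$p))
  invisible(x)
}

#' Rank-based comparison of a continuous variable across groups
#'
#' Two groups are compared with the Mann-Whitney U test (normal
#' approximation with tie correction, no continuity correction); three or
#' more with the Kruskal-Wallis test. For two groups the Kruskal-Wallis
#' chi-squared equals the square of the standardized Mann-Whitney Z.
#'
#' @param values numeric vector.
#' @param group grouping vector, coerced to factor.
#' @return list with `statistic`, `p`, `test` and `df` (Kruskal-Wallis only).
#' @export
rank_compare <- function(values, group) {
  group <- factor(group)
  keep <- !is.na(values) & !is.na(group)
  values <- values[keep]
  group <- droplevels(group[keep])
  stop_if(nlevels(group) < 2, "need at least 2 groups")
  stop_if(any(table(group) == 0), "empty group")
  if (nlevels(group) == 2) {
    ht <- stats::wilcox.test(values ~ group, exact = FALSE, correct = FALSE)
    list(statistic = unname(ht$statistic), p = ht$p.value,
         test = "mann-whitney", df = NA_integer_)
  } else {
    ht <- stats::kruskal.test(values, group)
    list(statistic = unname(ht$statistic), p = ht$p.value,
         test = "kruskal-wallis", df = unname(ht$parameter))
  }
}

#' Benjamini-Hochberg adjustment within a declared family
#'
#' Step-up false-discovery-rate correction. The family id is recorded on
#' the result so that reports can state which tests were corrected
#' together.
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @param family optional family identifier (character scalar).
#' @return adjusted p-values, with attribute `family`.
#' @export
bh_adjust <- function(p, family = NULL) {
  stop_if(any(p < 0 | p > 1, na.rm = TRUE), "p-values must be in [0, 1]")
  out <- stats::p.adjust(p, method = "BH")
  attr(out, "family") <- family
  out
}

#' Feature-inclusion filter for enrichment panels
#'
#' A feature enters an enrichment analysis if its cohort-wide frequency is
#' at least `min_cohort` or any subgroup-specific frequency is at least
#' `min_subgroup`. Pure predicate; order-invariant.
#'
#' @param cohort_freq cohort-wide frequency (proportion).
#' @param subgroup_freq numeric vector of per-subgroup frequencies (may be
#'   empty).
#' @param min_cohort cohort-wide threshold (default 0.05).
#' @param min_subgroup subgroup-specific threshold (default 0.10).
#' @return logical scalar.
#' @export
include_feature <- function(cohort_freq, subgroup_freq = numeric(),
                            min_cohort = 0.05, min_subgroup = 0.10) {
  isTRUE(cohort_freq >= min_cohort) ||
    any(subgroup_freq >= min_subgroup, na.rm = TRUE)
}
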