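# First-principles re-derivation of prognostic whole-chromosome
# aberration signatures: exhaustive search over k-of-set rules (subsets
# of candidate (chromosome, direction) features, each with a count
# threshold k) scored on progression-free survival by log-rank
# separation, with BH correction across the rule space.

#' k-of-set signature rule
#'
#' A rule is a set of (chromosome, direction) features written `"7+"`
#' (gain) / `"8-"` (loss), plus a threshold k: a tumour matches when at
#' least k of the features are present.
#'
#' @param features character vector like `c("7+", "8-", "11-")`; no
#'   duplicates, and a chromosome may appear with only one direction.
#' @param k integer threshold, 1 <= k <= number of features.
#' @return object of class `signature_rule`.
#' @export
signature_rule <- function(features, k) {
  stop_if(length(features) == 0, "features must be non-empty")
  stop_if(anyDuplicated(features) > 0, "duplicate features")
  chroms <- feature_chrom(features)
  stop_if(any(is.na(chroms)),
          "features must look like '<chromosome><+|->', e.g. '7+'")
  stop_if(anyDuplicated(chroms) > 0,
          "a chromosome may appear with at most one direction")
  stop_if(k < 1 || k > length(features), "k must be in 1..|features|")
  structure(list(features = features, k = as.integer(k)),
            class = "signature_rule")
}

feature_chrom <- function(features) {
  m <- regmatches(features, regexec("^([0-9]+)([+-])$", features))
  vapply(m, function(x) if (length(x) == 3) as.integer(x[2]) else NA_integer_,
         integer(1))
}

#' @export
print.signature_rule <- function(x, ...) {
  cat(format_rule(x), "\n")
  invisible(x)
}

#' Serialize / parse a signature rule
#'
#' The text form is `"7+,8-,11-;k=2"`.
#'
#' @param rule a [signature_rule()].
#' @return `format_rule`: character scalar; `parse_rule`: a
#'   `signature_rule`.
#' @export
format_rule <- function(rule) {
  sprintf("%s;k=%d", paste(rule$features, collapse = ","), rule$k)
}

#' @rdname format_rule
#' @param text serialized rule string.
#' @export
parse_rule <- function(text) {
  parts <- strsplit(text, ";k=", fixed = TRUE)[[1]]
  stop_if(length(parts) != 2, "malformed rule string: ", text)
  signature_rule(strsplit(parts[1], ",", fixed = TRUE)[[1]],
                 as.integer(parts[2]))
}

#' Does each patient match a signature rule?
#'
#' A patient matches when at least k of the rule's features are present.
#' Unassessable features (NA) count as absent.
#'
#' @param rule a [signature_rule()].
#' @param features logical feature matrix from [wca_features()].
#' @return logical vector, one element per patient.
#' @export
rule_matches <- function(rule, features) {
  miss <- setdiff(rule$features, colnames(features))
  stop_if(length(miss) > 0, "feature(s) not in matrix: ",
          paste(miss, collapse = ", "))
  cnt <- rowSums(features[, rule$features, drop = FALSE], na.rm = TRUE)
  cnt >= rule$k
}

#' Candidate features above a cohort frequency threshold
#'
#' Returns the (chromosome, direction) features whose cohort frequency is
#' at least `min_freq`, sorted by frequency descending then chromosome
#' number. i17q is not a whole-chromosome feature and is excluded from the
#' search space.
#'
#' @param features logical feature matrix from [wca_features()].
#' @param min_freq minimum cohort proportion (default 0.05).
#' @return data.frame: `feature`, `frequency`.
#' @export
enumerate_candidates <- function(features, min_freq = 0.05) {
  stop_if(nrow(features) == 0, "empty cohort")
  cols <- setdiff(colnames(features), "i17q")
  freq <- colMeans(features[, cols, drop = FALSE], na.rm = TRUE)
  keep <- freq >= min_freq
  feats <- cols[keep]
  freqs <- freq[keep]
  ord <- order(-freqs, feature_chrom(feats))
  data.frame(feature = feats[ord], frequency = unname(freqs[ord]))
}

# Low-overhead two-group survival statistics for the exhaustive search.
# Numerically identical to survdiff / coxph / concordance on the same
# data (asserted in the test suite); they skip the formula interface,
# which dominates run time when thousands of rules are scored.

fast_logrank2 <- function(time, event, g) {
  o <- order(time)
  time <- time[o]; event <- event[o] == 1; g <- g[o]
  t1 <- time[g]
  ut <- unique(time[event])
  n <- length(time)
  nrisk <- n - findInterval(ut, time, left.open = TRUE)
  nrisk1 <- sum(g) - findInterval(ut, sort(t1), left.open = TRUE)
  d <- as.vector(rowsum(as.numeric(event), time)[match(ut, sort(unique(time)))])
  d1 <- as.vector(rowsum(as.numeric(event & g), time)[match(ut, sort(unique(time)))])
  p1 <- nrisk1 / nrisk
  e1 <- d * p1
  v <- ifelse(nrisk > 1, d * p1 * (1 - p1) * (nrisk - d) / (nrisk - 1), 0)
  chi2 <- (sum(d1) - sum(e1))^2 / sum(v)
  list(chi2 = chi2, p = stats::pchisq(chi2, 1, lower.tail = FALSE))
}

fast_binary_cox_hr <- function(time, event, g) {
  # monotone-likelihood warnings are expected for rules whose positives
  # have no events; the HR is still reported alongside n_positive
  fit <- suppressWarnings(
    survival::coxph.fit(matrix(as.numeric(g), ncol = 1),
                        survival::Surv(time, event),
                        strata = NULL, offset = NULL, init = 0,
                        control = survival::coxph.control(),
                        weights = NULL, method = "efron",
                        rownames = NULL))
  exp(unname(fit$coefficients))
}

fast_cindex <- function(scores, time, event) {
  # concordance for risk scores: higher score, shorter survival
  survival::concordancefit(survival::Surv(time, event),
                           -scores)$concordance
}

#' Score one signature rule on progression-free survival
#'
#' Classifies patients by the rule and computes the two-group log-rank
#' statistic, the concordance of the (better-oriented) binary rule with
#' PFS, and the two-group Cox hazard ratio (rule-positive vs negative).
#' A rule is kept with a flagged null score when either class falls
#' below the minimum support: the asymptotic log-rank p-value is not
#' trustworthy for near-empty classes, so the candidate-frequency
#' convention (5% of the cohort) is applied to the rule classes as well.
#'
#' @param rule a [signature_rule()].
#' @param features logical feature matrix from [wca_features()].
#' @param time,event follow-up times and 0/1 event indicators.
#' @param min_support minimum proportion of the cohort required in each
#'   rule class (default 0.05).
#' @return one-row data.frame: `rule`, `n_features`, `k`, `n_positive`,
#'   `logrank_chi2`, `logrank_p`, `cindex`, `hazard_ratio`, `degenerate`.
#' @export
score_rule <- function(rule, features, time, event, min_support = 0.05) {
  pos <- rule_matches(rule, features)
  base <- data.frame(rule = format_rule(rule),
                     n_features = length(rule$features), k = rule$k,
                     n_positive = sum(pos))
  n_min <- min_support * length(pos)
  if (sum(pos) < n_min || sum(!pos) < n_min || sum(event) == 0) {
    return(cbind(base, data.frame(
      logrank_chi2 = NA_real_, logrank_p = NA_real_, cindex = NA_real_,
      hazard_ratio = NA_real_, degenerate = TRUE)))
  }
  lr <- fast_logrank2(time, event, pos)
  cr <- fast_cindex(as.numeric(pos), time, event)
  cbind(base, data.frame(
    logrank_chi2 = lr$chi2, logrank_p = lr$p,
    cindex = max(cr, 1 - cr),
    hazard_ratio = fast_binary_cox_hr(time, event, pos),
    degenerate = FALSE))
}

#' Exhaustive k-of-set signature search scored on PFS
#'
#' Scores every rule formed from a subset of the candidate features (up
#' to `max_set_size`, never combining both directions of one chromosome)
#' and every threshold k within `k_range`. Rules are ranked by smallest
#' log-rank p, tie-broken by larger c-index, then fewer features, then
#' smaller k; BH-adjusted p-values are computed across all rules tested.
#' Deterministic given the cohort.
#'
#' @param features logical feature matrix from [wca_features()].
#' @param time,event follow-up times and 0/1 event indicators.
#' @param candidates character vector of candidate features; default the
#'   [enumerate_candidates()] output at `min_freq`.
#' @param min_freq candidate frequency threshold when `candidates` is
#'   not given.
#' @param max_set_size largest feature-set size enumerated (default 5;
#'   keeps the search exact over the small post-filter candidate space).
#' @param k_range integer thresholds to try (default all 1..set size).
#' @param min_support minimum class proportion passed to [score_rule()].
#' @return ranked data.frame of [score_rule()] rows plus `p_adj` and
#'   `rank`.
#' @export
search_signatures <- function(features, time, event, candidates = NULL,
                              min_freq = 0.05, max_set_size = 5,
                              k_range = NULL, min_support = 0.05) {
  if (is.null(candidates))
    candidates <- enumerate_candidates(features, min_freq)$feature
  stop_if(length(candidates) == 0, "no candidate features")
  chroms <- feature_chrom(candidates)
  scores <- list()
  for (size in seq_len(min(max_set_size, length(candidates)))) {
    subsets <- utils::combn(length(candidates), size, simplify = FALSE)
    for (idx in subsets) {
      if (anyDuplicated(chroms[idx]) > 0) next  # one direction per chromosome
      ks <- intersect(k_range %||% seq_len(size), seq_len(size))
      for (k in ks) {
        rule <- signature_rule(candidates[idx], k)
        scores[[length(scores) + 1]] <-
          score_rule(rule, features, time, event, min_support = min_support)
      }
    }
  }
  stop_if(length(scores) == 0, "empty search space")
  out <- do.call(rbind, scores)
  out$p_adj <- bh_adjust(out$logrank_p, family = "signature-search")
  ord <- order(out$logrank_p, -out$cindex, out$n_features, out$k,
               out$rule, na.last = TRUE)
  out <- out[ord, ]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Pairwise association among WCA features (including i17q)
#'
#' For every pair of non-constant features: Fisher's exact test on the
#' 2x2 co-occurrence table, the sample odds ratio (Haldane 0.5 correction
#' when the table has a zero cell) as signed association, and BH-adjusted
#' p-values over all pairs. A hierarchical clustering order is computed
#' by average linkage on the distance d = (1 - phi) / 2, where phi is the
#' Pearson correlation of the binary features.
#'
#' @param features logical feature matrix from [wca_features()].
#' @param min_freq drop features rarer than this before testing (default
#'   0.05).
#' @return list: `pairs` (feature_a, feature_b, odds_ratio,
#'   log_odds_ratio, phi, p, p_adj), `excluded` (constant or rare
#'   features), `hclust`, `order` (clustered feature order).
#' @export
wca_association_matrix <- function(features, min_freq = 0.05) {
  features <- features[, colSums(is.na(features)) < nrow(features),
                       drop = FALSE]
  freq <- colMeans(features, na.rm = TRUE)
  constant <- freq %in% c(0, 1) | freq < min_freq
  excluded <- colnames(features)[constant]
  feats <- features[, !constant, drop = FALSE]
  stop_if(ncol(feats) < 2, "need >= 2 variable features")
  nm <- colnames(feats)
  pairs <- utils::combn(nm, 2, simplify = FALSE)
  rows <- lapply(pairs, function(pr) {
    a <- feats[, pr[1]]; b <- feats[, pr[2]]
    ok <- !is.na(a) & !is.na(b)
    tab <- table(factor(a[ok], c(FALSE, TRUE)), factor(b[ok], c(FALSE, TRUE)))
    p <- stats::fisher.test(tab)$p.value
    t2 <- tab + ifelse(any(tab == 0), 0.5, 0)  # Haldane correction
    or <- (t2[2, 2] * t2[1, 1]) / (t2[1, 2] * t2[2, 1])
    data.frame(feature_a = pr[1], feature_b = pr[2], odds_ratio = or,
               log_odds_ratio = log(or),
               phi = stats::cor(a[ok], b[ok]), p = p)
  })
  tab <- do.call(rbind, rows)
  tab$p_adj <- bh_adjust(tab$p, family = "wca-association")
  phi <- stats::cor(feats, use = "pairwise.complete.obs")
  hc <- stats::hclust(stats::as.dist((1 - phi) / 2), method = "average")
  list(pairs = tab, excluded = excluded, hclust = hc,
       order = nm[hc$order])
}
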