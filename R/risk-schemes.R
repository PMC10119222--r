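# The three-tier MB_Grp4 risk-stratification scheme (metastatic stage x
# WCA group x methylation subgroup 7), declarative comparator schemes,
# reclassification between schemes, and per-scheme survival performance.

#' Risk labels of the MB_Grp4 scheme, in increasing-risk order
#' @export
GRP4_RISK_LEVELS <- c("favourable", "high", "very_high")

#' Assign the MB_Grp4 three-tier risk group
#'
#' Favourable: non-metastatic (M0) patients who are WCA-FR or methylation
#' subgroup 7. Very-high: metastatic (M+) WCA-HR patients. High: the
#' remainder (M+ with WCA-FR, and M0 patients who are WCA-HR and not
#' subgroup 7). If a field needed for the reached decision is missing
#' (or the WCA class is unassessable) the patient is `"unclassifiable"`.
#'
#' @param m_stage `"M0"` / `"M+"` / NA.
#' @param wca_class `"WCA-FR"` / `"WCA-HR"` / `"unassessable"` / NA.
#' @param subgroup methylation subgroup label (`"1"`,`"5"`,...,`"8"`) or NA.
#' @return character vector with values in
#'   `c("favourable", "high", "very_high", "unclassifiable")`.
#' @export
assign_grp4_risk <- function(m_stage, wca_class, subgroup) {
  n <- max(length(m_stage), length(wca_class), length(subgroup))
  m_stage <- rep_len(as.character(m_stage), n)
  wca_class <- rep_len(as.character(wca_class), n)
  subgroup <- rep_len(as.character(subgroup), n)
  stop_if(!all(m_stage %in% c("M0", "M+") | is.na(m_stage)),
          "m_stage must be 'M0', 'M+' or NA")
  wca_class[!wca_class %in% c("WCA-FR", "WCA-HR")] <- NA_character_

  yes <- function(x) !is.na(x) & x  # NA-safe truth
  fr <- wca_class == "WCA-FR"
  hr <- wca_class == "WCA-HR"
  sg7 <- subgroup == "7"
  m0 <- m_stage == "M0"
  mp <- m_stage == "M+"

  out <- rep("unclassifiable", n)
  out[yes(m0) & (yes(fr) | yes(sg7))] <- "favourable"
  out[yes(m0) & yes(hr) & yes(!sg7)] <- "high"
  out[yes(mp) & yes(fr)] <- "high"
  out[yes(mp) & yes(hr)] <- "very_high"
  out
}

#' Declarative risk-scheme specification
#'
#' A scheme is an ordered list of rules, each a predicate over clinical
#' record columns mapped to a label; the first matching rule wins and
#' non-matching records take `default_label`. A record for which a
#' predicate cannot be decided (evaluates NA) before any rule matches is
#' `"unclassifiable"`.
#'
#' @param id scheme identifier.
#' @param rules list of `list(predicate =, label =)`; `predicate` is an
#'   unevaluated R expression (see [base::quote()]) over record columns.
#' @param default_label label for records matching no rule.
#' @param labels the scheme's full label set, in increasing-risk order.
#' @return object of class `scheme_spec`.
#' @export
scheme_spec <- function(id, rules, default_label, labels) {
  stop_if(!default_label %in% labels, "default_label must be in labels")
  for (r in rules)
    stop_if(!r$label %in% labels, "rule label not in label set: ", r$label)
  structure(list(id = id, rules = rules, default_label = default_label,
                 labels = labels),
            class = "scheme_spec")
}

#' The current clinical-trial comparator scheme
#'
#' Reconstruction of the conventional clinical risk dichotomy used by
#' current trials: high risk if metastatic, LCA histology, MYC or MYCN
#' amplification, or sub-total resection; standard risk otherwise.
#'
#' @return a [scheme_spec()] with labels standard < high.
#' @export
clinical_risk_scheme <- function() {
  scheme_spec(
    id = "clinical",
    rules = list(list(
      predicate = quote(m_stage == "M+" | histology == "LCA" |
                          myc_amp | mycn_amp | resection == "STR"),
      label = "high")),
    default_label = "standard",
    labels = c("standard", "high")
  )
}

#' Evaluate a scheme spec on patient records
#'
#' @param spec a [scheme_spec()].
#' @param records data.frame with the columns the predicates reference.
#' @param warn_dead warn about rules that match no record (default TRUE
#'   only in [check_scheme()]).
#' @return character label vector (scheme labels or `"unclassifiable"`).
#' @export
assign_scheme <- function(spec, records, warn_dead = FALSE) {
  stopifnot(inherits(spec, "scheme_spec"))
  n <- nrow(records)
  out <- rep(NA_character_, n)
  undecided <- rep(FALSE, n)  # hit an NA predicate before any match
  for (ri in seq_along(spec$rules)) {
    r <- spec$rules[[ri]]
    hit <- eval(r$predicate, records, parent.frame())
    stop_if(length(hit) != n, "predicate did not evaluate per-record")
    open <- is.na(out) & !undecided
    undecided <- undecided | (open & is.na(hit))
    assign_now <- open & !is.na(hit) & hit
    out[assign_now] <- r$label
    if (warn_dead && !any(assign_now))
      warning(sprintf("scheme '%s': rule %d ('%s') matched no record",
                      spec$id, ri, r$label))
  }
  out[undecided] <- "unclassifiable"
  out[is.na(out)] <- spec$default_label
  out
}

#' Coverage check for a scheme spec
#'
#' Evaluates the spec on a grid of complete-data records and warns about
#' dead (never-matching) rules; errors if any grid record is left
#' unclassifiable, since complete data must always be covered.
#'
#' @param spec a [scheme_spec()].
#' @param grid data.frame of complete-data records spanning the input
#'   space.
#' @return invisibly, the grid labels.
#' @export
check_scheme <- function(spec, grid) {
  labels <- assign_scheme(spec, grid, warn_dead = TRUE)
  stop_if(any(labels == "unclassifiable"),
          sprintf("scheme '%s' leaves complete-data records uncovered",
                  spec$id))
  invisible(labels)
}

#' Reclassification between two labelings of the same patients
#'
#' Cross-tabulates old versus new labels and reports the percentage of
#' patients reassigned, where a patient counts as reassigned unless the
#' (old, new) pair is in the equivalence map. The default map treats the
#' comparator's "high" as equivalent to the new scheme's "high" and
#' nothing else.
#'
#' @param old,new aligned label vectors (same patients, same order).
#' @param equivalence data.frame with columns `old`, `new` listing
#'   label pairs that count as "unchanged", or `"identity"` for
#'   old == new.
#' @return object of class `reclassification_report`: `crosstab` (counts),
#'   `fractions` (row-normalised), `flows` (source, target, count, for
#'   Sankey rendering), `percent_reassigned`.
#' @export
reclassify <- function(old, new,
                       equivalence = data.frame(old = "high", new = "high")) {
  stop_if(length(old) != length(new), "label vectors differ in length")
  if (identical(equivalence, "identity"))
    equivalence <- data.frame(old = sort(unique(old)),
                              new = sort(unique(old)))
  crosstab <- table(old = old, new = new)
  fractions <- prop.table(crosstab, margin = 1)
  flows <- as.data.frame(crosstab, responseName = "count",
                         stringsAsFactors = FALSE)
  names(flows) <- c("source", "target", "count")
  flows <- flows[flows$count > 0, ]
  rownames(flows) <- NULL
  unchanged <- paste(old, new) %in% paste(equivalence$old, equivalence$new)
  structure(
    list(crosstab = crosstab, fractions = fractions, flows = flows,
         percent_reassigned = 100 * mean(!unchanged)),
    class = "reclassification_report"
  )
}

#' @export
print.reclassification_report <- function(x, ...) {
  cat(sprintf("Reclassification: %.1f%% of patients reassigned\n",
              x$percent_reassigned))
  print(x$crosstab)
  invisible(x)
}

#' Survival performance of a risk scheme
#'
#' Per-group Kaplan-Meier survival at the horizon with log-log CI, the
#' overall log-rank test, and the scheme's discrimination as Harrell's
#' c-index of group-ordinal risk scores (label order = increasing risk),
#' optionally bias-corrected by bootstrap optimism. Unclassifiable or NA
#' labels are dropped; groups with zero patients are dropped with a
#' warning.
#'
#' @param labels risk labels per patient.
#' @param time,event follow-up times and 0/1 event indicators.
#' @param horizon evaluation horizon in years (default 5).
#' @param label_order label set in increasing-risk order; defaults to the
#'   MB_Grp4 order when all labels belong to it.
#' @param rounds bootstrap rounds for the optimism-corrected c-index
#'   (default 0 = apparent only).
#' @param seed seed for the bootstrap.
#' @return object of class `scheme_result`: `groups` data.frame (label,
#'   n, events, s_at_horizon, lower, upper), `logrank` (NULL and flagged
#'   if fewer than two groups), `cindex` [performance_report], `horizon`.
#' @export
evaluate_scheme <- function(labels, time, event, horizon = 5,
                            label_order = NULL, rounds = 0, seed = NULL) {
  keep <- !is.na(labels) & labels != "unclassifiable"
  labels <- labels[keep]; time <- time[keep]; event <- event[keep]
  stop_if(length(labels) == 0, "no classified patients")
  if (is.null(label_order)) {
    label_order <- if (all(labels %in% GRP4_RISK_LEVELS)) GRP4_RISK_LEVELS
                   else sort(unique(labels))
  }
  label_order <- label_order[label_order %in% labels]
  if (length(setdiff(unique(labels), label_order)) > 0)
    stop("labels outside label_order: ",
         paste(setdiff(unique(labels), label_order), collapse = ", "))

  groups <- do.call(rbind, lapply(label_order, function(g) {
    i <- labels == g
    km <- km_estimate(time[i], event[i])
    data.frame(label = g, n = sum(i), events = sum(event[i]),
               s_at_horizon = km_survival(km, horizon),
               lower = km_survival(km, horizon, "lower"),
               upper = km_survival(km, horizon, "upper"))
  }))

  single_group <- length(label_order) < 2
  logrank <- if (single_group) NULL
             else logrank_test(time, event, factor(labels, label_order))

  scores <- match(labels, label_order)
  cindex <- if (single_group) NULL else {
    dat <- data.frame(time = time, event = event, score = scores)
    optimism_corrected_cindex(
      dat,
      score_fun = function(train) function(newdata) newdata$score,
      rounds = rounds, seed = seed
    )
  }
  structure(
    list(groups = groups, logrank = logrank,
         logrank_flagged = single_group, cindex = cindex,
         horizon = horizon, label_order = label_order),
    class = "scheme_result"
  )
}

#' @export
print.scheme_result <- function(x, ...) {
  cat(sprintf("Scheme performance at %g years:\n", x$horizon))
  print(x$groups, digits = 3)
  if (!is.null(x$logrank))
    cat(sprintf("log-rank chi2 = %.3g (df %d), p = %.3g\n",
                x$logrank$chi2, x$logrank$df, x$logrank$p))
  else cat("log-rank undefined (single group)\n")
  if (!is.null(x$cindex)) print(x$cindex)
  invisible(x)
}
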