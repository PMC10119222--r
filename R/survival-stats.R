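# Survival machinery: Kaplan-Meier estimation, log-rank tests, Cox
# proportional-hazards fits with backwards selection and Schoenfeld
# diagnostics, Harrell's c-index with bootstrap optimism correction, and
# calibration at a fixed horizon. Standard estimators are delegated to the
# 'survival' package behind a small, stable surface; the validation
# wiring (optimism bootstrap, calibration pairs, selection loop) is
# implemented here.

#' Kaplan-Meier product-limit estimate
#'
#' @param time non-negative follow-up times (years).
#' @param event event indicator, 1 = progression, 0 = censored.
#' @return object of class `km_curve`: event/censoring times, survival
#'   probabilities, Greenwood variances, at-risk counts and log-log 95%
#'   confidence bounds. Query the step function with [km_survival()].
#' @export
km_estimate <- function(time, event) {
  stop_if(length(time) < 1, "need at least one observation")
  stop_if(any(!is.finite(time)) || any(time < 0), "times must be finite and >= 0")
  stop_if(!all(event %in% c(0, 1)), "event must be 0/1")
  fit <- survival::survfit(survival::Surv(time, event) ~ 1,
                           conf.type = "log-log")
  structure(
    list(time = fit$time, surv = fit$surv,
         # Greenwood: var(S) = S^2 * sum d/(n(n-d))
         var = fit$surv^2 * fit$std.err^2,
         n_risk = fit$n.risk, n_event = fit$n.event,
         n_censor = fit$n.censor,
         lower = fit$lower, upper = fit$upper, n = length(time)),
    class = "km_curve"
  )
}

#' Survival probability of a Kaplan-Meier curve at arbitrary times
#'
#' Right-continuous step-function lookup; S(t) = 1 for t before the first
#' event.
#'
#' @param km a `km_curve`.
#' @param t numeric vector of times.
#' @param what `"surv"` (default), `"lower"` or `"upper"`.
#' @return numeric vector of survival probabilities.
#' @export
km_survival <- function(km, t, what = c("surv", "lower", "upper")) {
  what <- match.arg(what)
  y <- km[[what]]
  # confidence bounds are undefined (NA/NaN) where S hits 0 or 1; keep as-is
  c(1, y)[findInterval(t, km$time) + 1L]
}

#' @export
print.km_curve <- function(x, ...) {
  cat(sprintf("Kaplan-Meier curve: n = %d, events = %d, S(last) = %.3f\n",
              x$n, sum(x$n_event), x$surv[length(x$surv)]))
  invisible(x)
}

#' Log-rank test across survival groups
#'
#' Standard (unweighted) log-rank chi-square with `groups - 1` degrees of
#' freedom.
#'
#' @param time,event follow-up times and 0/1 event indicators.
#' @param group grouping vector (>= 2 non-empty groups, >= 1 event).
#' @return list with `chi2`, `df`, `p`.
#' @export
logrank_test <- function(time, event, group) {
  group <- droplevels(factor(group))
  stop_if(nlevels(group) < 2, "need >= 2 non-empty groups")
  stop_if(sum(event) < 1, "need at least one event")
  sd <- survival::survdiff(survival::Surv(time, event) ~ group)
  df <- nlevels(group) - 1L
  list(chi2 = sd$chisq, df = df,
       p = stats::pchisq(sd$chisq, df, lower.tail = FALSE))
}

#' Cox proportional-hazards fit
#'
#' Maximises the partial likelihood (Efron tie handling by default) and
#' reports per-covariate hazard ratios with Wald 95% confidence intervals.
#' Monotone-likelihood fits (e.g. a group with no events) are flagged
#' rather than reported, so callers can fall back to a log-rank p-value.
#'
#' @param time,event follow-up times and 0/1 event indicators.
#' @param covariates data.frame of covariates (numeric, logical or factor);
#'   no covariate may be constant.
#' @param ties tie-handling method, `"efron"` (default) or `"breslow"`.
#' @return object of class `cox_fit` with a coefficient `table`
#'   (coef, hr, ci_lower, ci_upper, se, z, p), `loglik`, `n`, `n_event`,
#'   `converged`, `monotone` flag and the underlying `coxph` fit.
#' @export
cox_fit <- function(time, event, covariates, ties = c("efron", "breslow")) {
  ties <- match.arg(ties)
  covariates <- as.data.frame(covariates)
  stop_if(ncol(covariates) < 1, "need at least one covariate")
  stop_if(sum(event, na.rm = TRUE) < 1, "need at least one event")
  const <- vapply(covariates, function(v) length(unique(v[!is.na(v)])) < 2,
                  logical(1))
  stop_if(any(const), "constant covariate(s): ",
          paste(names(covariates)[const], collapse = ", "))

  df <- data.frame(.time = time, .event = event, covariates,
                   check.names = FALSE)
  df <- df[stats::complete.cases(df), , drop = FALSE]
  monotone <- FALSE
  fit <- withCallingHandlers(
    survival::coxph(
      survival::Surv(.time, .event) ~ .,
      data = df, ties = ties,
      control = survival::coxph.control(eps = 1e-9, iter.max = 100)
    ),
    warning = function(w) {
      if (grepl("infinite|converge|beta may be infinite", conditionMessage(w)))
        monotone <<- TRUE
      invokeRestart("muffleWarning")
    }
  )
  sm <- summary(fit)$coefficients
  monotone <- monotone || any(abs(stats::coef(fit)) > 15)
  tab <- data.frame(
    term = rownames(sm),
    coef = sm[, "coef"],
    hr = sm[, "exp(coef)"],
    ci_lower = exp(sm[, "coef"] - 1.96 * sm[, "se(coef)"]),
    ci_upper = exp(sm[, "coef"] + 1.96 * sm[, "se(coef)"]),
    se = sm[, "se(coef)"],
    z = sm[, "z"],
    p = sm[, "Pr(>|z|)"],
    row.names = NULL
  )
  structure(
    list(table = tab, loglik = fit$loglik[2], loglik_null = fit$loglik[1],
         n = fit$n, n_event = fit$nevent,
         converged = fit$iter < 100, monotone = monotone,
         ties = ties, fit = fit),
    class = "cox_fit"
  )
}

#' @export
print.cox_fit <- function(x, ...) {
  cat(sprintf("Cox PH fit (%s ties): n = %d, events = %d%s\n", x$ties,
              x$n, x$n_event,
              if (x$monotone) " [monotone likelihood flagged]" else ""))
  print(x$table, digits = 3)
  invisible(x)
}

#' Backwards selection for a multivariable Cox model
#'
#' Starting from the full model on complete cases, iteratively removes the
#' covariate with the largest Wald p-value at or above `alpha_stay`,
#' refitting after each removal, until every retained covariate has
#' p < `alpha_stay`.
#'
#' @inheritParams cox_fit
#' @param alpha_stay stay threshold on the Wald p-value (default 0.10).
#' @return list with the final `fit` (`NULL` if nothing is retained),
#'   `retained` covariate names, the complete-case `n` used, and a
#'   removal `trace` data.frame (step, dropped, p).
#' @export
backward_select <- function(time, event, covariates, alpha_stay = 0.10,
                            ties = "efron") {
  covariates <- as.data.frame(covariates)
  cc <- stats::complete.cases(data.frame(time, event, covariates))
  time <- time[cc]; event <- event[cc]
  covariates <- covariates[cc, , drop = FALSE]
  current <- names(covariates)
  trace <- data.frame(step = integer(), dropped = character(),
                      p = numeric())
  step <- 0L
  fit <- NULL
  while (length(current) > 0) {
    fit <- cox_fit(time, event, covariates[current], ties = ties)
    # factor covariates can expand to several terms; drop by worst term's
    # parent covariate
    pmax_term <- fit$table$term[which.max(fit$table$p)]
    pmax <- max(fit$table$p)
    if (pmax < alpha_stay) break
    victim <- current[vapply(current, function(v) startsWith(pmax_term, v),
                             logical(1))][1]
    step <- step + 1L
    trace <- rbind(trace,
                   data.frame(step = step, dropped = victim, p = pmax))
    current <- setdiff(current, victim)
    fit <- NULL
  }
  list(fit = fit, retained = current, n = length(time), trace = trace)
}

#' Proportional-hazards check via scaled Schoenfeld residuals
#'
#' Correlation test of the scaled Schoenfeld residuals against the rank of
#' event time, per covariate and globally.
#'
#' @param fit a [cox_fit()] result.
#' @return data.frame with rows per covariate plus `GLOBAL`, columns
#'   `term`, `chi2`, `df`, `p`.
#' @export
schoenfeld_ph_test <- function(fit) {
  stopifnot(inherits(fit, "cox_fit"))
  stop_if(fit$n_event < 3, "need at least 3 events for the PH test")
  zph <- survival::cox.zph(fit$fit, transform = "rank")
  tab <- as.data.frame(zph$table)
  data.frame(term = rownames(tab), chi2 = tab$chisq, df = tab$df,
             p = tab$p, row.names = NULL)
}

#' Harrell's concordance index
#'
#' Fraction of usable patient pairs whose risk scores are ordered
#' concordantly with their outcomes; ties in score count 0.5. Pairs that
#' are both censored, or where the shorter time is censored, are not
#' usable. Higher scores mean higher risk (shorter survival).
#'
#' @param scores finite numeric risk scores.
#' @param time,event follow-up times and 0/1 event indicators.
#' @return concordance in \[0, 1\].
#' @export
harrell_cindex <- function(scores, time, event) {
  stop_if(any(!is.finite(scores)), "scores must be finite")
  cf <- survival::concordance(survival::Surv(time, event) ~ scores,
                              reverse = TRUE)
  counts <- cf$count
  usable <- counts["concordant"] + counts["discordant"] + counts["tied.x"]
  stop_if(usable == 0, "no usable pairs")
  unname(cf$concordance)
}

#' Build a Cox linear-predictor scoring function
#'
#' Returns a model-spec closure for [optimism_corrected_cindex()]: given a
#' training data.frame (columns `time`, `event` and the covariates), fits
#' a Cox model and returns a function scoring new data by linear
#' predictor.
#'
#' @param covariate_names character vector of covariate columns.
#' @return function(train) -> function(newdata) -> numeric risk scores.
#' @export
cox_score_builder <- function(covariate_names) {
  force(covariate_names)
  function(train) {
    fit <- cox_fit(train$time, train$event,
                   train[, covariate_names, drop = FALSE])
    beta <- stats::coef(fit$fit)
    function(newdata) {
      mm <- stats::model.matrix(
        stats::reformulate(covariate_names),
        data = newdata
      )[, -1, drop = FALSE]
      drop(mm %*% beta)
    }
  }
}

#' Bias-corrected c-index by Harrell's optimism bootstrap
#'
#' For each of `rounds` bootstrap resamples, the model is refitted on the
#' resample and its c-index on the resample minus its c-index on the
#' original data is recorded; the mean difference is the optimism, and the
#' bias-corrected c-index is the apparent c-index minus the optimism.
#' Resamples without any event (or on which the model cannot be refitted)
#' are redrawn and counted.
#'
#' @param data data.frame with columns `time`, `event` and whatever
#'   `score_fun` needs.
#' @param score_fun model spec: function(train) returning a scoring
#'   function(newdata) -> numeric risk scores (see [cox_score_builder()]).
#' @param rounds bootstrap rounds (default 1000); 0 gives optimism 0.
#' @param seed integer seed controlling the resampling.
#' @return object of class `performance_report`: `apparent`, `optimism`,
#'   `corrected` (= apparent - optimism), `rounds`, `n_redrawn`,
#'   per-round `optimism_draws`.
#' @export
optimism_corrected_cindex <- function(data, score_fun, rounds = 1000,
                                      seed = NULL) {
  stopifnot(all(c("time", "event") %in% names(data)))
  stop_if(rounds < 0, "rounds must be >= 0")
  if (!is.null(seed)) set.seed(seed)
  scorer <- score_fun(data)
  apparent <- harrell_cindex(scorer(data), data$time, data$event)
  draws <- numeric(0)
  n_redrawn <- 0L
  n <- nrow(data)
  r <- 0L
  while (r < rounds) {
    idx <- sample.int(n, n, replace = TRUE)
    boot <- data[idx, , drop = FALSE]
    if (sum(boot$event) == 0) {
      n_redrawn <- n_redrawn + 1L
      next
    }
    res <- tryCatch({
      m <- score_fun(boot)
      c_boot <- harrell_cindex(m(boot), boot$time, boot$event)
      c_orig <- harrell_cindex(m(data), data$time, data$event)
      c_boot - c_orig
    }, error = function(e) NULL)
    if (is.null(res)) {
      n_redrawn <- n_redrawn + 1L
      next
    }
    draws <- c(draws, res)
    r <- r + 1L
  }
  optimism <- if (rounds == 0) 0 else mean(draws)
  structure(
    list(apparent = apparent, optimism = optimism,
         corrected = apparent - optimism, rounds = rounds,
         n_redrawn = n_redrawn, optimism_draws = draws),
    class = "performance_report"
  )
}

#' @export
print.performance_report <- function(x, ...) {
  cat(sprintf(
    "c-index: apparent %.3f, optimism %.3f (%d rounds, %d redrawn), bias-corrected %.3f\n",
    x$apparent, x$optimism, x$rounds, x$n_redrawn, x$corrected))
  invisible(x)
}

#' Calibration pairs at a fixed horizon
#'
#' Groups patients (by risk-scheme label or linear-predictor quantile) and
#' compares the mean model-predicted survival at the horizon with the
#' Kaplan-Meier observed survival at the horizon, per group.
#'
#' @param predicted per-patient predicted survival probability at
#'   `horizon` (in \[0, 1\]).
#' @param time,event follow-up times and 0/1 event indicators.
#' @param group grouping vector; each group must still have patients at
#'   risk (or events resolved) by `horizon`.
#' @param horizon evaluation time in years (default 5).
#' @return data.frame: `group`, `n`, `predicted` (group mean), `observed`
#'   (KM at horizon), `lower`, `upper` (log-log 95% CI).
#' @export
calibration_at <- function(predicted, time, event, group, horizon = 5) {
  stop_if(horizon < 0, "horizon must be >= 0")
  group <- droplevels(factor(group))
  out <- lapply(levels(group), function(g) {
    i <- group == g
    if (horizon == 0) {
      return(data.frame(group = g, n = sum(i),
                        predicted = mean(predicted[i]),
                        observed = 1, lower = 1, upper = 1))
    }
    km <- km_estimate(time[i], event[i])
    # undefined beyond last follow-up unless survival has already hit 0
    stop_if(max(time[i]) < horizon && km$surv[length(km$surv)] > 0,
            sprintf("group '%s' has no follow-up reaching the horizon", g))
    data.frame(group = g, n = sum(i),
               predicted = mean(predicted[i]),
               observed = km_survival(km, horizon),
               lower = km_survival(km, horizon, "lower"),
               upper = km_survival(km, horizon, "upper"))
  })
  do.call(rbind, out)
}
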