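test_that("Kaplan-Meier matches the hand product-limit computation", {
  km <- km_estimate(c(1, 2, 3), c(1, 1, 0))
  # S(2) = (1 - 1/3)(1 - 1/2) = 1/3
  expect_equal(km_survival(km, 2), 1 / 3, tolerance = 1e-12)
  expect_equal(km_survival(km, 1.5), 2 / 3, tolerance = 1e-12)
  expect_equal(km_survival(km, 0.5), 1)

  # Greenwood variance at t = 2: S^2 * (1/(3*2) + 1/(2*1))
  i <- which(km$time == 2)
  expect_equal(km$var[i], (1 / 3)^2 * (1 / 6 + 1 / 2), tolerance = 1e-12)

  # all censored: flat at 1
  km2 <- km_estimate(c(1, 2, 3), c(0, 0, 0))
  expect_equal(km_survival(km2, 10), 1)

  # single patient, event at 5: right-continuous step
  km3 <- km_estimate(5, 1)
  expect_equal(km_survival(km3, 4.9), 1)
  expect_equal(km_survival(km3, 5), 0)

  expect_error(km_estimate(c(-1, 2), c(1, 1)), "finite")
})

test_that("KM without censoring is the empirical survival function", {
  set.seed(10)
  t <- round(rexp(40), 2)
  km <- km_estimate(t, rep(1, 40))
  for (q in c(0.1, 0.5, 1, 2)) {
    expect_equal(km_survival(km, q), mean(t > q), tolerance = 1e-12)
  }
})

test_that("log-rank test matches a hand O-E table and handles groups", {
  # identical groups
  lr <- logrank_test(rep(c(1, 2, 3), 2), rep(1, 6), rep(c("a", "b"), each = 3))
  expect_equal(lr$chi2, 0, tolerance = 1e-12)

  # toy 6-patient two-group data vs explicit O-E computation
  time <- c(1, 2, 3, 4, 5, 6)
  event <- c(1, 1, 0, 1, 1, 1)
  g <- c(TRUE, FALSE, TRUE, TRUE, FALSE, FALSE)
  lr2 <- logrank_test(time, event, g)
  expect_equal(lr2$chi2, brute_logrank2(time, event, g), tolerance = 1e-10)

  # three groups: df = 2
  lr3 <- logrank_test(c(1, 2, 3, 4, 5, 6), rep(1, 6), rep(1:3, 2))
  expect_equal(lr3$df, 2)

  expect_error(logrank_test(1:4, rep(0, 4), rep(1:2, 2)), "event")
})

test_that("log-rank equals the Cox score test for a binary covariate", {
  set.seed(20)
  for (rep in 1:5) {
    n <- 30
    time <- rexp(n) # continuous: tie-free
    event <- rbinom(n, 1, 0.7)
    g <- rbinom(n, 1, 0.5)
    if (length(unique(g[event == 1])) < 2) next
    lr <- logrank_test(time, event, g)
    sc <- survival::coxph(survival::Surv(time, event) ~ g)$score
    expect_equal(lr$chi2, unname(sc), tolerance = 1e-6)
  }
})

test_that("Cox partial likelihood matches brute-force risk-set evaluation", {
  time <- c(2, 5, 7, 11)
  event <- c(1, 1, 0, 1)
  x <- c(0.5, -1, 2, 0)
  fit <- cox_fit(time, event, data.frame(x = x))
  beta <- fit$table$coef[1]
  expect_equal(fit$loglik, brute_cox_loglik(beta, time, event, x),
               tolerance = 1e-8)
  # the fitted coefficient maximises the brute-force likelihood
  expect_gt(fit$loglik, brute_cox_loglik(beta + 0.05, time, event, x))
  expect_gt(fit$loglik, brute_cox_loglik(beta - 0.05, time, event, x))
})

test_that("Cox fit recovers null and planted hazard ratios", {
  null_dat <- sim_binary_cohort(1000, hr = 1, seed = 30)
  fit0 <- cox_fit(null_dat$time, null_dat$event, null_dat["x"])
  expect_lt(abs(fit0$table$coef[1]), 0.15)
  expect_true(fit0$table$ci_lower[1] < 1 && 1 < fit0$table$ci_upper[1])

  dat <- sim_binary_cohort(2000, hr = 0.5, seed = 31)
  fit <- cox_fit(dat$time, dat$event, dat["x"])
  expect_gt(fit$table$hr[1], 0.4)
  expect_lt(fit$table$hr[1], 0.6)

  expect_error(cox_fit(dat$time, dat$event, data.frame(z = rep(1, 2000))),
               "constant")
})

test_that("Cox coefficient recovery is unbiased across seeds", {
  coefs <- vapply(1:20, function(s) {
    dat <- sim_binary_cohort(2000, hr = 0.5, seed = 100 + s)
    cox_fit(dat$time, dat$event, dat["x"])$table$coef[1]
  }, numeric(1))
  expect_lt(abs(mean(coefs) - log(0.5)), 0.05)
})

test_that("monotone likelihood (group without events) is flagged", {
  time <- c(1, 2, 3, 4, 5, 6, 7, 8)
  event <- c(1, 1, 1, 1, 0, 0, 0, 0)
  x <- c(0, 0, 0, 0, 1, 1, 1, 1) # no events among x = 1
  fit <- cox_fit(time, event, data.frame(x = x))
  expect_true(fit$monotone)
})

test_that("backwards selection keeps planted effects and drops noise", {
  # one strong (true HR 2.5) and one null covariate: the strong one is
  # always kept; the null one is dropped at the expected ~90% rate
  runs <- lapply(1:10, function(s) {
    dat <- sim_binary_cohort(2000, hr = 2.5, seed = 40 + s)
    set.seed(60 + s)
    dat$noise <- rnorm(2000)
    backward_select(dat$time, dat$event, dat[c("x", "noise")])
  })
  expect_true(all(vapply(runs, function(r) "x" %in% r$retained, logical(1))))
  dropped <- vapply(runs, function(r) !"noise" %in% r$retained, logical(1))
  expect_gte(sum(dropped), 7)

  # single strong candidate is retained unchanged
  dat <- sim_binary_cohort(2000, hr = 2.5, seed = 41)
  sel2 <- backward_select(dat$time, dat$event, dat["x"])
  expect_equal(sel2$retained, "x")
  expect_equal(nrow(sel2$trace), 0)

  # all-null candidates: empty retained set in the majority of seeds
  empty <- vapply(1:20, function(s) {
    nd <- sim_binary_cohort(300, hr = 1, seed = 200 + s)
    nd$z <- rnorm(300)
    length(backward_select(nd$time, nd$event, nd[c("x", "z")])$retained) == 0
  }, logical(1))
  expect_gt(mean(empty), 0.5)
})

test_that("Schoenfeld PH test separates proportional from time-varying", {
  ph_p <- vapply(1:50, function(s) {
    dat <- sim_binary_cohort(300, hr = 2, seed = 300 + s)
    fit <- cox_fit(dat$time, dat$event, dat["x"])
    tab <- schoenfeld_ph_test(fit)
    tab$p[tab$term == "GLOBAL"]
  }, numeric(1))
  expect_gte(mean(ph_p > 0.01), 0.90)

  # effect reverses at the (baseline) median: piecewise-exponential
  # hazard for the exposed arm, 4x baseline early and a third of it late
  tv_p <- vapply(1:50, function(s) {
    set.seed(400 + s)
    n <- 500
    x <- rbinom(n, 1, 0.5)
    m <- log(2) / 0.3
    r_early <- ifelse(x == 1, 0.6, 0.15)
    r_late <- ifelse(x == 1, 0.05, 0.15)
    t_ev <- rexp(n, r_early)
    late <- t_ev >= m
    t_ev[late] <- m + rexp(sum(late), r_late[late])
    cens <- runif(n, 5, 25)
    dat <- data.frame(time = pmin(t_ev, cens),
                      event = as.integer(t_ev <= cens), x = x)
    fit <- cox_fit(dat$time, dat$event, dat["x"])
    tab <- schoenfeld_ph_test(fit)
    tab$p[tab$term == "GLOBAL"]
  }, numeric(1))
  expect_gte(mean(tv_p < 0.05), 0.90)

  few <- cox_fit(c(1, 2, 3, 4), c(1, 0, 0, 0), data.frame(x = c(1, 0, 1, 0)))
  expect_error(schoenfeld_ph_test(few), "3 events")
})

test_that("c-index matches brute-force pair enumeration and extremes", {
  # perfect ordering, no censoring
  t <- c(5, 4, 3, 2, 1)
  expect_equal(harrell_cindex(c(1, 2, 3, 4, 5), t, rep(1, 5)), 1)
  # all scores equal: 0.5 by tie convention
  expect_equal(harrell_cindex(rep(2, 5), t, rep(1, 5)), 0.5)

  # toy sets with censoring vs enumeration oracle
  set.seed(50)
  for (rep in 1:10) {
    n <- 8
    time <- round(rexp(n), 3) # tie-free
    event <- rbinom(n, 1, 0.7)
    if (sum(event) == 0) next
    scores <- sample(1:4, n, replace = TRUE)
    expect_equal(harrell_cindex(scores, time, event),
                 brute_cindex(scores, time, event), tolerance = 1e-12)
  }
})

test_that("c-index is invariant to strictly monotone score transforms", {
  set.seed(60)
  time <- rexp(50); event <- rbinom(50, 1, 0.6); sc <- rnorm(50)
  base <- harrell_cindex(sc, time, event)
  expect_equal(harrell_cindex(exp(sc), time, event), base)
  expect_equal(harrell_cindex(3 * sc - 7, time, event), base)
  expect_equal(harrell_cindex(rank(sc), time, event), base)
})

test_that("optimism bootstrap: identity, determinism, direction", {
  dat <- sim_binary_cohort(150, hr = 0.5, seed = 70)
  builder <- cox_score_builder("x")

  r0 <- optimism_corrected_cindex(dat, builder, rounds = 0)
  expect_equal(r0$optimism, 0)
  expect_equal(r0$corrected, r0$apparent)

  r1 <- optimism_corrected_cindex(dat, builder, rounds = 25, seed = 71)
  r2 <- optimism_corrected_cindex(dat, builder, rounds = 25, seed = 71)
  expect_identical(r1, r2)
  expect_equal(r1$corrected, r1$apparent - r1$optimism)

  # overfit-prone spec: 10 null covariates at n = 60 inflate the
  # apparent c-index, so optimism is positive
  set.seed(72)
  over <- sim_binary_cohort(60, hr = 1, seed = 73)
  for (k in 1:10) over[[paste0("z", k)]] <- rnorm(60)
  ro <- optimism_corrected_cindex(over,
                                  cox_score_builder(paste0("z", 1:10)),
                                  rounds = 40, seed = 74)
  expect_gt(ro$optimism, 0)
})

test_that("calibration pairs behave at the horizon", {
  # perfectly specified exponential model at n = 5000
  set.seed(80)
  n <- 5000
  rate <- runif(n, 0.02, 0.3)
  t_ev <- rexp(n, rate)
  cens <- runif(n, 0, 15)
  time <- pmin(t_ev, cens); event <- as.integer(t_ev <= cens)
  pred5 <- exp(-5 * rate)
  grp <- cut(pred5, quantile(pred5, 0:4 / 4), include.lowest = TRUE,
             labels = c("q1", "q2", "q3", "q4"))
  cal <- calibration_at(pred5, time, event, grp, horizon = 5)
  expect_lt(max(abs(cal$predicted - cal$observed)), 0.05)

  # single group: observed equals the cohort KM at the horizon exactly
  km <- km_estimate(time, event)
  cal1 <- calibration_at(pred5, time, event, rep("all", n), horizon = 5)
  expect_equal(cal1$observed, km_survival(km, 5))

  # horizon 0: all pairs (1, 1)
  cal0 <- calibration_at(rep(1, n), time, event, grp, horizon = 0)
  expect_true(all(cal0$observed == 1))

  expect_error(
    calibration_at(c(0.9, 0.8), c(1, 2), c(0, 0), c("a", "a"), horizon = 5),
    "horizon")
})
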