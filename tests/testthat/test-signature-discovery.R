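test_that("signature rules validate, serialize and match", {
  rule <- signature_rule(c("7+", "8-", "11-"), 2)
  expect_equal(format_rule(rule), "7+,8-,11-;k=2")
  expect_equal(parse_rule("7+,8-,11-;k=2"), rule)

  expect_error(signature_rule(character(), 1), "non-empty")
  expect_error(signature_rule(c("7+", "7+"), 1), "duplicate")
  expect_error(signature_rule(c("7+", "7-"), 1), "one direction")
  expect_error(signature_rule(c("7+", "8-"), 3), "k must be")
  expect_error(signature_rule("banana", 1), "look like")

  feat <- cbind("7+" = c(TRUE, TRUE, FALSE, NA),
                "8-" = c(TRUE, FALSE, FALSE, TRUE),
                "11-" = c(FALSE, FALSE, TRUE, TRUE))
  expect_equal(rule_matches(rule, feat), c(TRUE, FALSE, FALSE, TRUE))
  expect_error(rule_matches(signature_rule("21-", 1), feat), "not in matrix")
})

test_that("candidate enumeration filters and orders by frequency", {
  n <- 100
  feat <- cbind("7+" = rep(c(TRUE, FALSE), c(40, 60)),
                "8-" = rep(c(TRUE, FALSE), c(30, 70)),
                "11-" = rep(c(TRUE, FALSE), c(20, 80)),
                "3-" = rep(c(TRUE, FALSE), c(2, 98)))
  cand <- enumerate_candidates(feat, min_freq = 0.05)
  expect_equal(cand$feature, c("7+", "8-", "11-"))
  expect_equal(cand$frequency, c(0.4, 0.3, 0.2))

  expect_equal(nrow(enumerate_candidates(feat, min_freq = 1.0)), 0)
  expect_error(enumerate_candidates(feat[0, , drop = FALSE]), "empty")
})

test_that("rule scoring agrees with the formula-interface estimators", {
  co <- generate_cohort(cohort_config(400, seed = 90))
  feat <- wca_features(co$wca)
  rule <- signature_rule(c("7+", "8-", "11-"), 2)
  sc <- score_rule(rule, feat, co$clinical$pfs_years, co$clinical$pfs_event)
  pos <- rule_matches(rule, feat)

  lr <- logrank_test(co$clinical$pfs_years, co$clinical$pfs_event, pos)
  expect_equal(sc$logrank_chi2, lr$chi2, tolerance = 1e-9)
  expect_equal(sc$logrank_p, lr$p, tolerance = 1e-9)

  fit <- cox_fit(co$clinical$pfs_years, co$clinical$pfs_event,
                 data.frame(pos = as.numeric(pos)))
  expect_equal(sc$hazard_ratio, fit$table$hr[1], tolerance = 1e-7)

  cr <- harrell_cindex(as.numeric(pos), co$clinical$pfs_years,
                       co$clinical$pfs_event)
  expect_equal(sc$cindex, max(cr, 1 - cr), tolerance = 1e-12)
})

test_that("degenerate rules are kept with flagged null scores", {
  feat <- cbind("7+" = rep(FALSE, 10), "8-" = rep(TRUE, 10))
  time <- 1:10; event <- rep(1, 10)
  sc <- score_rule(signature_rule("7+", 1), feat, time, event)
  expect_true(sc$degenerate)
  expect_true(is.na(sc$logrank_p))
  expect_equal(sc$n_positive, 0)

  # near-empty classes are not testable: flagged, kept with null score
  feat3 <- cbind("7+" = rep(c(TRUE, FALSE), c(2, 98)))
  sc3 <- score_rule(signature_rule("7+", 1), feat3,
                    seq_len(100), rep(1, 100))
  expect_true(sc3$degenerate)
  expect_equal(sc3$n_positive, 2)

  # two groups with identical survival: chi2 ~ 0, p ~ 1
  feat2 <- cbind("7+" = rep(c(TRUE, FALSE), each = 4))
  sc2 <- score_rule(signature_rule("7+", 1), feat2,
                    rep(c(1, 2, 3, 4), 2), rep(1, 8))
  expect_lt(sc2$logrank_chi2, 1e-10)
  expect_gt(sc2$logrank_p, 0.999)
})

test_that("planted favourable rule scores protective and significant", {
  rule <- signature_rule(c("7+", "8-", "11-"), 2)
  cfg <- cohort_config(2000, seed = 91,
                       planted = list(rule = rule, hr = 0.3,
                                      baseline_s5 = 0.6))
  co <- generate_cohort(cfg)
  feat <- wca_features(co$wca)
  sc <- score_rule(rule, feat, co$clinical$pfs_years, co$clinical$pfs_event)
  expect_lt(sc$hazard_ratio, 1)
  expect_lt(sc$logrank_p, 0.001)
})

test_that("the search space is enumerated exhaustively and ranked totally", {
  co <- generate_cohort(cohort_config(500, seed = 92))
  feat <- wca_features(co$wca)
  # 3 candidates, all subsets x thresholds: 3*1 + 3*2 + 1*3 = 12 rules
  ranked <- search_signatures(feat, co$clinical$pfs_years,
                              co$clinical$pfs_event,
                              candidates = c("7+", "8-", "11-"),
                              max_set_size = 3)
  expect_equal(nrow(ranked), 12)
  expect_equal(ranked$rank, 1:12)

  # both directions of one chromosome never co-occur in a rule
  ranked2 <- search_signatures(feat, co$clinical$pfs_years,
                               co$clinical$pfs_event,
                               candidates = c("7+", "7-", "8-"),
                               max_set_size = 3)
  expect_false(any(grepl("7\\+.*7-|7-.*7\\+", ranked2$rule)))

  # single candidate: exactly one rule
  one <- search_signatures(feat, co$clinical$pfs_years,
                           co$clinical$pfs_event, candidates = "7+")
  expect_equal(nrow(one), 1)

  # deterministic ranking
  again <- search_signatures(feat, co$clinical$pfs_years,
                             co$clinical$pfs_event,
                             candidates = c("7+", "8-", "11-"),
                             max_set_size = 3)
  expect_identical(ranked, again)

  expect_error(search_signatures(feat, co$clinical$pfs_years,
                                 co$clinical$pfs_event,
                                 candidates = character()), "no candidate")
})

test_that("planted signature is recovered as the top-ranked rule", {
  rule <- signature_rule(c("7+", "8-", "11-"), 2)
  hits <- vapply(1:5, function(s) {
    cfg <- cohort_config(2000, seed = 500 + s,
                         planted = list(rule = rule, hr = 0.3,
                                        baseline_s5 = 0.6))
    co <- generate_cohort(cfg)
    feat <- wca_features(co$wca)
    ranked <- search_signatures(feat, co$clinical$pfs_years,
                                co$clinical$pfs_event, max_set_size = 3)
    ranked$rule[1] == "7+,8-,11-;k=2"
  }, logical(1))
  expect_gte(sum(hits), 4)
})

test_that("association matrix recovers co-occurrence and independence", {
  # perfectly co-occurring features: Fisher p from hypergeometric
  a <- rep(c(TRUE, FALSE), each = 10)
  feat <- cbind("7+" = a, "8-" = a, "11-" = rep(c(TRUE, FALSE), 10))
  res <- wca_association_matrix(feat)
  pair <- res$pairs[res$pairs$feature_a == "7+" &
                      res$pairs$feature_b == "8-", ]
  expect_gt(pair$log_odds_ratio, 0)
  expect_equal(pair$p, 2 / choose(20, 10), tolerance = 1e-10)
  expect_equal(pair$p,
               brute_fisher2x2(table(factor(a, c(FALSE, TRUE)),
                                     factor(a, c(FALSE, TRUE)))),
               tolerance = 1e-10)

  # no self-pairs
  expect_false(any(res$pairs$feature_a == res$pairs$feature_b))

  # constant features are excluded and reported
  feat2 <- cbind(feat, "3-" = rep(FALSE, 20))
  res2 <- wca_association_matrix(feat2)
  expect_true("3-" %in% res2$excluded)

  # independent features: small association, non-significant typically
  set.seed(93)
  n <- 5000
  ind <- cbind("7+" = runif(n) < 0.3, "8-" = runif(n) < 0.3,
               "11-" = runif(n) < 0.2)
  res3 <- wca_association_matrix(ind)
  expect_lt(max(abs(res3$pairs$phi)), 0.05)
  expect_gt(min(res3$pairs$p_adj), 0.05)
})
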