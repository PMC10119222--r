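# Fixture builders and independent brute-force oracles. The oracles are
# deliberately naive (pair enumeration, explicit risk-set products,
# hand O-E tables) and never share code with the implementation paths
# they check.

ACRO_P <- c(13, 14, 15, 21, 22)

# Build a full 44-arm seg table for one patient; `states` is a named
# vector like c("7p" = "gain", "17q" = "gain"); unnamed arms are neutral
# (acrocentric p arms not assessable).
make_seg <- function(patient_id = "P1", states = c()) {
  seg <- expand.grid(chrom = 1:22, arm = c("p", "q"),
                     stringsAsFactors = FALSE)
  seg$patient_id <- patient_id
  seg$state <- ifelse(seg$chrom %in% ACRO_P & seg$arm == "p",
                      NA_character_, "neutral")
  for (nm in names(states)) {
    chrom <- as.integer(sub("[pq]$", "", nm))
    arm <- sub("^[0-9]+", "", nm)
    seg$state[seg$chrom == chrom & seg$arm == arm] <- states[[nm]]
  }
  seg[, c("patient_id", "chrom", "arm", "state")]
}

# Seg table where whole chromosomes are gained/lost (both assessable arms).
make_seg_whole <- function(patient_id = "P1", gains = c(), losses = c()) {
  states <- c()
  for (ch in gains) {
    states[paste0(ch, "q")] <- "gain"
    if (!ch %in% ACRO_P) states[paste0(ch, "p")] <- "gain"
  }
  for (ch in losses) {
    states[paste0(ch, "q")] <- "loss"
    if (!ch %in% ACRO_P) states[paste0(ch, "p")] <- "loss"
  }
  make_seg(patient_id, states)
}

# Harrell's c-index by explicit pair enumeration (higher score = higher
# risk). Usable pairs: distinct observed times where the earlier time is
# an event, or tied times with exactly one event.
brute_cindex <- function(scores, time, event) {
  n <- length(time)
  conc <- disc <- tied <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (time[i] == time[j]) {
      # tied times: usable only if exactly one is an event (the event
      # patient is the worse outcome)
      if (event[i] + event[j] != 1) next
      a <- if (event[i] == 1) i else j
      b <- if (event[i] == 1) j else i
    } else {
      a <- if (time[i] < time[j]) i else j   # earlier observation
      b <- if (time[i] < time[j]) j else i
      if (event[a] != 1) next                # censored-first pair unusable
    }
    if (scores[a] > scores[b]) conc <- conc + 1
    else if (scores[a] < scores[b]) disc <- disc + 1
    else tied <- tied + 1
  }
  (conc + 0.5 * tied) / (conc + disc + tied)
}

# Two-group log-rank chi-square from an explicit observed-minus-expected
# table over event times.
brute_logrank2 <- function(time, event, g) {
  ut <- sort(unique(time[event == 1]))
  O1 <- E1 <- V <- 0
  for (t in ut) {
    at_risk <- time >= t
    n <- sum(at_risk); n1 <- sum(at_risk & g)
    d <- sum(event == 1 & time == t)
    d1 <- sum(event == 1 & time == t & g)
    O1 <- O1 + d1
    E1 <- E1 + d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  (O1 - E1)^2 / V
}

# Cox log partial likelihood (no ties) at a given coefficient, by
# explicit risk-set sums.
brute_cox_loglik <- function(beta, time, event, x) {
  ll <- 0
  for (i in which(event == 1)) {
    risk <- time >= time[i]
    ll <- ll + beta * x[i] - log(sum(exp(beta * x[risk])))
  }
  ll
}

# Two-sided Fisher p for a 2x2 table by hypergeometric enumeration
# (probability-mass method, as fisher.test uses).
brute_fisher2x2 <- function(tab) {
  m <- sum(tab[1, ]); n <- sum(tab[2, ]); k <- sum(tab[, 1])
  support <- max(0, k - n):min(k, m)
  probs <- dhyper(support, m, n, k)
  p_obs <- dhyper(tab[1, 1], m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Independent reading of the three-tier risk rule, straight from the
# verbal definition (favourable: M0 and (WCA-FR or subgroup 7);
# very-high: M+ and WCA-HR; high: the rest).
oracle_grp4_risk <- function(m, wca, sg) {
  if (m == "M0" && (wca == "WCA-FR" || sg == "7")) "favourable"
  else if (m == "M+" && wca == "WCA-HR") "very_high"
  else "high"
}

# Small survival fixture with a known planted binary effect.
sim_binary_cohort <- function(n, hr, seed, p_pos = 0.3, base_rate = 0.15,
                              cens_max = 12) {
  set.seed(seed)
  x <- rbinom(n, 1, p_pos)
  t_ev <- rexp(n, rate = base_rate * hr^x)
  t_cn <- runif(n, 0, cens_max)
  data.frame(time = pmin(t_ev, t_cn), event = as.integer(t_ev <= t_cn),
             x = x)
}
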