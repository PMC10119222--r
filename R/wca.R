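# Whole-chromosome aberration (WCA) and isochromosome 17q calling from
# arm-level copy number, and classification into the favourable-risk
# signature group (WCA-FR: >= 2 of chr7 gain, chr8 loss, chr11 loss)
# versus its complement (WCA-HR).
#
# Input is a seg-style long table: one row per (patient_id, chrom, arm)
# with either a mean log2 ratio (`log2`) or a categorical `state` in
# {loss, neutral, gain}. Acrocentric short arms (13p, 14p, 15p, 21p, 22p)
# carry no assessable array content and are treated as not-assessable
# (NA state); those chromosomes are called on the q arm alone. Sex
# chromosomes are excluded throughout.

ARM_STATES <- c("loss", "neutral", "gain")

#' Call categorical arm states from mean log2 ratios
#'
#' An arm is called gain if its log2 ratio is at least `gain_thr`, loss if
#' at most `loss_thr`, otherwise neutral. Rows that already carry a
#' categorical state pass through unchanged; acrocentric p-arm rows stay
#' not-assessable.
#'
#' @param seg data.frame with columns `patient_id`, `chrom` (1-22),
#'   `arm` ("p"/"q") and `log2` and/or `state`.
#' @param gain_thr,loss_thr log2-ratio thresholds; must satisfy
#'   `loss_thr < 0 < gain_thr`. Defaults +/-0.15.
#' @return the seg table with a filled `state` column.
#' @export
call_arm_states <- function(seg, gain_thr = 0.15, loss_thr = -0.15) {
  seg <- validate_seg(seg)
  stop_if(!(loss_thr < 0 && 0 < gain_thr),
          "thresholds must satisfy loss_thr < 0 < gain_thr")
  if (is.null(seg$state)) seg$state <- NA_character_
  acro <- seg$chrom %in% ACROCENTRIC_P & seg$arm == "p"
  todo <- is.na(seg$state) & !acro
  if (any(todo)) {
    stop_if(is.null(seg$log2), "no log2 column to call states from")
    lg <- seg$log2[todo]
    stop_if(any(!is.finite(lg)),
            "non-finite log2 ratio in assessable arm rows")
    seg$state[todo] <- ifelse(lg >= gain_thr, "gain",
                              ifelse(lg <= loss_thr, "loss", "neutral"))
  }
  bad <- !is.na(seg$state) & !(seg$state %in% ARM_STATES)
  stop_if(any(bad), "invalid arm state: ",
          paste(unique(seg$state[bad]), collapse = ", "))
  seg$state[acro] <- NA_character_
  seg
}

validate_seg <- function(seg) {
  seg <- as.data.frame(seg)
  need <- c("patient_id", "chrom", "arm")
  miss <- setdiff(need, names(seg))
  stop_if(length(miss) > 0, "seg table missing column(s): ",
          paste(miss, collapse = ", "))
  seg$chrom <- as.integer(seg$chrom)
  stop_if(any(!seg$chrom %in% AUTOSOMES),
          "chrom must be an autosome 1-22")
  stop_if(any(!seg$arm %in% c("p", "q")), "arm must be 'p' or 'q'")
  seg
}

#' Call per-chromosome whole-chromosome aberrations and i17q
#'
#' A chromosome is called a whole-chromosome gain (loss) when all of its
#' assessable arms are gained (lost); acrocentric chromosomes are called
#' on the q arm alone. Isochromosome 17q (17p loss with 17q gain) is
#' called as its own marker, in which case chromosome 17's whole-call is
#' neutral; i17q never contributes to the WCA counts. A chromosome with
#' no assessable arm is unassessable (NA call) and excluded from counts.
#'
#' @param seg arm-level table with categorical `state` (see
#'   [call_arm_states()]).
#' @return data.frame of class `wca_profile`, one row per patient:
#'   `patient_id`, `chr1` ... `chr22` calls in {gain, neutral, loss, NA},
#'   `i17q`, `n_gains`, `n_losses`, `n_total`, `wca_class`.
#' @export
call_wca_profile <- function(seg) {
  seg <- validate_seg(seg)
  stop_if(is.null(seg$state), "seg table has no state column; run call_arm_states()")
  patients <- unique(seg$patient_id)
  pid_i <- match(seg$patient_id, patients)
  # one column per (chromosome, arm): p arms 1..22, q arms 23..44
  col_i <- seg$chrom + ifelse(seg$arm == "q", 22L, 0L)
  states <- matrix(NA_character_, nrow = length(patients), ncol = 44)
  states[cbind(pid_i, col_i)] <- seg$state

  calls <- matrix(NA_character_, nrow = length(patients), ncol = 22,
                  dimnames = list(NULL, paste0("chr", AUTOSOMES)))
  for (ch in AUTOSOMES) {
    p <- states[, ch]
    q <- states[, ch + 22L]
    n_avail <- (!is.na(p)) + (!is.na(q))
    all_gain <- n_avail > 0 &
      (is.na(p) | p == "gain") & (is.na(q) | q == "gain")
    all_loss <- n_avail > 0 &
      (is.na(p) | p == "loss") & (is.na(q) | q == "loss")
    calls[, ch] <- ifelse(n_avail == 0, NA_character_,
                          ifelse(all_gain, "gain",
                                 ifelse(all_loss, "loss", "neutral")))
  }
  i17q <- !is.na(states[, 17]) & !is.na(states[, 39]) &
    states[, 17] == "loss" & states[, 39] == "gain"
  calls[i17q, 17] <- "neutral"
  n_gains <- rowSums(calls == "gain", na.rm = TRUE)
  n_losses <- rowSums(calls == "loss", na.rm = TRUE)

  wca <- data.frame(patient_id = patients, as.data.frame(calls),
                    i17q = i17q, n_gains = n_gains, n_losses = n_losses,
                    n_total = n_gains + n_losses)
  wca$wca_class <- classify_wca(wca)
  class(wca) <- c("wca_profile", "data.frame")
  wca
}

#' Classify tumours into WCA-FR versus WCA-HR
#'
#' The favourable-risk signature counts S = \[chr7 = gain\] +
#' \[chr8 = loss\] + \[chr11 = loss\]; a tumour is WCA-FR when S >= 2 and
#' WCA-HR otherwise. If any of chromosomes 7, 8 or 11 is unassessable the
#' class is `"unassessable"`. Aberrations on other chromosomes never
#' change the class.
#'
#' @param wca a `wca_profile` data.frame (or any data.frame with `chr7`,
#'   `chr8`, `chr11` call columns).
#' @return character vector: `"WCA-FR"`, `"WCA-HR"` or `"unassessable"`.
#' @export
classify_wca <- function(wca) {
  stopifnot(all(c("chr7", "chr8", "chr11") %in% names(wca)))
  s <- (wca$chr7 == "gain") + (wca$chr8 == "loss") + (wca$chr11 == "loss")
  out <- ifelse(is.na(s), "unassessable",
                ifelse(s >= 2, "WCA-FR", "WCA-HR"))
  out
}

#' Binary feature matrix of whole-chromosome events (plus i17q)
#'
#' Expands a `wca_profile` table into per-patient logical columns named
#' `"7+"`, `"8-"`, ... (chromosome number plus direction, `+` gain,
#' `-` loss) and `"i17q"`. Used by the signature search and association
#' analyses.
#'
#' @param wca a [call_wca_profile()] result.
#' @param include_i17q include the i17q column (default TRUE).
#' @return logical matrix with rownames = patient ids.
#' @export
wca_features <- function(wca, include_i17q = TRUE) {
  cols <- lapply(AUTOSOMES, function(ch) {
    call <- wca[[paste0("chr", ch)]]
    cbind(gain = call == "gain", loss = call == "loss")
  })
  mat <- do.call(cbind, cols)
  colnames(mat) <- as.vector(vapply(
    AUTOSOMES, function(ch) c(paste0(ch, "+"), paste0(ch, "-")),
    character(2)))
  if (include_i17q) mat <- cbind(mat, i17q = wca$i17q)
  rownames(mat) <- wca$patient_id
  mat
}
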