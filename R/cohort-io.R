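# File interfaces: tab-separated cohort and seg-style arm copy-number
# tables with explicit "NA" missing markers, plain-text scheme-spec and
# pipeline-config files, survival-cohort eligibility filtering, and
# provenance records sufficient to reproduce deterministic stages.

CLINICAL_COLUMNS <- c("patient_id", "age_years", "sex", "m_stage",
                      "resection", "histology", "radiotherapy", "csi_dose",
                      "chemotherapy", "myc_amp", "mycn_amp", "subgroup",
                      "pfs_years", "pfs_event")

SEG_COLUMNS <- c("patient_id", "chrom", "arm", "state")

#' Restrict a cohort to survival-analysis-eligible patients
#'
#' Retains patients aged at least 3 years who received craniospinal
#' irradiation and whose PFS time and event are recorded; every exclusion
#' is counted per criterion (a patient can fail several).
#'
#' @param clinical clinical data.frame (see [read_cohort()] schema).
#' @return list: `eligible` (the retained rows), `n_excluded`,
#'   `exclusions` (named per-criterion counts: `age_lt_3`, `no_csi`,
#'   `missing_outcome`).
#' @export
filter_survival_cohort <- function(clinical) {
  age_ok <- !is.na(clinical$age_years) & clinical$age_years >= 3
  csi_ok <- !is.na(clinical$radiotherapy) & clinical$radiotherapy == "CSI"
  outcome_ok <- !is.na(clinical$pfs_years) & !is.na(clinical$pfs_event)
  keep <- age_ok & csi_ok & outcome_ok
  list(
    eligible = clinical[keep, , drop = FALSE],
    n_excluded = sum(!keep),
    exclusions = c(age_lt_3 = sum(!age_ok), no_csi = sum(!csi_ok),
                   missing_outcome = sum(!outcome_ok))
  )
}

read_tsv_checked <- function(path, required, col_classes) {
  stop_if(!file.exists(path), "file not found: ", path)
  df <- utils::read.delim(path, na.strings = "NA", sep = "\t",
                          colClasses = "character",
                          check.names = FALSE)
  unknown <- setdiff(names(df), required)
  stop_if(length(unknown) > 0, "unknown column(s) in ", path, ": ",
          paste(unknown, collapse = ", "))
  miss <- setdiff(required, names(df))
  stop_if(length(miss) > 0, "missing column(s) in ", path, ": ",
          paste(miss, collapse = ", "))
  for (col in names(col_classes)) {
    raw <- df[[col]]
    parsed <- switch(col_classes[[col]],
      numeric = suppressWarnings(as.numeric(raw)),
      integer = suppressWarnings(as.integer(raw)),
      logical = as.logical(raw),
      raw)
    bad <- which(!is.na(raw) & is.na(parsed))
    stop_if(length(bad) > 0,
            sprintf("non-parseable %s value in '%s' at data line(s) %s",
                    col_classes[[col]], col,
                    paste(utils::head(bad, 5), collapse = ", ")))
    df[[col]] <- parsed
  }
  df
}

#' Read / write a cohort as tab-separated text
#'
#' The clinical table uses the documented fixed header
#' (`patient_id`, `age_years`, `sex`, `m_stage`, `resection`,
#' `histology`, `radiotherapy`, `csi_dose`, `chemotherapy`, `myc_amp`,
#' `mycn_amp`, `subgroup`, `pfs_years`, `pfs_event`); the arm
#' copy-number table is seg-style (`patient_id`, `chrom`, `arm`,
#' `state`). Missing values are written and read as the token `NA`;
#' write-then-read is the identity on all fields. Unknown columns,
#' non-parseable values (reported with line numbers) and duplicate
#' patient ids are errors.
#'
#' @param clinical_path path to the clinical TSV.
#' @param arm_cn_path optional path to the arm copy-number TSV.
#' @return list with `clinical` and (if requested) `arm_cn` data.frames.
#' @export
read_cohort <- function(clinical_path, arm_cn_path = NULL) {
  clinical <- read_tsv_checked(
    clinical_path, CLINICAL_COLUMNS,
    c(age_years = "numeric", chemotherapy = "logical",
      myc_amp = "logical", mycn_amp = "logical",
      pfs_years = "numeric", pfs_event = "integer"))
  dup <- clinical$patient_id[duplicated(clinical$patient_id)]
  stop_if(length(dup) > 0, "duplicate patient_id: ",
          paste(unique(dup), collapse = ", "))
  out <- list(clinical = clinical)
  if (!is.null(arm_cn_path)) {
    seg <- read_tsv_checked(arm_cn_path, SEG_COLUMNS,
                            c(chrom = "integer"))
    extra <- setdiff(unique(seg$patient_id), clinical$patient_id)
    stop_if(length(extra) > 0, "arm table has unknown patient_id: ",
            paste(utils::head(extra, 5), collapse = ", "))
    out$arm_cn <- validate_seg(seg)
  }
  out
}

#' @rdname read_cohort
#' @param cohort a `synthetic_cohort` or a list with `clinical` and
#'   optionally `arm_cn`.
#' @param dir output directory (created if needed).
#' @return `write_cohort`: invisibly, the written file paths
#'   (`clinical.tsv`, `arm_cn.tsv`, `provenance.txt`).
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(clinical = file.path(dir, "clinical.tsv"))
  utils::write.table(cohort$clinical, paths["clinical"], sep = "\t",
                     quote = FALSE, row.names = FALSE, na = "NA")
  if (!is.null(cohort$arm_cn)) {
    paths["arm_cn"] <- file.path(dir, "arm_cn.tsv")
    utils::write.table(cohort$arm_cn[SEG_COLUMNS], paths["arm_cn"],
                       sep = "\t", quote = FALSE, row.names = FALSE,
                       na = "NA")
  }
  if (!is.null(cohort$provenance)) {
    paths["provenance"] <- write_provenance(cohort$provenance, dir)
  }
  invisible(paths)
}

write_provenance <- function(prov, dir) {
  path <- file.path(dir, "provenance.txt")
  cfg <- prov$config
  lines <- c(
    sprintf("package_version: %s", prov$package_version %||%
              as.character(utils::packageVersion("grp4risk"))),
    sprintf("seed: %d", prov$seed),
    sprintf("n_patients: %d", cfg$n_patients),
    sprintf("subgroup_probs: %s",
            paste(sprintf("%s=%g", names(cfg$subgroup_probs),
                          cfg$subgroup_probs), collapse = ",")),
    sprintf("metastatic_prob: %g", cfg$metastatic_prob),
    sprintf("survival_targets: %s",
            paste(sprintf("%s=%g", names(cfg$survival_targets),
                          cfg$survival_targets), collapse = ",")),
    sprintf("follow_up_years: %g", cfg$follow_up_years)
  )
  writeLines(lines, path)
  md5 <- unname(tools::md5sum(path))
  cat(sprintf("config_md5: %s\n", md5), file = path, append = TRUE)
  path
}

#' Write analysis report tables to a directory
#'
#' Each element of `results` is written as `<name>.tsv`; data.frames go
#' out as tab-separated tables, everything else as printed text.
#'
#' @param results named list of data.frames (or printable objects).
#' @param dir output directory.
#' @return invisibly, the written paths.
#' @export
write_reports <- function(results, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  for (nm in names(results)) {
    x <- results[[nm]]
    if (is.data.frame(x)) {
      p <- file.path(dir, paste0(nm, ".tsv"))
      utils::write.table(x, p, sep = "\t", quote = FALSE,
                         row.names = FALSE, na = "NA")
    } else {
      p <- file.path(dir, paste0(nm, ".txt"))
      utils::capture.output(print(x), file = p)
    }
    paths[nm] <- p
  }
  invisible(paths)
}

#' Read a scheme spec from a plain-text config file
#'
#' Format, one rule per line, evaluated in order:
#' ```
#' id: clinical
#' labels: standard, high
#' default: standard
#' m_stage == "M+" | histology == "LCA" -> high
#' ```
#' Lines starting with `#` are comments.
#'
#' @param path config file path.
#' @return a [scheme_spec()].
#' @export
read_scheme_spec <- function(path) {
  stop_if(!file.exists(path), "file not found: ", path)
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  take <- function(key) {
    hit <- grep(paste0("^", key, ":"), lines, value = TRUE)
    stop_if(length(hit) != 1, "scheme file needs exactly one '", key, ":' line")
    trimws(sub(paste0("^", key, ":"), "", hit))
  }
  id <- take("id")
  labels <- trimws(strsplit(take("labels"), ",")[[1]])
  default_label <- take("default")
  rule_lines <- grep("->", lines, value = TRUE, fixed = TRUE)
  rules <- lapply(rule_lines, function(ln) {
    parts <- strsplit(ln, "->", fixed = TRUE)[[1]]
    stop_if(length(parts) != 2, "malformed rule line: ", ln)
    list(predicate = str2lang(trimws(parts[1])), label = trimws(parts[2]))
  })
  scheme_spec(id, rules, default_label, labels)
}

#' Read a pipeline configuration file
#'
#' Plain-text `key: value` file. Recognised keys (all optional, shown
#' with defaults): `gain_thr` (0.15), `loss_thr` (-0.15), `min_freq`
#' (0.05), `max_set_size` (5), `horizon` (5), `rounds` (1000), `seed`
#' (1), `out_dir` ("."), plus free-form path entries.
#'
#' @param path config file path.
#' @return named list of class `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  stop_if(!file.exists(path), "file not found: ", path)
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- strsplit(lines, ":", fixed = TRUE)
  cfg <- list(gain_thr = 0.15, loss_thr = -0.15, min_freq = 0.05,
              max_set_size = 5, horizon = 5, rounds = 1000, seed = 1,
              out_dir = ".")
  for (pair in kv) {
    stop_if(length(pair) < 2, "malformed config line: ",
            paste(pair, collapse = ":"))
    key <- trimws(pair[1])
    val <- trimws(paste(pair[-1], collapse = ":"))
    num <- suppressWarnings(as.numeric(val))
    cfg[[key]] <- if (!is.na(num)) num else val
  }
  stop_if(cfg$horizon <= 0, "horizon must be > 0")
  stop_if(cfg$rounds < 0, "rounds must be >= 0")
  structure(cfg, class = "pipeline_config")
}
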