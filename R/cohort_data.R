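# Column dictionary for the patient table. Each entry: type plus, for
# enumerations, the admissible levels. `core` columns are required in both
# dialects; the rest are required only in the "fixture" dialect.
.patient_columns <- list(
  patient_id         = list(type = "character", core = TRUE),
  sex                = list(type = "enum", levels = c("M", "F")),
  age_years          = list(type = "numeric", min = 1),
  histology          = list(type = "enum",
                            levels = c("oligodendroglioma", "oligoastrocytoma",
                                       "astrocytoma", "GBM")),
  who_grade          = list(type = "enum", levels = c("II", "III", "IV")),
  idh1_status        = list(type = "enum",
                            levels = c("mutant", "wildtype", "unavailable")),
  codeletion_status  = list(type = "enum",
                            levels = c("codeleted", "non_codeleted",
                                       "unavailable")),
  tumor_location     = list(type = "character"),
  aed                = list(type = "character"),
  tumor_volume_cm3   = list(type = "numeric", min = 0),
  eor_percent        = list(type = "numeric", min = 76, max = 100),
  adjuvant_treatment = list(type = "enum",
                            levels = c("rt_plus_chemo", "rt_alone", "none")),
  kps                = list(type = "numeric", min = 70, max = 100),
  time_weeks         = list(type = "numeric", min = 1e-12, core = TRUE),
  event              = list(type = "binary", core = TRUE),
  oba_global_z       = list(type = "numeric", core = TRUE),
  nlgn3_tier         = list(type = "enum",
                            levels = c("low", "moderate", "high",
                                       "unavailable"))
)

#' Load and validate a patient table
#'
#' Reads a CSV of one row per patient carrying survival (progression-free
#' survival in weeks and a progression indicator), the cohort-based z-score
#' of global oscillatory brain activity, the semi-quantitative NLGN3
#' expression tier, and clinical covariates. Two dialects are supported:
#' `"fixture"` expects the full column dictionary (see
#' [patient_column_dictionary()]) and additionally checks the invariants of
#' the packaged 24-patient diffuse-glioma cohort, warning on any mismatch;
#' `"user"` requires only the analysis-critical columns (`patient_id`,
#' `time_weeks`, `event`, `oba_global_z`), matched case-insensitively, and
#' runs no cohort-count checks.
#'
#' @param path Path to a CSV file with a header row.
#' @param dialect `"fixture"` or `"user"`.
#' @param quiet Suppress the one-line load summary.
#' @return A validated `data.frame`, one row per patient.
#' @examples
#' tab <- load_patient_table(oscillomark_fixture_path())
#' table(tab$nlgn3_tier)
#' @export
load_patient_table <- function(path, dialect = c("fixture", "user"),
                               quiet = FALSE) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) {
    stop("patient table not found: ", path)
  }
  tab <- tryCatch(
    utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE),
    error = function(e) stop("schema error: cannot parse '", path, "': ",
                             conditionMessage(e))
  )
  if (nrow(tab) == 0L || ncol(tab) == 0L) {
    stop("schema error: '", path, "' contains no patient rows")
  }

  if (dialect == "user") {
    names(tab) <- .canonicalise_names(names(tab))
  }
  required <- if (dialect == "fixture") {
    names(.patient_columns)
  } else {
    names(.patient_columns)[vapply(.patient_columns,
                                   function(x) isTRUE(x$core), logical(1))]
  }
  missing_cols <- setdiff(required, names(tab))
  if (length(missing_cols)) {
    stop("schema error: missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }

  tab <- .validate_patient_rows(tab)

  if (dialect == "fixture") {
    .check_fixture_invariants(tab)
  }
  if (!quiet) {
    message(sprintf("loaded %d patients (%d progression events) from %s",
                    nrow(tab), sum(tab$event), basename(path)))
  }
  tab
}

.canonicalise_names <- function(nms) {
  canon <- names(.patient_columns)
  idx <- match(tolower(nms), tolower(canon))
  ifelse(is.na(idx), nms, canon[idx])
}

.validate_patient_rows <- function(tab) {
  if (!"patient_id" %in% names(tab)) {
    stop("schema error: missing column(s): patient_id")
  }
  ids <- as.character(tab$patient_id)
  if (anyDuplicated(ids)) {
    stop("duplicate patient_id: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  for (col in intersect(names(.patient_columns), names(tab))) {
    sp <- .patient_columns[[col]]
    x <- tab[[col]]
    if (sp$type %in% c("numeric", "binary")) {
      xn <- suppressWarnings(as.numeric(x))
      bad <- which(!is.na(x) & x != "" & is.na(xn))
      if (length(bad)) {
        stop("row-level error: patient ", ids[bad[1L]], ": column '", col,
             "' value '", x[bad[1L]], "' is not numeric")
      }
      if (sp$type == "binary" && any(!xn %in% c(0, 1), na.rm = TRUE)) {
        bad <- which(!xn %in% c(0, 1) & !is.na(xn))
        stop("row-level error: patient ", ids[bad[1L]], ": column '", col,
             "' must be 0 or 1")
      }
      if (!is.null(sp$min) && any(xn < sp$min, na.rm = TRUE)) {
        bad <- which(xn < sp$min)
        stop("row-level error: patient ", ids[bad[1L]], ": column '", col,
             "' value ", xn[bad[1L]], " below ", sp$min)
      }
      if (!is.null(sp$max) && any(xn > sp$max, na.rm = TRUE)) {
        bad <- which(xn > sp$max)
        stop("row-level error: patient ", ids[bad[1L]], ": column '", col,
             "' value ", xn[bad[1L]], " above ", sp$max)
      }
      tab[[col]] <- xn
    } else if (sp$type == "enum") {
      xc <- as.character(x)
      bad <- which(!is.na(xc) & !xc %in% sp$levels)
      if (length(bad)) {
        stop("row-level error: patient ", ids[bad[1L]], ": column '", col,
             "' value '", xc[bad[1L]], "' not one of {",
             paste(sp$levels, collapse = ", "), "}")
      }
      tab[[col]] <- xc
    } else {
      tab[[col]] <- as.character(x)
    }
  }
  tab$event <- as.integer(tab$event)
  tab
}

.check_fixture_invariants <- function(tab) {
  if (nrow(tab) != 24L) {
    warning("fixture dialect: expected 24 patients, found ", nrow(tab),
            " (count mismatch)")
  }
  if (sum(tab$event) != 17L) {
    warning("fixture dialect: expected 17 progression events, found ",
            sum(tab$event))
  }
  if ("nlgn3_tier" %in% names(tab)) {
    counts <- table(factor(tab$nlgn3_tier,
                           levels = c("low", "moderate", "high",
                                      "unavailable")))
    if (!identical(as.integer(counts), c(12L, 6L, 3L, 3L))) {
      warning("fixture dialect: NLGN3 tier counts ",
              paste(counts, collapse = "/"), " differ from expected 12/6/3/3")
    }
  }
  z <- tab$oba_global_z
  if (abs(mean(z)) > 0.02 || abs(stats::sd(z) - 1) > 0.05) {
    warning(sprintf(paste0("fixture dialect: global z-scores have mean %.3f",
                           " / SD %.3f; expected ~0 / ~1"),
                    mean(z), stats::sd(z)))
  }
  invisible(tab)
}

#' Write a patient table to CSV
#'
#' Inverse of [load_patient_table()]: writing then re-reading a table is the
#' identity on every field.
#'
#' @param records Patient table (`data.frame`).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_patient_table <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Path to the packaged 24-patient glioma cohort
#'
#' Returns the path of the CSV shipped with the package: 24 newly diagnosed
#' diffuse-glioma patients with progression-free survival (weeks from the
#' preoperative MEG), a progression indicator, the cohort-based z-score of
#' global broadband (0.5-48 Hz) oscillatory power, the NLGN3 expression tier
#' (low/moderate/high, 3 unavailable) and clinical covariates.
#'
#' @return File path (character scalar).
#' @export
oscillomark_fixture_path <- function() {
  system.file("extdata", "glioma_cohort.csv", package = "oscillomark",
              mustWork = TRUE)
}

#' Load the packaged glioma cohort
#'
#' Convenience wrapper: [load_patient_table()] on
#' [oscillomark_fixture_path()] with the `"fixture"` dialect.
#'
#' @param quiet Suppress the load summary message.
#' @return The validated 24-patient table.
#' @export
glioma_cohort <- function(quiet = TRUE) {
  load_patient_table(oscillomark_fixture_path(), dialect = "fixture",
                     quiet = quiet)
}

#' The patient-table column dictionary
#'
#' @return A `data.frame` describing every column of the patient CSV: name,
#'   type, and admissible values for enumerations.
#' @export
patient_column_dictionary <- function() {
  data.frame(
    column = names(.patient_columns),
    type = vapply(.patient_columns, function(x) x$type, character(1)),
    levels = vapply(.patient_columns, function(x) {
      if (x$type == "enum") paste(x$levels, collapse = "|") else ""
    }, character(1)),
    row.names = NULL
  )
}

#' Encode clinical covariates for confounder models
#'
#' Produces the covariate codings used by the bivariate Cox confounder
#' models, as pure functions of the patient table:
#'
#' * `age_le40` — 1 if age is 40 or under, 0 if over 40.
#' * `age_continuous` — age in years.
#' * `sex_code` — 1 male, 0 female.
#' * `kps_le80` — 1 if Karnofsky performance status is 80 or less, 0 if 90
#'   or more.
#' * `grade_ii` — 1 for WHO grade II, 0 for grade III-IV (grade II is the
#'   indicated level in the confounder models).
#' * `histology_code` — ordinal 1 oligodendroglioma, 2 oligoastrocytoma,
#'   3 astrocytoma/GBM.
#' * `idh1_code` — 1 wildtype, 0 mutant, `NA` unavailable.
#' * `molecular_3group` — 2016 WHO molecular groups: 1 IDH-mutant with
#'   1p/19q codeletion, 2 IDH-mutant non-codeleted, 3 IDH-wildtype. An
#'   IDH1-mutant astrocytoma without a 1p/19q assessment is labelled
#'   non-codeleted (group 2), the cohort's retrospective rule; a mutant
#'   non-astrocytoma without assessment stays `NA`; a wildtype record
#'   annotated as codeleted is contradictory under the 2016 scheme and is
#'   marked unclassifiable (`NA`).
#' * `treatment_code` — ordinal 1 radiotherapy plus chemotherapy,
#'   2 radiotherapy alone, 3 none.
#' * `volume_cm3` — tumor volume.
#'
#' Missing inputs propagate to `NA`; model fitting drops incomplete rows
#' listwise per model.
#'
#' @param records Validated patient table.
#' @return A `data.frame` of encodings, one row per patient.
#' @export
encode_covariates <- function(records) {
  idh <- records$idh1_status
  cod <- records$codeletion_status
  idh1_code <- ifelse(idh == "wildtype", 1,
                      ifelse(idh == "mutant", 0, NA_real_))
  # retrospective 1p/19q labelling for mutant astrocytomas
  cod_eff <- cod
  retro <- idh == "mutant" & records$histology == "astrocytoma" &
    cod == "unavailable"
  cod_eff[retro] <- "non_codeleted"
  molecular <- ifelse(
    idh == "wildtype" & cod != "codeleted", 3,
    ifelse(idh == "mutant" & cod_eff == "codeleted", 1,
           ifelse(idh == "mutant" & cod_eff == "non_codeleted", 2,
                  NA_real_)))
  data.frame(
    patient_id = records$patient_id,
    age_le40 = as.numeric(records$age_years <= 40),
    age_continuous = records$age_years,
    sex_code = as.numeric(records$sex == "M"),
    kps_le80 = as.numeric(records$kps <= 80),
    grade_ii = as.numeric(records$who_grade == "II"),
    histology_code = c(oligodendroglioma = 1, oligoastrocytoma = 2,
                       astrocytoma = 3, GBM = 3)[records$histology],
    idh1_code = idh1_code,
    molecular_3group = molecular,
    treatment_code = c(rt_plus_chemo = 1, rt_alone = 2,
                       none = 3)[records$adjuvant_treatment],
    volume_cm3 = records$tumor_volume_cm3,
    row.names = NULL
  )
}
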