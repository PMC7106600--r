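#' The 25-item Psychological Vulnerability Questionnaire schema
#'
#' Returns the column dictionary of the PVQ cohort format: the five OQ-45.2
#' items (answer positions 0--4 on a frequency Likert scale), six DEQ items
#' (1 = totally agree .. 7 = totally disagree), fourteen RFL items
#' (1 = not important .. 6 = extremely important), eight sociodemographic
#' fields and the suicidal-behavior status. Item responses are stored exactly
#' as answer positions; reverse keying is a scoring concern (see
#' [score_oq()]), never applied at ingest.
#'
#' @param age_bands Which age-band coding to use: `"table7"` (bands
#'   18-28, 28-38, ..., >78, the instrument's printed coding) or `"table3"`
#'   (14-19, 20-29, ..., 60+, the enrollment coding). The two codings are
#'   both in circulation for this instrument; neither is asserted as
#'   canonical. Band intervals are left-closed: an age equal to a shared
#'   boundary (e.g. 28 under the `"table7"` coding) falls in the upper band.
#' @return A list with elements `items` (tibble: column, instrument, item,
#'   min, max), `demographics` (named list of level vectors), `sb_levels`,
#'   and `columns` (the full ordered column set of a cohort file).
#' @export
#' @examples
#' sch <- pvq_schema()
#' sch$items
pvq_schema <- function(age_bands = c("table7", "table3")) {
  age_bands <- match.arg(age_bands)
  items <- tibble::tibble(
    column = c(
      paste0("oq_", c(3, 8, 13, 24, 31)),
      paste0("deq_", c(3, 16, 19, 48, 56, 62)),
      paste0("rfl_", c(2, 5, 10, 12, 14, 17, 19, 20, 22, 24, 25, 40, 45, 50))
    ),
    instrument = rep(c("oq", "deq", "rfl"), c(5L, 6L, 14L)),
    item = c(3, 8, 13, 24, 31, 3, 16, 19, 48, 56, 62,
             2, 5, 10, 12, 14, 17, 19, 20, 22, 24, 25, 40, 45, 50),
    min = rep(c(0L, 1L, 1L), c(5L, 6L, 14L)),
    max = rep(c(4L, 7L, 6L), c(5L, 6L, 14L))
  )
  age_levels <- switch(age_bands,
    table7 = c("18-28", "28-38", "38-48", "48-58", "58-68", "68-78", ">78"),
    table3 = c("14-19", "20-29", "30-39", "40-49", "50-59", "60+")
  )
  demographics <- list(
    diagnosis = c("mild_depressive", "moderate_depressive", "major_depressive",
                  "bipolar", "adjustment", "anxiety", "mixed_episode",
                  "dysthymia", "other"),
    children = c("0", "1", "2", "3", "4", "5+"),
    gender = c("woman", "man", "other"),
    age_band = age_levels,
    schooling = c("basic", "secondary", "technical", "university"),
    cohabitation = c("alone", "friends", "couple", "family"),
    marital_status = c("single", "married", "separated", "widow", "free_union"),
    occupation = c("employed", "student", "unemployed", "housewife",
                   "retired/not_working")
  )
  sb_levels <- c("none", "ideation", "attempt_low_severity",
                 "attempt_high_severity")
  list(
    items = items,
    demographics = demographics,
    sb_levels = sb_levels,
    age_bands = age_bands,
    columns = c("patient_id", items$column, names(demographics), "sb_status")
  )
}

#' Convert a raw age in years to an age band
#'
#' Bands are left-closed: a boundary age belongs to the lower band.
#'
#' @param age Numeric vector of ages in years.
#' @param schema A schema from [pvq_schema()]; its `age_bands` choice decides
#'   the band set.
#' @return Character vector of band labels.
#' @export
age_to_band <- function(age, schema = pvq_schema()) {
  lv <- schema$demographics$age_band
  if (schema$age_bands == "table7") {
    idx <- findInterval(age, c(18, 28, 38, 48, 58, 68))  # left-closed bands
    idx[age > 78] <- 7L           # ">78" is strictly above the last band
  } else {
    idx <- findInterval(age, c(14, 20, 30, 40, 50, 60))
  }
  idx[idx < 1L] <- NA_integer_
  lv[idx]
}

#' Validate a cohort tibble against the PVQ schema
#'
#' Checks that all schema columns are present, every item response lies in
#' its declared scale range, every categorical field uses a declared level,
#' and `sb_status` is present for every record.
#'
#' @param cohort A data frame with one row per patient.
#' @param schema Schema from [pvq_schema()].
#' @return A tibble of validation problems (patient_id, field, value,
#'   problem); zero rows when the cohort is valid. A missing required column
#'   is an error, not a problem row.
#' @export
validate_cohort <- function(cohort, schema = pvq_schema()) {
  cohort <- tibble::as_tibble(cohort)
  missing_cols <- setdiff(schema$columns, names(cohort))
  if (length(missing_cols) > 0) {
    rlang::abort(
      paste0("cohort is missing required column(s): ",
             paste(missing_cols, collapse = ", ")),
      class = "pvq_schema_error"
    )
  }
  probs <- list()
  pid <- as.character(cohort$patient_id)
  for (i in seq_len(nrow(schema$items))) {
    col <- schema$items$column[i]
    v <- cohort[[col]]
    bad <- which(is.na(v) | v != round(v) | v < schema$items$min[i] |
                   v > schema$items$max[i])
    if (length(bad) > 0) {
      probs[[length(probs) + 1L]] <- tibble::tibble(
        patient_id = pid[bad], field = col, value = as.character(v[bad]),
        problem = "out_of_range"
      )
    }
  }
  for (col in names(schema$demographics)) {
    v <- as.character(cohort[[col]])
    bad <- which(is.na(v) | !(v %in% schema$demographics[[col]]))
    if (length(bad) > 0) {
      probs[[length(probs) + 1L]] <- tibble::tibble(
        patient_id = pid[bad], field = col, value = v[bad],
        problem = "invalid_level"
      )
    }
  }
  v <- as.character(cohort$sb_status)
  bad <- which(is.na(v) | !(v %in% schema$sb_levels))
  if (length(bad) > 0) {
    probs[[length(probs) + 1L]] <- tibble::tibble(
      patient_id = pid[bad], field = "sb_status", value = v[bad],
      problem = "invalid_level"
    )
  }
  if (length(probs) == 0) {
    tibble::tibble(patient_id = character(), field = character(),
                   value = character(), problem = character())
  } else {
    dplyr::bind_rows(probs)
  }
}

#' Read a PVQ cohort from CSV
#'
#' Reads a UTF-8 CSV with one row per patient and the column dictionary of
#' [pvq_schema()]. In strict mode any invalid value aborts with the
#' offending patient, field and value; otherwise invalid records are dropped
#' with a warning that counts them.
#'
#' @param path File path.
#' @param strict Abort on the first invalid record instead of dropping it.
#' @param schema Schema from [pvq_schema()].
#' @return A validated cohort tibble. The number of dropped records is
#'   attached as attribute `"n_dropped"`.
#' @export
read_cohort <- function(path, strict = FALSE, schema = pvq_schema()) {
  if (!file.exists(path)) {
    rlang::abort(paste0("cohort file does not exist: ", path),
                 class = "pvq_io_error")
  }
  header <- names(readr::read_csv(path, n_max = 0, show_col_types = FALSE,
                                  progress = FALSE))
  missing_cols <- setdiff(schema$columns, header)
  if (length(missing_cols) > 0) {
    rlang::abort(
      paste0("cohort file is missing required column(s): ",
             paste(missing_cols, collapse = ", ")),
      class = "pvq_schema_error"
    )
  }
  item_cols <- stats::setNames(
    rep(list(readr::col_double()), nrow(schema$items)), schema$items$column)
  cohort <- readr::read_csv(
    path, show_col_types = FALSE, progress = FALSE,
    col_types = do.call(readr::cols, c(
      list(patient_id = readr::col_character(),
           sb_status = readr::col_character()),
      item_cols
    ))
  )
  cohort <- cohort[, schema$columns]
  probs <- validate_cohort(cohort, schema)
  if (nrow(probs) > 0) {
    if (strict) {
      p <- probs[1, ]
      rlang::abort(
        sprintf("invalid value in cohort: patient_id=%s field=%s value=%s (%s)",
                p$patient_id, p$field, p$value, p$problem),
        class = "pvq_validation_error"
      )
    }
    bad_ids <- unique(probs$patient_id)
    rlang::warn(sprintf("dropped %d invalid record(s): %s",
                        length(bad_ids),
                        paste(utils::head(bad_ids, 5), collapse = ", ")))
    cohort <- cohort[!(as.character(cohort$patient_id) %in% bad_ids), ]
  }
  structure(cohort, n_dropped = if (nrow(probs) > 0) length(unique(probs$patient_id)) else 0L)
}

#' Write a PVQ cohort to CSV
#'
#' Columns are written in the stable schema order, so write-read-write
#' round-trips are byte-identical.
#'
#' @param cohort Validated cohort tibble.
#' @param path Output file path.
#' @param schema Schema from [pvq_schema()].
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path, schema = pvq_schema()) {
  cohort <- tibble::as_tibble(cohort)
  probs <- validate_cohort(cohort, schema)
  if (nrow(probs) > 0) {
    rlang::abort("refusing to write an invalid cohort; see validate_cohort()",
                 class = "pvq_validation_error")
  }
  readr::write_csv(cohort[, schema$columns], path, progress = FALSE)
  invisible(path)
}

#' Derive the binary suicidal-behavior group label
#'
#' A record belongs to the `with_sb` group when its status records suicidal
#' ideation or a suicide attempt (of either severity) within the preceding
#' year, and to `without_sb` otherwise.
#'
#' @param sb_status Character vector of statuses (`none`, `ideation`,
#'   `attempt_low_severity`, `attempt_high_severity`).
#' @return Character vector with levels `with_sb` / `without_sb`.
#' @export
#' @examples
#' derive_sb_group(c("none", "ideation", "attempt_high_severity"))
derive_sb_group <- function(sb_status) {
  sb_status <- as.character(sb_status)
  lv <- pvq_schema()$sb_levels
  bad <- sb_status[!sb_status %in% lv]
  if (length(bad) > 0) {
    rlang::abort(paste0("unknown sb_status value(s): ",
                        paste(unique(bad), collapse = ", ")),
                 class = "pvq_validation_error")
  }
  ifelse(sb_status == "none", "without_sb", "with_sb")
}
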