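# Long-format growth tables: reading, validation, inclusion filtering.
#
# The universal input is a cohort: one row per stature measurement with a
# subject id, sex (F/M), decimal age in years and stature in cm.  Validation
# is strict -- invalid rows abort the read rather than being dropped, since
# growth modelling is sensitive to silent data loss.

.SEX_CODES <- c(
  "F" = "F", "M" = "M", "f" = "F", "m" = "M",
  "female" = "F", "male" = "M", "Female" = "F", "Male" = "M"
)

#' Construct and validate a growth cohort
#'
#' @param data A data frame with columns `id`, `sex`, `age`, `stature`
#'   (decimal years and cm).
#' @return A validated `growth_cohort` data frame, sorted by subject then age.
#' @export
growth_cohort <- function(data) {
  need <- c("id", "sex", "age", "stature")
  miss <- setdiff(need, names(data))
  if (length(miss) > 0)
    sg_error(paste("missing columns:", paste(miss, collapse = ", ")),
             "sitargrowth_format_error")
  df <- data.frame(
    id = as.character(data$id),
    sex = as.character(data$sex),
    age = as.numeric(data$age),
    stature = as.numeric(data$stature),
    stringsAsFactors = FALSE
  )
  bad_sex <- !df$sex %in% names(.SEX_CODES)
  if (any(bad_sex))
    sg_error(sprintf("unrecognized sex code(s): %s (row %d)",
                     df$sex[which(bad_sex)[1]], which(bad_sex)[1]),
             "sitargrowth_validation_error")
  df$sex <- unname(.SEX_CODES[df$sex])
  if (anyNA(df$age) || any(!is.finite(df$age)))
    sg_error(sprintf("non-finite age (row %d)",
                     which(!is.finite(df$age))[1]),
             "sitargrowth_parse_error")
  if (anyNA(df$stature) || any(!is.finite(df$stature)))
    sg_error(sprintf("non-finite stature (row %d)",
                     which(!is.finite(df$stature))[1]),
             "sitargrowth_parse_error")
  if (any(df$age <= 0 | df$age >= 30))
    sg_error(sprintf("age outside (0, 30) (row %d)",
                     which(df$age <= 0 | df$age >= 30)[1]),
             "sitargrowth_validation_error")
  if (any(df$stature <= 50 | df$stature >= 230))
    sg_error(sprintf("stature outside (50, 230) cm (row %d)",
                     which(df$stature <= 50 | df$stature >= 230)[1]),
             "sitargrowth_validation_error")
  # one sex per subject
  sex_by_id <- tapply(df$sex, df$id, function(s) length(unique(s)))
  if (any(sex_by_id > 1))
    sg_error(sprintf("subject %s has more than one sex code",
                     names(sex_by_id)[sex_by_id > 1][1]),
             "sitargrowth_validation_error")
  ord <- order(df$id, df$age)
  df <- df[ord, , drop = FALSE]
  dup <- duplicated(df[, c("id", "age")])
  if (any(dup))
    sg_error(sprintf("duplicate (subject, age) measurement: subject %s at age %.4g (row %d of sorted data)",
                     df$id[dup][1], df$age[dup][1], which(dup)[1]),
             "sitargrowth_validation_error")
  rownames(df) <- NULL
  class(df) <- c("growth_cohort", "data.frame")
  df
}

#' Read a long-format growth table from CSV
#'
#' Expects a header row with columns `id,sex,age_years,stature_cm`;
#' `column_map` remaps non-default names, e.g.
#' `list(id = "child", age = "agedec")`.  Sex codes `F/M/female/male`
#' (any case) are normalized to `F`/`M`; other codings can be remapped via
#' `sex_codes`, e.g. `c("0" = "F", "1" = "M")`.
#'
#' @param path CSV file path.
#' @param column_map Optional named list mapping canonical names
#'   (`id`, `sex`, `age`, `stature`) to the file's column names.
#' @param sex_codes Optional named character vector translating the file's
#'   sex codes to `F`/`M`.
#' @return A validated [growth_cohort()].
#' @export
read_long_csv <- function(path, column_map = NULL, sex_codes = NULL) {
  if (!file.exists(path))
    sg_error(paste("file not found:", path), "sitargrowth_format_error")
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  defaults <- list(id = "id", sex = "sex", age = "age_years", stature = "stature_cm")
  map <- utils::modifyList(defaults, as.list(column_map %||% list()))
  miss <- unlist(map)[!unlist(map) %in% names(raw)]
  if (length(miss) > 0)
    sg_error(paste("missing column(s) in", path, ":", paste(miss, collapse = ", ")),
             "sitargrowth_format_error")
  df <- data.frame(
    id = raw[[map$id]], sex = raw[[map$sex]],
    age = suppressWarnings(as.numeric(raw[[map$age]])),
    stature = suppressWarnings(as.numeric(raw[[map$stature]])),
    stringsAsFactors = FALSE
  )
  bad_age <- is.na(df$age) & !is.na(raw[[map$age]])
  if (any(bad_age))
    sg_error(sprintf("non-numeric age %s (row %d)",
                     raw[[map$age]][bad_age][1], which(bad_age)[1]),
             "sitargrowth_parse_error")
  bad_st <- is.na(df$stature) & !is.na(raw[[map$stature]])
  if (any(bad_st))
    sg_error(sprintf("non-numeric stature %s (row %d)",
                     raw[[map$stature]][bad_st][1], which(bad_st)[1]),
             "sitargrowth_parse_error")
  if (!is.null(sex_codes)) {
    known <- df$sex %in% names(sex_codes)
    df$sex[known] <- unname(sex_codes[df$sex[known]])
  }
  cohort <- growth_cohort(df)
  message(sprintf("read %d records, %d subjects from %s",
                  nrow(cohort), length(unique(cohort$id)), path))
  cohort
}

#' Write a cohort as a long-format CSV
#'
#' Inverse of [read_long_csv()]: columns `id,sex,age_years,stature_cm`,
#' full precision.
#'
#' @param cohort A [growth_cohort()].
#' @param path Output file path.
#' @export
write_long_csv <- function(cohort, path) {
  stopifnot(inherits(cohort, "growth_cohort"))
  out <- data.frame(
    id = cohort$id, sex = cohort$sex,
    age_years = format(cohort$age, digits = 17, scientific = FALSE, trim = TRUE),
    stature_cm = format(cohort$stature, digits = 17, scientific = FALSE, trim = TRUE),
    stringsAsFactors = FALSE
  )
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Cohort inclusion criteria
#'
#' The default rules mirror longitudinal pubertal-growth practice: a subject
#' is included if it has (a) at least `min_measurements` measurements inside
#' the sex-specific pubertal window (closed interval, 9.9-14.0 y girls /
#' 10.9-15.0 y boys), (b) its first measurement inside the sex-specific
#' entry window, and (c) follow-up to at least the sex-specific minimum last
#' age.
#'
#' @param min_measurements Minimum number of in-window measurements.
#' @param pubertal_window Named list `F`/`M` of closed age intervals.
#' @param entry_window Named list `F`/`M` of closed age intervals for the
#'   first measurement.
#' @param min_followup_age Named list `F`/`M`: minimum age of the last
#'   measurement.
#' @export
inclusion_criteria <- function(min_measurements = 4,
                               pubertal_window = list(F = c(9.9, 14.0), M = c(10.9, 15.0)),
                               entry_window = list(F = c(6, 9.9), M = c(6, 10.9)),
                               min_followup_age = list(F = 14.0, M = 15.0)) {
  if (min_measurements < 1)
    sg_error("min_measurements must be >= 1", "sitargrowth_config_error")
  for (w in c(pubertal_window, entry_window))
    if (w[1] >= w[2])
      sg_error("interval lower bound must be below upper bound",
               "sitargrowth_config_error")
  structure(
    list(min_measurements = min_measurements, pubertal_window = pubertal_window,
         entry_window = entry_window, min_followup_age = min_followup_age),
    class = "inclusion_criteria"
  )
}

#' Apply the cohort inclusion filter
#'
#' Pure subject-level row selection: surviving records are untouched, and
#' the filter is idempotent.
#'
#' @param cohort A [growth_cohort()].
#' @param criteria An [inclusion_criteria()] object.
#' @return A list with elements `cohort` (the filtered cohort) and `report`
#'   (one row per subject with logical columns `rule_a`, `rule_b`, `rule_c`
#'   and `included`).
#' @export
apply_inclusion_filter <- function(cohort, criteria = inclusion_criteria()) {
  stopifnot(inherits(cohort, "growth_cohort"), inherits(criteria, "inclusion_criteria"))
  ids <- unique(cohort$id)
  report <- do.call(rbind, lapply(ids, function(i) {
    rec <- cohort[cohort$id == i, ]
    sex <- rec$sex[1]
    pw <- criteria$pubertal_window[[sex]]
    ew <- criteria$entry_window[[sex]]
    fu <- criteria$min_followup_age[[sex]]
    data.frame(
      id = i, sex = sex,
      rule_a = sum(rec$age >= pw[1] & rec$age <= pw[2]) >= criteria$min_measurements,
      rule_b = rec$age[1] >= ew[1] && rec$age[1] <= ew[2],
      rule_c = rec$age[nrow(rec)] >= fu,
      stringsAsFactors = FALSE
    )
  }))
  report$included <- report$rule_a & report$rule_b & report$rule_c
  keep <- report$id[report$included]
  out <- cohort[cohort$id %in% keep, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("growth_cohort", "data.frame")
  if (nrow(out) == 0)
    warning("inclusion filter excluded every subject")
  list(cohort = out, report = report)
}

#' Tabulate measurements per participant
#'
#' One row per distinct measurement count, mirroring the usual
#' "distribution of the number of measurements per participant" table of
#' longitudinal growth studies.
#'
#' @param cohort A [growth_cohort()].
#' @return Data frame with columns `count`, `all`, `F`, `M`; column sums
#'   partition the subject counts.
#' @export
measurement_count_table <- function(cohort) {
  stopifnot(inherits(cohort, "growth_cohort"))
  per_subj <- stats::aggregate(list(count = cohort$age),
                               by = list(id = cohort$id), FUN = length)
  sex <- cohort$sex[match(per_subj$id, cohort$id)]
  counts <- sort(unique(per_subj$count))
  data.frame(
    count = counts,
    all = vapply(counts, function(k) sum(per_subj$count == k), integer(1)),
    F = vapply(counts, function(k) sum(per_subj$count == k & sex == "F"), integer(1)),
    M = vapply(counts, function(k) sum(per_subj$count == k & sex == "M"), integer(1))
  )
}
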