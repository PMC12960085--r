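#' Column schema for cohort files
#'
#' Maps the column names of a delimited cohort file onto the fields of a
#' participant record. Defaults mirror the packaged derivation table.
#'
#' @param subject_id,ve_peak,age,weight,height,vo2peak,hr_max,vo2vent_measured,sex
#'   Column names in the input file. `vo2vent_measured` and `sex` may be
#'   absent from the file.
#' @return A named character vector of class `cohort_schema`.
#' @export
#' @examples
#' cohort_schema(vo2peak = "VO2max")
cohort_schema <- function(subject_id = "subject_id",
                          ve_peak = "ve_peak",
                          age = "age",
                          weight = "weight",
                          height = "height",
                          vo2peak = "vo2peak",
                          hr_max = "hr_max",
                          vo2vent_measured = "vo2vent_measured",
                          sex = "sex") {
  structure(c(subject_id = subject_id, ve_peak = ve_peak, age = age,
              weight = weight, height = height, vo2peak = vo2peak,
              hr_max = hr_max, vo2vent_measured = vo2vent_measured,
              sex = sex),
            class = "cohort_schema")
}

# fields that must parse as numbers and their physiological ranges
.predictor_fields <- c("ve_peak", "age", "weight", "height", "vo2peak", "hr_max")

.field_ranges <- list(
  ve_peak = c(0, Inf), age = c(10, 100), weight = c(30, 200),
  height = c(120, 230), vo2peak = c(0, Inf), hr_max = c(60, 230)
)

# row-wise invariant check; returns character vector of violation messages
.check_records <- function(df) {
  msgs <- character(0)
  for (f in .predictor_fields) {
    rng <- .field_ranges[[f]]
    v <- df[[f]]
    lo_ok <- if (rng[1] == 0) v > 0 else v >= rng[1]
    bad <- which(!is.finite(v) | !lo_ok | v > rng[2])
    if (length(bad)) {
      msgs <- c(msgs, sprintf("row %d: %s = %s outside [%s, %s]",
                              bad, f, format(v[bad]), rng[1], rng[2]))
    }
  }
  if (!is.null(df$vo2vent_measured)) {
    m <- df$vo2vent_measured
    bad <- which(!is.na(m) & (m <= 0 | m >= df$vo2peak))
    if (length(bad)) {
      msgs <- c(msgs, sprintf(
        "row %d: vo2vent_measured = %s not in (0, vo2peak = %s)",
        bad, format(m[bad]), format(df$vo2peak[bad])))
    }
  }
  msgs
}

#' Construct a cohort table
#'
#' A cohort table is a data frame with one row per participant (or per trial,
#' before [select_peak_trials()]) and a `volume_condition` tag recording
#' whether expired-ventilation volumes are expressed STPD or BTPS. All model
#' fitting requires STPD.
#'
#' @param records Data frame with columns `subject_id`, `ve_peak` (L·min⁻¹),
#'   `age` (years), `weight` (kg), `height` (cm), `vo2peak` (L·min⁻¹),
#'   `hr_max` (beats·min⁻¹) and optionally `vo2vent_measured` (L·min⁻¹) and
#'   `sex` (`"F"`, `"M"` or `"unknown"`).
#' @param volume_condition `"STPD"` or `"BTPS"`.
#' @return An object of class `cohort_table` (a data frame).
#' @export
cohort_table <- function(records, volume_condition = c("STPD", "BTPS")) {
  volume_condition <- match.arg(volume_condition)
  records <- as.data.frame(records)
  need <- c("subject_id", .predictor_fields)
  miss <- setdiff(need, names(records))
  if (length(miss)) {
    vc_stop("schema_error", "missing column(s): ", paste(miss, collapse = ", "))
  }
  for (f in .predictor_fields) {
    if (!is.numeric(records[[f]])) {
      vc_stop("parse_error", "column '", f, "' is not numeric")
    }
  }
  if (is.null(records$sex)) records$sex <- "unknown"
  records$sex <- as.character(records$sex)
  records$sex[!records$sex %in% c("F", "M")] <- "unknown"
  msgs <- .check_records(records)
  if (length(msgs)) {
    vc_stop("validation_error", "invalid participant record(s):\n  ",
            paste(msgs, collapse = "\n  "))
  }
  structure(records,
            volume_condition = volume_condition,
            class = c("cohort_table", "data.frame"))
}

#' @export
print.cohort_table <- function(x, ...) {
  cat(sprintf("Cohort of %d record(s), %d subject(s), VE volumes %s\n",
              nrow(x), length(unique(x$subject_id)), volume_condition(x)))
  print(as.data.frame(x), ...)
  invisible(x)
}

#' Volume condition of a cohort or breath series
#'
#' @param x A [cohort_table()] or [rie_series()].
#' @return `"STPD"` or `"BTPS"`.
#' @export
volume_condition <- function(x) attr(x, "volume_condition")

#' Read a cohort from a delimited text file
#'
#' Reads a comma- (default) or tab-delimited file, maps its columns through a
#' [cohort_schema()], validates every row against the participant-record
#' invariants and returns a [cohort_table()]. Rows that violate an invariant
#' are reported with their row index; a missing mapped column is a schema
#' error and a non-numeric cell a parse error naming row and column.
#'
#' @param path File path.
#' @param schema A [cohort_schema()].
#' @param sep Field separator; `NULL` (default) tries comma then tab.
#' @param volume_condition Volume condition tag for the `ve_peak` column.
#' @return A [cohort_table()].
#' @export
#' @examples
#' t1 <- load_cohort(system.file("extdata", "table1_derivation.csv",
#'                               package = "ventcost"))
#' nrow(t1)  # 42
load_cohort <- function(path, schema = cohort_schema(), sep = NULL,
                        volume_condition = "STPD") {
  if (!file.exists(path)) vc_stop("schema_error", "file not found: ", path)
  read1 <- function(s) {
    utils::read.csv(path, sep = s, stringsAsFactors = FALSE,
                    colClasses = "character", check.names = FALSE)
  }
  raw <- if (is.null(sep)) {
    r <- tryCatch(read1(","), error = function(e) NULL)
    if (is.null(r) || ncol(r) < 2) r <- tryCatch(read1("\t"), error = function(e) NULL)
    r
  } else read1(sep)
  if (is.null(raw) || nrow(raw) == 0 || ncol(raw) < 2) {
    vc_stop("schema_error", "no parseable rows in ", path)
  }
  need <- c("subject_id", .predictor_fields)
  miss <- need[!schema[need] %in% names(raw)]
  if (length(miss)) {
    vc_stop("schema_error", "column(s) not found in file: ",
            paste(schema[miss], collapse = ", "))
  }
  out <- data.frame(subject_id = raw[[schema[["subject_id"]]]],
                    stringsAsFactors = FALSE)
  for (f in .predictor_fields) {
    v <- suppressWarnings(as.numeric(raw[[schema[[f]]]]))
    bad <- which(is.na(v) & !is.na(raw[[schema[[f]]]]) & nzchar(raw[[schema[[f]]]]))
    if (length(bad)) {
      vc_stop("parse_error", "non-numeric value in column '", schema[[f]],
              "', row(s) ", paste(bad, collapse = ", "))
    }
    out[[f]] <- v
  }
  if (schema[["vo2vent_measured"]] %in% names(raw)) {
    out$vo2vent_measured <- suppressWarnings(
      as.numeric(raw[[schema[["vo2vent_measured"]]]]))
  }
  if (schema[["sex"]] %in% names(raw)) out$sex <- raw[[schema[["sex"]]]]
  cohort_table(out, volume_condition = volume_condition)
}

#' Write a cohort to a delimited text file
#'
#' Numeric fields are written with full precision so that
#' `load_cohort(write_cohort(x))` round-trips to at least six significant
#' digits.
#'
#' @param cohort A [cohort_table()].
#' @param path Output file path.
#' @param sep Field separator (default comma).
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path, sep = ",") {
  utils::write.csv(as.data.frame(cohort), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Keep one peak trial per subject
#'
#' Model derivation uses a single peak VO2vent value per subject to preserve
#' independence across rows. For each `subject_id` the row with the maximal
#' `vo2vent_measured` is kept; ties are broken by maximal `ve_peak`, then by
#' first occurrence.
#'
#' @param cohort A [cohort_table()], possibly with repeated `subject_id`.
#' @return A [cohort_table()] with one row per subject, in order of first
#'   appearance.
#' @export
select_peak_trials <- function(cohort) {
  stopifnot(inherits(cohort, "cohort_table"))
  df <- as.data.frame(cohort)
  ids <- unique(df$subject_id)
  keep <- vapply(ids, function(s) {
    i <- which(df$subject_id == s)
    m <- if (is.null(df$vo2vent_measured)) rep(NA_real_, length(i)) else
      df$vo2vent_measured[i]
    cand <- if (all(is.na(m))) i else i[!is.na(m) & m == max(m, na.rm = TRUE)]
    if (length(cand) > 1) cand <- cand[df$ve_peak[cand] == max(df$ve_peak[cand])]
    cand[1]
  }, integer(1))
  cohort_table(df[keep, , drop = FALSE],
               volume_condition = volume_condition(cohort))
}

#' Per-column mean and sample standard deviation of a cohort
#'
#' Reproduces the Mean/SD footer block of the derivation table: mean and
#' sample (n − 1 denominator) standard deviation of every numeric column.
#'
#' @param cohort A [cohort_table()] with at least two records.
#' @return A data frame with rows `mean` and `sd`, one column per numeric
#'   field present.
#' @export
#' @examples
#' summarize_cohort(table1_cohort())
summarize_cohort <- function(cohort) {
  stopifnot(inherits(cohort, "cohort_table"))
  df <- as.data.frame(cohort)
  if (nrow(df) < 2) vc_stop("insufficient_data", "need at least 2 records")
  num <- names(df)[vapply(df, is.numeric, logical(1))]
  out <- rbind(mean = vapply(df[num], mean, 0, na.rm = TRUE),
               sd = vapply(df[num], stats::sd, 0, na.rm = TRUE))
  as.data.frame(out)
}

#' Express a volume rate as a percentage of a maximum
#'
#' `100 * part / whole`, used to express VO2vent as a percentage of VO2max.
#'
#' @param part Numerator volume rate (L·min⁻¹), `>= 0`.
#' @param whole Denominator volume rate (L·min⁻¹), `> 0`.
#' @return Percentage (vectorised).
#' @export
#' @examples
#' percent_of_max(0.53, 2.24)  # 23.66
percent_of_max <- function(part, whole) {
  if (any(whole <= 0)) vc_stop("domain_error", "whole must be > 0")
  if (any(part < 0)) vc_stop("domain_error", "part must be >= 0")
  100 * part / whole
}

#' Packaged derivation cohort (n = 42)
#'
#' The 42-participant derivation table: one peak VO2vent observation per
#' subject with the six predictors, VE volumes STPD.
#'
#' @return A [cohort_table()] with 42 records.
#' @export
table1_cohort <- function() {
  load_cohort(system.file("extdata", "table1_derivation.csv",
                          package = "ventcost", mustWork = TRUE))
}

#' Packaged application table (n = 14)
#'
#' Per-subject VO2max, predicted VO2vent at VO2max and VO2vent as a
#' percentage of VO2max for the 14-cyclist application sample.
#'
#' @return A data frame with columns `subject_id`, `sex`, `vo2max`,
#'   `vo2vent`, `percent_vent_of_max`.
#' @export
table2_application <- function() {
  utils::read.csv(system.file("extdata", "table2_application.csv",
                              package = "ventcost", mustWork = TRUE),
                  stringsAsFactors = FALSE)
}
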