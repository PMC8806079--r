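# Cohort data model: participant-level table with exposure biomarkers,
# intermediate variables, outcome and covariates, plus CSV round-trip I/O.

#' @keywords internal
msg_stop <- function(class, fmt, ...) {
  stop(structure(
    class = c(class, "medsupp_error", "error", "condition"),
    list(message = sprintf(fmt, ...), call = sys.call(-1))
  ))
}

# Enumerated category levels (fixed CSV vocabulary).
SEX_LEVELS      <- c("male", "female")
RACE_LEVELS     <- c("white", "black")
PA_LEVELS       <- c("none", "moderate", "vigorous")
ALCOHOL_LEVELS  <- c("never", "<=1 day/week", "2-3 days/week", "4-7 days/week")

# Fixed CSV dialect: lower-snake-case headers, "." decimal separator,
# missing values as empty cells, below-LOD biomarkers as "<LOD" strings.
COHORT_COLUMNS <- c(
  "age", "sex", "race", "physical_activity", "alcohol_use",
  "current_smoker", "cotinine", "crp", "bmi", "ltl_bp", "ts_ratio"
)
# ltl_bp / ts_ratio: at least one must be present per row.
MANDATORY_COLUMNS <- setdiff(COHORT_COLUMNS, c("ltl_bp", "ts_ratio"))

#' Construct a cohort table
#'
#' A `cohort_table` is a data frame with one row per participant and a fixed
#' column vocabulary: `age` (years), `sex` (`male`/`female`), `race`
#' (`white`/`black`), `physical_activity` (`none`/`moderate`/`vigorous`),
#' `alcohol_use` (`never`, `<=1 day/week`, `2-3 days/week`, `4-7 days/week`),
#' `current_smoker` (logical), `cotinine` (serum cotinine, ng/mL), `crp`
#' (serum C-reactive protein, mg/dL), `bmi` (kg/m^2), and leukocyte telomere
#' length as `ltl_bp` (base pairs) and/or `ts_ratio` (telomere-to-single-copy
#' ratio).  Biomarker values below the assay limit of detection are carried
#' in the companion columns `cotinine_lod` / `crp_lod` (the LOD threshold,
#' `NA` for quantified values); the value column itself is `NA` for a
#' below-LOD entry.
#'
#' @param data data frame with the columns above (`cotinine_lod`/`crp_lod`
#'   optional; created as all-`NA` when absent).
#' @param provenance free-text provenance (source file or generator seed).
#' @return a `cohort_table`.
#' @export
cohort_table <- function(data, provenance = "unspecified") {
  if (!is.data.frame(data) || nrow(data) == 0L)
    msg_stop("medsupp_input_error", "cohort must be a non-empty data frame")
  missing_cols <- setdiff(MANDATORY_COLUMNS, names(data))
  if (length(missing_cols) > 0L)
    msg_stop("medsupp_format_error", "missing mandatory column(s): %s",
             paste(missing_cols, collapse = ", "))
  if (!any(c("ltl_bp", "ts_ratio") %in% names(data)))
    msg_stop("medsupp_format_error",
             "at least one of 'ltl_bp', 'ts_ratio' must be present")
  for (col in c("ltl_bp", "ts_ratio"))
    if (!col %in% names(data)) data[[col]] <- NA_real_
  for (col in c("cotinine_lod", "crp_lod"))
    if (!col %in% names(data)) data[[col]] <- NA_real_
  num_cols <- c("age", "cotinine", "crp", "bmi", "ltl_bp", "ts_ratio",
                "cotinine_lod", "crp_lod")
  for (col in num_cols) data[[col]] <- as.numeric(data[[col]])
  data$current_smoker <- as.logical(data$current_smoker)
  for (col in c("sex", "race", "physical_activity", "alcohol_use"))
    data[[col]] <- as.character(data[[col]])
  out <- data[, c(COHORT_COLUMNS[1:9], "cotinine_lod", "crp_lod",
                  "ltl_bp", "ts_ratio")]
  class(out) <- c("cohort_table", "data.frame")
  attr(out, "provenance") <- provenance
  out
}

#' @export
print.cohort_table <- function(x, ...) {
  cat(sprintf("<cohort_table> %d participants (provenance: %s)\n",
              nrow(x), attr(x, "provenance")))
  print(utils::head(as.data.frame(x), 6L))
  if (nrow(x) > 6L) cat(sprintf("... %d more rows\n", nrow(x) - 6L))
  invisible(x)
}

# Parse a biomarker CSV field: numeric, "<LOD" string, or empty (missing).
# Returns list(value, lod) vectors.
parse_lod_field <- function(x, field) {
  x <- trimws(as.character(x))
  value <- rep(NA_real_, length(x))
  lod <- rep(NA_real_, length(x))
  below <- !is.na(x) & grepl("^<", x)
  plain <- !is.na(x) & !below & nzchar(x)
  lod_num <- suppressWarnings(as.numeric(sub("^<", "", x[below])))
  if (anyNA(lod_num))
    msg_stop("medsupp_format_error",
             "unparseable below-LOD entry in column '%s'", field)
  lod[below] <- lod_num
  val_num <- suppressWarnings(as.numeric(x[plain]))
  if (anyNA(val_num))
    msg_stop("medsupp_format_error",
             "non-numeric entry in column '%s'", field)
  value[plain] <- val_num
  list(value = value, lod = lod)
}

#' Read a cohort CSV
#'
#' Reads a participant table in the fixed cohort dialect (see
#' [cohort_table()]): UTF-8, comma separated, `.` decimal separator, header
#' row matching the documented column names, empty cells for missing values,
#' and below-LOD biomarker entries encoded as `"<LOD"` strings such as
#' `"<0.05"`.
#'
#' @param path path to an existing CSV file.
#' @return a validated [cohort_table()] with `provenance = path`.
#' @export
read_cohort <- function(path) {
  if (!file.exists(path))
    msg_stop("medsupp_input_error", "file not found: %s", path)
  raw <- utils::read.csv(path, colClasses = "character",
                         check.names = FALSE, na.strings = NULL)
  if (nrow(raw) == 0L)
    msg_stop("medsupp_input_error", "empty cohort file: %s", path)
  missing_cols <- setdiff(MANDATORY_COLUMNS, names(raw))
  if (length(missing_cols) > 0L)
    msg_stop("medsupp_format_error", "missing mandatory column(s): %s",
             paste(missing_cols, collapse = ", "))
  blank_to_na <- function(x) {
    x <- trimws(x); x[!nzchar(x)] <- NA_character_; x
  }
  raw[] <- lapply(raw, blank_to_na)
  num_or_na <- function(x, field) {
    out <- suppressWarnings(as.numeric(x))
    bad <- !is.na(x) & is.na(out)
    if (any(bad))
      msg_stop("medsupp_format_error",
               "non-numeric entry in column '%s' (row %d)",
               field, which(bad)[1L])
    out
  }
  cot <- parse_lod_field(raw$cotinine, "cotinine")
  crp <- parse_lod_field(raw$crp, "crp")
  df <- data.frame(
    age = num_or_na(raw$age, "age"),
    sex = raw$sex,
    race = raw$race,
    physical_activity = raw$physical_activity,
    alcohol_use = raw$alcohol_use,
    current_smoker = as.logical(raw$current_smoker),
    cotinine = cot$value, cotinine_lod = cot$lod,
    crp = crp$value, crp_lod = crp$lod,
    bmi = num_or_na(raw$bmi, "bmi"),
    ltl_bp = if ("ltl_bp" %in% names(raw))
      num_or_na(raw$ltl_bp, "ltl_bp") else NA_real_,
    ts_ratio = if ("ts_ratio" %in% names(raw))
      num_or_na(raw$ts_ratio, "ts_ratio") else NA_real_,
    stringsAsFactors = FALSE
  )
  cohort_table(df, provenance = path)
}

# Format a numeric column for CSV so that read_cohort() recovers the same
# double (15 significant digits round-trip all values the generator emits).
fmt_num <- function(x) {
  vapply(x, function(v) {
    if (is.na(v)) return("")
    s <- sprintf("%.15g", v)
    if (as.numeric(s) != v) s <- sprintf("%.17g", v)
    s
  }, character(1))
}

#' Write a cohort CSV
#'
#' Inverse of [read_cohort()]: missing values become empty cells, below-LOD
#' biomarker entries become `"<LOD"` strings.
#'
#' @param cohort a [cohort_table()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  stopifnot(inherits(cohort, "cohort_table"))
  lod_field <- function(value, lod) {
    out <- fmt_num(value)
    below <- !is.na(lod)
    out[below] <- paste0("<", fmt_num(lod[below]))
    out
  }
  out <- data.frame(
    age = fmt_num(cohort$age),
    sex = ifelse(is.na(cohort$sex), "", cohort$sex),
    race = ifelse(is.na(cohort$race), "", cohort$race),
    physical_activity = ifelse(is.na(cohort$physical_activity), "",
                               cohort$physical_activity),
    alcohol_use = ifelse(is.na(cohort$alcohol_use), "", cohort$alcohol_use),
    current_smoker = ifelse(is.na(cohort$current_smoker), "",
                            ifelse(cohort$current_smoker, "TRUE", "FALSE")),
    cotinine = lod_field(cohort$cotinine, cohort$cotinine_lod),
    crp = lod_field(cohort$crp, cohort$crp_lod),
    bmi = fmt_num(cohort$bmi),
    ltl_bp = fmt_num(cohort$ltl_bp),
    ts_ratio = fmt_num(cohort$ts_ratio),
    stringsAsFactors = FALSE
  )
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Validate a cohort table
#'
#' Reports, per field, the number of missing values and the number of range
#' or category violations (age outside [18, 120], BMI outside (10, 80),
#' non-positive biomarkers, unknown category levels, rows lacking both
#' telomere measures).  Purely diagnostic: the data are not modified and no
#' rows are dropped.
#'
#' @param cohort a [cohort_table()].
#' @return a `validation_report`: data frame with columns `field`,
#'   `n_missing`, `n_invalid`, plus attribute `n_rows`.  Serializable with
#'   [report_to_json()].
#' @export
validate_cohort <- function(cohort) {
  stopifnot(inherits(cohort, "cohort_table"))
  n <- nrow(cohort)
  rows <- list()
  add <- function(field, missing, invalid) {
    rows[[field]] <<- data.frame(field = field,
                                 n_missing = sum(missing),
                                 n_invalid = sum(invalid, na.rm = TRUE),
                                 stringsAsFactors = FALSE)
  }
  add("age", is.na(cohort$age),
      !is.na(cohort$age) & (cohort$age < 18 | cohort$age > 120))
  cat_check <- function(field, levels) {
    x <- cohort[[field]]
    add(field, is.na(x), !is.na(x) & !(x %in% levels))
  }
  cat_check("sex", SEX_LEVELS)
  cat_check("race", RACE_LEVELS)
  cat_check("physical_activity", PA_LEVELS)
  cat_check("alcohol_use", ALCOHOL_LEVELS)
  add("current_smoker", is.na(cohort$current_smoker), FALSE)
  # below-LOD values count as observed, not missing
  cot_obs <- !is.na(cohort$cotinine) | !is.na(cohort$cotinine_lod)
  add("cotinine", !cot_obs, !is.na(cohort$cotinine) & cohort$cotinine <= 0)
  crp_obs <- !is.na(cohort$crp) | !is.na(cohort$crp_lod)
  add("crp", !crp_obs, !is.na(cohort$crp) & cohort$crp <= 0)
  add("bmi", is.na(cohort$bmi),
      !is.na(cohort$bmi) & (cohort$bmi <= 10 | cohort$bmi >= 80))
  ltl_obs <- !is.na(cohort$ltl_bp) | !is.na(cohort$ts_ratio)
  add("ltl", !ltl_obs,
      (!is.na(cohort$ltl_bp) & cohort$ltl_bp <= 0) |
        (!is.na(cohort$ts_ratio) & cohort$ts_ratio <= 0))
  report <- do.call(rbind, rows)
  rownames(report) <- NULL
  attr(report, "n_rows") <- n
  class(report) <- c("validation_report", "data.frame")
  report
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf("<validation_report> %d rows checked\n", attr(x, "n_rows")))
  print(as.data.frame(x))
  invisible(x)
}

#' Serialize a validation report to JSON
#'
#' @param report a `validation_report` from [validate_cohort()].
#' @param path optional file path; when `NULL` the JSON string is returned.
#' @return JSON string (invisibly, when written to file).
#' @export
report_to_json <- function(report, path = NULL) {
  payload <- list(
    n_rows = attr(report, "n_rows"),
    fields = as.data.frame(report)
  )
  json <- jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA)
  if (!is.null(path)) {
    writeLines(json, path)
    return(invisible(json))
  }
  json
}

#' Declare a third-variable model
#'
#' A `model_spec` names the roles each cohort variable plays in the
#' decomposition: the predictor X (exposure), the outcome Y, zero to two
#' third variables Z (candidate mediators/suppressors), and the adjustment
#' covariates.  `transforms` maps variable names to `"log"` or `"identity"`;
#' right-skewed biomarkers (cotinine, CRP) are log-transformed by default.
#'
#' @param predictor name of X (default `"cotinine"`).
#' @param outcome name of Y (default `"ltl_bp"`).
#' @param third_variables character vector of 0-2 Z names.
#' @param covariates adjustment variables.
#' @param transforms named character vector, values `"log"` or `"identity"`.
#' @return a `model_spec`.
#' @export
model_spec <- function(predictor = "cotinine",
                       outcome = "ltl_bp",
                       third_variables = c("bmi", "crp"),
                       covariates = c("age", "race", "sex",
                                      "physical_activity", "alcohol_use"),
                       transforms = c(cotinine = "log", crp = "log")) {
  known <- c(COHORT_COLUMNS)
  vars <- c(predictor, outcome, third_variables, covariates)
  unknown <- setdiff(vars, known)
  if (length(unknown) > 0L)
    msg_stop("medsupp_spec_error", "unknown variable(s): %s",
             paste(unknown, collapse = ", "))
  if (anyDuplicated(vars))
    msg_stop("medsupp_spec_error",
             "predictor, outcome, third variables and covariates must be mutually distinct")
  if (length(third_variables) > 2L)
    msg_stop("medsupp_spec_error", "at most two third variables supported")
  if (!all(transforms %in% c("log", "identity")))
    msg_stop("medsupp_spec_error", "transforms must be 'log' or 'identity'")
  structure(list(predictor = predictor, outcome = outcome,
                 third_variables = third_variables, covariates = covariates,
                 transforms = transforms),
            class = "model_spec")
}

#' @export
print.model_spec <- function(x, ...) {
  cat("<model_spec>\n")
  cat("  X (predictor):      ", x$predictor, "\n")
  cat("  Y (outcome):        ", x$outcome, "\n")
  cat("  Z (third variables):",
      if (length(x$third_variables)) paste(x$third_variables, collapse = ", ")
      else "(none)", "\n")
  cat("  covariates:         ", paste(x$covariates, collapse = ", "), "\n")
  invisible(x)
}
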