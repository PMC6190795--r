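## Study data model: long-format concentration-time data with one row per
## event. Canonical columns:
##   id            subject label
##   evid          1 = dose, 0 = observation
##   time          minutes since first dose
##   amt           dose amount, mg/kg (dose rows; NA on observation rows)
##   conc          total serum concentration, ug/mL (observation rows)
##   bloq          1 if the observation is below the limit of quantification
##   bw, age, creatinine, surgery_time   continuous covariates
##   health, breed, sex                  categorical covariates (coded)

CANONICAL_COLUMNS <- c("id", "evid", "time", "amt", "conc", "bloq",
                       "bw", "age", "creatinine", "surgery_time",
                       "health", "breed", "sex")
COVARIATE_COLUMNS <- c("bw", "age", "creatinine", "surgery_time",
                       "health", "breed", "sex")
CONTINUOUS_COVARIATES <- c("bw", "age", "creatinine", "surgery_time")
CATEGORICAL_LEVELS <- list(health = 0:1, breed = 0:1, sex = 0:2)

#' Assemble a study dataset from a long-format event table
#'
#' Validates and canonicalizes a long-format table of dosing events and
#' timed observations with per-subject covariates. Within each subject,
#' rows are ordered doses-first then observations by time; covariates must
#' be constant within subject.
#'
#' @param data A data frame with the canonical columns `id`, `evid` (1 dose,
#'   0 observation), `time` (min), `amt` (mg/kg, dose rows), `conc` (µg/mL,
#'   observation rows), `bloq` (0/1), and covariates `bw`, `age`,
#'   `creatinine`, `surgery_time`, `health`, `breed`, `sex`.
#' @return An object of class `study_dataset`: a list with elements `data`
#'   (the canonicalized long table) and `n_observations`.
#' @seealso [read_study()], [write_study()], [generate_study()]
#' @export
study_dataset <- function(data) {
  if (!is.data.frame(data)) {
    stop_cefapop("cefapop_format_error", "data must be a data frame")
  }
  missing_cols <- setdiff(CANONICAL_COLUMNS, names(data))
  if (length(missing_cols)) {
    stop_cefapop("cefapop_format_error",
                 "missing required column(s): ",
                 paste(missing_cols, collapse = ", "))
  }
  data <- as.data.frame(data)[CANONICAL_COLUMNS]
  if (nrow(data) == 0) {
    stop_cefapop("cefapop_validation_error", "dataset has no rows")
  }
  data$id <- as.character(data$id)
  for (col in c("evid", "time", "amt", "conc", "bloq",
                CONTINUOUS_COVARIATES)) {
    if (!is.numeric(data[[col]]) && !all(is.na(data[[col]]))) {
      suppressWarnings(num <- as.numeric(data[[col]]))
      bad <- which(!is.na(data[[col]]) & is.na(num))
      if (length(bad)) {
        stop_cefapop("cefapop_validation_error",
                     "non-numeric value in column '", col,
                     "' at row ", bad[1])
      }
      data[[col]] <- num
    }
    data[[col]] <- as.numeric(data[[col]])
  }
  data$health <- as.integer(data$health)
  data$breed <- as.integer(data$breed)
  data$sex <- as.integer(data$sex)

  validate_study_rows(data)

  # canonical order: by subject (first appearance), doses before
  # observations, then time
  first_seen <- match(data$id, unique(data$id))
  ord <- order(first_seen, -data$evid, data$time)
  data <- data[ord, , drop = FALSE]
  rownames(data) <- NULL

  structure(
    list(data = data, n_observations = sum(data$evid == 0)),
    class = "study_dataset"
  )
}

#' @noRd
validate_study_rows <- function(data) {
  bad <- which(!is.finite(data$time) | data$time < 0)
  if (length(bad)) {
    stop_cefapop("cefapop_validation_error",
                 "negative or missing time at row ", bad[1])
  }
  if (!all(data$evid %in% c(0, 1))) {
    bad <- which(!data$evid %in% c(0, 1))
    stop_cefapop("cefapop_validation_error",
                 "event type (evid) must be 0 or 1; offending row ", bad[1])
  }
  is_dose <- data$evid == 1
  bad <- which(is_dose & (!is.finite(data$amt) | data$amt <= 0))
  if (length(bad)) {
    stop_cefapop("cefapop_validation_error",
                 "dose row with missing or non-positive amount at row ",
                 bad[1])
  }
  data$bloq[is.na(data$bloq)] <- 0
  is_obs <- data$evid == 0
  bad <- which(is_obs & data$bloq == 0 &
                 (!is.finite(data$conc) | data$conc <= 0))
  if (length(bad)) {
    stop_cefapop("cefapop_validation_error",
                 "observation with missing or non-positive concentration ",
                 "(and not flagged below the LOQ) at row ", bad[1])
  }
  for (col in COVARIATE_COLUMNS) {
    if (anyNA(data[[col]])) {
      stop_cefapop("cefapop_validation_error",
                   "missing covariate '", col, "' at row ",
                   which(is.na(data[[col]]))[1],
                   "; covariate missingness is not supported")
    }
  }
  for (col in CONTINUOUS_COVARIATES) {
    if (any(data[[col]] <= 0)) {
      stop_cefapop("cefapop_validation_error",
                   "continuous covariate '", col, "' must be > 0 (row ",
                   which(data[[col]] <= 0)[1], ")")
    }
  }
  for (col in names(CATEGORICAL_LEVELS)) {
    ok <- data[[col]] %in% CATEGORICAL_LEVELS[[col]]
    if (!all(ok)) {
      stop_cefapop("cefapop_validation_error",
                   "categorical covariate '", col, "' outside coding {",
                   paste(CATEGORICAL_LEVELS[[col]], collapse = ","),
                   "} at row ", which(!ok)[1])
    }
  }
  # per-subject checks
  for (sid in unique(data$id)) {
    rows <- data[data$id == sid, , drop = FALSE]
    if (!any(rows$evid == 1)) {
      stop_cefapop("cefapop_validation_error",
                   "subject ", sid, " has no dose event")
    }
    first_dose <- min(rows$time[rows$evid == 1])
    obs <- rows[rows$evid == 0, , drop = FALSE]
    if (nrow(obs) && any(obs$time < first_dose)) {
      stop_cefapop("cefapop_validation_error",
                   "subject ", sid, " has an observation before the first ",
                   "dose")
    }
    for (col in COVARIATE_COLUMNS) {
      if (length(unique(rows[[col]])) > 1) {
        stop_cefapop("cefapop_validation_error",
                     "covariate '", col, "' varies within subject ", sid)
      }
    }
  }
  invisible(TRUE)
}

#' @export
print.study_dataset <- function(x, ...) {
  cat(sprintf("Study dataset: %d subjects, %d observations, %d dose events\n",
              n_subjects(x), x$n_observations, sum(x$data$evid == 1)))
  obs <- x$data[x$data$evid == 0, ]
  if (nrow(obs)) {
    cat(sprintf("  time range %g-%g min; %d observation(s) below LOQ\n",
                min(obs$time), max(obs$time), sum(obs$bloq == 1)))
  }
  invisible(x)
}

#' @export
as.data.frame.study_dataset <- function(x, ...) x$data

#' Number of subjects in a study dataset
#' @param dataset A [study_dataset()].
#' @return Integer subject count.
#' @export
n_subjects <- function(dataset) length(unique(dataset$data$id))

#' Number of observation rows in a study dataset
#' @param dataset A [study_dataset()].
#' @return Integer observation count.
#' @export
n_observations <- function(dataset) dataset$n_observations

#' Per-subject covariate table (one row per subject)
#' @param dataset A [study_dataset()].
#' @return Data frame with `id` and the seven covariates, one row per
#'   subject, in subject order.
#' @export
subject_covariates <- function(dataset) {
  d <- dataset$data
  keep <- !duplicated(d$id)
  out <- d[keep, c("id", COVARIATE_COLUMNS)]
  rownames(out) <- NULL
  out
}

#' Split a study dataset into per-subject records
#'
#' @param dataset A [study_dataset()].
#' @return Named list (by subject id); each element has `id`, `doses`
#'   (a [dose_events()] frame), `observations` (data frame with `time`,
#'   `conc`, `bloq`), and `covariates` (one-row data frame).
#' @export
split_subjects <- function(dataset) {
  d <- dataset$data
  ids <- unique(d$id)
  out <- lapply(ids, function(sid) {
    rows <- d[d$id == sid, , drop = FALSE]
    doses <- rows[rows$evid == 1, c("time", "amt")]
    obs <- rows[rows$evid == 0, c("time", "conc", "bloq")]
    rownames(doses) <- rownames(obs) <- NULL
    list(
      id = sid,
      doses = dose_events(doses$time, doses$amt),
      observations = obs,
      covariates = rows[1, COVARIATE_COLUMNS]
    )
  })
  names(out) <- ids
  out
}

#' Default column mapping for study files
#'
#' @return Named character vector mapping canonical column names to file
#'   column names (identity by default).
#' @export
default_dialect <- function() {
  setNames(CANONICAL_COLUMNS, CANONICAL_COLUMNS)
}

#' Read a long-format study file
#'
#' Reads a delimited text file (comma default; tab accepted) with a header
#' row into a validated [study_dataset()]. Column names can be remapped via
#' `dialect`: either a named character vector / list mapping canonical
#' names to file column names, or the path of a YAML-style `key: value`
#' file with such a mapping.
#'
#' @param path Path of the file to read.
#' @param dialect Optional column mapping (see Details).
#' @param sep Field separator; `","` (default) or `"\t"`.
#' @return A [study_dataset()].
#' @export
read_study <- function(path, dialect = NULL, sep = ",") {
  if (!file.exists(path)) {
    stop_cefapop("cefapop_io_error", "file not found: ", path)
  }
  map <- resolve_dialect(dialect)
  raw <- utils::read.csv(path, sep = sep, comment.char = "#",
                         stringsAsFactors = FALSE, check.names = FALSE)
  missing_cols <- setdiff(unname(map), names(raw))
  if (length(missing_cols)) {
    stop_cefapop("cefapop_format_error",
                 "missing required column(s) in ", path, ": ",
                 paste(missing_cols, collapse = ", "))
  }
  data <- raw[unname(map)]
  names(data) <- names(map)
  study_dataset(data)
}

#' @noRd
resolve_dialect <- function(dialect) {
  map <- default_dialect()
  if (is.null(dialect)) return(map)
  if (is.character(dialect) && length(dialect) == 1 && file.exists(dialect)) {
    dialect <- yaml::read_yaml(dialect)
  }
  dialect <- unlist(dialect)
  unknown <- setdiff(names(dialect), CANONICAL_COLUMNS)
  if (length(unknown)) {
    stop_cefapop("cefapop_format_error",
                 "dialect maps unknown column(s): ",
                 paste(unknown, collapse = ", "))
  }
  map[names(dialect)] <- dialect
  map
}

#' Write a study dataset to delimited text
#'
#' Emits the canonical long format (comma-separated, header row, UTF-8)
#' readable by [read_study()]; the write/read roundtrip reproduces the
#' dataset exactly up to numeric formatting.
#'
#' @param dataset A [study_dataset()].
#' @param path Output file path.
#' @param sep Field separator (default comma).
#' @return Invisibly, `path`.
#' @export
write_study <- function(dataset, path, sep = ",") {
  if (!inherits(dataset, "study_dataset")) {
    stop_cefapop("cefapop_format_error", "dataset must be a study_dataset")
  }
  if (nrow(dataset$data) == 0 || n_subjects(dataset) == 0) {
    stop_cefapop("cefapop_validation_error", "nothing to write: no subjects")
  }
  ok <- tryCatch({
    utils::write.table(dataset$data, path, sep = sep, row.names = FALSE,
                       quote = FALSE, fileEncoding = "UTF-8")
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) {
    stop_cefapop("cefapop_io_error", "could not write study file: ", path)
  }
  invisible(path)
}

#' Covariate summary table
#'
#' One row per continuous covariate with mean, SD, minimum, maximum and
#' median over subjects, plus per-level counts for the categorical
#' covariates. With a single subject the SD is reported as `NA`.
#'
#' @param dataset A [study_dataset()].
#' @return A list with elements `continuous` (data frame: covariate, mean,
#'   sd, min, max, median) and `categorical` (data frame: covariate, level,
#'   n).
#' @export
summarize_covariates <- function(dataset) {
  cov <- subject_covariates(dataset)
  if (nrow(cov) == 0) {
    stop_cefapop("cefapop_validation_error", "empty dataset")
  }
  cont <- do.call(rbind, lapply(CONTINUOUS_COVARIATES, function(col) {
    x <- cov[[col]]
    data.frame(covariate = col, mean = mean(x),
               sd = if (length(x) > 1) stats::sd(x) else NA_real_,
               min = min(x), max = max(x), median = stats::median(x))
  }))
  cat_rows <- list()
  for (col in names(CATEGORICAL_LEVELS)) {
    for (lev in CATEGORICAL_LEVELS[[col]]) {
      cat_rows[[length(cat_rows) + 1]] <- data.frame(
        covariate = col, level = lev, n = sum(cov[[col]] == lev))
    }
  }
  list(continuous = cont, categorical = do.call(rbind, cat_rows))
}
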