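cohort_columns <- c("age", "sex", "afp", "pivka2", "hcc",
                    "subgroup", "time", "event")

#' Write a cohort CSV
#'
#' Fixed header `age,sex,afp,pivka2,hcc,subgroup,time,event`; missing
#' `time`/`event` are written as empty fields. Extra columns are appended
#' after the standard ones.
#'
#' @param cohort Cohort data frame.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  for (col in c("subgroup", "time", "event"))
    if (is.null(cohort[[col]])) cohort[[col]] <- NA
  extra <- setdiff(names(cohort), cohort_columns)
  cohort <- cohort[, c(cohort_columns, extra), drop = FALSE]
  utils::write.csv(cohort, path, row.names = FALSE, quote = FALSE,
                   na = "")
  invisible(path)
}

#' Read and validate a cohort CSV
#'
#' Requires columns `age`, `sex`, `afp`, `pivka2`, `hcc`. Rows with
#' missing or nonpositive marker values are rejected with their line
#' numbers (there must be no missing AFP/PIVKA-II). Optional `subgroup`,
#' `time`, `event` columns and any extra columns are passed through; an
#' `event` requires a `time`.
#'
#' @param path CSV file path.
#' @return Cohort data frame.
#' @export
read_cohort <- function(path) {
  co <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("age", "sex", "afp", "pivka2", "hcc")
  miss <- setdiff(need, names(co))
  if (length(miss))
    stop("cohort file is missing required column(s): ",
         paste(miss, collapse = ", "))
  bad <- which(is.na(co$afp) | is.na(co$pivka2) |
               co$afp <= 0 | co$pivka2 <= 0)
  if (length(bad))
    stop("missing or nonpositive marker values in row(s): ",
         paste(bad, collapse = ", "))
  if (!is.null(co$event) && any(!is.na(co$event) & is.na(co$time)))
    stop("rows with an event indicator must have a follow-up time")
  co
}

#' Read a pipeline configuration file
#'
#' JSON (`.json`) or YAML (`.yml`/`.yaml`) with fields mirroring the
#' [run_pipeline()] arguments.
#'
#' @param path Config file path.
#' @return Named list.
#' @export
read_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "json")
    jsonlite::read_json(path, simplifyVector = TRUE)
  else if (ext %in% c("yml", "yaml"))
    yaml::read_yaml(path)
  else stop("config must be .json, .yml or .yaml")
}
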