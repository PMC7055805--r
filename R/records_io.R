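#' Default column mapping for patient record files
#'
#' Maps the canonical field names used throughout the package to the column
#' names found in a delimited input file. Override individual entries to read
#' files with different headers.
#'
#' @return Named character vector with entries `record_id`, `dob`, `gender`,
#'   `province`, `city`, `district`.
#' @export
default_record_columns <- function() {
  c(
    record_id = "record_id", dob = "dob", gender = "gender",
    province = "province", city = "city", district = "district"
  )
}

.record_fields <- c("record_id", "dob", "gender", "province", "city", "district")

#' Read patient demographic records from a delimited text file
#'
#' Reads one record per row with an opaque identifier, date of birth, gender
#' and a three-level residence address (province, city, district). Dates must
#' be ISO 8601 (`YYYY-MM-DD`); any other dialect is treated as missing rather
#' than guessed, with a warning, because silently re-interpreting an ambiguous
#' date format can corrupt birth years. Dates in the future of
#' `reference_date` are likewise set to missing. Gender values other than
#' `M`/`F` (case-insensitive) become missing with a warning.
#'
#' @param path Path to a UTF-8 delimited text file with a header row.
#' @param delim Field delimiter, `","` (default) or `"\t"`.
#' @param columns Named character vector mapping canonical field names to file
#'   column names; see [default_record_columns()].
#' @param reference_date Latest admissible date of birth (default today).
#' @return A tibble with columns `record_id`, `dob` (`Date`), `gender`,
#'   `province`, `city`, `district`; row order matches the file.
#' @export
read_records <- function(path, delim = ",", columns = default_record_columns(),
                         reference_date = Sys.Date()) {
  if (!file.exists(path)) {
    stop("record file not found: ", path, call. = FALSE)
  }
  if (!all(.record_fields %in% names(columns))) {
    stop(
      "`columns` must map all of: ", paste(.record_fields, collapse = ", "),
      call. = FALSE
    )
  }
  raw <- readr::read_delim(
    path,
    delim = delim, col_types = readr::cols(.default = readr::col_character()),
    na = c("", "NA"), trim_ws = TRUE, progress = FALSE,
    show_col_types = FALSE
  )
  absent <- setdiff(unname(columns[.record_fields]), names(raw))
  if (length(absent) > 0) {
    stop(
      "schema error: mapped column(s) not in file header: ",
      paste(absent, collapse = ", "),
      call. = FALSE
    )
  }

  rec <- tibble(
    record_id = raw[[columns[["record_id"]]]],
    dob_raw   = raw[[columns[["dob"]]]],
    gender    = raw[[columns[["gender"]]]],
    province  = raw[[columns[["province"]]]],
    city      = raw[[columns[["city"]]]],
    district  = raw[[columns[["district"]]]]
  )

  if (any(is.na(rec$record_id) | rec$record_id == "")) {
    stop("validation error: empty record_id at row(s) ",
      paste(head(which(is.na(rec$record_id) | rec$record_id == ""), 5L),
        collapse = ", "
      ),
      call. = FALSE
    )
  }
  dup <- unique(rec$record_id[duplicated(rec$record_id)])
  if (length(dup) > 0) {
    stop("validation error: duplicated record_id: ",
      paste(head(dup, 10L), collapse = ", "),
      call. = FALSE
    )
  }

  dob <- parse_iso_date(rec$dob_raw)
  n_unparseable <- sum(!is.na(rec$dob_raw) & is.na(dob))
  if (n_unparseable > 0) {
    warning(
      n_unparseable, " DOB value(s) not valid ISO 8601 dates; set to missing",
      call. = FALSE
    )
  }
  future <- !is.na(dob) & dob > as.Date(reference_date)
  if (any(future)) {
    warning(
      sum(future), " DOB value(s) after the reference date; set to missing",
      call. = FALSE
    )
    dob[future] <- as.Date(NA)
  }

  gender <- toupper(trimws(rec$gender))
  bad_gender <- !is.na(gender) & !gender %in% c("M", "F")
  if (any(bad_gender)) {
    warning(
      sum(bad_gender), " gender value(s) not in {M, F}; set to missing",
      call. = FALSE
    )
    gender[bad_gender] <- NA_character_
  }

  tibble(
    record_id = rec$record_id,
    dob = dob,
    gender = gender,
    province = rec$province,
    city = rec$city,
    district = rec$district
  )
}

# Strict ISO 8601 parse: anything not matching YYYY-MM-DD, or not a real
# calendar date, becomes NA.
parse_iso_date <- function(x) {
  out <- rep(as.Date(NA), length(x))
  ok <- !is.na(x) & grepl("^\\d{4}-\\d{2}-\\d{2}$", x)
  parsed <- as.Date(x[ok], format = "%Y-%m-%d")
  out[ok] <- parsed
  out
}

#' Filter records on address completeness and sentinel dates of birth
#'
#' Applies the two data-quality exclusions used before risk analysis: records
#' missing any residence-address component, and records carrying an obviously
#' erroneous placeholder DOB (by default `1900-01-01`). Each excluded record is
#' attributed to exactly one rule, in the order missing address first, then
#' sentinel DOB, so the report is deterministic.
#'
#' Records with missing gender or missing (non-sentinel) DOB are retained here;
#' they are dropped, and counted, only when a policy view is built
#' (see [apply_policy()]).
#'
#' @param records Tibble as returned by [read_records()].
#' @param sentinel_dobs Non-empty vector of `Date` values treated as data-entry
#'   defects; default `1900-01-01`.
#' @return A list with `records` (the retained tibble, original order) and
#'   `report`, a `filter_report` with counts `n_input`, `n_missing_address`,
#'   `n_sentinel_dob`, `n_retained`.
#' @export
filter_records <- function(records, sentinel_dobs = as.Date("1900-01-01")) {
  sentinel_dobs <- as.Date(sentinel_dobs)
  if (length(sentinel_dobs) == 0 || anyNA(sentinel_dobs)) {
    stop("`sentinel_dobs` must be a non-empty vector of valid dates",
      call. = FALSE
    )
  }
  missing_addr <- is.na(records$province) | is.na(records$city) |
    is.na(records$district)
  sentinel <- !missing_addr & !is.na(records$dob) &
    records$dob %in% sentinel_dobs

  report <- new_filter_report(
    n_input = nrow(records),
    n_missing_address = sum(missing_addr),
    n_sentinel_dob = sum(sentinel),
    n_retained = sum(!missing_addr & !sentinel)
  )
  list(records = records[!missing_addr & !sentinel, , drop = FALSE],
       report = report)
}

new_filter_report <- function(n_input, n_missing_address, n_sentinel_dob,
                              n_retained) {
  stopifnot(n_retained + n_missing_address + n_sentinel_dob == n_input)
  structure(
    list(
      n_input = as.integer(n_input),
      n_missing_address = as.integer(n_missing_address),
      n_sentinel_dob = as.integer(n_sentinel_dob),
      n_retained = as.integer(n_retained)
    ),
    class = "filter_report"
  )
}

#' @export
print.filter_report <- function(x, ...) {
  cat("Record filter report\n")
  cat(sprintf("  n_input           : %d\n", x$n_input))
  cat(sprintf("  n_missing_address : %d\n", x$n_missing_address))
  cat(sprintf("  n_sentinel_dob    : %d\n", x$n_sentinel_dob))
  cat(sprintf("  n_retained        : %d\n", x$n_retained))
  invisible(x)
}

#' @export
format.filter_report <- function(x, ...) {
  paste0(
    "n_input=", x$n_input,
    " n_missing_address=", x$n_missing_address,
    " n_sentinel_dob=", x$n_sentinel_dob,
    " n_retained=", x$n_retained
  )
}

#' Write patient records to a delimited text file
#'
#' Inverse of [read_records()]: `read_records(write_records(r, path))`
#' reproduces `r` field for field, including missing values (written as empty
#' fields). Dates are written as ISO 8601.
#'
#' @param records Tibble of patient records.
#' @param path Destination path.
#' @param delim Field delimiter.
#' @return `path`, invisibly.
#' @export
write_records <- function(records, path, delim = ",") {
  out <- records
  out$dob <- format(out$dob, "%Y-%m-%d")
  readr::write_delim(out, path, delim = delim, na = "")
  invisible(path)
}
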