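.granularities <- c("day", "month", "year", "decade")

#' Define a quasi-identifier generalization policy
#'
#' A policy says how finely the date of birth and the surrogate ZIP code
#' appear in the quasi-identifier tuple used for risk analysis. Two named
#' policies are fixed by convention: the *limited dataset* keeps full DOB and
#' the full 9-digit ZIP; the *safe harbor* view generalizes DOB to birth year
#' and truncates the ZIP to its first 6 digits. `custom` policies support
#' arbitrary sweeps.
#'
#' @param name One of `"limited"`, `"safe_harbor"`, `"custom"`.
#' @param dob_granularity One of `"day"`, `"month"`, `"year"`, `"decade"`.
#' @param zip_prefix_len Integer in `[0, 9]`; how many leading ZIP digits the
#'   key retains. `0` drops geography from the key entirely.
#' @param topcode_age_at Optional age (in years) at or above which all
#'   patients share one pooled DOB component (the HIPAA "ages over 89" rule);
#'   `NULL` (default) disables top-coding.
#' @return A `policy_spec` object.
#' @export
policy_spec <- function(name = c("custom", "limited", "safe_harbor"),
                        dob_granularity = "day",
                        zip_prefix_len = 9L,
                        topcode_age_at = NULL) {
  name <- match.arg(name)
  if (!dob_granularity %in% .granularities) {
    stop("`dob_granularity` must be one of: ",
      paste(.granularities, collapse = ", "),
      call. = FALSE
    )
  }
  if (length(zip_prefix_len) != 1L || is.na(zip_prefix_len) ||
    zip_prefix_len != as.integer(zip_prefix_len) ||
    zip_prefix_len < 0L || zip_prefix_len > 9L) {
    stop("`zip_prefix_len` must be a single integer in [0, 9]", call. = FALSE)
  }
  if (!is.null(topcode_age_at)) {
    if (length(topcode_age_at) != 1L || is.na(topcode_age_at) ||
      topcode_age_at < 1) {
      stop("`topcode_age_at` must be NULL or a single positive age",
        call. = FALSE
      )
    }
    topcode_age_at <- as.integer(topcode_age_at)
  }
  if (name == "limited" &&
    !(dob_granularity == "day" && zip_prefix_len == 9L &&
      is.null(topcode_age_at))) {
    stop("the limited policy is fixed: day granularity, 9-digit zip, ",
      "no top-coding",
      call. = FALSE
    )
  }
  if (name == "safe_harbor" && dob_granularity != "year") {
    stop("the safe harbor policy generalizes DOB to year", call. = FALSE)
  }
  structure(
    list(
      name = name,
      dob_granularity = dob_granularity,
      zip_prefix_len = as.integer(zip_prefix_len),
      topcode_age_at = topcode_age_at
    ),
    class = "policy_spec"
  )
}

#' @rdname policy_spec
#' @export
policy_limited <- function() {
  policy_spec("limited", dob_granularity = "day", zip_prefix_len = 9L)
}

#' @rdname policy_spec
#' @export
policy_safe_harbor <- function(zip_prefix_len = 6L, topcode_age_at = NULL) {
  policy_spec("safe_harbor",
    dob_granularity = "year",
    zip_prefix_len = zip_prefix_len, topcode_age_at = topcode_age_at
  )
}

#' @export
print.policy_spec <- function(x, ...) {
  cat(sprintf(
    "Policy '%s': DOB -> %s, ZIP prefix %d%s\n",
    x$name, x$dob_granularity, x$zip_prefix_len,
    if (is.null(x$topcode_age_at)) {
      ""
    } else {
      sprintf(", ages >= %d pooled", x$topcode_age_at)
    }
  ))
  invisible(x)
}

generalize_dob <- function(dob, granularity) {
  switch(granularity,
    day = format(dob, "%Y-%m-%d"),
    month = format(dob, "%Y-%m"),
    year = format(dob, "%Y"),
    decade = {
      yr <- as.integer(format(dob, "%Y"))
      out <- sprintf("%ds", (yr %/% 10L) * 10L)
      out[is.na(dob)] <- NA_character_
      out
    }
  )
}

# completed years between dob and reference date
age_at <- function(dob, reference_date) {
  ref <- as.POSIXlt(as.Date(reference_date))
  d <- as.POSIXlt(dob)
  age <- ref$year - d$year
  before_birthday <- (ref$mon < d$mon) | (ref$mon == d$mon & ref$mday < d$mday)
  age - as.integer(before_birthday)
}

#' Build the quasi-identifier view of encoded records under a policy
#'
#' Transforms each encoded record into the (DOB component, gender, ZIP
#' component) tuple the g-distinct statistic bins on. DOB is generalized to
#' the policy's granularity (`day` -> `"YYYY-MM-DD"`, `month` -> `"YYYY-MM"`,
#' `year` -> `"YYYY"`, `decade` -> `"YYY0s"`), the ZIP is truncated to the
#' policy's prefix length, and, when top-coding is on, every patient at or
#' above the threshold age shares the pooled DOB component `"<age>+"`.
#' Records with any missing component are dropped and counted so the
#' statistic stays well defined.
#'
#' @param records Encoded record tibble (with `zip`; see
#'   [encode_addresses()]).
#' @param spec A `policy_spec`.
#' @param reference_date Date at which ages are computed; required only when
#'   `spec$topcode_age_at` is set.
#' @return A `qi_view`: list with `policy`, `keys` (tibble `dob_component`,
#'   `gender`, `zip_component`), `n_input` and `n_dropped_missing`.
#' @export
apply_policy <- function(records, spec, reference_date = NULL) {
  stopifnot(inherits(spec, "policy_spec"))
  complete <- !is.na(records$dob) & !is.na(records$gender) &
    !is.na(records$zip)
  kept <- records[complete, , drop = FALSE]

  dob_component <- generalize_dob(kept$dob, spec$dob_granularity)
  if (!is.null(spec$topcode_age_at)) {
    if (is.null(reference_date)) {
      stop("`reference_date` is required when top-coding is enabled",
        call. = FALSE
      )
    }
    pooled <- age_at(kept$dob, reference_date) >= spec$topcode_age_at
    dob_component[pooled] <- sprintf("%d+", spec$topcode_age_at)
  }
  zip_component <- substr(kept$zip, 1L, spec$zip_prefix_len)

  structure(
    list(
      policy = spec,
      keys = tibble(
        dob_component = dob_component,
        gender = kept$gender,
        zip_component = zip_component
      ),
      n_input = nrow(records),
      n_dropped_missing = nrow(records) - nrow(kept)
    ),
    class = "qi_view"
  )
}

#' @export
print.qi_view <- function(x, ...) {
  cat(sprintf(
    "Quasi-identifier view under policy '%s': %d key(s), %d dropped missing\n",
    x$policy$name, nrow(x$keys), x$n_dropped_missing
  ))
  invisible(x)
}

#' Export a quasi-identifier view for audit
#'
#' Writes one key tuple per row as delimited text.
#'
#' @param view A `qi_view`.
#' @param path Destination path.
#' @param delim Field delimiter.
#' @return `path`, invisibly.
#' @export
write_view <- function(view, path, delim = ",") {
  readr::write_delim(view$keys, path, delim = delim, na = "")
  invisible(path)
}

#' Is one policy a coarsening of another?
#'
#' `is_coarsening(fine, coarse)` is `TRUE` exactly when the view produced by
#' `coarse` is a deterministic function of the view produced by `fine`: the
#' DOB granularity is coarser or equal, the ZIP prefix is shorter or equal,
#' and top-coding is reproducible (both off, both at the same threshold, or
#' the fine view is day-granular so exact ages can be recomputed; a pooled
#' DOB component can never be un-pooled). Coarsening can only merge
#' equivalence classes, so it never increases uniqueness.
#'
#' @param fine,coarse `policy_spec` objects.
#' @return `TRUE` or `FALSE`.
#' @export
is_coarsening <- function(fine, coarse) {
  stopifnot(inherits(fine, "policy_spec"), inherits(coarse, "policy_spec"))
  rank <- match(c(fine$dob_granularity, coarse$dob_granularity), .granularities)
  gran_ok <- rank[2] >= rank[1]
  zip_ok <- coarse$zip_prefix_len <= fine$zip_prefix_len
  ft <- fine$topcode_age_at
  ct <- coarse$topcode_age_at
  topcode_ok <-
    if (is.null(ft) && is.null(ct)) {
      TRUE
    } else if (is.null(ft)) {
      # coarse pools by age: exact age only recoverable from full DOB
      fine$dob_granularity == "day"
    } else if (is.null(ct)) {
      FALSE
    } else {
      ft == ct
    }
  gran_ok && zip_ok && topcode_ok
}
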