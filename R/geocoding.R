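.gazetteer_cols <- c(
  "province", "city", "district", "pad_code", "city_code", "district_code"
)

# Canonical form used for address matching: trimmed, Unicode NFC.
# Exact matching only -- fuzzy address resolution is out of scope by design.
normalize_address <- function(x) {
  stringi::stri_trans_nfc(trimws(x))
}

address_key <- function(province, city, district) {
  paste(
    normalize_address(province),
    normalize_address(city),
    normalize_address(district),
    sep = .key_sep
  )
}

#' Construct and validate a gazetteer
#'
#' A gazetteer maps each (province, city, district) address triple to a triple
#' of fixed-width numeric codes: a 2-digit provincial-level administrative
#' division (PAD) code, a 3-digit city code and a 4-digit district code. Codes
#' are opaque digit strings, never numbers, so leading zeros survive. The
#' concatenation `pad_code + city_code + district_code` is the 9-digit
#' surrogate ZIP code of the triple.
#'
#' @param entries Data frame with character columns `province`, `city`,
#'   `district`, `pad_code`, `city_code`, `district_code`.
#' @return A validated `gazetteer` tibble.
#' @export
gazetteer <- function(entries) {
  entries <- as_tibble(entries)
  absent <- setdiff(.gazetteer_cols, names(entries))
  if (length(absent) > 0) {
    stop("gazetteer is missing column(s): ", paste(absent, collapse = ", "),
      call. = FALSE
    )
  }
  entries <- entries[.gazetteer_cols]
  for (col in .gazetteer_cols) {
    entries[[col]] <- as.character(entries[[col]])
  }

  widths <- c(pad_code = 2L, city_code = 3L, district_code = 4L)
  for (col in names(widths)) {
    pattern <- sprintf("^[0-9]{%d}$", widths[[col]])
    bad <- which(!grepl(pattern, entries[[col]]))
    if (length(bad) > 0) {
      stop(
        "gazetteer validation error: ", col, " must be exactly ",
        widths[[col]], " digits; offending row(s): ",
        paste(head(bad, 10L), collapse = ", "),
        call. = FALSE
      )
    }
  }

  akey <- address_key(entries$province, entries$city, entries$district)
  dup <- which(duplicated(akey))
  if (length(dup) > 0) {
    stop(
      "gazetteer validation error: duplicate address triple(s) at row(s): ",
      paste(head(dup, 10L), collapse = ", "),
      call. = FALSE
    )
  }
  zip <- paste0(entries$pad_code, entries$city_code, entries$district_code)
  dupz <- which(duplicated(zip))
  if (length(dupz) > 0) {
    stop(
      "gazetteer validation error: distinct address triples share a code ",
      "triple at row(s): ", paste(head(dupz, 10L), collapse = ", "),
      call. = FALSE
    )
  }

  structure(entries, class = c("gazetteer", class(entries)))
}

#' Load a gazetteer from a delimited text file
#'
#' @param path Path to a delimited file with columns `province`, `city`,
#'   `district`, `pad_code`, `city_code`, `district_code`.
#' @param delim Field delimiter.
#' @return A validated `gazetteer` tibble; width or uniqueness violations are
#'   rejected with the offending row numbers.
#' @export
load_gazetteer <- function(path, delim = ",") {
  if (!file.exists(path)) {
    stop("gazetteer file not found: ", path, call. = FALSE)
  }
  raw <- readr::read_delim(
    path,
    delim = delim, col_types = readr::cols(.default = readr::col_character()),
    na = c("", "NA"), trim_ws = TRUE, progress = FALSE, show_col_types = FALSE
  )
  gazetteer(raw)
}

#' Write a gazetteer to a delimited text file
#'
#' @param gaz A `gazetteer`.
#' @param path Destination path.
#' @param delim Field delimiter.
#' @return `path`, invisibly.
#' @export
write_gazetteer <- function(gaz, path, delim = ",") {
  readr::write_delim(as_tibble(gaz), path, delim = delim, na = "")
  invisible(path)
}

#' Encode residence addresses into 9-digit surrogate ZIP codes
#'
#' Looks each record's (province, city, district) triple up in the gazetteer
#' (exact match after whitespace trimming and Unicode NFC normalization) and
#' attaches the concatenated 9-digit surrogate ZIP. Triples absent from the
#' gazetteer are never guessed: their `zip` is `NA` and they are counted in
#' the encoding report; downstream risk analysis excludes them.
#'
#' @param records Tibble of filtered patient records (all address components
#'   present; run [filter_records()] first).
#' @param gaz A `gazetteer`.
#' @return A list with `records` (input tibble plus a `zip` column) and
#'   `report`, an `encoding_report` with `n_records`, `n_mapped`,
#'   `n_unmapped`, the distinct `unmapped_triples`, and `pad_counts`
#'   (records per PAD code among mapped rows).
#' @export
encode_addresses <- function(records, gaz) {
  if (!inherits(gaz, "gazetteer")) {
    gaz <- gazetteer(gaz)
  }
  incomplete <- is.na(records$province) | is.na(records$city) |
    is.na(records$district)
  if (any(incomplete)) {
    stop(
      sum(incomplete), " record(s) have missing address components; ",
      "apply filter_records() before encoding",
      call. = FALSE
    )
  }

  gkey <- address_key(gaz$province, gaz$city, gaz$district)
  gzip <- paste0(gaz$pad_code, gaz$city_code, gaz$district_code)
  rkey <- address_key(records$province, records$city, records$district)
  idx <- match(rkey, gkey)

  out <- records
  out$zip <- gzip[idx]

  unmapped <- is.na(idx)
  unmapped_triples <- unique(
    records[unmapped, c("province", "city", "district"), drop = FALSE]
  )
  pad_counts <- tibble(pad_code = substr(out$zip[!unmapped], 1L, 2L)) |>
    count(.data$pad_code, name = "n_records")

  report <- structure(
    list(
      n_records = nrow(records),
      n_mapped = sum(!unmapped),
      n_unmapped = sum(unmapped),
      unmapped_triples = as_tibble(unmapped_triples),
      pad_counts = pad_counts
    ),
    class = "encoding_report"
  )
  list(records = out, report = report)
}

#' @export
print.encoding_report <- function(x, ...) {
  cat("Address encoding report\n")
  cat(sprintf("  n_records : %d\n", x$n_records))
  cat(sprintf("  n_mapped  : %d\n", x$n_mapped))
  cat(sprintf("  n_unmapped: %d", x$n_unmapped))
  if (x$n_unmapped > 0) {
    cat(sprintf(" (%d distinct triple(s))", nrow(x$unmapped_triples)))
  }
  cat("\n")
  invisible(x)
}

#' Partition encoded records by provincial-level administrative division
#'
#' Groups records by the first two digits of their surrogate ZIP code (the
#' PAD code). Every encoded record lands in exactly one group.
#'
#' @param records Tibble with a complete `zip` column (drop unmapped rows
#'   first).
#' @return A `pad_partition`: a named list of tibbles keyed by PAD code in
#'   ascending code order, with attribute `n_pads` (number of nonempty
#'   groups).
#' @export
partition_by_pad <- function(records) {
  if (nrow(records) > 0 && anyNA(records$zip)) {
    stop(
      "records contain unmapped addresses (NA zip); ",
      "exclude them before partitioning",
      call. = FALSE
    )
  }
  if (nrow(records) == 0) {
    groups <- stats::setNames(list(), character(0))
  } else {
    pad <- substr(records$zip, 1L, 2L)
    groups <- split(records, pad)
    groups <- groups[order(names(groups))]
  }
  structure(groups, n_pads = length(groups), class = "pad_partition")
}

#' Number of nonempty PAD groups in a partition
#'
#' @param partition A `pad_partition`.
#' @return Integer count of nonempty groups.
#' @export
n_pads <- function(partition) {
  stopifnot(inherits(partition, "pad_partition"))
  attr(partition, "n_pads")
}

#' @export
print.pad_partition <- function(x, ...) {
  sizes <- vapply(x, nrow, integer(1))
  cat(sprintf(
    "PAD partition: %d nonempty group(s), %d record(s)\n",
    attr(x, "n_pads"), sum(sizes)
  ))
  if (length(sizes) > 0) {
    cat("  sizes: ", paste0(names(sizes), "=", sizes, collapse = " "), "\n")
  }
  invisible(x)
}
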