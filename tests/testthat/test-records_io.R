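test_that("well-formed files read back one record per row, in file order", {
  path <- write_tmp_csv(tibble::tibble(
    record_id = c("P1", "P2", "P3"),
    dob = c("1965-07-21", "1980-12-31", "1990-03-05"),
    gender = c("F", "M", "F"),
    province = c("ProvA", "ProvA", "ProvB"),
    city = c("CityA1", "CityA2", "CityB1"),
    district = c("DistA1a", "DistA2a", "DistB1a")
  ))
  rec <- read_records(path)
  expect_equal(nrow(rec), 3L)
  expect_equal(rec$record_id, c("P1", "P2", "P3"))
  expect_equal(rec$dob, as.Date(c("1965-07-21", "1980-12-31", "1990-03-05")))
  expect_equal(rec$gender, c("F", "M", "F"))
})

test_that("non-ISO and impossible dates become missing with a warning", {
  path <- write_tmp_csv(tibble::tibble(
    record_id = c("P1", "P2", "P3"),
    dob = c("31/12/1980", "2001-02-29", "1970-01-15"),
    gender = "F", province = "ProvA", city = "CityA1", district = "DistA1a"
  ))
  expect_warning(rec <- read_records(path), "ISO 8601")
  expect_true(is.na(rec$dob[1]))
  expect_true(is.na(rec$dob[2]))
  expect_equal(rec$dob[3], as.Date("1970-01-15"))
  # record retained despite the bad date
  expect_equal(rec$record_id[1], "P1")
})

test_that("dates after the reference date are treated as missing", {
  path <- write_tmp_csv(tibble::tibble(
    record_id = c("P1", "P2"),
    dob = c("2050-01-01", "1970-01-15"),
    gender = "M", province = "ProvA", city = "CityA1", district = "DistA1a"
  ))
  expect_warning(
    rec <- read_records(path, reference_date = as.Date("2020-01-01")),
    "reference date"
  )
  expect_true(is.na(rec$dob[1]))
  expect_false(is.na(rec$dob[2]))
})

test_that("duplicate record ids are a validation error naming the id", {
  path <- write_tmp_csv(tibble::tibble(
    record_id = c("P1", "P1"),
    dob = "1970-01-15",
    gender = "F", province = "ProvA", city = "CityA1", district = "DistA1a"
  ))
  expect_error(read_records(path), "P1")
})

test_that("missing files and missing mapped columns raise distinct errors", {
  expect_error(read_records(file.path(tempdir(), "nope.csv")), "not found")
  path <- write_tmp_csv(tibble::tibble(
    record_id = "P1", dob = "1970-01-15", gender = "F",
    province = "ProvA", city = "CityA1"
  ))
  expect_error(read_records(path), "schema error.*district")
})

test_that("unrecognized gender values become missing with a warning", {
  path <- write_tmp_csv(tibble::tibble(
    record_id = c("P1", "P2", "P3"),
    dob = "1970-01-15",
    gender = c("X", "m", "F"),
    province = "ProvA", city = "CityA1", district = "DistA1a"
  ))
  expect_warning(rec <- read_records(path), "gender")
  expect_equal(rec$gender, c(NA, "M", "F"))
})

test_that("filtering applies the two exclusion rules with first-match attribution", {
  rec <- tibble::tibble(
    record_id = sprintf("P%d", 1:5),
    dob = as.Date(c(
      "1970-01-15", "1900-01-01", "1980-02-02", "1985-03-03", "1990-04-04"
    )),
    gender = "F",
    province = c("ProvA", "ProvA", NA, "ProvA", "ProvA"),
    city = "CityA1",
    district = "DistA1a"
  )
  out <- filter_records(rec)
  expect_equal(out$report$n_input, 5L)
  expect_equal(out$report$n_missing_address, 1L)
  expect_equal(out$report$n_sentinel_dob, 1L)
  expect_equal(out$report$n_retained, 3L)
  expect_equal(out$records$record_id, c("P1", "P4", "P5"))

  # a record failing both rules counts once, under missing address
  both <- rec
  both$province[2] <- NA
  out2 <- filter_records(both)
  expect_equal(out2$report$n_missing_address, 2L)
  expect_equal(out2$report$n_sentinel_dob, 0L)
  expect_equal(
    out2$report$n_retained + out2$report$n_missing_address +
      out2$report$n_sentinel_dob,
    out2$report$n_input
  )
})

test_that("clean input passes through unchanged and filtering is idempotent", {
  rec <- toy_records()
  out <- filter_records(rec)
  expect_identical(out$records, rec)
  expect_equal(out$report$n_retained, nrow(rec))

  again <- filter_records(out$records)
  expect_identical(again$records, out$records)
  expect_equal(again$report$n_missing_address, 0L)
  expect_equal(again$report$n_sentinel_dob, 0L)
})

test_that("empty input filters to empty output with zero counts", {
  rec <- toy_records()[0, ]
  out <- filter_records(rec)
  expect_equal(nrow(out$records), 0L)
  expect_equal(out$report$n_input, 0L)
  expect_equal(out$report$n_retained, 0L)
})

test_that("filter counts agree with a row-by-row recount on generated data", {
  cfg <- population_config(
    n_patients = 1000L, missing_address_rate = 0.1,
    sentinel_dob_rate = 0.05, seed = 42L
  )
  rec <- generate_population(cfg)$records
  out <- filter_records(rec)

  addr_ok <- !is.na(rec$province) & !is.na(rec$city) & !is.na(rec$district)
  sentinel <- !is.na(rec$dob) & rec$dob == as.Date("1900-01-01")
  expect_equal(out$report$n_retained, sum(addr_ok & !sentinel))
  expect_equal(out$report$n_missing_address, sum(!addr_ok))
  expect_equal(out$report$n_sentinel_dob, sum(addr_ok & sentinel))
  expect_equal(
    out$report$n_retained + out$report$n_missing_address +
      out$report$n_sentinel_dob,
    out$report$n_input
  )
})

test_that("sentinel list must be non-empty and is configurable", {
  rec <- toy_records()
  expect_error(filter_records(rec, sentinel_dobs = as.Date(character(0))))
  out <- filter_records(rec, sentinel_dobs = as.Date("1980-12-31"))
  expect_equal(out$report$n_sentinel_dob, 1L)
  expect_equal(out$records$record_id, c("P1", "P3"))
})

test_that("write then read is the identity on records, including missingness", {
  rec <- toy_records()
  rec$dob[2] <- NA
  rec$gender[3] <- NA
  rec$province[1] <- NA
  path <- withr::local_tempfile(fileext = ".csv")
  write_records(rec, path)
  expect_equal(read_records(path), rec)
})

test_that("writing an empty record set yields a header-only file", {
  path <- withr::local_tempfile(fileext = ".csv")
  write_records(toy_records()[0, ], path)
  expect_equal(length(readLines(path)), 1L)
  expect_equal(nrow(read_records(path)), 0L)
})

test_that("writing the same records twice is byte-identical", {
  rec <- generate_population(
    population_config(n_patients = 10000L, seed = 9L)
  )$records
  p1 <- withr::local_tempfile(fileext = ".csv")
  p2 <- withr::local_tempfile(fileext = ".csv")
  write_records(rec, p1)
  write_records(rec, p2)
  expect_identical(readBin(p1, "raw", file.size(p1)),
    readBin(p2, "raw", file.size(p2)))
})

test_that("tab-delimited round trips work too", {
  rec <- toy_records()
  path <- withr::local_tempfile(fileext = ".tsv")
  write_records(rec, path, delim = "\t")
  expect_equal(read_records(path, delim = "\t"), rec)
})
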