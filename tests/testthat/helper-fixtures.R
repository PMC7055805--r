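toy_gazetteer <- function() {
  gazetteer(tibble::tibble(
    province = c("ProvA", "ProvA", "ProvA", "ProvB"),
    city = c("CityA1", "CityA1", "CityA2", "CityB1"),
    district = c("DistA1a", "DistA1b", "DistA2a", "DistB1a"),
    pad_code = c("11", "11", "11", "12"),
    city_code = c("011", "011", "012", "012"),
    district_code = c("0108", "0109", "0201", "0201")
  ))
}

toy_records <- function() {
  tibble::tibble(
    record_id = c("P1", "P2", "P3"),
    dob = as.Date(c("1965-07-21", "1980-12-31", "1990-03-05")),
    gender = c("F", "M", "F"),
    province = c("ProvA", "ProvA", "ProvB"),
    city = c("CityA1", "CityA2", "CityB1"),
    district = c("DistA1a", "DistA2a", "DistB1a")
  )
}

# encoded-record tibble built directly from parallel vectors, for tests that
# need precise control over keys
encoded_tbl <- function(dob, gender, zip, id = NULL) {
  n <- length(zip)
  tibble::tibble(
    record_id = if (is.null(id)) sprintf("E%03d", seq_len(n)) else id,
    dob = as.Date(dob),
    gender = gender,
    province = rep("p", n),
    city = rep("c", n),
    district = rep("d", n),
    zip = zip
  )
}

write_tmp_csv <- function(df, env = parent.frame()) {
  path <- withr::local_tempfile(fileext = ".csv", .local_envir = env)
  readr::write_csv(df, path, na = "")
  path
}

# One shared "paper_like" pipeline run, cached across acceptance blocks.
.fixture_cache <- new.env(parent = emptyenv())

paper_like_run <- function() {
  if (is.null(.fixture_cache$paper_like)) {
    bundle <- generate_population(scenario_presets()$paper_like)
    filtered <- filter_records(bundle$records)
    enc <- encode_addresses(filtered$records, bundle$gazetteer)
    usable <- enc$records[!is.na(enc$records$zip), , drop = FALSE]
    .fixture_cache$paper_like <- list(
      bundle = bundle,
      filter_report = filtered$report,
      usable = usable,
      partition = partition_by_pad(usable),
      hist_limited = compute_bins(apply_policy(usable, policy_limited())),
      hist_safe = compute_bins(apply_policy(usable, policy_safe_harbor()))
    )
  }
  .fixture_cache$paper_like
}
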