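#' Per-PAD 1-distinct risk table
#'
#' For each nonempty provincial-level administrative division (PAD), bins the
#' PAD's records under the given policy and reports its population, the
#' number of unique (1-distinct) patients, and the unique percentage. Binning
#' is within-PAD; because the surrogate ZIP of a PAD is prefix-disjoint from
#' every other PAD's, this coincides with binning nationwide and restricting
#' to the PAD whenever the policy keeps at least 2 ZIP digits.
#'
#' Rows are sorted by ascending population, ties broken by ascending PAD
#' code, matching the conventional presentation of uniqueness-versus-sample-
#' size plots (log-log axes; the log transform is left to plotting).
#'
#' @param partition A `pad_partition` of encoded records.
#' @param spec A `policy_spec`.
#' @param reference_date Passed to [apply_policy()] (needed only with
#'   top-coding).
#' @return Tibble with columns `pad_code`, `population`, `unique_count`,
#'   `unique_pct`, `policy`. `population` counts the patients actually
#'   binned (complete quasi-identifier tuples).
#' @export
pad_risk_table <- function(partition, spec, reference_date = NULL) {
  stopifnot(inherits(partition, "pad_partition"), inherits(spec, "policy_spec"))
  rows <- lapply(names(partition), function(pad) {
    view <- apply_policy(partition[[pad]], spec,
      reference_date = reference_date
    )
    hist <- compute_bins(view)
    pop <- n_total(hist)
    uniq <- if (pop > 0) as.integer(h_of_g(hist, 1L)) else 0L
    tibble(
      pad_code = pad,
      population = pop,
      unique_count = uniq,
      unique_pct = if (pop > 0) 100 * uniq / pop else NA_real_
    )
  })
  out <- bind_rows(rows)
  if (nrow(out) == 0) {
    out <- tibble(
      pad_code = character(0), population = integer(0),
      unique_count = integer(0), unique_pct = numeric(0)
    )
  }
  out$policy <- spec$name
  out[order(out$population, out$pad_code), , drop = FALSE]
}

#' Rank correlation between PAD population and unique percentage
#'
#' Spearman's rank correlation between a PAD's sampled population and its
#' 1-distinct percentage. Larger samples give each quasi-identifier tuple
#' more chances to recur, so on homogeneous populations the correlation is
#' expected to be negative: uniqueness falls as the sample grows.
#'
#' Undefined cases -- fewer than 3 rows, constant population ranks, or
#' constant unique percentages -- return `NA` with a warning rather than a
#' coefficient, so degenerate tables are reported explicitly.
#'
#' @param table A tibble from [pad_risk_table()].
#' @return Spearman's rho in `[-1, 1]`, or `NA_real_` when undefined.
#' @export
trend_statistic <- function(table) {
  stopifnot(all(c("population", "unique_pct") %in% names(table)))
  ok <- !is.na(table$unique_pct)
  pop <- table$population[ok]
  pct <- table$unique_pct[ok]
  if (length(pop) < 3) {
    warning("trend undefined: fewer than 3 PADs with defined uniqueness",
      call. = FALSE
    )
    return(NA_real_)
  }
  if (length(unique(pop)) == 1 || length(unique(pct)) == 1) {
    warning("trend undefined: constant ranks", call. = FALSE)
    return(NA_real_)
  }
  stats::cor(pop, pct, method = "spearman")
}

#' Export a per-PAD risk table as delimited text
#'
#' @param table Tibble from [pad_risk_table()].
#' @param path Destination path.
#' @param delim Field delimiter.
#' @return `path`, invisibly.
#' @export
write_pad_risk_table <- function(table, path, delim = ",") {
  readr::write_delim(table, path, delim = delim, na = "")
  invisible(path)
}
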