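#' Bin quasi-identifier keys into an equivalence-class size histogram
#'
#' Patients are grouped by exact equality of their quasi-identifier tuple;
#' each group is an equivalence class ("bin"). The histogram records, for
#' every class size `i`, the number of bins holding exactly `i` patients,
#' written `|bin(i)|`. It is the sufficient statistic for all g-distinct
#' quantities: patients in bins of size `<= g` are the g-distinct (or rarer)
#' individuals.
#'
#' @param x A `qi_view`, a data frame of key components (one row per
#'   patient), or a character vector of ready-made keys.
#' @return A `class_size_histogram`: tibble with columns `class_size`,
#'   `num_bins` (both positive, sorted by `class_size`) and attribute
#'   `n_total`, satisfying `sum(class_size * num_bins) == n_total`.
#' @export
compute_bins <- function(x) {
  UseMethod("compute_bins")
}

#' @export
compute_bins.qi_view <- function(x) {
  compute_bins(x$keys)
}

#' @export
compute_bins.data.frame <- function(x) {
  if (any(vapply(x, anyNA, logical(1)))) {
    stop("quasi-identifier keys must be complete (no missing components)",
      call. = FALSE
    )
  }
  keys <- do.call(paste, c(as.list(x), sep = .key_sep))
  compute_bins(keys)
}

#' @export
compute_bins.character <- function(x) {
  if (anyNA(x)) {
    stop("quasi-identifier keys must be complete (no missing components)",
      call. = FALSE
    )
  }
  if (length(x) == 0) {
    return(new_class_size_histogram(integer(0), integer(0), 0L))
  }
  class_sizes <- tabulate(match(x, unique(x)))
  tab <- tabulate(class_sizes)
  sizes <- which(tab > 0)
  new_class_size_histogram(sizes, tab[sizes], length(x))
}

new_class_size_histogram <- function(class_size, num_bins, n_total) {
  class_size <- as.integer(class_size)
  num_bins <- as.integer(num_bins)
  stopifnot(
    length(class_size) == length(num_bins),
    all(class_size > 0), all(num_bins > 0),
    !is.unsorted(class_size, strictly = TRUE),
    sum(as.numeric(class_size) * num_bins) == n_total
  )
  structure(
    tibble(class_size = class_size, num_bins = num_bins),
    n_total = as.integer(n_total),
    class = c("class_size_histogram", class(tibble()))
  )
}

#' Total number of patients summarized by a histogram or curve
#'
#' @param x A `class_size_histogram` or `risk_curve`.
#' @return Integer patient count `N`.
#' @export
n_total <- function(x) {
  attr(x, "n_total")
}

#' Cumulative g-distinct count h(g)
#'
#' An individual is *g-distinct* when at most `g - 1` other individuals share
#' their quasi-identifier tuple. The cumulative count is
#' `h(g) = sum_{i=1}^{g} i * |bin(i)|`: the number of patients lying in
#' equivalence classes of size at most `g`, i.e. the population at risk at
#' threshold `g`.
#'
#' @param hist A `class_size_histogram`.
#' @param g Vector of positive integer thresholds.
#' @return Numeric vector of patient counts, one per element of `g`.
#' @export
h_of_g <- function(hist, g) {
  stopifnot(inherits(hist, "class_size_histogram"))
  if (length(g) == 0 || anyNA(g) || any(g < 1) || any(g != floor(g))) {
    stop("`g` must contain positive integers", call. = FALSE)
  }
  if (nrow(hist) == 0) {
    return(rep(0, length(g)))
  }
  cum <- cumsum(as.numeric(hist$class_size) * hist$num_bins)
  idx <- findInterval(g, hist$class_size)
  ifelse(idx == 0, 0, cum[pmax(idx, 1L)])
}

#' Cumulative risk curve over all class sizes
#'
#' Materializes `(g, h(g), h(g)/N)` for every `g` from 1 to the largest class
#' size. The fraction column is the share of the population that is
#' g-distinct or rarer; it is non-decreasing and reaches exactly 1 at the
#' maximum class size.
#'
#' @param hist A `class_size_histogram` with `n_total > 0`.
#' @return A `risk_curve` tibble with columns `g`, `h_g`, `fraction` and
#'   attribute `n_total`.
#' @export
risk_curve <- function(hist) {
  stopifnot(inherits(hist, "class_size_histogram"))
  n <- n_total(hist)
  if (is.null(n) || n == 0) {
    stop(
      "risk_curve() needs a nonempty population; ",
      "check upstream filters and encoding",
      call. = FALSE
    )
  }
  gmax <- max(hist$class_size)
  g <- seq_len(gmax)
  h <- h_of_g(hist, g)
  structure(
    tibble(g = g, h_g = h, fraction = h / n),
    n_total = n,
    class = c("risk_curve", class(tibble()))
  )
}

#' Fraction of the population that is unique (1-distinct)
#'
#' `h(1)/N`: the share of patients whose quasi-identifier tuple is shared by
#' nobody else, i.e. the uniquely identifiable share.
#'
#' @param hist A `class_size_histogram` with `n_total > 0`.
#' @return A fraction in `[0, 1]`.
#' @export
unique_fraction <- function(hist) {
  stopifnot(inherits(hist, "class_size_histogram"))
  n <- n_total(hist)
  if (is.null(n) || n == 0) {
    stop(
      "unique_fraction() needs a nonempty population; ",
      "check upstream filters and encoding",
      call. = FALSE
    )
  }
  h_of_g(hist, 1L) / n
}

#' Smallest g whose at-risk fraction reaches a target
#'
#' Answers threshold queries such as "what indistinguishability level covers
#' 95% of the population?": the minimal `g` with `h(g)/N >= p`. For `p = 1`
#' this is the maximum class size.
#'
#' @param curve A `risk_curve`.
#' @param p Target fraction in `(0, 1]`.
#' @return A positive integer `g`.
#' @export
g_for_fraction <- function(curve, p) {
  stopifnot(inherits(curve, "risk_curve"))
  if (length(p) != 1L || is.na(p) || p <= 0 || p > 1) {
    stop("`p` must be a single fraction in (0, 1]", call. = FALSE)
  }
  curve$g[which(curve$fraction >= p)[1L]]
}

#' @export
print.class_size_histogram <- function(x, ...) {
  cat(sprintf(
    "Equivalence-class size histogram: N = %d, %d distinct class size(s)\n",
    n_total(x), nrow(x)
  ))
  NextMethod()
}

#' @export
print.risk_curve <- function(x, ...) {
  cat(sprintf(
    "g-distinct risk curve: N = %d, max class size %d\n",
    n_total(x), if (nrow(x)) max(x$g) else 0L
  ))
  NextMethod()
}

#' Export a class-size histogram as delimited text
#'
#' Columns: `class_size`, `num_bins`, `num_patients`
#' (`class_size * num_bins`).
#'
#' @param hist A `class_size_histogram`.
#' @param path Destination path.
#' @param delim Field delimiter.
#' @return `path`, invisibly.
#' @export
write_histogram <- function(hist, path, delim = ",") {
  out <- tibble(
    class_size = hist$class_size,
    num_bins = hist$num_bins,
    num_patients = hist$class_size * hist$num_bins
  )
  readr::write_delim(out, path, delim = delim)
  invisible(path)
}

#' Export a risk curve as delimited text
#'
#' Columns: `g`, `h_g`, `fraction`. With `log_thin = TRUE` only an
#' approximately log-spaced subset of `g` values is written (always including
#' g = 1 and the maximum class size), which keeps export sizes manageable
#' when the largest class holds thousands of patients, as is typical for
#' strongly generalized views.
#'
#' @param curve A `risk_curve`.
#' @param path Destination path.
#' @param delim Field delimiter.
#' @param log_thin Keep only log-spaced `g` values.
#' @param points Approximate number of points kept when thinning.
#' @return `path`, invisibly.
#' @export
write_risk_curve <- function(curve, path, delim = ",", log_thin = FALSE,
                             points = 200L) {
  out <- as_tibble(curve)
  if (log_thin && nrow(out) > points) {
    gmax <- max(out$g)
    keep <- unique(c(1L, round(10^seq(0, log10(gmax), length.out = points)),
      gmax))
    out <- out[out$g %in% keep, , drop = FALSE]
  }
  readr::write_delim(out, path, delim = delim)
  invisible(path)
}
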