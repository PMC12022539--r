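#' Age-accretion growth parameters
#'
#' The train grows by annual addition of whole follicle rows in alternating
#' 10/11, so eyespot number is an intrinsically determined trait: within an
#' age class it cannot vary, and the lifetime total rises in steps of 10 or
#' 11 toward a ceiling. Train length rises asymptotically with age.
#'
#' @param rows_per_year Rows added per breeding season (default 1).
#' @param max_rows Ceiling on total rows (default 19, the top of the observed
#'   17--19 specimen range; pass `Inf` for the uncapped lifetime scenario).
#' @param n_fishtail_rows Oldest rows bearing fishtail feathers (3--5).
#' @param n_minor_rows Newest rows bearing minor eyespots (2--3).
#' @param length_asymptote Asymptotic train length (cm).
#' @param length_rate Exponential approach rate (per year).
#' @param first_row_size Size (10 or 11) of the first-formed (oldest) row.
#' @param age_offset Age (years) at which the first row appears minus one;
#'   rows at age a are `min(rows_per_year * (a - age_offset), max_rows)`.
#' @return A `growth_params` object.
#' @export
growth_params <- function(rows_per_year = 1, max_rows = 19,
                          n_fishtail_rows = 4, n_minor_rows = 2,
                          length_asymptote = 150, length_rate = 0.3,
                          first_row_size = 10, age_offset = 0) {
  check_number(rows_per_year, "rows_per_year", positive = TRUE, integer = TRUE)
  if (!identical(max_rows, Inf))
    check_number(max_rows, "max_rows", positive = TRUE, integer = TRUE)
  check_number(n_fishtail_rows, "n_fishtail_rows", nonneg = TRUE, integer = TRUE)
  check_number(n_minor_rows, "n_minor_rows", nonneg = TRUE, integer = TRUE)
  check_number(length_asymptote, "length_asymptote", positive = TRUE)
  check_number(length_rate, "length_rate", positive = TRUE)
  check_number(age_offset, "age_offset", nonneg = TRUE)
  if (is.finite(max_rows) && n_fishtail_rows + n_minor_rows > max_rows)
    stop_invalid("fishtail + minor rows exceed max_rows")
  if (!first_row_size %in% c(10, 11))
    stop_invalid("`first_row_size` must be 10 or 11")
  structure(list(rows_per_year = rows_per_year, max_rows = max_rows,
                 n_fishtail_rows = n_fishtail_rows,
                 n_minor_rows = n_minor_rows,
                 length_asymptote = length_asymptote,
                 length_rate = length_rate,
                 first_row_size = as.integer(first_row_size),
                 age_offset = age_offset),
            class = "growth_params")
}

#' Follicle rows present at a given age
#'
#' @param age Age in years (>= 0); vectorised.
#' @param params A [growth_params()].
#' @return Integer row count, capped at `max_rows`.
#' @examples
#' rows_at_age(18, growth_params()) # 18
#' @export
rows_at_age <- function(age, params = growth_params()) {
  if (any(!is.finite(age)) || any(age < 0))
    stop_invalid("`age` must be finite and >= 0")
  n <- pmin(params$rows_per_year * pmax(age - params$age_offset, 0),
            params$max_rows)
  as.integer(floor(n))
}

# Row sizes ordered oldest (posterior, first-formed) to newest.
growth_row_sizes <- function(n, first_row_size) {
  if (n == 0) return(integer(0))
  rep(c(first_row_size, 21L - first_row_size), length.out = n)
}

#' Visible (full) eyespot count at a given age
#'
#' The alternating 10/11 sum over the rows present, minus the oldest
#' fishtail-bearing rows and the newest minor-eyespot rows. Sixteen
#' eyespot-bearing rows give 168, inside the 165--170 band reported for
#' mature males.
#'
#' @inheritParams rows_at_age
#' @return Integer count (never negative); vectorised over `age`.
#' @export
eyespot_count_at_age <- function(age, params = growth_params()) {
  vapply(rows_at_age(age, params), function(n) {
    sizes <- growth_row_sizes(n, params$first_row_size)
    nf <- min(params$n_fishtail_rows, n)
    nm <- min(params$n_minor_rows, n - nf)
    total <- sum(sizes)
    ft <- if (nf > 0) sum(sizes[seq_len(nf)]) else 0L
    mn <- if (nm > 0) sum(sizes[seq.int(n - nm + 1L, n)]) else 0L
    max(as.integer(total - ft - mn), 0L)
  }, integer(1))
}

#' Asymptotic train length at a given age
#'
#' `length_asymptote * (1 - exp(-length_rate * age))`: strictly increasing,
#' concave (each year's gain smaller than the last), bounded by the
#' asymptote.
#'
#' @inheritParams rows_at_age
#' @return Length in cm; vectorised over `age`.
#' @export
train_length <- function(age, params = growth_params()) {
  if (any(!is.finite(age)) || any(age < 0))
    stop_invalid("`age` must be finite and >= 0")
  params$length_asymptote * (1 - exp(-params$length_rate * age))
}

#' Growth trajectory over a range of ages
#'
#' @param params A [growth_params()].
#' @param ages Ages (years) to tabulate.
#' @return data.frame with `age`, `n_rows`, `total_follicles`,
#'   `visible_eyespots`, `fishtail_count`, `minor_count`, `train_length`.
#' @export
growth_trajectory <- function(params = growth_params(), ages = 0:20) {
  n <- rows_at_age(ages, params)
  tot <- vapply(n, function(k) sum(growth_row_sizes(k, params$first_row_size)),
                integer(1))
  eye <- eyespot_count_at_age(ages, params)
  ft <- vapply(n, function(k) {
    sizes <- growth_row_sizes(k, params$first_row_size)
    nf <- min(params$n_fishtail_rows, k)
    if (nf > 0) sum(sizes[seq_len(nf)]) else 0L
  }, integer(1))
  data.frame(age = ages, n_rows = n, total_follicles = tot,
             visible_eyespots = eye, fishtail_count = ft,
             minor_count = tot - eye - ft,
             train_length = train_length(ages, params))
}
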