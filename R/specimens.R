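#' Parameters for the synthetic museum-specimen generator
#'
#' Defaults emulate the published summary statistics of the museum series:
#' 17--19 follicle rows, fishtail feathers from 3--4 rows, minor eyespots on
#' 2--3 anterior rows, eyespot-feather lengths (ESL) and fishtail-feather
#' lengths (FTL) drawn from Normal distributions with the printed means/SDs
#' (truncated at zero), and a small per-feather damage probability to mimic
#' breakage and handling loss.
#'
#' @param species `"cristatus"` (Indian blue) or `"muticus"` (green); selects
#'   the length defaults.
#' @param n_rows_support Integer set the row count is drawn from (uniform).
#' @param fishtail_rows_support Integer set for fishtail row counts.
#' @param minor_rows_support Integer set for minor-eyespot row counts.
#' @param damage_rate Per-feather independent probability of damage.
#' @param esl_mean,esl_sd,ftl_mean,ftl_sd Length distribution parameters
#'   (cm); `NULL` picks the species default.
#' @param first_row_size Size of the first-formed (oldest) row.
#' @return A `specimen_params` object.
#' @export
specimen_params <- function(species = c("cristatus", "muticus"),
                            n_rows_support = 17:19,
                            fishtail_rows_support = c(3L, 4L),
                            minor_rows_support = c(2L, 3L),
                            damage_rate = 0.02,
                            esl_mean = NULL, esl_sd = NULL,
                            ftl_mean = NULL, ftl_sd = NULL,
                            first_row_size = 10) {
  species <- match.arg(species)
  defaults <- switch(species,
    cristatus = c(esl_mean = 112.68, esl_sd = 25.58,
                  ftl_mean = 134.15, ftl_sd = 32.17),
    muticus = c(esl_mean = 101.66, esl_sd = 25.53,
                ftl_mean = 120.16, ftl_sd = 29.49))
  if (is.null(esl_mean)) esl_mean <- defaults[["esl_mean"]]
  if (is.null(esl_sd)) esl_sd <- defaults[["esl_sd"]]
  if (is.null(ftl_mean)) ftl_mean <- defaults[["ftl_mean"]]
  if (is.null(ftl_sd)) ftl_sd <- defaults[["ftl_sd"]]
  if (!is.numeric(n_rows_support) || length(n_rows_support) < 1 ||
      any(n_rows_support < 1) || any(n_rows_support != round(n_rows_support)))
    stop_invalid("`n_rows_support` must be positive integers")
  if (!is.numeric(fishtail_rows_support) || any(fishtail_rows_support < 0))
    stop_invalid("`fishtail_rows_support` must be non-negative integers")
  if (!is.numeric(minor_rows_support) || any(minor_rows_support < 0))
    stop_invalid("`minor_rows_support` must be non-negative integers")
  check_number(damage_rate, "damage_rate", nonneg = TRUE)
  if (damage_rate > 1) stop_invalid("`damage_rate` must be in [0, 1]")
  check_number(esl_sd, "esl_sd", nonneg = TRUE)
  check_number(ftl_sd, "ftl_sd", nonneg = TRUE)
  if (!first_row_size %in% c(10, 11))
    stop_invalid("`first_row_size` must be 10 or 11")
  if (max(fishtail_rows_support) + max(minor_rows_support) >
      min(n_rows_support))
    stop_invalid("fishtail + minor rows can exceed the smallest row count")
  structure(list(species = species,
                 n_rows_support = as.integer(n_rows_support),
                 fishtail_rows_support = as.integer(fishtail_rows_support),
                 minor_rows_support = as.integer(minor_rows_support),
                 damage_rate = damage_rate,
                 esl_mean = esl_mean, esl_sd = esl_sd,
                 ftl_mean = ftl_mean, ftl_sd = ftl_sd,
                 first_row_size = as.integer(first_row_size)),
            class = "specimen_params")
}

# Normal truncated at 0 via inverse-CDF sampling.
rtruncnorm0 <- function(n, mean, sd) {
  if (sd == 0) return(rep(max(mean, 0), n))
  p0 <- stats::pnorm(0, mean, sd)
  stats::qnorm(stats::runif(n, p0, 1), mean, sd)
}

# Deterministic class sums for a specimen's rows (oldest-first sizes).
class_counts <- function(n_rows, n_fishtail, n_minor, first_row_size) {
  sizes <- growth_row_sizes(n_rows, first_row_size)
  nf <- min(n_fishtail, n_rows)
  nm <- min(n_minor, n_rows - nf)
  ft <- if (nf > 0) sum(sizes[seq_len(nf)]) else 0L
  mn <- if (nm > 0) sum(sizes[seq.int(n_rows - nm + 1L, n_rows)]) else 0L
  c(eyespot = as.integer(sum(sizes) - ft - mn), fishtail = as.integer(ft),
    minor = as.integer(mn))
}

#' Generate synthetic museum-specimen records
#'
#' Each record samples a row count and class-row counts from their supports,
#' computes the lattice-predicted feather counts deterministically (the
#' developmental constraint: counts are fixed given the rows), removes
#' damaged feathers binomially, and draws feather lengths from the truncated
#' Normal length model. Damage-corrected counts (each damaged feather counted
#' as if present, the published counting convention) are reported alongside
#' the raw counts.
#'
#' @param n Number of specimens (>= 1).
#' @param params A [specimen_params()].
#' @param seed RNG seed (required; identical seed gives identical records).
#' @return data.frame of `specimen_record`s, one row per specimen.
#' @examples
#' head(generate_specimens(5, specimen_params(), seed = 1))
#' @export
generate_specimens <- function(n, params = specimen_params(), seed) {
  check_number(n, "n", positive = TRUE, integer = TRUE)
  if (!inherits(params, "specimen_params"))
    stop_invalid("`params` must be a specimen_params")
  if (missing(seed) || is.null(seed))
    stop_invalid("`seed` is required: pass an integer RNG seed")
  check_number(seed, "seed", integer = TRUE)
  set.seed(seed)
  # sample() treats a length-1 vector as 1:x; degenerate supports must stay fixed
  draw <- function(support) if (length(support) == 1L) rep(support, n) else
    sample(support, n, replace = TRUE)
  n_rows <- draw(params$n_rows_support)
  n_ft <- draw(params$fishtail_rows_support)
  n_mn <- draw(params$minor_rows_support)
  pred <- t(mapply(class_counts, n_rows, n_ft, n_mn,
                   MoreArgs = list(first_row_size = params$first_row_size)))
  dmg_eye <- stats::rbinom(n, pred[, "eyespot"], params$damage_rate)
  dmg_ft <- stats::rbinom(n, pred[, "fishtail"], params$damage_rate)
  data.frame(
    specimen_id = seq_len(n),
    species = params$species,
    n_rows = as.integer(n_rows),
    n_fishtail_rows = as.integer(n_ft),
    n_minor_rows = as.integer(n_mn),
    eyespot_feather_count = as.integer(pred[, "eyespot"] - dmg_eye),
    eyespot_feather_count_corrected = as.integer(pred[, "eyespot"]),
    fishtail_feather_count = as.integer(pred[, "fishtail"] - dmg_ft),
    fishtail_feather_count_corrected = as.integer(pred[, "fishtail"]),
    minor_feather_count = as.integer(pred[, "minor"]),
    n_damaged = as.integer(dmg_eye + dmg_ft),
    esl_cm = rtruncnorm0(n, params$esl_mean, params$esl_sd),
    ftl_cm = rtruncnorm0(n, params$ftl_mean, params$ftl_sd),
    stringsAsFactors = FALSE)
}

#' Summarise specimen records in the published table layout
#'
#' Per species and measured column: N, mean, sample SD (n - 1 denominator),
#' min, and max.
#'
#' @param records A [generate_specimens()] data.frame (or any data.frame with
#'   a `species` column and numeric measurement columns).
#' @param columns Measurement columns to summarise.
#' @return data.frame with `species`, `variable`, `n`, `mean`, `sd`, `min`,
#'   `max`.
#' @export
summarize_specimens <- function(records,
                                columns = c("n_rows",
                                            "eyespot_feather_count",
                                            "eyespot_feather_count_corrected",
                                            "fishtail_feather_count",
                                            "esl_cm", "ftl_cm")) {
  if (!is.data.frame(records) || nrow(records) == 0)
    stop_empty("`records` must be a non-empty data.frame")
  columns <- intersect(columns, names(records))
  if (length(columns) == 0)
    stop_invalid("no requested columns present in `records`")
  sp <- if ("species" %in% names(records)) records$species else
    rep("all", nrow(records))
  out <- do.call(rbind, lapply(split(records, sp), function(g) {
    lbl <- if ("species" %in% names(g)) g$species[1] else "all"
    do.call(rbind, lapply(columns, function(col) {
      v <- g[[col]]
      data.frame(species = lbl, variable = col, n = length(v),
                 mean = mean(v), sd = if (length(v) > 1) stats::sd(v) else 0,
                 min = min(v), max = max(v), stringsAsFactors = FALSE)
    }))
  }))
  rownames(out) <- NULL
  out
}
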