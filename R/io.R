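# Configuration, provenance and file output for the pipeline. All artifacts
# get a sidecar JSON with the config hash, seed and package version so any
# output can be traced to the run that produced it.

#' Default run configuration
#'
#' @return Nested list mirroring the YAML config layout: `seed` plus
#'   `lattice`, `expansion`, `classify`, `metrics`, `growth`, `specimens`
#'   blocks.
#' @export
default_run_config <- function() {
  list(
    seed = NULL,
    lattice = list(alignment = "zigzag", row_sizes = "alt_10_11",
                   first_row_size = 10, n_rows = 18, row_pitch = 1,
                   within_row_pitch = 1),
    expansion = list(fan_span = 180, base_radius = 5, radial_pitch = 1,
                     midline_angle = 90),
    classify = list(n_fishtail_rows = 4, n_minor_rows = 2),
    metrics = list(classes = "eyespot"),
    growth = list(rows_per_year = 1, max_rows = 19, n_fishtail_rows = 4,
                  n_minor_rows = 2, length_asymptote = 150,
                  length_rate = 0.3, first_row_size = 10, ages = 0:20),
    specimens = list(species = "cristatus", n = 21, damage_rate = 0.02))
}

merge_config <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(base[[nm]]) && is.list(override[[nm]]))
      base[[nm]] <- merge_config(base[[nm]], override[[nm]])
    else base[[nm]] <- override[[nm]]
  }
  base
}

#' Read a YAML run configuration
#'
#' Unspecified fields fall back to [default_run_config()].
#'
#' @param path Path to a YAML file.
#' @return Config list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path))
    stop(errorCondition(sprintf("config file not found: %s", path),
                        class = c("pavotrain_io_error", "error")))
  merge_config(default_run_config(), yaml::read_yaml(path))
}

config_hash <- function(config) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  yaml::write_yaml(config, tmp)
  unname(tools::md5sum(tmp))
}

write_sidecar <- function(config, out_dir, outputs) {
  info <- list(config_hash = config_hash(config), seed = config$seed,
               package_version = as.character(utils::packageVersion("pavotrain")),
               outputs = outputs)
  jsonlite::write_json(info, file.path(out_dir, "run_info.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
}

ensure_out_dir <- function(out_dir) {
  if (!dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir))
    stop(errorCondition(sprintf("cannot create output directory: %s", out_dir),
                        class = c("pavotrain_io_error", "error")))
  invisible(out_dir)
}

config_lattice <- function(config) {
  lc <- config$lattice
  scheme <- arrangement_scheme(lc$alignment, lc$row_sizes, lc$first_row_size)
  build_lattice(scheme, lc$n_rows, lc$row_pitch, lc$within_row_pitch)
}

config_geometry <- function(config) {
  ec <- config$expansion
  expansion_geometry(ec$fan_span, ec$base_radius, ec$radial_pitch,
                     ec$midline_angle)
}

#' Run the lattice-to-pattern simulation and write its artifacts
#'
#' Builds the configured lattice, expands it, classifies feathers, computes
#' the metric bundle, and writes `lattice.csv`, `pattern.csv`,
#' `pattern.svg`, `metrics.json` and a `run_info.json` sidecar to `out_dir`.
#'
#' @param config Config list (see [default_run_config()]).
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the `pattern_metrics`.
#' @export
run_simulate <- function(config = default_run_config(), out_dir) {
  ensure_out_dir(out_dir)
  lat <- config_lattice(config)
  pat <- expand_train(lat, config_geometry(config))
  pat <- classify_feathers(pat, config$classify$n_fishtail_rows,
                           config$classify$n_minor_rows)
  met <- pattern_metrics(pat, classes = config$metrics$classes)
  export_lattice(lat, file.path(out_dir, "lattice.csv"),
                 file.path(out_dir, "lattice.json"))
  export_pattern(pat, file.path(out_dir, "pattern.csv"))
  render_svg(pat, file.path(out_dir, "pattern.svg"))
  jsonlite::write_json(unclass(met), file.path(out_dir, "metrics.json"),
                       auto_unbox = TRUE, digits = NA)
  write_sidecar(config, out_dir,
                c("lattice.csv", "lattice.json", "pattern.csv", "pattern.svg",
                  "metrics.json"))
  invisible(met)
}

#' Compare pattern metrics across arrangement schemes
#'
#' Runs the four simulated arrangements (10/11 zigzag, 10/11 parallel,
#' 10/10 zigzag, 11/11 zigzag) under one shared geometry and tabulates their
#' metrics.
#'
#' @param config Config list; the `lattice` block's scheme fields are
#'   overridden per row.
#' @param schemes data.frame with `alignment` and `row_sizes` columns; the
#'   default lists the four standard arrangements.
#' @return data.frame: one row per scheme with the metric columns.
#' @export
compare_schemes <- function(config = default_run_config(),
                            schemes = data.frame(
                              alignment = c("zigzag", "parallel", "zigzag",
                                            "zigzag"),
                              row_sizes = c("alt_10_11", "alt_10_11",
                                            "const_10", "const_11"),
                              stringsAsFactors = FALSE)) {
  out <- lapply(seq_len(nrow(schemes)), function(i) {
    cfg <- config
    cfg$lattice$alignment <- schemes$alignment[i]
    cfg$lattice$row_sizes <- schemes$row_sizes[i]
    lat <- config_lattice(cfg)
    pat <- expand_train(lat, config_geometry(cfg))
    pat <- classify_feathers(pat, cfg$classify$n_fishtail_rows,
                             cfg$classify$n_minor_rows)
    met <- pattern_metrics(pat, classes = cfg$metrics$classes)
    data.frame(scheme = paste(schemes$row_sizes[i], schemes$alignment[i]),
               alignment = schemes$alignment[i],
               row_sizes = schemes$row_sizes[i],
               n_points = met$n_points, hexagonality = met$hexagonality,
               nn_distance_cv = met$nn_distance_cv,
               symmetry_error = met$symmetry_error,
               n_radial_lines = met$n_radial_lines, density = met$density,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Run the scheme comparison and write `compare.csv`
#'
#' @inheritParams run_simulate
#' @return Invisibly, the comparison data.frame.
#' @export
run_compare <- function(config = default_run_config(), out_dir) {
  ensure_out_dir(out_dir)
  cmp <- compare_schemes(config)
  utils::write.csv(cmp, file.path(out_dir, "compare.csv"), row.names = FALSE)
  write_sidecar(config, out_dir, "compare.csv")
  invisible(cmp)
}

#' Run the growth model and write `trajectory.csv`
#'
#' @inheritParams run_simulate
#' @return Invisibly, the trajectory data.frame.
#' @export
run_grow <- function(config = default_run_config(), out_dir) {
  ensure_out_dir(out_dir)
  gc <- config$growth
  max_rows <- gc$max_rows
  if (is.character(max_rows) || is.null(max_rows)) max_rows <- Inf
  params <- growth_params(gc$rows_per_year, max_rows, gc$n_fishtail_rows,
                          gc$n_minor_rows, gc$length_asymptote,
                          gc$length_rate, gc$first_row_size)
  ages <- gc$ages
  if (length(ages) == 2 && is.numeric(ages)) ages <- seq(ages[1], ages[2])
  traj <- growth_trajectory(params, ages)
  utils::write.csv(traj, file.path(out_dir, "trajectory.csv"),
                   row.names = FALSE)
  write_sidecar(config, out_dir, "trajectory.csv")
  invisible(traj)
}

#' Generate synthetic specimens and write record + summary CSVs
#'
#' Requires `config$seed`; there is no silent default for the RNG.
#'
#' @inheritParams run_simulate
#' @return Invisibly, the records data.frame.
#' @export
run_specimens <- function(config = default_run_config(), out_dir) {
  ensure_out_dir(out_dir)
  if (is.null(config$seed))
    stop_invalid("`config$seed` is required for specimen generation")
  sc <- config$specimens
  params <- specimen_params(species = sc$species,
                            damage_rate = sc$damage_rate)
  recs <- generate_specimens(sc$n, params, seed = config$seed)
  utils::write.csv(recs, file.path(out_dir, "specimens.csv"),
                   row.names = FALSE)
  utils::write.csv(summarize_specimens(recs),
                   file.path(out_dir, "specimen_summary.csv"),
                   row.names = FALSE)
  write_sidecar(config, out_dir, c("specimens.csv", "specimen_summary.csv"))
  invisible(recs)
}
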