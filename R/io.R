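#' Load an instrument configuration and well map from file
#'
#' Reads a YAML or JSON configuration (dispatched on file extension) with keys
#' `n_rings`, `n_radii`, `combo_order`, `n_dilutions`,
#' `seconds_per_position`, `droplets_per_position_ml`, and `layout`. `layout`
#' is either the string `"dilution"` (canonical layout, enforcing
#' `n_rings = n_dilutions = combo_order`) or a list of well entries with keys
#' `ring`, `radius` and either `drug` + `dilution` or `kind: cell|empty`;
#' slots not listed are empty. Every violated constraint is reported in a
#' single error.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A list with elements `config` (`instrument_config`) and `wellmap`
#'   (`well_map`).
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
                yaml = , yml = yaml::read_yaml(path),
                json = jsonlite::read_json(path, simplifyVector = TRUE),
                stop("unsupported config format '.", ext, "' (use YAML or JSON)"))
  need <- c("n_rings", "n_radii", "combo_order")
  missing <- setdiff(need, names(raw))
  if (length(missing) > 0L)
    stop("config is missing required keys: ", paste(missing, collapse = ", "))
  cfg <- structure(
    list(n_rings = as.integer(raw$n_rings),
         n_radii = as.integer(raw$n_radii),
         combo_order = as.integer(raw$combo_order),
         n_dilutions = as.integer(raw$n_dilutions %||% raw$n_rings),
         seconds_per_position = as.numeric(raw$seconds_per_position %||% 10),
         droplets_per_position_ml =
           as.integer(raw$droplets_per_position_ml %||% 192)),
    class = "instrument_config")
  layout <- raw$layout %||% "dilution"
  dilution_mode <- identical(layout, "dilution")
  v <- validate_config(cfg, dilution_mode = dilution_mode)
  if (!is_valid_config(v))
    stop("invalid configuration in ", path, ":\n  ",
         paste(v$violations, collapse = "\n  "), call. = FALSE)
  wm <- if (dilution_mode) {
    make_dilution_layout(cfg)
  } else {
    entries <- if (is.data.frame(layout)) layout else
      do.call(rbind, lapply(layout, function(e) data.frame(
        ring = e$ring, radius = e$radius,
        kind = e$kind %||% "drug",
        drug = e$drug %||% NA_integer_,
        dilution = e$dilution %||% NA_integer_,
        stringsAsFactors = FALSE)))
    well_map(cfg, entries)
  }
  list(config = cfg, wellmap = wm)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Export the standard design table as CSV
#'
#' Writes the [design_table()] for the standard 27-configuration sweep (or a
#' custom grid) as UTF-8 comma-separated values with a header row. Counts are
#' written exactly, with no thousands separators; the two time columns are
#' rounded to `time_digits` decimal places (default 4); all other columns are
#' exact integers.
#'
#' @param path Output CSV path.
#' @param grid Configuration grid, as in [design_table()].
#' @inheritParams ml_screen_time_days
#' @param time_digits Decimal places for the time columns.
#' @return The exported data frame, invisibly.
#' @export
export_design_table <- function(path, grid = standard_design_grid(),
                                seconds_per_position = 10,
                                droplets_per_position_ml = 192,
                                time_digits = 4) {
  dt <- design_table(grid, seconds_per_position, droplets_per_position_ml)
  out <- data.frame(
    r = dt$r, n_rad = dt$n_rad,
    n_combinations = dt$total_combinations,
    n_meaningful = dt$meaningful_combinations,
    n_circumferential = dt$circumferential_combinations,
    n_radial = dt$radial_combinations,
    n_positions = dt$positions_with_dilution,
    time_days = round(dt$screen_time_days, time_digits),
    time_ml_days = round(dt$ml_screen_time_days, time_digits))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(out)
}

#' Write a run manifest
#'
#' Records a config snapshot, package version, seed and md5 digests of the
#' output files of a run, so any export can be reproduced from the command
#' line alone.
#'
#' @param path Manifest output path (JSON).
#' @param config Arbitrary config snapshot (list).
#' @param seed Integer seed(s) used, or `NULL`.
#' @param outputs Character vector of output file paths to digest.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(path, config = list(), seed = NULL,
                           outputs = character()) {
  digests <- if (length(outputs) > 0L)
    as.list(tools::md5sum(outputs)) else list()
  manifest <- list(
    tool = "rotoscreen",
    version = as.character(utils::packageVersion("rotoscreen")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = seed,
    config = config,
    outputs = digests)
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}
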