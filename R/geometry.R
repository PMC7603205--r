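#' Instrument configuration
#'
#' Describes a rotary dispensing instrument: `n_rings` concentric rings of
#' wells crossed by `n_radii` radial shuttle paths, dispensing combinations of
#' `combo_order` droplets. In the dilution design every ring holds one
#' dilution level of each drug, and the instrument restriction
#' `n_rings == n_dilutions == combo_order` applies.
#'
#' All indices used by the package are 0-based: ring 0 is the innermost ring,
#' radii are numbered clockwise from 0, and dilution level 0 is the most
#' concentrated stock (levels increase with dilution).
#'
#' @param n_rings Number of concentric rings (positive integer).
#' @param n_radii Number of radii, i.e. wells per ring (positive integer).
#' @param combo_order Droplets per combination, `r` (positive integer,
#'   at most `n_rings * n_radii`).
#' @param n_dilutions Number of dilution levels per drug; defaults to
#'   `n_rings`, the canonical dilution design.
#' @param seconds_per_position Cycle time charged per rotor position, in
#'   seconds (default 10).
#' @param droplets_per_position_ml Dispensing parallelism assumed by the
#'   single-ring machine-learning time model, in droplets per position
#'   (default 192, the well count of the full 48 x 4 instrument).
#' @return An object of class `instrument_config`.
#' @examples
#' cfg <- instrument_config(3, 3, 3)
#' total_combinations(cfg)  # 84
#' @export
instrument_config <- function(n_rings, n_radii, combo_order,
                              n_dilutions = n_rings,
                              seconds_per_position = 10,
                              droplets_per_position_ml = 192) {
  cfg <- structure(
    list(n_rings = as.integer(n_rings),
         n_radii = as.integer(n_radii),
         combo_order = as.integer(combo_order),
         n_dilutions = as.integer(n_dilutions),
         seconds_per_position = as.numeric(seconds_per_position),
         droplets_per_position_ml = as.integer(droplets_per_position_ml)),
    class = "instrument_config")
  v <- validate_config(cfg, dilution_mode = FALSE)
  if (!is_valid_config(v))
    stop("invalid instrument configuration:\n  ",
         paste(v$violations, collapse = "\n  "), call. = FALSE)
  cfg
}

#' Validate an instrument configuration
#'
#' Checks structural invariants of a configuration. With
#' `dilution_mode = TRUE` the dilution-design restriction
#' `n_rings == n_dilutions == combo_order` is also enforced. Violations are
#' returned, not thrown: the result is the configuration itself when valid,
#' otherwise a `config_violations` object listing every violated constraint.
#'
#' @param config An `instrument_config` (or a bare list with the same fields).
#' @param dilution_mode Logical; enforce the dilution-design restriction.
#' @return `config` unchanged when valid; otherwise a `config_violations`
#'   object with a `violations` character vector.
#' @export
validate_config <- function(config, dilution_mode = FALSE) {
  v <- character()
  num1 <- function(x) length(x) == 1L && is.numeric(x) && is.finite(x)
  if (!num1(config$n_rings) || config$n_rings < 1)
    v <- c(v, "n_rings must be a positive integer")
  if (!num1(config$n_radii) || config$n_radii < 1)
    v <- c(v, "n_radii must be a positive integer")
  if (!num1(config$combo_order) || config$combo_order < 1)
    v <- c(v, "combo_order must be a positive integer")
  if (num1(config$n_rings) && num1(config$n_radii) && num1(config$combo_order) &&
      config$combo_order > config$n_rings * config$n_radii)
    v <- c(v, sprintf("combo_order (%d) exceeds well count n_rings*n_radii (%d)",
                      config$combo_order, config$n_rings * config$n_radii))
  if (!num1(config$n_dilutions) || config$n_dilutions < 1)
    v <- c(v, "n_dilutions must be a positive integer")
  if (!num1(config$seconds_per_position) || config$seconds_per_position <= 0)
    v <- c(v, "seconds_per_position must be > 0")
  if (!num1(config$droplets_per_position_ml) || config$droplets_per_position_ml < 1)
    v <- c(v, "droplets_per_position_ml must be a positive integer")
  if (dilution_mode && num1(config$n_rings) && num1(config$n_dilutions) &&
      num1(config$combo_order) &&
      !(config$n_rings == config$n_dilutions &&
        config$n_dilutions == config$combo_order))
    v <- c(v, sprintf(
      "dilution design requires n_rings = n_dilutions = combo_order (got %d, %d, %d)",
      config$n_rings, config$n_dilutions, config$combo_order))
  if (length(v) == 0L) config
  else structure(list(violations = v, config = config),
                 class = "config_violations")
}

#' @export
print.config_violations <- function(x, ...) {
  cat("invalid instrument configuration:\n")
  cat(paste0("  - ", x$violations, collapse = "\n"), "\n")
  invisible(x)
}

#' Test whether validate_config() accepted a configuration
#'
#' @param x Return value of [validate_config()].
#' @return `TRUE` when `x` is a valid configuration, `FALSE` when it is a
#'   violation report.
#' @export
is_valid_config <- function(x) !inherits(x, "config_violations")

#' Construct a well map
#'
#' A well map assigns content to every (ring, radius) slot of an instrument.
#' Content is either a drug at a dilution level, a cell/organoid well, or an
#' empty slot. Cell wells never participate in drug-redundancy logic.
#'
#' @param config An `instrument_config`.
#' @param wells A data frame with one row per well and columns `ring`,
#'   `radius`, `kind` (one of `"drug"`, `"cell"`, `"empty"`), `drug` and
#'   `dilution` (integer ids, `NA` unless `kind == "drug"`). Slots not listed
#'   are filled as empty.
#' @return An object of class `well_map`: a list with elements `config` and
#'   `wells` (a data frame ordered by ring then radius, one row per slot).
#' @export
well_map <- function(config, wells) {
  stopifnot(inherits(config, "instrument_config"))
  req <- c("ring", "radius", "kind")
  if (!all(req %in% names(wells)))
    stop("wells must have columns ring, radius, kind")
  if (is.null(wells$drug)) wells$drug <- NA_integer_
  if (is.null(wells$dilution)) wells$dilution <- NA_integer_
  key <- paste(wells$ring, wells$radius)
  if (anyDuplicated(key))
    stop("duplicate (ring, radius) well assignments: ",
         paste(unique(key[duplicated(key)]), collapse = ", "))
  if (any(wells$ring < 0 | wells$ring >= config$n_rings))
    stop("well ring index out of range [0, n_rings)")
  if (any(wells$radius < 0 | wells$radius >= config$n_radii))
    stop("well radius index out of range [0, n_radii)")
  if (!all(wells$kind %in% c("drug", "cell", "empty")))
    stop("well kind must be one of 'drug', 'cell', 'empty'")
  bad <- wells$kind == "drug" &
    (is.na(wells$drug) | is.na(wells$dilution) |
       wells$dilution < 0 | wells$dilution >= config$n_dilutions)
  if (any(bad))
    stop("drug wells must carry a drug id and a dilution level in [0, n_dilutions)")
  # fill unlisted slots as empty, canonical (ring, radius) order
  full <- expand.grid(radius = seq_len(config$n_radii) - 1L,
                      ring = seq_len(config$n_rings) - 1L)[, c("ring", "radius")]
  full <- full[order(full$ring, full$radius), ]
  idx <- match(paste(full$ring, full$radius), key)
  out <- data.frame(
    ring = as.integer(full$ring),
    radius = as.integer(full$radius),
    kind = ifelse(is.na(idx), "empty", wells$kind[idx]),
    drug = ifelse(is.na(idx), NA_integer_, as.integer(wells$drug[idx])),
    dilution = ifelse(is.na(idx), NA_integer_, as.integer(wells$dilution[idx])),
    stringsAsFactors = FALSE)
  out$drug[out$kind != "drug"] <- NA_integer_
  out$dilution[out$kind != "drug"] <- NA_integer_
  rownames(out) <- NULL
  structure(list(config = config, wells = out), class = "well_map")
}

#' Canonical dilution layout
#'
#' Builds the canonical dilution well map: well (ring i, radius j) holds drug
#' j at dilution level i, so each radius holds serial dilutions of a single
#' drug and each ring holds one dilution level of every drug. Requires
#' `n_dilutions == n_rings`.
#'
#' @param config An `instrument_config` with `n_dilutions == n_rings`.
#' @return A `well_map` with `n_rings * n_radii` drug wells.
#' @examples
#' wm <- make_dilution_layout(instrument_config(3, 3, 3))
#' nrow(wm$wells)  # 9 wells: drugs {0,1,2} x dilutions {0,1,2}
#' @export
make_dilution_layout <- function(config) {
  stopifnot(inherits(config, "instrument_config"))
  if (config$n_dilutions != config$n_rings)
    stop("canonical dilution layout requires n_dilutions == n_rings (got ",
         config$n_dilutions, " and ", config$n_rings, ")")
  g <- expand.grid(radius = seq_len(config$n_radii) - 1L,
                   ring = seq_len(config$n_rings) - 1L)
  wells <- data.frame(ring = as.integer(g$ring),
                      radius = as.integer(g$radius),
                      kind = "drug",
                      drug = as.integer(g$radius),
                      dilution = as.integer(g$ring),
                      stringsAsFactors = FALSE)
  well_map(config, wells)
}

#' @export
print.well_map <- function(x, ...) {
  cat(sprintf("well map: %d rings x %d radii (%d wells: %d drug, %d cell, %d empty)\n",
              x$config$n_rings, x$config$n_radii, nrow(x$wells),
              sum(x$wells$kind == "drug"), sum(x$wells$kind == "cell"),
              sum(x$wells$kind == "empty")))
  invisible(x)
}

#' Look up a well by position
#'
#' @param wm A `well_map`.
#' @param ring,radius 0-based indices.
#' @return The one-row data frame describing the well.
#' @export
well_at <- function(wm, ring, radius) {
  stopifnot(inherits(wm, "well_map"))
  wm$wells[wm$wells$ring == ring & wm$wells$radius == radius, , drop = FALSE]
}
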