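#' Exact binomial coefficient
#'
#' Computes C(n, r) by the multiplicative recurrence, keeping every
#' intermediate an exact integer (each partial product is itself a binomial
#' coefficient, so the running division is always exact). Values are exact as
#' long as they stay below 2^53; every count arising from instrument designs
#' in scope (at most C(192, 4) = 54,870,480) is far below that.
#'
#' @param n,r Non-negative integers (vectorized; recycled).
#' @return C(n, r), with C(n, r) = 0 when r > n.
#' @examples
#' binom_exact(9, 3)    # 84
#' binom_exact(192, 4)  # 54870480
#' @export
binom_exact <- function(n, r) {
  if (any(n < 0) || any(r < 0)) stop("binom_exact: arguments must be non-negative")
  if (any(n != floor(n)) || any(r != floor(r)))
    stop("binom_exact: arguments must be integers")
  one <- function(n, r) {
    if (r > n) return(0)
    r <- min(r, n - r)
    acc <- 1
    if (r > 0) for (k in seq_len(r)) acc <- acc * (n - r + k) / k
    acc <- round(acc)
    if (acc > 2^53) warning("binom_exact: result exceeds 2^53; no longer exact")
    acc
  }
  mapply(one, n, r)
}

#' Total combinations without dilution reduction
#'
#' The number of r-droplet combinations available from a full instrument,
#' C(n_rings * n_radii, r).
#'
#' @param config An `instrument_config`.
#' @return Exact integer count.
#' @export
total_combinations <- function(config) {
  stopifnot(inherits(config, "instrument_config"))
  binom_exact(config$n_rings * config$n_radii, config$combo_order)
}

#' Rotor positions for the unreduced screen
#'
#' The instrument dispenses up to `n_radii` combinations per rotor position,
#' so the unreduced screen needs C(n_rings*n_radii, r) / n_radii positions.
#' When `n_radii` does not divide the total the value is returned fractional
#' with attribute `integral = FALSE`.
#'
#' @param config An `instrument_config`.
#' @return Number of positions, with logical attribute `integral`.
#' @examples
#' positions_no_dilution(instrument_config(3, 3, 3))  # 28
#' @export
positions_no_dilution <- function(config) {
  tot <- total_combinations(config)
  p <- tot / config$n_radii
  structure(p, integral = (p == round(p)))
}

#' Meaningful combinations under the dilution design
#'
#' Closed-form count of non-redundant ("meaningful") combinations for the
#' dilution design with `n_rings = n_dilutions = r`:
#' `r * n_rad^(r-1) * (n_rad - r + 1)`. A combination is redundant when it
#' contains two or more dilutions of the same drug; such droplets are skipped.
#' The closed form is empirical (established by inspection and checked against
#' enumeration, see [oracle_report()]); it reduces to `r^r` when
#' `n_rad == r` and to `2 n_rad (n_rad - 1)` when `r == 2`.
#'
#' @param r Combination order (and number of rings/dilutions), `r >= 1`.
#' @param n_rad Number of radii (drugs), `n_rad >= r`.
#' @return Exact integer count.
#' @examples
#' meaningful_combinations(3, 3)   # 27 (down from 84 unreduced)
#' meaningful_combinations(4, 48)  # 19906560
#' @export
meaningful_combinations <- function(r, n_rad) {
  check_rn(r, n_rad)
  r * n_rad^(r - 1) * (n_rad - r + 1)
}

#' Circumferential meaningful combinations
#'
#' Meaningful combinations whose wells all lie on a single ring: each of the
#' `r` rings contributes C(n_rad, r) single-dilution combinations, so the
#' count is `r * C(n_rad, r)`. Cross-checked against enumeration in
#' [oracle_report()].
#'
#' @inheritParams meaningful_combinations
#' @return Exact integer count.
#' @export
circumferential_combinations <- function(r, n_rad) {
  check_rn(r, n_rad)
  r * binom_exact(n_rad, r)
}

#' Radial/mixed meaningful combinations
#'
#' Meaningful combinations spanning more than one ring, i.e. the meaningful
#' total minus the circumferential count.
#'
#' @inheritParams meaningful_combinations
#' @return Exact integer count (non-negative).
#' @export
radial_combinations <- function(r, n_rad) {
  meaningful_combinations(r, n_rad) - circumferential_combinations(r, n_rad)
}

#' Rotor positions for the dilution-reduced screen
#'
#' The dilution screen dispenses `n_rad` combinations per position, so it
#' needs `meaningful_combinations(r, n_rad) / n_rad` positions. The division
#' is always exact (the closed form carries an explicit factor of `n_rad` for
#' `r >= 2`, and equals `n_rad` itself at `r = 1`); an integrality assertion
#' guards the arithmetic anyway.
#'
#' @inheritParams meaningful_combinations
#' @return Exact integer position count.
#' @examples
#' positions_with_dilution(4, 48)  # 414720
#' @export
positions_with_dilution <- function(r, n_rad) {
  m <- meaningful_combinations(r, n_rad)
  p <- m / n_rad
  if (p != round(p))
    stop("internal consistency error: meaningful count not divisible by n_rad")
  p
}

#' Screen duration in days
#'
#' @param positions Number of rotor positions (non-negative).
#' @param seconds_per_position Cycle time per position in seconds (default 10).
#' @return Duration in days: `positions * seconds_per_position / 86400`.
#' @examples
#' screen_time_days(414720, 10)  # 48 days
#' @export
screen_time_days <- function(positions, seconds_per_position = 10) {
  if (any(positions < 0)) stop("positions must be non-negative")
  if (any(seconds_per_position <= 0)) stop("seconds_per_position must be > 0")
  positions * seconds_per_position / 86400
}

#' Single-ring machine-learning screen duration in days
#'
#' Time model for the staged (machine-learning) search's first step: a single
#' ring holds one dilution of all `n_rad` drugs, requiring C(n_rad, r)
#' combinations of `r` droplets each, dispensed at
#' `droplets_per_position_ml` droplets per position.
#'
#' @inheritParams meaningful_combinations
#' @param seconds_per_position Cycle time per position in seconds (default 10).
#' @param droplets_per_position_ml Droplets dispensed per position (default
#'   192, the full instrument's well count).
#' @return Duration in days.
#' @examples
#' round(ml_screen_time_days(4, 48), 4)  # 0.4692
#' @export
ml_screen_time_days <- function(r, n_rad, seconds_per_position = 10,
                                droplets_per_position_ml = 192) {
  check_rn(r, n_rad)
  droplets <- binom_exact(n_rad, r) * r
  screen_time_days(droplets / droplets_per_position_ml, seconds_per_position)
}

check_rn <- function(r, n_rad) {
  if (any(r < 1) || any(r != floor(r))) stop("r must be a positive integer")
  if (any(n_rad < r)) stop("n_rad must be >= r")
  if (any(n_rad != floor(n_rad))) stop("n_rad must be an integer")
  invisible(TRUE)
}

#' All design quantities for one dilution configuration
#'
#' Computes every count and time for a dilution design (`n_rings = n_dilutions
#' = r`) with `n_rad` radii: total combinations with and without redundancy
#' reduction, their circumferential/radial decompositions, position counts,
#' and the full-screen and single-ring machine-learning screen durations.
#'
#' @inheritParams ml_screen_time_days
#' @return A one-row data frame of class `design_counts` with columns `r`,
#'   `n_rad`, `n_ring`, `total_combinations`, `meaningful_combinations`,
#'   `circumferential_combinations`, `radial_combinations`,
#'   `circumferential_no_dilution`, `radial_no_dilution`,
#'   `positions_no_dilution`, `positions_with_dilution`, `screen_time_days`,
#'   `ml_screen_time_days`.
#' @examples
#' design_counts(3, 3)
#' @export
design_counts <- function(r, n_rad, seconds_per_position = 10,
                          droplets_per_position_ml = 192) {
  check_rn(r, n_rad)
  tot <- binom_exact(r * n_rad, r)
  m <- meaningful_combinations(r, n_rad)
  circ <- circumferential_combinations(r, n_rad)
  # unreduced decomposition: single-ring subsets vs the rest
  circ0 <- r * binom_exact(n_rad, r)
  pwd <- positions_with_dilution(r, n_rad)
  out <- data.frame(
    r = r, n_rad = n_rad, n_ring = r,
    total_combinations = tot,
    meaningful_combinations = m,
    circumferential_combinations = circ,
    radial_combinations = m - circ,
    circumferential_no_dilution = circ0,
    radial_no_dilution = tot - circ0,
    positions_no_dilution = tot / n_rad,
    positions_with_dilution = pwd,
    screen_time_days = screen_time_days(pwd, seconds_per_position),
    ml_screen_time_days = ml_screen_time_days(r, n_rad, seconds_per_position,
                                              droplets_per_position_ml))
  class(out) <- c("design_counts", class(out))
  out
}

#' Standard configuration sweep of the 48 x 4 commercial instrument
#'
#' The 27 (r, n_rad) configurations conventionally tabulated for the proposed
#' 48-drug, 4-dilution instrument: r = 2 with n_rad in {2,3,4,6,8,10,20,30,48},
#' r = 3 with n_rad in {3,4,6,8,10,20,30,40,48}, and r = 4 with n_rad in
#' {4,6,8,10,20,30,35,40,48}.
#'
#' @return A 27-row data frame with columns `r` and `n_rad`.
#' @export
standard_design_grid <- function() {
  data.frame(
    r = rep(2:4, each = 9L),
    n_rad = c(2L, 3L, 4L, 6L, 8L, 10L, 20L, 30L, 48L,
              3L, 4L, 6L, 8L, 10L, 20L, 30L, 40L, 48L,
              4L, 6L, 8L, 10L, 20L, 30L, 35L, 40L, 48L))
}

#' Design table over a grid of configurations
#'
#' Evaluates [design_counts()] for each (r, n_rad) pair, by default the 27
#' standard configurations of [standard_design_grid()].
#'
#' @param grid Data frame with columns `r` and `n_rad`; defaults to
#'   [standard_design_grid()].
#' @inheritParams ml_screen_time_days
#' @return A data frame with one [design_counts()] row per configuration.
#' @examples
#' dt <- design_table()
#' dt[dt$r == 4 & dt$n_rad == 48, "meaningful_combinations"]  # 19906560
#' @export
design_table <- function(grid = standard_design_grid(),
                         seconds_per_position = 10,
                         droplets_per_position_ml = 192) {
  rows <- lapply(seq_len(nrow(grid)), function(i)
    design_counts(grid$r[i], grid$n_rad[i], seconds_per_position,
                  droplets_per_position_ml))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
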