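#' Enumerate all r-droplet combinations of a well map
#'
#' Yields every r-subset of the non-empty wells exactly once, in deterministic
#' lexicographic order of well index (wells ordered by ring then radius).
#' Combinations are unordered well subsets; dispensing order is a scheduler
#' concern.
#'
#' @param wm A `well_map`.
#' @param r Combination order.
#' @param max_cells Refuse to enumerate more than this many combinations
#'   (default 1e6), so the brute-force oracle cannot be invoked at full
#'   commercial scale by accident.
#' @return An integer matrix with `r` rows; each column is one combination of
#'   well indices (1-based row numbers into `wm$wells`).
#' @examples
#' wm <- make_dilution_layout(instrument_config(3, 3, 3))
#' ncol(enumerate_combinations(wm, 3))  # 84
#' @export
enumerate_combinations <- function(wm, r, max_cells = 1e6) {
  stopifnot(inherits(wm, "well_map"))
  idx <- which(wm$wells$kind != "empty")
  if (r > length(idx))
    stop("r (", r, ") exceeds the number of non-empty wells (", length(idx), ")")
  size <- binom_exact(length(idx), r)
  if (size > max_cells)
    stop(sprintf("enumeration would produce %s combinations (> max_cells = %s)",
                 format(size, big.mark = ","), format(max_cells, big.mark = ",")))
  m <- utils::combn(idx, r)
  storage.mode(m) <- "integer"
  m
}

#' Is a combination dilution-redundant?
#'
#' A combination is redundant when it contains two or more dilutions of the
#' same drug; only one dilution of each drug is informative, so redundant
#' combinations are skipped by the dilution design. Cell/organoid wells never
#' trigger redundancy.
#'
#' @param wm A `well_map`.
#' @param combo Integer vector of well indices (rows of `wm$wells`).
#' @return Logical scalar.
#' @export
is_redundant <- function(wm, combo) {
  stopifnot(inherits(wm, "well_map"))
  drugs <- wm$wells$drug[combo]
  drugs <- drugs[wm$wells$kind[combo] == "drug"]
  anyDuplicated(drugs) > 0L
}

#' Enumerate the meaningful (non-redundant) combinations
#'
#' Filters [enumerate_combinations()] by [is_redundant()] and reports the
#' surviving count alongside the closed-form value of
#' [meaningful_combinations()] with an explicit agreement flag. For the
#' canonical dilution layout the two agree exactly when `r == 2` (any
#' `n_rad`) or `n_rad == r`; for `n_rad > r >= 3` the set-theoretic filter
#' counts `C(n_rad, r) * r^r` combinations, which exceeds the closed form
#' (e.g. 108 vs 96 at r = 3, n_rad = 4). Both counts are always reported; the
#' discrepancy is flagged, never silently reconciled.
#'
#' @inheritParams enumerate_combinations
#' @return A list with elements `combos` (integer matrix, one column per
#'   meaningful combination), `n_meaningful`, `n_total`, `closed_form` (the
#'   closed-form count, or `NA` when the layout is not a canonical dilution
#'   design), and `agrees` (logical).
#' @export
filter_meaningful <- function(wm, r, max_cells = 1e6) {
  all_c <- enumerate_combinations(wm, r, max_cells = max_cells)
  keep <- !apply(all_c, 2L, function(co) is_redundant(wm, co))
  cf <- NA_real_
  cfg <- wm$config
  if (is_canonical_dilution(wm) && cfg$n_rings == r && r <= cfg$n_radii)
    cf <- meaningful_combinations(r, cfg$n_radii)
  list(combos = all_c[, keep, drop = FALSE],
       n_meaningful = sum(keep),
       n_total = ncol(all_c),
       closed_form = cf,
       agrees = if (is.na(cf)) NA else sum(keep) == cf)
}

is_canonical_dilution <- function(wm) {
  w <- wm$wells
  all(w$kind == "drug") &&
    wm$config$n_dilutions == wm$config$n_rings &&
    all(w$drug == w$radius) && all(w$dilution == w$ring)
}

#' Classify a combination as circumferential or radial/mixed
#'
#' Circumferential combinations have all member wells on a single ring (they
#' can be dispensed by ring rotation alone); any combination spanning two or
#' more rings requires radial or mixed movements.
#'
#' @inheritParams is_redundant
#' @return `"circumferential"` or `"radial/mixed"`.
#' @export
classify_combination <- function(wm, combo) {
  stopifnot(inherits(wm, "well_map"))
  if (length(unique(wm$wells$ring[combo])) == 1L) "circumferential"
  else "radial/mixed"
}

#' Brute-force oracle report for a dilution design
#'
#' Builds the canonical dilution layout for (r rings, n_rad radii, r
#' dilutions), enumerates all combinations, applies the redundancy filter and
#' the circumferential classifier, and compares each enumerated count with its
#' closed form. This is the empirical check backing the closed forms: the
#' meaningful closed form is known to match enumeration for `r == 2` and for
#' `n_rad == r`, and to disagree for `n_rad > r >= 3` (the report carries
#' per-quantity equality flags rather than asserting agreement).
#'
#' @inheritParams meaningful_combinations
#' @param max_cells Enumeration size bound; exceeding it is an error stating
#'   the estimated size.
#' @return A list with `enumerated` and `closed_form` sub-lists (each with
#'   `total`, `meaningful`, `circumferential`) and a logical `agree` vector.
#' @examples
#' oracle_report(3, 3)$agree  # all TRUE
#' oracle_report(3, 4)$agree[["meaningful"]]  # FALSE: 108 enumerated vs 96
#' @export
oracle_report <- function(r, n_rad, max_cells = 1e6) {
  check_rn(r, n_rad)
  cfg <- instrument_config(r, n_rad, r, n_dilutions = r)
  wm <- make_dilution_layout(cfg)
  fm <- filter_meaningful(wm, r, max_cells = max_cells)
  circ_enum <- sum(apply(fm$combos, 2L, function(co)
    classify_combination(wm, co) == "circumferential"))
  enumerated <- list(total = fm$n_total,
                     meaningful = fm$n_meaningful,
                     circumferential = circ_enum)
  closed <- list(total = total_combinations(cfg),
                 meaningful = meaningful_combinations(r, n_rad),
                 circumferential = circumferential_combinations(r, n_rad))
  agree <- c(total = enumerated$total == closed$total,
             meaningful = enumerated$meaningful == closed$meaningful,
             circumferential = enumerated$circumferential == closed$circumferential)
  list(r = r, n_rad = n_rad, enumerated = enumerated, closed_form = closed,
       agree = agree)
}
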