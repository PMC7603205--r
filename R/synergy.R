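#' Hill dose-response curve
#'
#' Standard single-agent sigmoid: effect(d) = emax * d^h / (ec50^h + d^h),
#' with effect(0) = 0, monotone nondecreasing, and effect(d) < emax <= 1.
#' Effects are fractional responses in [0, 1] (e.g. fraction of cells killed).
#'
#' @param emax Maximal effect, in (0, 1].
#' @param ec50 Dose of half-maximal effect (arbitrary concentration units, > 0).
#' @param hill Hill slope (> 0).
#' @return An object of class `hill_curve`.
#' @export
hill_curve <- function(emax, ec50, hill = 1) {
  stopifnot(emax > 0, emax <= 1, ec50 > 0, hill > 0)
  structure(list(emax = emax, ec50 = ec50, hill = hill), class = "hill_curve")
}

#' Effect of a dose under a Hill curve
#'
#' @param curve A `hill_curve`.
#' @param dose Non-negative dose(s).
#' @return Effect(s) in [0, emax).
#' @export
hill_effect <- function(curve, dose) {
  stopifnot(inherits(curve, "hill_curve"), all(dose >= 0))
  dh <- dose^curve$hill
  ifelse(dose == 0, 0, curve$emax * dh / (curve$ec50^curve$hill + dh))
}

#' Equi-effective dose under a Hill curve (inverse)
#'
#' @param curve A `hill_curve`.
#' @param effect Effect in [0, emax).
#' @return The dose producing `effect`.
#' @export
hill_inverse <- function(curve, effect) {
  stopifnot(inherits(curve, "hill_curve"),
            all(effect >= 0), all(effect < curve$emax))
  ifelse(effect == 0, 0,
         curve$ec50 * (effect / (curve$emax - effect))^(1 / curve$hill))
}

#' Bliss independence expectation
#'
#' Multiplicative null model for the combined effect of independently acting
#' drugs: expected = 1 - prod(1 - e_i).
#'
#' @param effects Single-agent effects, each in [0, 1].
#' @return Expected combined effect in [0, 1]; monotone nondecreasing in each
#'   argument, and equal to `e` for a single agent (`bliss_expected(c(e, 0))
#'   == e`).
#' @examples
#' bliss_expected(c(0.5, 0.5))  # 0.75
#' @export
bliss_expected <- function(effects) {
  if (any(effects < 0 | effects > 1))
    stop("effects must lie in [0, 1]")
  1 - prod(1 - effects)
}

#' Loewe additivity expectation
#'
#' Dose-additivity null model: the expected combined effect E solves
#' sum_i d_i / D_i(E) = 1, where D_i(E) is the single-agent dose of drug i
#' producing effect E (the inverse Hill curve). Solved numerically by
#' bisection-safeguarded root finding to tolerance 1e-9 on the bracket
#' (0, min emax). Satisfies the sham-combination principle: splitting one
#' drug's dose across identical curves leaves the expectation unchanged.
#'
#' @param doses Non-negative doses, one per drug.
#' @param curves List of `hill_curve` objects, one per drug.
#' @return Expected combined effect in [0, min emax). All-zero doses give 0.
#' @examples
#' cv <- hill_curve(1, 1, 1)
#' loewe_expected(c(1, 1), list(cv, cv))  # effect of dose 2: 2/3
#' @export
loewe_expected <- function(doses, curves) {
  stopifnot(length(doses) == length(curves), all(doses >= 0))
  lapply(curves, function(cv) stopifnot(inherits(cv, "hill_curve")))
  active <- which(doses > 0)
  if (length(active) == 0L) return(0)
  if (length(active) == 1L)
    return(hill_effect(curves[[active]], doses[active]))
  emaxs <- vapply(curves[active], `[[`, numeric(1), "emax")
  hi <- min(emaxs) * (1 - 1e-12)
  f <- function(E) {
    s <- sum(vapply(active, function(i)
      doses[i] / hill_inverse(curves[[i]], E), numeric(1)))
    s - 1
  }
  if (f(hi) > 0)
    stop("Loewe expectation undefined: combined doses exceed the attainable ",
         "effect of the weakest curve (no root bracket)")
  stats::uniroot(f, lower = min(emaxs) * 1e-12, upper = hi,
                 tol = 1e-12)$root
}

#' Three-level interaction score
#'
#' Scores an observed combined effect against a reference expectation with a
#' single threshold tau: synergistic interactions (observed exceeding the
#' expectation by more than tau) score 2, antagonistic interactions (falling
#' short by more than tau) score 0, and additive interactions score 1.
#'
#' @param observed,expected Effects in [0, 1].
#' @param tau Positive classification threshold on the excess (default 0.1).
#' @return A list of class `interaction_score` with `value` (0, 1 or 2) and
#'   `excess` (observed - expected).
#' @export
score_interaction <- function(observed, expected, tau = 0.1) {
  if (tau <= 0) stop("tau must be positive")
  if (any(c(observed, expected) < 0) || any(c(observed, expected) > 1))
    stop("observed and expected effects must lie in [0, 1]")
  excess <- observed - expected
  value <- if (excess > tau) 2L else if (-excess > tau) 0L else 1L
  structure(list(value = value, excess = excess), class = "interaction_score")
}

#' Generate a synthetic multi-drug response surface
#'
#' Builds a reproducible dose-response model for `n_drugs` drugs at
#' `n_dilutions` dilution levels each. Every drug gets a Hill curve (drawn
#' from realistic ranges unless supplied) and a serial-dilution dose ladder:
#' dilution level 0 (the most concentrated) doses `top_dose_factor * ec50`,
#' and each deeper level divides the dose by `dilution_factor` (default
#' 10-fold). The observed effect of a combination is the reference expectation
#' (Bliss or Loewe) plus the strengths of any planted interactions whose drug
#' set is contained in the combination, plus additive Gaussian noise, clipped
#' to [0, 1]. With no interactions and zero noise the surface equals the
#' reference model exactly.
#'
#' Noise is deterministic per combination (a RNG substream keyed on the
#' surface seed and the combination's (drug, dilution) content), so repeated
#' or reordered queries reproduce the same observation.
#'
#' @param n_drugs Number of drugs (drug ids 0..n_drugs-1).
#' @param n_dilutions Dilution levels per drug (level 0 most concentrated).
#' @param interactions List of planted deviations, each a list with `drugs`
#'   (integer vector of drug ids) and `strength` (real; positive = synergy,
#'   negative = antagonism).
#' @param noise_sd Standard deviation of additive Gaussian noise on the
#'   observed effect (default 0).
#' @param seed Integer seed controlling curve draws and noise.
#' @param reference `"bliss"` or `"loewe"`.
#' @param top_dose_factor Dose at dilution level 0, as a multiple of each
#'   drug's ec50 (default 10).
#' @param dilution_factor Fold-dilution between consecutive levels (default 10).
#' @param curves Optional list of `hill_curve` objects (length `n_drugs`) to
#'   use instead of random draws.
#' @return An object of class `response_surface`.
#' @export
generate_surface <- function(n_drugs, n_dilutions, interactions = list(),
                             noise_sd = 0, seed = 1,
                             reference = c("bliss", "loewe"),
                             top_dose_factor = 10, dilution_factor = 10,
                             curves = NULL) {
  reference <- match.arg(reference)
  stopifnot(n_drugs >= 1, n_dilutions >= 1, noise_sd >= 0,
            top_dose_factor > 0, dilution_factor > 1)
  for (it in interactions)
    stopifnot(all(it$drugs >= 0), all(it$drugs < n_drugs),
              is.numeric(it$strength))
  if (is.null(curves)) {
    curves <- with_preserved_rng(seed, {
      lapply(seq_len(n_drugs), function(j)
        hill_curve(emax = stats::runif(1, 0.6, 0.95),
                   ec50 = 10^stats::runif(1, -0.5, 0.5),
                   hill = stats::runif(1, 0.8, 2)))
    })
  } else {
    stopifnot(length(curves) == n_drugs)
  }
  ec50s <- vapply(curves, `[[`, numeric(1), "ec50")
  doses <- outer(dilution_factor^-(seq_len(n_dilutions) - 1L),
                 ec50s * top_dose_factor)  # [dilution level + 1, drug id + 1]
  structure(list(n_drugs = n_drugs, n_dilutions = n_dilutions,
                 curves = curves, doses = doses,
                 interactions = interactions, noise_sd = noise_sd,
                 seed = as.integer(seed), reference = reference),
            class = "response_surface")
}

# Run expr with its own RNG stream, restoring the caller's .Random.seed.
with_preserved_rng <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Deterministic 31-bit hash of a combination's content, mixed with the seed.
combo_stream_seed <- function(seed, drugs, dilutions) {
  ord <- order(drugs, dilutions)
  h <- seed %% 2147483647
  for (v in as.integer(rbind(drugs[ord], dilutions[ord]))) {
    h <- (h * 1103515 + v + 12345) %% 2147483647
  }
  as.integer(h)
}

#' Reference (expected) effect of a combination
#'
#' Expected combined effect of the given drugs at the given dilution levels
#' under the surface's reference model (Bliss or Loewe), with no planted
#' interactions and no noise.
#'
#' @param surface A `response_surface`.
#' @param drugs Integer vector of drug ids (0-based, distinct).
#' @param dilutions Integer vector of dilution levels (0-based), one per drug.
#' @return Expected effect in [0, 1].
#' @export
expected_effect <- function(surface, drugs, dilutions) {
  stopifnot(inherits(surface, "response_surface"),
            length(drugs) == length(dilutions),
            anyDuplicated(drugs) == 0L,
            all(drugs >= 0), all(drugs < surface$n_drugs),
            all(dilutions >= 0), all(dilutions < surface$n_dilutions))
  d <- surface$doses[cbind(dilutions + 1L, drugs + 1L)]
  if (surface$reference == "bliss") {
    e <- vapply(seq_along(drugs), function(i)
      hill_effect(surface$curves[[drugs[i] + 1L]], d[i]), numeric(1))
    bliss_expected(e)
  } else {
    loewe_expected(d, surface$curves[drugs + 1L])
  }
}

#' Observed effect of a combination
#'
#' The reference expectation shifted by every planted interaction contained in
#' the combination's drug set, plus per-combination Gaussian noise, clipped to
#' [0, 1].
#'
#' @inheritParams expected_effect
#' @return Observed effect in [0, 1]; deterministic for a given surface.
#' @export
observed_effect <- function(surface, drugs, dilutions) {
  e <- expected_effect(surface, drugs, dilutions)
  for (it in surface$interactions)
    if (all(it$drugs %in% drugs)) e <- e + it$strength
  if (surface$noise_sd > 0) {
    s <- combo_stream_seed(surface$seed, drugs, dilutions)
    e <- e + with_preserved_rng(s, stats::rnorm(1, 0, surface$noise_sd))
  }
  min(max(e, 0), 1)
}

#' Score one combination on a surface
#'
#' @inheritParams expected_effect
#' @param tau Classification threshold (see [score_interaction()]).
#' @return An `interaction_score`.
#' @export
score_combo <- function(surface, drugs, dilutions, tau = 0.1) {
  score_interaction(observed_effect(surface, drugs, dilutions),
                    expected_effect(surface, drugs, dilutions), tau)
}

#' Staged ring-by-ring synergy search
#'
#' Simulates the staged search that replaces the exhaustive dilution screen:
#' step one tests every r-drug combination on a single ring (one dilution
#' level) with circumferential movements only; any combination scoring 2
#' (synergistic) triggers focus mode, which tests all non-redundant dilution
#' assignments of the implicated drug set (`n_dilutions^r` combinations).
#' Under the `"single-dilution-first"` strategy the search stops after the
#' first ring that yields a confirmed synergistic set; under
#' `"exhaustive-ml"` every ring is screened. Rings are visited from level 0
#' (most concentrated) outward; the search terminates after all rings at the
#' latest.
#'
#' Counters follow the instrument's time model: each tested combination uses
#' `r` droplets, positions are charged at `droplets_per_position_ml` droplets
#' per position, and model time is positions x seconds_per_position.
#'
#' @param surface A `response_surface`.
#' @param config An `instrument_config` whose `n_radii` equals the surface's
#'   drug count and `n_rings`/`n_dilutions` the surface's dilution count.
#' @param strategy `"single-dilution-first"` or `"exhaustive-ml"`.
#' @param tau Synergy threshold (see [score_interaction()]).
#' @return An object of class `search_result`: list with `found_sets` (list
#'   of drug-id vectors scoring 2), `combos_tested`, `droplets_used`,
#'   `positions_used`, `model_time_days`, and `steps` (data frame log of
#'   rings and focus stages visited).
#' @export
ring_search <- function(surface, config,
                        strategy = c("single-dilution-first", "exhaustive-ml"),
                        tau = 0.1) {
  strategy <- match.arg(strategy)
  stopifnot(inherits(surface, "response_surface"),
            inherits(config, "instrument_config"))
  if (config$n_radii != surface$n_drugs)
    stop("config n_radii (", config$n_radii,
         ") must equal the surface's drug count (", surface$n_drugs, ")")
  if (config$n_rings != surface$n_dilutions)
    stop("config n_rings (", config$n_rings,
         ") must equal the surface's dilution count (", surface$n_dilutions, ")")
  r <- config$combo_order
  drugs_all <- seq_len(surface$n_drugs) - 1L
  found <- list()
  combos_tested <- 0
  steps <- list()
  for (ring in seq_len(config$n_rings) - 1L) {
    sets <- utils::combn(drugs_all, r)
    hits <- list()
    for (i in seq_len(ncol(sets))) {
      ds <- sets[, i]
      sc <- score_combo(surface, ds, rep(ring, r), tau)
      if (sc$value == 2L) hits[[length(hits) + 1L]] <- ds
    }
    combos_tested <- combos_tested + ncol(sets)
    steps[[length(steps) + 1L]] <- data.frame(
      stage = "ring", ring = ring, combos_tested = ncol(sets),
      hits = length(hits), stringsAsFactors = FALSE)
    confirmed <- list()
    for (hs in hits) {
      # focus mode: all dilution assignments of the implicated drugs
      # (non-redundant by construction: drugs are distinct)
      grid <- as.matrix(expand.grid(rep(list(seq_len(surface$n_dilutions) - 1L),
                                        r)))
      hit2 <- FALSE
      for (gi in seq_len(nrow(grid))) {
        sc <- score_combo(surface, hs, as.integer(grid[gi, ]), tau)
        if (sc$value == 2L) hit2 <- TRUE
      }
      combos_tested <- combos_tested + nrow(grid)
      steps[[length(steps) + 1L]] <- data.frame(
        stage = "focus", ring = ring, combos_tested = nrow(grid),
        hits = as.integer(hit2), stringsAsFactors = FALSE)
      if (hit2) confirmed[[length(confirmed) + 1L]] <- hs
    }
    keys <- vapply(found, paste, character(1), collapse = "-")
    for (cs in confirmed)
      if (!paste(cs, collapse = "-") %in% keys)
        found[[length(found) + 1L]] <- cs
    if (strategy == "single-dilution-first" && length(found) > 0L) break
  }
  droplets <- r * combos_tested
  positions <- ceiling(droplets / config$droplets_per_position_ml)
  structure(list(found_sets = found,
                 combos_tested = combos_tested,
                 droplets_used = droplets,
                 positions_used = positions,
                 model_time_days = screen_time_days(
                   positions, config$seconds_per_position),
                 steps = do.call(rbind, steps)),
            class = "search_result")
}

#' @export
print.search_result <- function(x, ...) {
  cat(sprintf(
    "synergy search: %d combinations tested (%d droplets, %d positions, %.4g days); %d synergistic set(s)\n",
    x$combos_tested, x$droplets_used, x$positions_used, x$model_time_days,
    length(x$found_sets)))
  invisible(x)
}
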