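test_that("Bliss independence behaves as a null model", {
  expect_equal(bliss_expected(c(0.5, 0.5)), 0.75)
  expect_equal(bliss_expected(c(0.37, 0)), 0.37)  # null agent is the identity
  expect_equal(bliss_expected(c(0.2, 0.3, 0.5)), 0.72)   # 1 - 0.8*0.7*0.5
  expect_equal(bliss_expected(c(0.2, 0.3, 0.6)), 0.776)  # 1 - 0.8*0.7*0.4
  expect_error(bliss_expected(c(0.5, 1.2)), "\\[0, 1\\]")
  # monotone nondecreasing in each argument
  for (e in seq(0, 1, 0.25))
    expect_gte(bliss_expected(c(0.4, e)), bliss_expected(c(0.4, max(e - 0.25, 0))))
})

test_that("Loewe additivity matches single-agent effects and closed forms", {
  cv <- hill_curve(1, 1, 1)
  # single nonzero dose: exactly the Hill effect
  expect_equal(loewe_expected(c(0.7, 0), list(cv, hill_curve(0.8, 2, 1.5))),
               hill_effect(cv, 0.7))
  expect_equal(loewe_expected(c(0, 0), list(cv, cv)), 0)
  # two identical unit curves at dose (1, 1): effect of dose 2 = 2/3
  expect_equal(loewe_expected(c(1, 1), list(cv, cv)), 2 / 3, tolerance = 1e-9)
  # single drug: Bliss and Loewe agree (both give the Hill effect)
  cv2 <- hill_curve(0.9, 3, 2)
  d <- 1.7
  expect_equal(loewe_expected(d, list(cv2)),
               bliss_expected(hill_effect(cv2, d)))
  # degenerate case: doses exceed the weakest curve's attainable effect
  expect_error(
    loewe_expected(c(0.01, 10), list(hill_curve(0.3, 1, 1), hill_curve(0.9, 1, 1))),
    "no root bracket")
})

test_that("Loewe is sham-combination invariant for identical-curve splits", {
  set.seed(101)
  for (i in 1:25) {
    cv <- hill_curve(runif(1, 0.5, 1), 10^runif(1, -1, 1), runif(1, 0.5, 3))
    d <- 10^runif(1, -1, 1) * cv$ec50
    w <- runif(3); w <- w / sum(w)
    split3 <- loewe_expected(d * w, list(cv, cv, cv))
    expect_equal(split3, hill_effect(cv, d), tolerance = 1e-6)
  }
})

test_that("interaction scoring maps excess to the 0/1/2 scale", {
  expect_equal(score_interaction(0.5, 0.5, 0.1)$value, 1L)       # additive
  expect_equal(score_interaction(0.7, 0.5, 0.1)$value, 2L)       # synergy
  expect_equal(score_interaction(0.3, 0.5, 0.1)$value, 0L)       # antagonism
  expect_equal(score_interaction(0.58, 0.5, 0.1)$value, 1L)      # within tau
  expect_equal(score_interaction(0.7, 0.5, 0.1)$excess, 0.2)
  expect_error(score_interaction(0.5, 0.5, 0), "positive")
  expect_error(score_interaction(1.2, 0.5, 0.1), "\\[0, 1\\]")
})

test_that("a clean surface equals the reference model and scores all 1", {
  surf <- generate_surface(5, 3, noise_sd = 0, seed = 7)
  for (tau in c(0.01, 0.1, 0.5)) {
    sets <- utils::combn(0:4, 3)
    for (i in seq_len(ncol(sets))) {
      dil <- (i %% 3) + c(0L, 1L, 2L) %% 3L
      dil <- dil %% 3L
      sc <- score_combo(surf, sets[, i], dil, tau)
      expect_identical(sc$value, 1L)
      expect_identical(sc$excess, 0)
    }
  }
})

test_that("planted interactions shift observations by their strength", {
  curves <- replicate(4, hill_curve(0.8, 1, 1), simplify = FALSE)
  plus <- generate_surface(4, 3, curves = curves, seed = 3,
                           interactions = list(list(drugs = 0:2, strength = 0.3)))
  minus <- generate_surface(4, 3, curves = curves, seed = 3,
                            interactions = list(list(drugs = 0:2, strength = -0.3)))
  # at the deepest dilution the reference is small, so the shift is unclipped
  expect_equal(score_combo(plus, 0:2, c(2, 2, 2), 0.1)$value, 2L)
  expect_equal(score_combo(minus, 0:2, c(2, 2, 2), 0.1)$value, 0L)
  expect_equal(observed_effect(plus, 0:2, c(2, 2, 2)) -
                 expected_effect(plus, 0:2, c(2, 2, 2)), 0.3)
  # a combination not containing the planted set is untouched
  expect_equal(score_combo(plus, c(0, 1, 3), c(2, 2, 2), 0.1)$value, 1L)
  # the shift applies at any dilution of the planted drugs (clipped to [0,1])
  obs0 <- observed_effect(plus, 0:2, c(0, 0, 0))
  expect_lte(obs0, 1)
  expect_gte(obs0, expected_effect(plus, 0:2, c(0, 0, 0)))
})

test_that("surface noise is reproducible and query-order independent", {
  surf <- generate_surface(6, 3, noise_sd = 0.05, seed = 11)
  a1 <- observed_effect(surf, c(0, 2, 4), c(0, 1, 2))
  b1 <- observed_effect(surf, c(1, 3, 5), c(2, 2, 2))
  b2 <- observed_effect(surf, c(1, 3, 5), c(2, 2, 2))
  a2 <- observed_effect(surf, c(0, 2, 4), c(0, 1, 2))
  expect_identical(a1, a2)
  expect_identical(b1, b2)
  # permuting the well order of the same combination changes nothing
  expect_identical(a1, observed_effect(surf, c(4, 0, 2), c(2, 0, 1)))
  # a fresh surface with the same seed reproduces observations exactly
  surf2 <- generate_surface(6, 3, noise_sd = 0.05, seed = 11)
  expect_identical(a1, observed_effect(surf2, c(0, 2, 4), c(0, 1, 2)))
})

test_that("ring search on a null surface screens every ring and finds nothing", {
  surf <- generate_surface(6, 3, noise_sd = 0, seed = 2)
  cfg <- instrument_config(3, 6, 3)
  res <- ring_search(surf, cfg, "exhaustive-ml", tau = 0.1)
  expect_equal(length(res$found_sets), 0)
  expect_equal(res$combos_tested, 3 * binom_exact(6, 3))  # one ring at a time
  expect_equal(res$droplets_used, 3 * res$combos_tested)
  expect_equal(res$positions_used,
               ceiling(res$droplets_used / cfg$droplets_per_position_ml))
  expect_equal(res$model_time_days,
               screen_time_days(res$positions_used, cfg$seconds_per_position))
  expect_equal(res$steps$stage, rep("ring", 3))
  expect_equal(res$steps$ring, 0:2)  # monotone ring progression
})

test_that("a planted ring-0 synergy is found in step one with a bounded budget", {
  curves <- replicate(5, hill_curve(0.5, 1, 1.2), simplify = FALSE)
  surf <- generate_surface(5, 3, curves = curves, seed = 4,
                           interactions = list(list(drugs = c(1, 2, 4),
                                                    strength = 0.3)))
  cfg <- instrument_config(3, 5, 3)
  res <- ring_search(surf, cfg, "single-dilution-first", tau = 0.1)
  expect_equal(res$found_sets, list(c(1L, 2L, 4L)))
  expect_equal(res$steps$ring[1], 0)
  expect_lte(res$combos_tested, binom_exact(5, 3) + 27)
})

test_that("synergy visible only at deep dilution is reached by ring progression", {
  # strong, shallow curves: the reference saturates near 1 on rings 0-1, so a
  # +0.12 shift is clipped away there and only detectable on the deepest ring
  curves <- replicate(5, hill_curve(0.95, 1, 1), simplify = FALSE)
  surf <- generate_surface(5, 3, curves = curves, seed = 5,
                           dilution_factor = 3,
                           interactions = list(list(drugs = 0:2,
                                                    strength = 0.12)))
  cfg <- instrument_config(3, 5, 3)
  res <- ring_search(surf, cfg, "single-dilution-first", tau = 0.1)
  expect_equal(res$found_sets, list(0:2))
  rings <- res$steps$ring[res$steps$stage == "ring"]
  expect_equal(rings, 0:2)           # visited every ring up to the deepest
  expect_true(all(diff(rings) > 0))  # monotone progression
})

test_that("the staged search recovers planted triples cheaply across seeds", {
  exhaustive <- meaningful_combinations(3, 8)
  hitrate <- 0
  for (seed in 1:20) {
    set.seed(seed)
    planted <- sort(sample(0:7, 3))
    surf <- generate_surface(8, 3, noise_sd = 0.02, seed = seed,
                             interactions = list(list(drugs = planted,
                                                      strength = 0.3)))
    cfg <- instrument_config(3, 8, 3)
    res <- ring_search(surf, cfg, "single-dilution-first", tau = 0.1)
    keys <- vapply(res$found_sets, paste, character(1), collapse = "-")
    if (paste(planted, collapse = "-") %in% keys) hitrate <- hitrate + 1
    expect_lt(res$combos_tested, exhaustive)
  }
  expect_gte(hitrate, 19)
})
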