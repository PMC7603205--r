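---
title: "Design theory of rotary droplet combination screens"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Design theory of rotary droplet combination screens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rotoscreen)
```

## The instrument and its combinatorics

A rotary droplet dispenser holds wells on `n_rings` concentric rings crossed
by `n_radii` radial shuttle paths. Rings rotate (circumferential movements),
shuttles travel along a radius collecting droplets from the wells they align
with (radial movements), and the two can interleave (mixed movements). A
combination of order $r$ is a set of $r$ droplets drawn from distinct wells
and mixed. With $n = N_{ring} N_{rad}$ filled wells, the unreduced screen
contains $\binom{n}{r}$ combinations, and because each rotor position feeds up
to $N_{rad}$ parallel outlet lines, it needs $\binom{n}{r}/N_{rad}$ rotor
positions.

Drug screens need dose ranges, so wells hold serial dilutions. In the
canonical dilution layout, radius $j$ carries drug $j$ and ring $i$ carries
dilution level $i$ (level 0 the most concentrated stock), under the design
restriction $N_{ring} = N_{dil} = r$. Any combination containing two or more
dilutions of the *same* drug is redundant — it tests no new drug set — and is
skipped. The package's figure of merit for the reduced screen is the closed
form

$$ {}_nC_r' = r \, N_{rad}^{\,r-1} (N_{rad} - r + 1), $$

with the circumferential share $N_c' = r\binom{N_{rad}}{r}$ (all wells on one
ring), the radial/mixed share $N_r' = {}_nC_r' - N_c'$, and
$N_p' = {}_nC_r'/N_{rad}$ positions (the division is exact for every valid
$r$). For the introductory $3\times3$ build this reduces 84 combinations to
27; for the commercial $48\times4$ instrument, 54,870,480 to 19,906,560,
dispensed in 414,720 positions.

```{r}
design_counts(3, 3)[, c("total_combinations", "meaningful_combinations",
                        "positions_no_dilution", "positions_with_dilution")]
```

## What the closed form counts — and what it does not

The reduced-count formula is empirical: it is stated by inspection, not
derived, and the package treats it accordingly. The brute-force oracle
(`oracle_report()`) enumerates every $r$-subset of wells and applies the
redundancy filter literally ("no drug twice"). The two constructions agree
exactly for $r = 2$ at any $N_{rad}$, and for $N_{rad} = r$ (where both give
$r^r$). For $N_{rad} > r \ge 3$ they disagree: the set-theoretic filter keeps
$\binom{N_{rad}}{r} r^r$ combinations (e.g. 108 at $r=3$, $N_{rad}=4$), more
than the closed form's 96, while the stricter "one well per ring" reading
gives fewer. Which geometric reachability rule the closed form encodes is not
recoverable, so the package always reports both counts with an explicit
agreement flag and never silently reconciles them. Every tabulated design
value uses the closed form; the enumerator is the oracle, not the product.

```{r}
oracle_report(3, 4)$agree
```

Enumeration is bounded (`max_cells`, default $10^6$ combinations) so the
oracle cannot be invoked at commercial scale by accident; the closed forms are
instant at any scale.

## Time models and the design table

Screen time is charged per rotor position at a constant cycle time,
10 s/position by default; that constant is not printed anywhere as a formula
but is recovered by calibration against the tabulated rows (236,800 positions
↔ 27.4 days gives 10.0 s), and it is exposed as a configuration parameter.
`design_table()` reproduces the standard 27-configuration sweep of the
$48\times4$ instrument; the test suite asserts every count column exactly.
Three entries of the published table are flagged rather than reproduced: a
malformed radial count at $(r{=}4, N_{rad}{=}40)$ (the identity
$N_r' = {}_nC_r' - N_c'$ gives 9,106,440), a full-screen time at
$(r{=}3, N_{rad}{=}48)$ of 0.5 days that contradicts its own position count
(6624 positions × 10 s = 0.767 days), and a rounding discrepancy at
$(r{=}2, N_{rad}{=}3)$.

The "machine-learning" time column models the staged search's first step: one
ring of $N_{rad}$ single-dilution wells needs $\binom{N_{rad}}{r} r$ droplets,
dispensed at 192 droplets per position — the full instrument's well count,
kept configurable since the parallelism of that mode is a design assumption,
not a stated constant.

## The scheduler

`plan_screen()` turns a target combination list into rotor positions and
shuttle passes. A position is a tuple of ring offsets (well-pitch units,
clockwise); a pass on radius $k$ collects the wells aligned there. Greedy
first-fit packing places each combination on the first open position/radius
whose offsets are compatible; combinations taking several wells from one ring
align their first well through the base offsets and fetch the rest by
intra-position ring increments, which the trace counts separately because
position accounting for mixed movements is otherwise undefined. The planner
claims no optimality: plans are verified (`simulate_plan()` replays geometry
and asserts a complete, duplicate-free ledger and $r \times$ targets
droplets), bounded (within twice $\lceil \text{targets}/N_{rad} \rceil$ on all
tested configurations), and deterministic (byte-identical exports), while the
closed-form $N_p$, $N_p'$ remain the instrument's ideal. The greedy plan for
the full $3\times3$ screen uses 34 positions against the ideal 28; matching
the ideal exactly is a scheduling optimization left open.

## Synthetic response surfaces and synergy scoring

No measured dose-response data accompanies the design theory, so the synergy
machinery is exercised on synthetic surfaces. Each drug gets a Hill curve
$E(d) = E_{max} d^h / (EC_{50}^h + d^h)$, with defaults drawn once per
surface seed from ranges a screening scientist would call routine:
$E_{max} \sim U(0.6, 0.95)$, $EC_{50}$ log-uniform over one decade, and
$h \sim U(0.8, 2)$. The dose ladder is a 10-fold serial dilution topped at
$10\times EC_{50}$ per drug — deep enough that the most dilute ring sits well
below $EC_{50}$ — both configurable since no dilution ratio is prescribed by
the design.

Reference (null) models are Bliss independence,
$E_{exp} = 1 - \prod_i (1 - e_i)$, and Loewe additivity, the $E$ solving
$\sum_i d_i / D_i(E) = 1$ with $D_i$ the inverse Hill curve, found by
`stats::uniroot` on the bracket $(0, \min E_{max})$ at tolerance $10^{-12}$
(the sham-combination identity holds to $10^{-6}$ in the tests; doses whose
combined demand exceeds the weakest curve's ceiling have no root and raise an
error rather than returning a clipped value). Interactions are scored on the
three-level scale: observed minus expected beyond a threshold $\tau$ is
synergy (score 2), below $-\tau$ antagonism (score 0), otherwise additivity
(score 1). The scale names no statistic beyond this, so excess-over-reference
with a single $\tau$ (default 0.1 effect units) is the simplest faithful
implementation; no multiple-testing correction is applied, which is a known
limitation when $\tau$ is small relative to noise.

Planted interactions shift the observed effect of every combination containing
the planted drug set by a constant, before clipping to $[0,1]$; noise is
additive Gaussian, drawn from a per-combination RNG substream keyed on the
surface seed and the combination's content, so observations are reproducible
and independent of query order. With zero noise and no interactions the
surface equals its reference model exactly and every score is 1.

## The staged (ring-by-ring) search

`ring_search()` implements the staged strategy that replaces the exhaustive
dilution screen: screen all $\binom{N_{rad}}{r}$ single-dilution combinations
on ring 0 by circumferential movements; any score-2 set triggers focus mode,
which tests all $N_{dil}^r$ dilution assignments of the implicated drugs;
otherwise move to the next ring. `single-dilution-first` stops at the first
ring yielding a confirmed set, `exhaustive-ml` screens every ring. Clipping
makes the most concentrated ring insensitive when the reference is near 1, so
detection naturally deepens with the ring index — the tests include a surface
whose planted synergy is only detectable on the deepest ring.

The recovery property is evaluated under fixed study conditions chosen once:
3 rings/dilutions, 8 drugs, one planted synergistic triple of strength +0.3,
noise sd 0.02, $\tau = 0.1$, Bliss reference. Over 100 seeded surfaces the
staged search must recover the planted triple at least 95 times while always
testing strictly fewer combinations than the exhaustive meaningful screen
(1152 at this size). These sizes keep the whole suite under a minute on one
CPU while still exercising every ring and the focus machinery.

## What the synthetic surfaces do not show

The generator emulates smooth monotone single-agent curves, constant-shift
interactions, homoscedastic noise, and a perfectly executed dose ladder. Real
screens add curve-fit error, plate/droplet effects, non-constant interaction
surfaces, and biological replicates; passing the recovery property here shows
the search logic and budget accounting are correct, not that the thresholds
transfer to laboratory data. Droplet formation physics, refill logistics and
optical readout are outside the model entirely; time accounting stops at
positions × cycle time.

## Numerical choices

Counts are computed by the multiplicative binomial recurrence in double
precision, which is exact below $2^{53}$ — five orders of magnitude above the
largest in-scope count, $\binom{192}{4}$ — and the binomial property tests run
at $r \le 6$, covering the full design range while staying in the exact
regime. Times are floating point and rounded only at presentation (CSV export
rounds the two time columns to 4 decimals; counts are written exactly, without
thousands separators). Ties in the scheduler are broken by target order, then
position order, then radius index, making every export deterministic.
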