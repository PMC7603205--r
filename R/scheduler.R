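#' Plan a dispensing screen
#'
#' Produces a feasible dispensing plan covering every target combination
#' exactly once. A rotor *position* is a tuple of circumferential ring offsets
#' (in well-pitch units, one per ring); at each position up to `n_radii`
#' shuttle passes — one per outlet radius — each collect `r` droplets and
#' dispense one combination. A well on ring `i` at home radius `j` aligns with
#' radius `(j + offset_i) mod n_radii`.
#'
#' Combinations using at most one well per ring are dispensed by aligning all
#' their wells on the pass radius. When a combination takes several wells from
#' the same ring (circumferential/mixed movements), the first well per ring is
#' aligned through the position's base offsets and the remaining wells are
#' collected by incremental ring steps within the pass; such intra-position
#' steps are counted in the execution trace but do not open new positions.
#'
#' The planner is greedy (first fit): each target is placed on the first open
#' position and free radius whose base offsets are compatible. It makes no
#' optimality claim; the closed-form position counts
#' ([positions_no_dilution()], [positions_with_dilution()]) remain the
#' instrument's ideal. The plan is deterministic given the well map and
#' target order.
#'
#' @param wm A `well_map`.
#' @param targets Integer matrix with `r` rows (one column per combination of
#'   well indices, as returned by [enumerate_combinations()] or
#'   [filter_meaningful()]), or a list of integer vectors.
#' @return An object of class `dispensing_plan`: list with `config`,
#'   `targets` (canonicalized matrix), `offsets` (list of per-position ring
#'   offset vectors), `passes` (data frame: `position`, `radius`, `combo_id`,
#'   `intra_steps`) and `ledger` (data frame mapping each combination to its
#'   position and pass).
#' @examples
#' wm <- make_dilution_layout(instrument_config(3, 3, 3))
#' plan <- plan_screen(wm, enumerate_combinations(wm, 3))
#' simulate_plan(plan, wm)$droplets  # 252 = 84 x 3
#' @export
plan_screen <- function(wm, targets) {
  stopifnot(inherits(wm, "well_map"))
  if (is.list(targets) && !is.matrix(targets))
    targets <- if (length(targets) == 0L) matrix(integer(), nrow = 0L)
               else vapply(targets, identity, integer(length(targets[[1L]])))
  if (!is.matrix(targets)) targets <- as.matrix(targets)
  n_rad <- wm$config$n_radii
  n_ring <- wm$config$n_rings
  m <- ncol(targets)
  if (m == 0L) {
    return(structure(list(config = wm$config, targets = targets,
                          offsets = list(),
                          passes = empty_passes(), ledger = empty_ledger()),
                     class = "dispensing_plan"))
  }
  targets <- apply(targets, 2L, sort)
  if (!is.matrix(targets)) targets <- matrix(targets, ncol = m)
  r <- nrow(targets)
  keys <- apply(targets, 2L, paste, collapse = "-")
  if (anyDuplicated(keys))
    stop("targets must be distinct combinations")
  for (c_i in seq_len(m)) {
    co <- targets[, c_i]
    if (anyDuplicated(co) > 0L)
      stop("combination ", keys[c_i], " repeats a well")
    if (any(wm$wells$kind[co] == "empty"))
      stop("infeasible target: combination ", keys[c_i],
           " references an empty well")
  }

  offsets <- list()                 # per position: integer vector, NA = free
  used_radii <- list()              # per position: logical vector length n_rad
  pass_pos <- integer(m); pass_rad <- integer(m); pass_steps <- integer(m)

  for (c_i in seq_len(m)) {
    co <- targets[, c_i]
    rings <- wm$wells$ring[co]
    radii <- wm$wells$radius[co]
    by_ring <- split(radii, rings)                # names: 0-based ring index
    ring_ids <- as.integer(names(by_ring))
    jfirst <- vapply(by_ring, min, numeric(1))
    extras <- vapply(by_ring, function(x) length(x) - 1L, integer(1))

    placed <- FALSE
    for (p in seq_along(offsets)) {
      free_k <- which(!used_radii[[p]]) - 1L
      for (k in free_k) {
        req <- (k - jfirst) %% n_rad
        cur <- offsets[[p]][ring_ids + 1L]
        if (all(is.na(cur) | cur == req)) {
          offsets[[p]][ring_ids + 1L] <- as.integer(req)
          used_radii[[p]][k + 1L] <- TRUE
          pass_pos[c_i] <- p; pass_rad[c_i] <- k
          placed <- TRUE
          break
        }
      }
      if (placed) break
    }
    if (!placed) {
      k <- as.integer(jfirst[1L])   # anchor the lowest used ring at offset 0
      p <- length(offsets) + 1L
      offsets[[p]] <- rep(NA_integer_, n_ring)
      offsets[[p]][ring_ids + 1L] <- as.integer((k - jfirst) %% n_rad)
      used_radii[[p]] <- rep(FALSE, n_rad)
      used_radii[[p]][k + 1L] <- TRUE
      pass_pos[c_i] <- p; pass_rad[c_i] <- k
    }
    # intra-position increments: distance walked to fetch extra wells per ring
    p <- pass_pos[c_i]; k <- pass_rad[c_i]
    off <- offsets[[p]][ring_ids + 1L]
    steps <- 0L
    for (g in seq_along(ring_ids)) {
      if (extras[g] > 0L) {
        others <- setdiff(by_ring[[g]], jfirst[g])
        steps <- steps + sum((k - ((others + off[g]) %% n_rad)) %% n_rad)
      }
    }
    pass_steps[c_i] <- as.integer(steps)
  }
  offsets <- lapply(offsets, function(o) { o[is.na(o)] <- 0L; o })
  passes <- data.frame(position = pass_pos, radius = pass_rad,
                       combo_id = seq_len(m), intra_steps = pass_steps)
  passes <- passes[order(passes$position, passes$radius), ]
  rownames(passes) <- NULL
  ledger <- data.frame(combo_id = passes$combo_id, key = keys[passes$combo_id],
                       position = passes$position, radius = passes$radius,
                       stringsAsFactors = FALSE)
  structure(list(config = wm$config, targets = targets, offsets = offsets,
                 passes = passes, ledger = ledger),
            class = "dispensing_plan")
}

empty_passes <- function()
  data.frame(position = integer(), radius = integer(),
             combo_id = integer(), intra_steps = integer())
empty_ledger <- function()
  data.frame(combo_id = integer(), key = character(),
             position = integer(), radius = integer(),
             stringsAsFactors = FALSE)

#' @export
print.dispensing_plan <- function(x, ...) {
  cat(sprintf("dispensing plan: %d combinations in %d positions (%d passes)\n",
              ncol(x$targets), length(x$offsets), nrow(x$passes)))
  invisible(x)
}

#' Replay and verify a dispensing plan
#'
#' Replays every position and shuttle pass of a plan against the well-map
#' geometry, asserting that each pass's combination is reachable (first well
#' per ring aligned by the base offsets, extra wells by intra-position ring
#' increments), that no radius is used twice within a position, and that the
#' ledger covers every target combination exactly once. Violations raise an
#' error pinpointing the position and pass.
#'
#' @param plan A `dispensing_plan`.
#' @param wm The `well_map` the plan was built against.
#' @return A list of counts: `positions`, `passes`, `droplets`,
#'   `intra_steps`, and `elapsed_days` (model time via [screen_time_days()]).
#' @export
simulate_plan <- function(plan, wm) {
  stopifnot(inherits(plan, "dispensing_plan"), inherits(wm, "well_map"))
  n_rad <- wm$config$n_radii
  seen <- character()
  for (i in seq_len(nrow(plan$passes))) {
    p <- plan$passes$position[i]; k <- plan$passes$radius[i]
    co <- sort(plan$targets[, plan$passes$combo_id[i]])
    off <- plan$offsets[[p]]
    if (any(off < 0L) || any(off >= n_rad))
      stop("position ", p, ": ring offsets out of range")
    rings <- wm$wells$ring[co]; radii <- wm$wells$radius[co]
    if (any(wm$wells$kind[co] == "empty"))
      stop("position ", p, " pass on radius ", k, ": empty well collected")
    for (g in unique(rings)) {
      js <- radii[rings == g]
      aligned <- (min(js) + off[g + 1L]) %% n_rad
      if (aligned != k)
        stop("position ", p, " pass on radius ", k,
             ": well (ring ", g, ", radius ", min(js),
             ") aligns at radius ", aligned, ", not the pass radius")
    }
    key <- paste(co, collapse = "-")
    if (key %in% seen)
      stop("ledger violation at position ", p, " radius ", k,
           ": combination ", key, " dispensed more than once")
    seen <- c(seen, key)
  }
  by_pos <- split(plan$passes$radius, plan$passes$position)
  for (p in names(by_pos))
    if (anyDuplicated(by_pos[[p]]))
      stop("position ", p, ": radius used by more than one pass")
  target_keys <- if (ncol(plan$targets) > 0L)
    apply(plan$targets, 2L, function(co) paste(sort(co), collapse = "-"))
  else character()
  if (!setequal(seen, target_keys) || length(seen) != length(target_keys))
    stop("ledger violation: dispensed set does not match the target set")
  list(positions = length(plan$offsets),
       passes = nrow(plan$passes),
       droplets = nrow(plan$targets) * ncol(plan$targets),
       intra_steps = sum(plan$passes$intra_steps),
       elapsed_days = screen_time_days(length(plan$offsets),
                                       plan$config$seconds_per_position))
}

#' Combinations dispensed per rotor position
#'
#' The realized parallelism of a plan, to compare with the instrument's ideal
#' of `n_radii` combinations per position.
#'
#' @param plan A non-empty `dispensing_plan`.
#' @return Combinations per position (real).
#' @export
position_efficiency <- function(plan) {
  stopifnot(inherits(plan, "dispensing_plan"))
  if (length(plan$offsets) == 0L) stop("plan is empty")
  ncol(plan$targets) / length(plan$offsets)
}

#' Export a dispensing plan as CSV
#'
#' One row per shuttle pass: position id, semicolon-joined ring offsets, pass
#' radius, combination id, and the wells collected (`ring:radius`,
#' semicolon-joined, in collection order). Deterministic given the plan.
#'
#' @param plan A `dispensing_plan`.
#' @param wm The matching `well_map`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_plan_csv <- function(plan, wm, path) {
  rows <- plan$passes
  off <- vapply(rows$position, function(p)
    paste(plan$offsets[[p]], collapse = ";"), character(1))
  wellstr <- vapply(rows$combo_id, function(ci) {
    co <- plan$targets[, ci]
    ord <- order(wm$wells$ring[co], wm$wells$radius[co])
    paste(sprintf("%d:%d", wm$wells$ring[co][ord], wm$wells$radius[co][ord]),
          collapse = ";")
  }, character(1))
  out <- data.frame(position_id = rows$position, ring_offsets = off,
                    radius = rows$radius, combo_id = rows$combo_id,
                    intra_steps = rows$intra_steps, wells = wellstr,
                    stringsAsFactors = FALSE)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
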