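#' Retarget a solute-temperature ladder toward a target acceptance ratio
#'
#' Cost-density equalization: each adjacent pair's cost is
#' `c_m = -log(max(a_m, eps))`, spread as a piecewise-constant density over
#' log-temperature.  The new total range is chosen so that the total cost
#' equals `(M - 1) * (-log(target))` (extrapolating the last pair's density
#' beyond the current top when the ladder must expand), and the new
#' temperatures are placed at equal-cost quantiles.  The bottom temperature
#' and the replica count never change.  A fixed point is reached exactly when
#' every measured acceptance equals the target.
#'
#' Acceptances are floored at `eps` (default 1e-3) so that a dead pair has
#' finite cost, and capped just below 1 so that a saturated pair has a small
#' positive cost; the log-range growth per call is capped at a factor of 3 to
#' keep single-round extrapolation from overshooting on near-unit
#' acceptances.
#'
#' @param ladder strictly increasing solute temperatures, K.
#' @param pair_acceptances measured acceptance ratios, length
#'   `length(ladder) - 1`.
#' @param target desired acceptance ratio in (0, 1).
#' @param eps acceptance floor.
#' @param move `"all"` (default) moves every temperature except the bottom;
#'   `"top"` moves only the top temperature.
#' @return new ladder, same length, bottom unchanged, strictly increasing.
#' @export
retarget_ladder <- function(ladder, pair_acceptances, target, eps = 1e-3,
                            move = c("all", "top")) {
  move <- match.arg(move)
  M <- length(ladder)
  if (length(pair_acceptances) != M - 1) {
    stop("need one acceptance per adjacent pair")
  }
  if (is.unsorted(ladder, strictly = TRUE)) stop("ladder must be increasing")
  if (!(target > 0 && target < 1)) stop("target must lie in (0, 1)")
  if (M == 1) return(ladder)
  x <- log(ladder)
  w <- diff(x)
  cost <- -log(pmax(pmin(pair_acceptances, 1 - 1e-9), eps))
  cost <- pmax(cost, 1e-9)
  rho <- cost / w
  ctot <- sum(cost)
  cstar <- (M - 1) * (-log(target))
  cum <- c(0, cumsum(cost))
  # new top: equal-cost point at cstar, extrapolating the last density
  if (cstar <= ctot) {
    seg <- findInterval(cstar, cum, rightmost.closed = TRUE)
    seg <- min(seg, M - 1)
    x_top <- x[seg] + (cstar - cum[seg]) / rho[seg]
  } else {
    x_top <- x[M] + (cstar - ctot) / rho[M - 1]
  }
  x_top <- min(x_top, x[1] + 3 * (x[M] - x[1]))
  if (move == "top") {
    new_x <- c(x[1:(M - 1)], max(x_top, x[M - 1] + 1e-6))
    out <- exp(new_x)
    out[1:(M - 1)] <- ladder[1:(M - 1)]
    return(out)
  }
  q <- seq(0, cstar, length.out = M)
  new_x <- vapply(q, function(ci) {
    if (ci >= ctot) return(x[M] + (ci - ctot) / rho[M - 1])
    seg <- max(1, min(findInterval(ci, cum, rightmost.closed = TRUE), M - 1))
    x[seg] + (ci - cum[seg]) / rho[seg]
  }, numeric(1))
  new_x[M] <- x_top
  # enforce strict monotonicity against degenerate densities
  for (i in 2:M) new_x[i] <- max(new_x[i], new_x[i - 1] + 1e-6)
  out <- exp(new_x)
  out[1] <- ladder[1]
  out
}

# measured acceptance per adjacent pair of the given dimension, with the
# denominator counted per the scheduler's parity rule (attempts appear in the
# log only when their parity phase was active)
.pair_acceptance <- function(log, dimension, n_levels) {
  att <- log$attempts
  att <- att[att$dimension == dimension, , drop = FALSE]
  vapply(seq_len(n_levels - 1), function(a) {
    sel <- att$pair_a == a
    if (!any(sel)) return(NA_real_)
    mean(att$accepted[sel])
  }, numeric(1))
}

#' Tune solute temperatures by multi-round short gREST runs
#'
#' For each requested CV state (window center), iterates: run a short
#' 1D-gREST simulation with the ligand restrained at that center, measure the
#' per-pair acceptance ratios, and [retarget_ladder()] toward the target.
#' The exchange-attempt period grows geometrically across rounds (default
#' 0.21 ps to 2.1 ps over 5 rounds) while the per-round simulation length is
#' fixed, so early rounds measure acceptance from many cheap attempts and
#' late rounds from production-like spacing.  The final ladder is the
#' element-wise mean of the per-state results.
#'
#' @param sys a `system_model`.
#' @param ladder_init initial solute temperatures, K.
#' @param states CV values (window centers) at which to tune, Angstrom;
#'   typically bound, intermediate, unbound.
#' @param rounds number of tuning rounds per state.
#' @param target target acceptance ratio; either a scalar or a per-round
#'   schedule of length `rounds`.
#' @param window_k restraint force constant during tuning, kcal/mol/A^2.
#' @param round_ps simulated time per replica per round, ps; scalar or one
#'   value per round.  The default (`NULL`) allots 150 attempt phases per
#'   round, so rounds lengthen as the attempt period ramps up and every round
#'   measures acceptance from a comparable number of attempts.
#' @param periods exchange-attempt periods per round, ps (default geometric
#'   0.21 -> 2.1).
#' @param equil_ps equilibration before each round's attempts, ps.
#' @param cv the CV (defaults to the system's).
#' @param seed master seed.
#' @param T0 thermostat temperature, K.
#' @param dyn a [dynamics_params()] template.
#' @param move passed to [retarget_ladder()].
#' @param damping fraction of the proposed log-temperature step applied per
#'   round (1 = undamped); scalar or per-round.  The exchange cost between
#'   adjacent solute temperatures grows roughly quadratically with their
#'   log-spacing, so the undamped linear-density update oscillates around the
#'   target instead of settling; the default `NULL` uses the
#'   stochastic-approximation schedule 1/(r+1) (half the proposed step in
#'   round 1, shrinking thereafter), which contracts the iteration and damps
#'   measurement noise in late rounds.
#' @return list of class `tuning_history`: `rounds` (data.frame with one row
#'   per state x round: ladder, acceptances, period), `states_used`,
#'   `final_ladder`, `per_state_final` (matrix states x M).
#' @export
tune_temperatures <- function(sys, ladder_init, states, rounds = 5L,
                              target = 0.2, window_k = 2, round_ps = NULL,
                              periods = NULL, equil_ps = 5, cv = sys$cv_default,
                              seed = 1L, T0 = 310, dyn = dynamics_params(),
                              move = "all", damping = 0.5) {
  if (length(states) < 1 || rounds < 1) stop("need >= 1 state and round")
  if (length(target) == 1) target <- rep(target, rounds)
  if (length(target) != rounds) stop("target must be scalar or per-round")
  if (is.null(periods)) {
    periods <- if (rounds == 1) 2.1 else 0.21 * 10^((seq_len(rounds) - 1) /
                                                      (rounds - 1))
  }
  if (is.null(round_ps)) round_ps <- 150 * periods
  round_ps <- rep_len(round_ps, rounds)
  if (is.null(damping)) damping <- 1 / (seq_len(rounds) + 1)
  damping <- rep_len(damping, rounds)
  rows <- list()
  finals <- matrix(NA_real_, length(states), length(ladder_init))
  for (si in seq_along(states)) {
    ladder <- ladder_init
    start <- conformation_at_cv(sys, states[si], cv)
    for (r in seq_len(rounds)) {
      win <- list(umbrella_window(states[si], window_k, cv))
      grid <- replica_grid(sys, ladder, win, init_coords = start,
                           seed = seed + 1000L * si + r, T0 = T0)
      n_att <- max(4L, as.integer(round(round_ps[r] / periods[r])))
      res <- run_2d(grid, segment_ps = periods[r], n_attempts = n_att,
                    equil_ps = equil_ps, dims = "gREST", dyn = dyn)
      acc <- .pair_acceptance(res$log, "gREST", length(ladder))
      acc[is.na(acc)] <- 0
      proposal <- retarget_ladder(ladder, acc, target[r], move = move)
      new_ladder <- exp((1 - damping[r]) * log(ladder) +
                          damping[r] * log(proposal))
      new_ladder[1] <- ladder[1]
      rows[[length(rows) + 1L]] <- data.frame(
        state = states[si], round = r, period_ps = periods[r],
        n_attempts = n_att,
        ladder = I(list(ladder)), acceptances = I(list(acc)),
        new_ladder = I(list(new_ladder)))
      ladder <- new_ladder
    }
    finals[si, ] <- ladder
  }
  structure(list(rounds = do.call(rbind, rows), states_used = states,
                 per_state_final = finals,
                 final_ladder = colMeans(finals), target = target,
                 version = 1L),
            class = "tuning_history")
}

#' Histogram of CV samples on fixed breaks
#'
#' @param x CV samples, Angstrom.
#' @param breaks bin edges (regular grid recommended; 0.1 A default bins via
#'   [cv_breaks()]).
#' @return list of class `cv_histogram` with `breaks`, `counts`, `prob`.
#' @export
cv_histogram <- function(x, breaks) {
  cuts <- findInterval(x, breaks, rightmost.closed = TRUE)
  cuts <- cuts[cuts >= 1 & cuts <= length(breaks) - 1]
  counts <- tabulate(cuts, nbins = length(breaks) - 1)
  structure(list(breaks = breaks, counts = counts,
                 prob = if (sum(counts)) counts / sum(counts) else counts),
            class = "cv_histogram")
}

#' Regular histogram breaks covering a CV range
#'
#' @param lo,hi range, Angstrom.
#' @param bin bin width, Angstrom (default 0.1).
#' @return numeric vector of edges.
#' @export
cv_breaks <- function(lo, hi, bin = 0.1) {
  seq(floor(lo / bin) * bin, ceiling(hi / bin) * bin, by = bin)
}

#' Overlap coefficient of two normalized histograms
#'
#' `sum_bins min(p_a, p_b)`: 1 for identical histograms, 0 for disjoint
#' supports.
#'
#' @param hist_a,hist_b [cv_histogram()]s on identical breaks.
#' @return overlap in `[0, 1]`.
#' @export
overlap_coefficient <- function(hist_a, hist_b) {
  if (!isTRUE(all.equal(hist_a$breaks, hist_b$breaks))) {
    stop("histogram binning mismatch")
  }
  sum(pmin(hist_a$prob, hist_b$prob))
}

.next_k <- function(k, menu = c(2, 3, 4)) {
  higher <- menu[menu > k + 1e-9]
  if (length(higher)) min(higher) else max(menu, k)
}

#' Tune umbrella windows from a trial run
#'
#' Diagnoses a 1D-REUS trial (single solute temperature) and proposes a
#' better window set: (a) adjacent pairs whose histogram overlap falls below
#' `overlap_min` or whose acceptance falls below `acc_min` get a midpoint
#' window inserted at their neighbors' maximum force constant; (b) CV
#' intervals where the pooled ("united") density falls below `gap_frac` of
#' its mean flag the surrounding inter-center interval for insertion too, and
#' there the force constant is escalated along `k_menu` (2 -> 3 -> 4
#' kcal/mol/A^2 by default) -- both for the inserted midpoint and for
#' existing windows whose centers lie inside the gap (stiffer umbrellas hold
#' replicas against the free-energy gradient that empties those regions).
#' Windows are never removed.
#'
#' @param windows list of [umbrella_window()]s of the trial, ordered by
#'   center.
#' @param cv_series list (per window) of CV sample vectors from the trial.
#' @param acceptance per-adjacent-pair acceptance ratios from the trial log.
#' @param overlap_min,acc_min,gap_frac thresholds.
#' @param k_menu force-constant escalation menu; set `continuous_k = TRUE`
#'   to escalate by multiplying 1.5x instead.
#' @param continuous_k escalate multiplicatively instead of along the menu.
#' @param bin histogram bin width, Angstrom.
#' @return list of class `window_tuning_report`: `histograms`, `united`,
#'   `overlaps`, `acceptance`, `flagged_pairs`, `flagged_gaps` (data.frame of
#'   CV intervals), `proposals` (data.frame center/k of inserted windows),
#'   `new_windows` (full proposed window list).
#' @export
tune_windows <- function(windows, cv_series, acceptance,
                         overlap_min = 0.03, acc_min = 0.05, gap_frac = 0.10,
                         k_menu = c(2, 3, 4), continuous_k = FALSE,
                         bin = 0.1) {
  K <- length(windows)
  if (!length(cv_series) || !any(vapply(cv_series, length, integer(1)) > 0)) {
    stop("empty trial data")
  }
  centers <- vapply(windows, `[[`, numeric(1), "center")
  ks <- vapply(windows, `[[`, numeric(1), "k")
  rng <- range(unlist(cv_series), centers)
  breaks <- cv_breaks(rng[1] - bin, rng[2] + bin, bin)
  hists <- lapply(cv_series, cv_histogram, breaks = breaks)
  united <- cv_histogram(unlist(cv_series), breaks)
  overlaps <- vapply(seq_len(K - 1), function(a) {
    overlap_coefficient(hists[[a]], hists[[a + 1]])
  }, numeric(1))

  # density gaps between the first and last centers
  mids <- (breaks[-1] + breaks[-length(breaks)]) / 2
  inside <- mids >= centers[1] & mids <= centers[K]
  dens <- united$prob
  mean_dens <- mean(dens[inside])
  gap_bin <- inside & dens < gap_frac * mean_dens
  gaps <- .runs_to_intervals(gap_bin, breaks)

  flagged_pairs <- which(overlaps < overlap_min |
                           (!is.na(acceptance) & acceptance < acc_min))
  gap_pairs <- integer(0)
  if (nrow(gaps)) {
    for (g in seq_len(nrow(gaps))) {
      hit <- which(centers[-K] < gaps$hi[g] & centers[-1] > gaps$lo[g])
      gap_pairs <- union(gap_pairs, hit)
    }
  }
  insert_pairs <- sort(union(flagged_pairs, gap_pairs))

  escalate <- function(k) {
    if (continuous_k) 1.5 * k else .next_k(k, k_menu)
  }
  proposals <- NULL
  for (a in insert_pairs) {
    # escalation is driven by coverage gaps: a midpoint inserted into a
    # flagged gap takes the next force constant up, one inserted for low
    # acceptance alone keeps its neighbors' stiffness
    k_new <- if (a %in% gap_pairs) escalate(max(ks[a], ks[a + 1])) else
      max(ks[a], ks[a + 1])
    proposals <- rbind(proposals, data.frame(
      center = (centers[a] + centers[a + 1]) / 2, k = k_new))
  }
  new_ks <- ks
  if (nrow(gaps)) {
    for (i in seq_len(K)) {
      in_gap <- any(centers[i] >= gaps$lo & centers[i] <= gaps$hi)
      if (in_gap) new_ks[i] <- escalate(ks[i])
    }
  }
  cvdef <- windows[[1]]$cv
  all_centers <- c(centers, if (!is.null(proposals)) proposals$center)
  all_ks <- c(new_ks, if (!is.null(proposals)) proposals$k)
  ord <- order(all_centers)
  new_windows <- lapply(ord, function(i) {
    umbrella_window(all_centers[i], all_ks[i], cvdef)
  })
  if (is.null(proposals)) {
    proposals <- data.frame(center = numeric(0), k = numeric(0))
  } else {
    proposals <- proposals[order(proposals$center), , drop = FALSE]
  }
  structure(list(histograms = hists, united = united, overlaps = overlaps,
                 acceptance = acceptance, flagged_pairs = flagged_pairs,
                 flagged_gaps = gaps, proposals = proposals,
                 new_windows = new_windows, version = 1L),
            class = "window_tuning_report")
}

.runs_to_intervals <- function(flag, breaks) {
  out <- data.frame(lo = numeric(0), hi = numeric(0))
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  for (i in seq_along(r$values)) {
    if (isTRUE(r$values[i])) {
      out <- rbind(out, data.frame(lo = breaks[starts[i]],
                                   hi = breaks[ends[i] + 1]))
    }
  }
  out
}

#' Run a 1D-REUS trial and collect tuning inputs
#'
#' Convenience wrapper: runs REUS-only exchanges at a single solute
#' temperature and returns the pieces [tune_windows()] consumes.
#'
#' @param sys a `system_model`.
#' @param windows list of [umbrella_window()]s.
#' @param n_attempts attempt phases.
#' @param segment_ps time between attempts, ps.
#' @param equil_ps equilibration, ps.
#' @param init_coords per-window initial coordinates (default: ligand
#'   translated to each center).
#' @param seed master seed.
#' @param T0 thermostat temperature, K.
#' @param Tm solute temperature of the trial, K (default T0).
#' @param dyn a [dynamics_params()] template.
#' @param stride within-segment CV sampling stride, steps.
#' @return list with `windows`, `cv_series`, `acceptance`, `log`, `trajs`.
#' @export
reus_trial <- function(sys, windows, n_attempts = 200L, segment_ps = 2.1,
                       equil_ps = 10, init_coords = NULL, seed = 1L, T0 = 310,
                       Tm = T0, dyn = dynamics_params(), stride = 0L) {
  cvdef <- windows[[1]]$cv
  if (is.null(init_coords)) {
    init_coords <- lapply(windows, function(w) {
      conformation_at_cv(sys, w$center, cvdef)
    })
  }
  grid <- replica_grid(sys, Tm, windows, init_coords = init_coords,
                       seed = seed, T0 = T0)
  res <- run_2d(grid, segment_ps = segment_ps, n_attempts = n_attempts,
                equil_ps = equil_ps, dims = "REUS", dyn = dyn,
                stride = stride)
  K <- length(windows)
  cv_series <- lapply(seq_len(K), function(k) {
    res$trajs$cv_A[res$trajs$window_index == k]
  })
  list(windows = windows, cv_series = cv_series,
       acceptance = .pair_acceptance(res$log, "REUS", K), log = res$log,
       trajs = res$trajs)
}
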