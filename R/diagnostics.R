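#' Per-pair exchange acceptance profile
#'
#' Accepted/attempted per adjacent parameter pair and dimension, with the
#' denominator counted per the scheduler's parity rule (a pair is "attempted"
#' only in phases where its parity is active).  Pairs with zero attempts get
#' `NA` (undefined), never 0.
#'
#' @param log an `exchange_log` from [run_2d()].
#' @param cumulative_after drop attempts at or before this attempt index
#'   before computing ratios (0 = use everything); exposes the windowed
#'   variant alongside the cumulative one.
#' @return data.frame: `dimension`, `pair_a`, `pair_b`, `attempted`,
#'   `accepted`, `ratio`.
#' @export
acceptance_profile <- function(log, cumulative_after = 0L) {
  if (!nrow(log$attempts)) {
    return(data.frame(dimension = character(0), pair_a = integer(0),
                      pair_b = integer(0), attempted = integer(0),
                      accepted = integer(0), ratio = numeric(0)))
  }
  att <- log$attempts[log$attempts$attempt > cumulative_after, , drop = FALSE]
  out <- list()
  for (dm in unique(c("gREST", "REUS"))) {
    n_levels <- if (dm == "gREST") log$M else log$K
    if (n_levels < 2) next
    for (a in seq_len(n_levels - 1)) {
      sel <- att$dimension == dm & att$pair_a == a
      n_att <- sum(sel)
      n_acc <- sum(att$accepted[sel])
      out[[length(out) + 1L]] <- data.frame(
        dimension = dm, pair_a = a, pair_b = a + 1L, attempted = n_att,
        accepted = n_acc,
        ratio = if (n_att > 0) n_acc / n_att else NA_real_)
    }
  }
  do.call(rbind, out)
}

#' Replay an exchange log's decisions from its recorded (delta, u) pairs
#'
#' Recomputes every outcome as `metropolis(delta, u)` and returns the same
#' table as [acceptance_profile()]; exact agreement certifies that the logged
#' decision variables reproduce the logged outcomes.
#'
#' @param log an `exchange_log`.
#' @return data.frame as in [acceptance_profile()].
#' @export
replay_acceptance <- function(log) {
  log2 <- log
  log2$attempts$accepted <- vapply(seq_len(nrow(log$attempts)), function(i) {
    metropolis(log$attempts$delta[i], log$attempts$u[i])
  }, logical(1))
  acceptance_profile(log2)
}

#' Visitation matrices and uniformity entropy
#'
#' Fraction of snapshots each replica spends at each parameter index, per
#' dimension, plus the Shannon entropy of each replica's visitation row
#' normalized by `log(n_indices)` so that 1 means perfectly uniform and 0
#' means pinned.
#'
#' @param log an `exchange_log`.
#' @return list with `grest` and `reus`, each a list of `matrix` (replicas x
#'   indices, rows summing to 1) and `entropy` (per replica).
#' @export
visitation <- function(log) {
  snaps <- log$snapshots
  if (!nrow(snaps)) stop("log has no snapshots")
  one_dim <- function(col, n_idx) {
    reps <- sort(unique(snaps$replica))
    mat <- matrix(0, length(reps), n_idx)
    for (ri in seq_along(reps)) {
      tab <- tabulate(snaps[[col]][snaps$replica == reps[ri]], nbins = n_idx)
      mat[ri, ] <- tab / sum(tab)
    }
    rownames(mat) <- reps
    entropy <- apply(mat, 1, function(p) {
      p <- p[p > 0]
      if (n_idx == 1) return(1)
      -sum(p * log(p)) / log(n_idx)
    })
    list(matrix = mat, entropy = entropy)
  }
  list(grest = one_dim("temp_index", log$M),
       reus = one_dim("window_index", log$K))
}

#' Completed round trips per replica
#'
#' A round trip is one full traversal of the parameter ladder: reaching one
#' end, then the opposite end, then the first end again counts one trip
#' (symmetric in the starting end).
#'
#' @param log an `exchange_log`.
#' @param dimension `"gREST"` or `"REUS"`.
#' @return named integer vector of completed trips per replica.
#' @export
round_trips <- function(log, dimension = c("REUS", "gREST")) {
  dimension <- match.arg(dimension)
  col <- if (dimension == "gREST") "temp_index" else "window_index"
  n_idx <- if (dimension == "gREST") log$M else log$K
  snaps <- log$snapshots
  reps <- sort(unique(snaps$replica))
  vapply(reps, function(r) {
    idx <- snaps[[col]][snaps$replica == r][order(snaps$attempt[snaps$replica == r])]
    ends <- idx[idx == 1 | idx == n_idx]
    if (n_idx == 1 || !length(ends)) return(0L)
    ends <- ends[c(TRUE, diff(ends) != 0)]   # collapse repeats
    max(0L, as.integer((length(ends) - 1) %/% 2))
  }, integer(1), USE.NAMES = TRUE) -> out
  names(out) <- reps
  out
}

#' Per-window CV distribution report at one solute temperature
#'
#' Per-window normalized histograms (default 0.1 A bins), the pooled
#' ("united") distribution over all windows (all frames pooled equally, then
#' renormalized), adjacent-pair overlap coefficients, and flagged coverage
#' gaps using the same rule as [tune_windows()].
#'
#' @param trajs frame table from [run_2d()] (columns `cv_A`, `temp_index`,
#'   `window_index`).
#' @param log the matching `exchange_log` (for window count/centers).
#' @param temp_index solute-temperature index to condition on.
#' @param bin histogram bin width, Angstrom.
#' @param gap_frac density-gap threshold as a fraction of the mean united
#'   density between the first and last window centers.
#' @return list of class `reus_distribution_report`: `histograms`, `united`,
#'   `overlaps`, `per_window_stats` (mean/sd/n per window), `flagged_gaps`.
#' @export
reus_distribution_report <- function(trajs, log, temp_index = 1L, bin = 0.1,
                                     gap_frac = 0.10) {
  sel <- trajs$temp_index == temp_index & is.finite(trajs$cv_A)
  if (!any(sel)) stop("no CV series at the requested temperature index")
  tr <- trajs[sel, , drop = FALSE]
  K <- log$K
  centers <- log$centers
  rng <- range(tr$cv_A, centers)
  breaks <- cv_breaks(rng[1] - bin, rng[2] + bin, bin)
  series <- lapply(seq_len(K), function(k) tr$cv_A[tr$window_index == k])
  hists <- lapply(series, cv_histogram, breaks = breaks)
  united <- cv_histogram(tr$cv_A, breaks)
  overlaps <- if (K >= 2) {
    vapply(seq_len(K - 1), function(a) {
      overlap_coefficient(hists[[a]], hists[[a + 1]])
    }, numeric(1))
  } else numeric(0)
  stats <- data.frame(
    window = seq_len(K), center = centers, k = log$ks,
    n = vapply(series, length, integer(1)),
    mean = vapply(series, function(x) if (length(x)) mean(x) else NA_real_,
                  numeric(1)),
    sd = vapply(series, function(x) if (length(x) > 1) sd(x) else NA_real_,
                numeric(1)))
  mids <- (breaks[-1] + breaks[-length(breaks)]) / 2
  inside <- mids >= centers[1] & mids <= centers[length(centers)]
  gaps <- if (any(inside)) {
    .runs_to_intervals(inside & united$prob < gap_frac *
                         mean(united$prob[inside]), breaks)
  } else data.frame(lo = numeric(0), hi = numeric(0))
  structure(list(histograms = hists, united = united, overlaps = overlaps,
                 per_window_stats = stats, flagged_gaps = gaps,
                 breaks = breaks),
            class = "reus_distribution_report")
}

#' Bound-pose hit ratio
#'
#' Percentage of replicas whose minimum ligand RMSD over the run falls
#' strictly below `cutoff` at least once, plus the per-replica
#' (initial RMSD, min RMSD) table used for initial-vs-best scatters.
#'
#' @param rmsd_series list of per-replica ligand-RMSD series (Angstrom), or a
#'   data.frame with columns `initial_rmsd` and `min_rmsd`.
#' @param cutoff RMSD cutoff, Angstrom (default 1; strict `<`).
#' @return list of class `hit_ratio_report`: `hit_pct`, `cutoff`, `table`
#'   (replica, initial_rmsd, min_rmsd, hit).
#' @export
hit_ratio <- function(rmsd_series, cutoff = 1) {
  if (is.data.frame(rmsd_series)) {
    tab <- rmsd_series
    if (is.null(tab$replica)) tab$replica <- seq_len(nrow(tab))
  } else {
    if (!length(rmsd_series)) stop("need at least one replica")
    tab <- data.frame(
      replica = seq_along(rmsd_series),
      initial_rmsd = vapply(rmsd_series, function(x) x[1], numeric(1)),
      min_rmsd = vapply(rmsd_series, min, numeric(1)))
  }
  tab$hit <- tab$min_rmsd < cutoff
  structure(list(hit_pct = 100 * mean(tab$hit), cutoff = cutoff, table = tab),
            class = "hit_ratio_report")
}

#' Ligand-RMSD series per replica from recorded frame coordinates
#'
#' @param result a `rex_result` from [run_2d()] run with
#'   `record_coords = TRUE`.
#' @param sys the `system_model`.
#' @param ref a [pose_reference()] (default: fit on protein beads, RMSD over
#'   ligand beads of the reference pose).
#' @return list of numeric RMSD series, one per replica.
#' @export
replica_rmsd_series <- function(result, sys, ref = NULL) {
  if (is.null(result$frame_coords)) stop("run_2d was not run with record_coords")
  if (is.null(ref)) {
    ref <- pose_reference(sys$reference_pose,
                          which(sys$beads$role == "protein"),
                          which(sys$beads$role == "ligand"))
  }
  masses <- sys$beads$mass
  n_rep <- result$log$M * result$log$K
  out <- vector("list", n_rep)
  for (t in seq_along(result$frame_coords)) {
    for (r in seq_len(n_rep)) {
      fc <- result$frame_coords[[t]][[r]]
      if (is.null(fc)) next
      vals <- vapply(seq_len(dim(fc)[1]), function(f) {
        ligand_rmsd(fc[f, , ], ref, masses)
      }, numeric(1))
      out[[r]] <- c(out[[r]], vals)
    }
  }
  out
}

#' Per-replica coordinate trajectories from a run
#'
#' Concatenates the recorded frame coordinates of each replica across all
#' attempt segments.
#'
#' @param result a `rex_result` from [run_2d()] run with
#'   `record_coords = TRUE`.
#' @return list (one per replica) of arrays frames x beads x 3.
#' @export
replica_coord_trajs <- function(result) {
  if (is.null(result$frame_coords)) {
    stop("run_2d was not run with record_coords")
  }
  n_rep <- result$log$M * result$log$K
  lapply(seq_len(n_rep), function(r) {
    do.call(abind3, lapply(result$frame_coords, `[[`, r))
  })
}

#' Aggregate sampling-efficiency report
#'
#' Bundles every diagnostic for one production run: acceptance profiles in
#' both dimensions, visitation matrices with uniformity entropies, round-trip
#' counts, the per-window CV distribution report at the base temperature, and
#' (when coordinates were recorded) the bound-pose hit ratio.
#'
#' @param result a `rex_result` from [run_2d()].
#' @param sys the `system_model`.
#' @param hit_cutoff RMSD cutoff for [hit_ratio()], Angstrom.
#' @param ref optional [pose_reference()].
#' @return list of class `efficiency_report`.
#' @export
efficiency_report <- function(result, sys, hit_cutoff = 1, ref = NULL) {
  log <- result$log
  rep_hits <- NULL
  if (!is.null(result$frame_coords) &&
      length(result$frame_coords) && !is.null(result$frame_coords[[1]])) {
    series <- replica_rmsd_series(result, sys, ref)
    rep_hits <- hit_ratio(series, hit_cutoff)
  }
  structure(list(
    acceptance = acceptance_profile(log),
    visitation = visitation(log),
    round_trips = list(reus = round_trips(log, "REUS"),
                       grest = round_trips(log, "gREST")),
    reus_distributions = reus_distribution_report(result$trajs, log),
    hits = rep_hits,
    version = 1L), class = "efficiency_report")
}
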