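#' Metropolis acceptance decision
#'
#' Accepts an exchange iff `u < exp(-delta)`; a non-positive delta is always
#' accepted.
#'
#' @param delta dimensionless exchange criterion.
#' @param u uniform draw in `[0, 1)`.
#' @return logical.
#' @export
metropolis <- function(delta, u) {
  if (u < 0 || u >= 1) stop("u must lie in [0, 1)")
  delta <= 0 || u < exp(-delta)
}

#' gREST exchange criterion between two replicas
#'
#' For replicas i (at lambda_m) and j (at lambda_n), both thermostatted at
#' T0, the exchange criterion is
#' `delta = beta0 * [(E_n(x_i) + E_m(x_j)) - (E_m(x_i) + E_n(x_j))]`
#' where `E_m(x) = lambda_m E_uu + sqrt(lambda_m) E_uv + E_vv + E_restraint`.
#' Restraint and vv terms enter identically on both sides and cancel; only
#' the solute components matter.
#'
#' @param bd_i,bd_j [energy()] breakdowns of the two replicas' current
#'   configurations.
#' @param lambda_m,lambda_n scaling factors currently held by i and j.
#' @param T0 thermostat temperature, K.
#' @return dimensionless delta.
#' @export
grest_delta <- function(bd_i, bd_j, lambda_m, lambda_n, T0 = 310) {
  duu <- bd_i$E_uu - bd_j$E_uu
  duv <- bd_i$E_uv - bd_j$E_uv
  .beta0(T0) * ((lambda_n - lambda_m) * duu +
                  (sqrt(lambda_n) - sqrt(lambda_m)) * duv)
}

#' Umbrella window for REUS
#'
#' Harmonic bias `U(xi) = k (xi - center)^2` on the COM-distance CV (no
#' factor 1/2).
#'
#' @param center window center, Angstrom.
#' @param k force constant, kcal/mol/A^2.
#' @param cv the shared [cv_definition()].
#' @return list of class `umbrella_window`.
#' @export
umbrella_window <- function(center, k, cv) {
  if (k <= 0) stop("window force constant must be positive")
  structure(list(center = center, k = k, cv = cv), class = "umbrella_window")
}

#' REUS exchange criterion between two replicas
#'
#' `delta = beta0 * [U_n(xi_i) + U_m(xi_j) - U_m(xi_i) - U_n(xi_j)]` with
#' `U_m(xi) = k_m (xi - c_m)^2`.  Both windows must restrain the same CV.
#'
#' @param xi_i,xi_j current CV values of the two replicas, Angstrom.
#' @param win_m,win_n the [umbrella_window()]s currently held by i and j.
#' @param T0 thermostat temperature, K.
#' @return dimensionless delta.
#' @export
reus_delta <- function(xi_i, xi_j, win_m, win_n, T0 = 310) {
  if (!identical(win_m$cv$name, win_n$cv$name) ||
      !identical(win_m$cv$anchor_beads, win_n$cv$anchor_beads) ||
      !identical(win_m$cv$ligand_beads, win_n$cv$ligand_beads)) {
    stop("CV mismatch between windows")
  }
  u <- function(w, xi) w$k * (xi - w$center)^2
  .beta0(T0) * ((u(win_n, xi_i) + u(win_m, xi_j)) -
                  (u(win_m, xi_i) + u(win_n, xi_j)))
}

#' Alternating exchange schedule
#'
#' With both dimensions active, attempts cycle with period 4:
#' 0 -> (gREST, even), 1 -> (REUS, even), 2 -> (gREST, odd),
#' 3 -> (REUS, odd).  With a single active dimension the parity alternates
#' with period 2.  Within a phase, even parity attempts pairs (1,2), (3,4),
#' ... and odd parity (2,3), (4,5), ... along the active dimension at fixed
#' index in the other dimension.
#'
#' @param attempt_index 0-based attempt counter.
#' @param dims character vector of active dimensions, subset of
#'   `c("gREST", "REUS")`.
#' @return list with `dimension` and `parity` (`"even"`/`"odd"`).
#' @export
exchange_schedule <- function(attempt_index, dims = c("gREST", "REUS")) {
  stopifnot(attempt_index >= 0, length(dims) >= 1,
            all(dims %in% c("gREST", "REUS")))
  if (length(dims) == 2) {
    phase <- attempt_index %% 4
    list(dimension = dims[1 + (phase %% 2)],
         parity = if (phase < 2) "even" else "odd")
  } else {
    list(dimension = dims[1],
         parity = if (attempt_index %% 2 == 0) "even" else "odd")
  }
}

# 1-based lower indices of the adjacent pairs attempted in a phase
.parity_pairs <- function(n_levels, parity) {
  if (n_levels < 2) return(integer(0))
  starts <- if (parity == "even") seq(1, n_levels - 1, by = 2)
            else if (n_levels >= 3) seq(2, n_levels - 1, by = 2)
            else integer(0)
  as.integer(starts)
}

#' Construct a 2D replica grid
#'
#' Creates M x K replicas, one per (solute temperature, umbrella window)
#' pair, with the identity mapping replica_id = (window_index - 1) * M +
#' temp_index.  Exchanges later permute the mapping, never the states'
#' identities or noise streams.
#'
#' @param sys a `system_model`.
#' @param ladder increasing solute temperatures, K (length M).
#' @param windows list of [umbrella_window()]s ordered by center (length K).
#' @param init_coords a single n x 3 matrix used for every replica, or a list
#'   of K matrices (one per window, e.g. from [pull()]).
#' @param seed master seed (velocities, noise streams, exchange draws).
#' @param T0 thermostat temperature, K.
#' @return list of class `replica_grid`.
#' @export
replica_grid <- function(sys, ladder, windows, init_coords = NULL, seed = 1L,
                         T0 = 310) {
  if (is.unsorted(ladder, strictly = TRUE)) {
    stop("ladder must be strictly increasing")
  }
  centers <- vapply(windows, `[[`, numeric(1), "center")
  if (is.unsorted(centers, strictly = TRUE)) {
    stop("window centers must be strictly increasing")
  }
  if (ladder[1] < T0) stop("ladder must start at or above T0")
  M <- length(ladder); K <- length(windows)
  if (is.null(init_coords)) init_coords <- sys$reference_pose
  coords_for <- function(k) {
    if (is.list(init_coords)) init_coords[[k]] else init_coords
  }
  states <- vector("list", M * K)
  for (k in seq_len(K)) {
    for (m in seq_len(M)) {
      id <- (k - 1L) * M + m
      states[[id]] <- replica_state(sys, seed = seed, replica_id = id,
                                    temp_index = m, window_index = k,
                                    coords = coords_for(k), T_init = T0)
    }
  }
  structure(list(sys = sys, ladder = ladder, windows = windows,
                 states = states, T0 = T0, seed = as.integer(seed),
                 M = M, K = K),
            class = "replica_grid")
}

# replica id currently holding (temp_index m, window_index k)
.grid_holder <- function(grid, m, k) {
  for (s in grid$states) {
    if (s$temp_index == m && s$window_index == k) return(s$replica_id)
  }
  stop("broken mapping: no replica holds (", m, ", ", k, ")")
}

.grid_mapping <- function(grid) {
  data.frame(
    replica = vapply(grid$states, `[[`, integer(1), "replica_id"),
    temp_index = vapply(grid$states, `[[`, integer(1), "temp_index"),
    window_index = vapply(grid$states, `[[`, integer(1), "window_index")
  )
}

#' Run a (1D or 2D) gREST/REUS replica-exchange simulation
#'
#' Equilibrates every replica without exchange attempts, then alternates
#' propagation segments with Metropolis exchange attempts following
#' [exchange_schedule()].  Accepted exchanges swap parameter indices between
#' the two replicas; coordinates, velocities and noise streams stay put.
#' Velocities are not rescaled: every replica runs at the same thermostat
#' temperature, so the kinetic term cancels exactly in both dimensions.
#'
#' @param grid a [replica_grid()].
#' @param segment_ps propagation time between attempts, ps.
#' @param n_attempts number of attempt phases (each phase attempts all pairs
#'   of the active parity).
#' @param equil_ps equilibration time before the first attempt, ps.
#' @param dims active exchange dimensions (default both).
#' @param dyn a [dynamics_params()] template; its `n_steps` is ignored.
#' @param stride within-segment frame stride in steps (0 records only
#'   segment-end frames).
#' @param record_coords keep coordinates for every recorded frame.
#' @param progress_every print a progress line every this many attempts
#'   (0 = silent).
#' @return list of class `rex_result` with `log` (an `exchange_log`),
#'   `trajs` (data.frame of recorded frames tagged with replica and current
#'   parameter indices), `frame_coords` (list by replica, if requested), and
#'   the final `grid`.
#' @export
run_2d <- function(grid, segment_ps = 2.1, n_attempts = 100L, equil_ps = 0,
                   dims = c("gREST", "REUS"), dyn = dynamics_params(),
                   stride = 0L, record_coords = FALSE, progress_every = 0L) {
  sys <- .with_compiled(grid$sys)
  M <- grid$M; K <- grid$K
  n_rep <- M * K
  lambdas <- grid$T0 / grid$ladder
  seg_steps <- max(1L, as.integer(round(segment_ps / dyn$dt)))
  dyn_seg <- dyn; dyn_seg$n_steps <- seg_steps
  dyn_seg$T_sim <- grid$T0
  dyn_seg$seed <- grid$seed

  restr_for <- function(s) list(umbrella_restraint(
    grid$windows[[s$window_index]]$cv,
    grid$windows[[s$window_index]]$center,
    grid$windows[[s$window_index]]$k))
  scale_for <- function(s) scaling_params(grid$T0, grid$ladder[s$temp_index])

  # equilibration without attempts
  if (equil_ps > 0) {
    dyn_eq <- dyn_seg
    dyn_eq$n_steps <- max(1L, as.integer(round(equil_ps / dyn$dt)))
    for (r in seq_len(n_rep)) {
      grid$states[[r]] <- propagate(grid$states[[r]], sys, scale_for(grid$states[[r]]),
                                    restr_for(grid$states[[r]]), dyn_eq)$state
    }
  }

  attempts <- vector("list", n_attempts)
  snapshots <- vector("list", n_attempts + 1L)
  trajs <- vector("list", n_attempts)
  coords_acc <- if (record_coords) vector("list", n_attempts) else NULL
  snapshots[[1]] <- cbind(attempt = 0L, .grid_mapping(grid))
  u_counter <- 0L

  for (t in seq_len(n_attempts)) {
    tcur <- equil_ps + (t - 1) * segment_ps
    seg_frames <- vector("list", n_rep)
    bds <- vector("list", n_rep)
    cvs <- numeric(n_rep)
    for (r in seq_len(n_rep)) {
      s <- grid$states[[r]]
      pg <- propagate(s, sys, scale_for(s), restr_for(s), dyn_seg,
                      stride = if (stride > 0) stride else seg_steps,
                      record_coords = record_coords, t0 = tcur)
      grid$states[[r]] <- pg$state
      fr <- pg$frames
      fr$replica <- s$replica_id
      fr$temp_index <- s$temp_index
      fr$window_index <- s$window_index
      seg_frames[[r]] <- fr
      if (record_coords) coords_acc[[t]][[r]] <- pg$frame_coords
      last <- nrow(fr)
      cvs[r] <- fr$cv_A[last]
      bds[[r]] <- list(E_uu = fr$E_uu[last], E_uv = fr$E_uv[last])
    }
    trajs[[t]] <- do.call(rbind, seg_frames)

    sch <- exchange_schedule(t - 1L, dims)
    recs <- list()
    if (sch$dimension == "gREST" && M >= 2) {
      for (k in seq_len(K)) {
        for (a in .parity_pairs(M, sch$parity)) {
          ri <- .grid_holder(grid, a, k)
          rj <- .grid_holder(grid, a + 1L, k)
          delta <- grest_delta(bds[[ri]], bds[[rj]], lambdas[a],
                               lambdas[a + 1L], grid$T0)
          u <- .hash_u01(grid$seed, 2e6 + t, u_counter)
          u_counter <- u_counter + 1L
          acc <- metropolis(delta, u)
          if (acc) {
            grid$states[[ri]]$temp_index <- a + 1L
            grid$states[[rj]]$temp_index <- a
          }
          recs[[length(recs) + 1L]] <- data.frame(
            attempt = t, dimension = "gREST", parity = sch$parity,
            pair_a = a, pair_b = a + 1L, other_index = k,
            replica_i = ri, replica_j = rj, delta = delta, u = u,
            accepted = acc)
        }
      }
    } else if (sch$dimension == "REUS" && K >= 2) {
      for (m in seq_len(M)) {
        for (a in .parity_pairs(K, sch$parity)) {
          ri <- .grid_holder(grid, m, a)
          rj <- .grid_holder(grid, m, a + 1L)
          delta <- reus_delta(cvs[ri], cvs[rj], grid$windows[[a]],
                              grid$windows[[a + 1L]], grid$T0)
          u <- .hash_u01(grid$seed, 2e6 + t, u_counter)
          u_counter <- u_counter + 1L
          acc <- metropolis(delta, u)
          if (acc) {
            grid$states[[ri]]$window_index <- a + 1L
            grid$states[[rj]]$window_index <- a
          }
          recs[[length(recs) + 1L]] <- data.frame(
            attempt = t, dimension = "REUS", parity = sch$parity,
            pair_a = a, pair_b = a + 1L, other_index = m,
            replica_i = ri, replica_j = rj, delta = delta, u = u,
            accepted = acc)
        }
      }
    }
    attempts[[t]] <- if (length(recs)) do.call(rbind, recs) else NULL
    snapshots[[t + 1L]] <- cbind(attempt = t, .grid_mapping(grid))
    if (progress_every > 0 && t %% progress_every == 0) {
      message(sprintf("attempt %d / %d", t, n_attempts))
    }
  }

  att <- do.call(rbind, attempts[!vapply(attempts, is.null, logical(1))])
  if (is.null(att)) {
    att <- data.frame(attempt = integer(0), dimension = character(0),
                      parity = character(0), pair_a = integer(0),
                      pair_b = integer(0), other_index = integer(0),
                      replica_i = integer(0), replica_j = integer(0),
                      delta = numeric(0), u = numeric(0),
                      accepted = logical(0))
  }
  log <- structure(list(attempts = att,
                        snapshots = do.call(rbind, snapshots),
                        M = M, K = K, dims = dims,
                        segment_ps = segment_ps, equil_ps = equil_ps,
                        seed = grid$seed, T0 = grid$T0,
                        ladder = grid$ladder,
                        centers = vapply(grid$windows, `[[`, numeric(1),
                                         "center"),
                        ks = vapply(grid$windows, `[[`, numeric(1), "k"),
                        version = 1L),
                   class = "exchange_log")
  structure(list(log = log, trajs = do.call(rbind, trajs),
                 frame_coords = coords_acc, grid = grid),
            class = "rex_result")
}
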