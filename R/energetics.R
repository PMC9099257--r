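#' Solute-tempering scaling parameters
#'
#' In gREST a replica at solute temperature Tm runs at the thermostat
#' temperature T0 with its solute-solute energy terms scaled by
#' lambda = T0 / Tm and solute-solvent cross terms by sqrt(lambda) (the REST2
#' convention).  lambda = 1 recovers the unscaled Hamiltonian.
#'
#' @param T0 simulation (thermostat) temperature, K.
#' @param Tm solute temperature, K; must satisfy Tm >= T0.
#' @return list of class `scaling_params` with `T0`, `Tm`, `lambda`.
#' @export
scaling_params <- function(T0 = 310, Tm = T0) {
  if (!(T0 > 0) || Tm < T0) stop("require Tm >= T0 > 0")
  structure(list(T0 = T0, Tm = Tm, lambda = T0 / Tm),
            class = "scaling_params")
}

#' Harmonic umbrella restraint on the COM-distance CV
#'
#' Energy U = k (xi - center)^2 with xi the mass-weighted COM distance of the
#' CV (note: no factor 1/2).  Umbrella energies are reported as restraint
#' energy and are never scaled by lambda.
#'
#' @param cv a [cv_definition()].
#' @param center window center, Angstrom.
#' @param k force constant, kcal/mol/A^2.
#' @return list of class `umbrella_restraint`.
#' @export
umbrella_restraint <- function(cv, center, k) {
  if (k <= 0) stop("umbrella force constant must be positive")
  structure(list(cv = cv, center = center, k = k),
            class = "umbrella_restraint")
}

#' Positional restraints on selected beads
#'
#' Energy sum_i k |x_i - p_i|^2 (no factor 1/2).  Reported as restraint
#' energy, never scaled by lambda.
#'
#' @param beads integer bead ids.
#' @param ref n x 3 matrix of full-system reference coordinates (rows for
#'   `beads` are used).
#' @param k force constant, kcal/mol/A^2.
#' @return list of class `positional_restraint`.
#' @export
positional_restraint <- function(beads, ref, k) {
  if (k < 0) stop("positional restraint k must be >= 0")
  structure(list(beads = as.integer(beads),
                 points = ref[beads, , drop = FALSE], k = k),
            class = "positional_restraint")
}

# Pack a list of restraints (umbrella_restraint / positional_restraint) for
# the engine; also returns the compiled CV groups of the umbrella (if any).
.compile_restraints <- function(sys, restraints) {
  if (is.null(restraints)) return(list())
  if (inherits(restraints, "umbrella_restraint") ||
      inherits(restraints, "positional_restraint")) {
    restraints <- list(restraints)
  }
  pos <- NULL
  umb <- NULL
  for (r in restraints) {
    if (inherits(r, "positional_restraint")) {
      if (r$k > 0) {
        pos <- rbind(pos, cbind(r$beads - 1, r$points, r$k))
      }
    } else if (inherits(r, "umbrella_restraint")) {
      if (!is.null(umb)) stop("at most one umbrella restraint per replica")
      umb <- c(.compile_cv(sys, r$cv), list(center = r$center, k = r$k))
    } else {
      stop("unknown restraint type")
    }
  }
  out <- list()
  if (!is.null(pos)) out$pos <- pos
  if (!is.null(umb)) out$umb <- umb
  out
}

.compile_cv <- function(sys, cv) {
  validate_cv(sys, cv)
  m <- sys$beads$mass
  aw <- m[cv$anchor_beads]; lw <- m[cv$ligand_beads]
  list(anchor = as.integer(cv$anchor_beads - 1), awt = aw / sum(aw),
       ligand = as.integer(cv$ligand_beads - 1), lwt = lw / sum(lw))
}

#' Term-decomposed potential energy with gREST scaling
#'
#' Evaluates the potential split into solute-solute (`E_uu`), solute-solvent
#' (`E_uv`), solvent-solvent (`E_vv`, including box walls), and restraint
#' (`E_restraint`) parts, plus the lambda-scaled total
#' `scaled_total = lambda E_uu + sqrt(lambda) E_uv + E_vv + E_restraint`.
#'
#' A bonded/nonbonded term is uu if all its beads are solute-flagged, vv if
#' none are, uv otherwise; tethers follow their bead's flag; walls are always
#' vv; restraints are never scaled.
#'
#' @param sys a `system_model`.
#' @param coords n x 3 coordinates, Angstrom.
#' @param scaling a [scaling_params()]; default unscaled.
#' @param restraints list of restraints (see [umbrella_restraint()],
#'   [positional_restraint()]) or NULL.
#' @return list of class `energy_breakdown` with the four components,
#'   `total_unscaled`, and `scaled_total` (kcal/mol).
#' @export
energy <- function(sys, coords, scaling = scaling_params(), restraints = NULL) {
  coords <- as.matrix(coords)
  if (nrow(coords) != nrow(sys$beads) || ncol(coords) != 3) {
    stop("coordinate/bead-count mismatch")
  }
  res <- .energy_cpp(coords, .compile_system(sys),
                     scaling$lambda, .compile_restraints(sys, restraints),
                     FALSE)
  structure(res[c("E_uu", "E_uv", "E_vv", "E_restraint", "total_unscaled",
                  "scaled_total")], class = "energy_breakdown")
}

#' Analytic forces of the scaled Hamiltonian
#'
#' Gradient of `scaled_total` from [energy()], with the same sign convention
#' as MD engines (force = -gradient).
#'
#' @inheritParams energy
#' @return n x 3 matrix of forces, kcal/mol/A.
#' @export
forces <- function(sys, coords, scaling = scaling_params(),
                   restraints = NULL) {
  coords <- as.matrix(coords)
  if (nrow(coords) != nrow(sys$beads) || ncol(coords) != 3) {
    stop("coordinate/bead-count mismatch")
  }
  .energy_cpp(coords, .compile_system(sys), scaling$lambda,
              .compile_restraints(sys, restraints), TRUE)$forces
}

#' Langevin dynamics parameters
#'
#' @param dt timestep, ps.
#' @param gamma friction coefficient, 1/ps.
#' @param T_sim thermostat temperature, K (always the base temperature T0 in
#'   gREST; the solute temperature enters only via lambda).
#' @param n_steps number of BAOAB steps.
#' @param seed master seed; per-replica noise streams are derived as
#'   hash(seed, replica_id, segment_counter).
#' @return list of class `dynamics_params`.
#' @export
dynamics_params <- function(dt = 0.01, gamma = 1, T_sim = 310, n_steps = 1000L,
                            seed = 1L) {
  if (dt <= 0 || gamma <= 0 || T_sim <= 0 || n_steps < 0) {
    stop("invalid dynamics parameters")
  }
  structure(list(dt = dt, gamma = gamma, T_sim = T_sim,
                 n_steps = as.integer(n_steps), seed = as.integer(seed)),
            class = "dynamics_params")
}

#' Create a replica state
#'
#' Holds one replica's coordinates, velocities, parameter indices, and the
#' counter of its private noise stream.  Velocities are drawn from the
#' Maxwell-Boltzmann distribution at `T_init` using a stream derived from
#' `(seed, replica_id)` only, independent of R's global RNG.
#'
#' @param sys a `system_model`.
#' @param seed master seed.
#' @param replica_id integer replica identity (fixed for the run; exchanges
#'   swap parameters, never identities or noise streams).
#' @param temp_index,window_index 1-based parameter indices currently held.
#' @param coords starting coordinates (default: reference pose).
#' @param T_init temperature for velocity initialization, K.
#' @return list of class `replica_state`.
#' @export
replica_state <- function(sys, seed = 1L, replica_id = 1L, temp_index = 1L,
                          window_index = 1L, coords = sys$reference_pose,
                          T_init = 310) {
  n <- nrow(sys$beads)
  v <- matrix(0, n, 3)
  free <- !sys$beads$frozen
  k <- 0L
  for (i in which(free)) {
    sdv <- sqrt(kB * T_init * .acc_fac / sys$beads$mass[i])
    for (d in 1:3) {
      # inverse-normal from two hashed uniforms (Box-Muller, first value)
      u1 <- .hash_u01(seed, 1e6 + replica_id, 2L * k)
      u2 <- .hash_u01(seed, 1e6 + replica_id, 2L * k + 1L)
      u1 <- max(u1, 1e-15)
      v[i, d] <- sdv * sqrt(-2 * log(u1)) * cos(2 * pi * u2)
      k <- k + 1L
    }
  }
  structure(list(coords = as.matrix(coords), vels = v,
                 replica_id = as.integer(replica_id),
                 temp_index = as.integer(temp_index),
                 window_index = as.integer(window_index), segment = 0L),
            class = "replica_state")
}

#' Propagate a replica with BAOAB Langevin dynamics
#'
#' Integrates `params$n_steps` steps at the thermostat temperature
#' `params$T_sim` under the lambda-scaled Hamiltonian plus restraints.  The
#' noise stream is derived from `(params$seed, state$replica_id,
#' state$segment)`, and the segment counter is advanced, so repeated calls
#' continue a deterministic per-replica stream.  Exchanging parameters
#' between replicas does not touch their streams.
#'
#' @param state a [replica_state()].
#' @param sys a `system_model`.
#' @param scaling a [scaling_params()].
#' @param restraints restraint list (umbrella and/or positional) or NULL.
#' @param params a [dynamics_params()].
#' @param stride record a frame every `stride` steps (0 = no frames).
#' @param cv CV definition whose value is recorded per frame (default: the
#'   system's); NULL disables CV recording.
#' @param record_coords keep full coordinates per recorded frame.
#' @param t0 time offset for the frame table, ps.
#' @return list with the updated `state`, a `frames` data.frame (step,
#'   time_ps, cv_A, E_uu, E_uv, E_vv, E_restraint, total_unscaled,
#'   scaled_total), and (optionally) `frame_coords`, an array
#'   frames x beads x 3.
#' @export
propagate <- function(state, sys, scaling = scaling_params(),
                      restraints = NULL, params = dynamics_params(),
                      stride = 0L, cv = sys$cv_default, record_coords = FALSE,
                      t0 = 0) {
  csys <- .compile_system(sys)
  cre <- .compile_restraints(sys, restraints)
  cvg <- if (is.null(cv)) list() else .compile_cv(sys, cv)
  frame_cols <- c("step", "time_ps", "cv_A", "E_uu", "E_uv", "E_vv",
                  "E_restraint", "total_unscaled", "scaled_total")
  if (params$n_steps == 0L) {
    fr <- as.data.frame(setNames(rep(list(numeric(0)), 9), frame_cols))
    return(list(state = state, frames = fr, frame_coords = NULL))
  }
  stream <- .stream_seed(params$seed, state$replica_id, state$segment)
  res <- .propagate_cpp(state$coords, state$vels, csys, scaling$lambda, cre,
                        cvg, params$dt, params$gamma, params$T_sim,
                        params$n_steps, as.integer(stride), stream,
                        record_coords, t0)
  state$coords <- res$coords
  state$vels <- res$vels
  state$segment <- state$segment + 1L
  fr <- as.data.frame(res$frames)
  names(fr) <- frame_cols
  fc <- NULL
  if (record_coords && nrow(fr) > 0) {
    n <- nrow(sys$beads)
    fc <- aperm(array(res$frame_coords, dim = c(3, n, nrow(fr))), c(3, 2, 1))
  }
  list(state = state, frames = fr, frame_coords = fc, final_cv = res$cv)
}

#' Mean kinetic energy per degree of freedom
#'
#' Convenience for equipartition checks: 0.5 m v^2 summed over free beads,
#' divided by the number of degrees of freedom, in kcal/mol (should equal
#' kB T / 2 at equilibrium).
#'
#' @param sys a `system_model`.
#' @param vels n x 3 velocity matrix, A/ps.
#' @return scalar, kcal/mol.
#' @export
kinetic_per_dof <- function(sys, vels) {
  free <- !sys$beads$frozen
  ke <- 0.5 * sum(sys$beads$mass[free] * rowSums(vels[free, , drop = FALSE]^2)) /
    .acc_fac
  ke / (3 * sum(free))
}
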