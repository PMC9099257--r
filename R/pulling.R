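#' Equidistant pulling/window targets along the CV
#'
#' @param cv_min,cv_max range endpoints, Angstrom (`cv_max > cv_min`).
#' @param n number of targets (>= 2), spacing `(cv_max - cv_min) / (n - 1)`.
#' @return numeric vector of n CV values from `cv_min` to `cv_max` inclusive.
#' @export
equidistant_targets <- function(cv_min, cv_max, n) {
  if (n < 2) stop("need n >= 2 targets")
  if (!(cv_max > cv_min)) stop("cv_max must exceed cv_min")
  seq(cv_min, cv_max, length.out = n)
}

#' Stepwise umbrella pulling schedule
#'
#' @param targets ordered CV targets, Angstrom; strictly increasing for
#'   `direction = "forward"`, strictly decreasing for `"reverse"`.
#' @param k_pull umbrella force constant, kcal/mol/A^2 (E = k (xi - c)^2).
#' @param step_ps simulation time per pulling step, ps.
#' @param direction `"forward"` (out of the pocket) or `"reverse"`.
#' @param protein_restraint_k positional restraint on protein beads during
#'   pulling, kcal/mol/A^2 (0 disables).
#' @return list of class `pull_schedule`.
#' @export
pull_schedule <- function(targets, k_pull = 4, step_ps = 30,
                          direction = c("forward", "reverse"),
                          protein_restraint_k = 1) {
  direction <- match.arg(direction)
  if (k_pull <= 0) stop("k_pull must be positive")
  mono <- if (direction == "forward") !is.unsorted(targets, strictly = TRUE)
          else !is.unsorted(rev(targets), strictly = TRUE)
  if (!mono) stop("targets must be strictly monotone in the stated direction")
  structure(list(targets = targets, k_pull = k_pull, step_ps = step_ps,
                 direction = direction,
                 protein_restraint_k = protein_restraint_k),
            class = "pull_schedule")
}

#' Generate initial window conformations by stepwise umbrella pulling
#'
#' For each target in order, simulates `step_ps` under an umbrella
#' `U = k_pull (xi - target)^2` plus positional restraints on all non-frozen
#' protein beads at their starting positions.  The final frame of each step
#' is both the stored initial structure for that window and the start of the
#' next step.  If the CV fails to come within `tol` of a target at step end,
#' a warning is recorded in the result (not raised).
#'
#' @param sys a `system_model`.
#' @param start n x 3 starting conformation (bound pose for forward pulls;
#'   for reverse pulls typically the last forward conformation).
#' @param schedule a [pull_schedule()].
#' @param seed master seed for the Langevin noise.
#' @param cv CV definition (defaults to the system's).
#' @param dyn a [dynamics_params()] template.
#' @param tol target-tracking warning tolerance, Angstrom.
#' @param stride quality-trajectory frame stride, steps.
#' @param T0 thermostat temperature, K.
#' @return list of class `pull_result`: `conformations` (list of n x 3
#'   matrices, one per target), `achieved_cv`, `targets`, `warnings`,
#'   `quality` (frame table with coordinates: `frames`, `frame_coords`,
#'   `frame_target`), `schedule`.
#' @export
pull <- function(sys, start, schedule, seed = 1L, cv = sys$cv_default,
                 dyn = dynamics_params(), tol = 1.0, stride = 25L, T0 = 310) {
  sys <- .with_compiled(sys)
  prot <- which(sys$beads$role == "protein" & !sys$beads$frozen)
  restr_pos <- if (schedule$protein_restraint_k > 0 && length(prot)) {
    positional_restraint(prot, start, schedule$protein_restraint_k)
  } else NULL
  state <- replica_state(sys, seed = seed, replica_id = 1L, coords = start,
                         T_init = T0)
  dyn_step <- dyn
  dyn_step$n_steps <- max(1L, as.integer(round(schedule$step_ps / dyn$dt)))
  dyn_step$T_sim <- T0
  dyn_step$seed <- seed
  confs <- vector("list", length(schedule$targets))
  achieved <- numeric(length(schedule$targets))
  warns <- character(0)
  frames <- list(); fcoords <- list(); ftarget <- list()
  t0 <- 0
  for (i in seq_along(schedule$targets)) {
    tgt <- schedule$targets[i]
    restr <- c(list(umbrella_restraint(cv, tgt, schedule$k_pull)),
               if (!is.null(restr_pos)) list(restr_pos))
    pg <- propagate(state, sys, scaling_params(T0, T0), restr, dyn_step,
                    stride = stride, cv = cv, record_coords = TRUE, t0 = t0)
    state <- pg$state
    confs[[i]] <- state$coords
    achieved[i] <- pg$final_cv
    if (abs(achieved[i] - tgt) > tol) {
      warns <- c(warns, sprintf(
        "step %d: CV %.2f A missed target %.2f A by more than %.1f A",
        i, achieved[i], tgt, tol))
    }
    frames[[i]] <- pg$frames
    fcoords[[i]] <- pg$frame_coords
    ftarget[[i]] <- rep(tgt, nrow(pg$frames))
    t0 <- t0 + schedule$step_ps
  }
  fr <- do.call(rbind, frames)
  fc <- do.call(abind3, fcoords)
  structure(list(conformations = confs, achieved_cv = achieved,
                 targets = schedule$targets, warnings = warns,
                 quality = list(frames = fr, frame_coords = fc,
                                frame_target = unlist(ftarget)),
                 schedule = schedule, seed = as.integer(seed)),
            class = "pull_result")
}

# bind 3D arrays along the first (frame) dimension
abind3 <- function(...) {
  xs <- list(...)
  xs <- xs[!vapply(xs, is.null, logical(1))]
  if (!length(xs)) return(NULL)
  n <- dim(xs[[1]])[2]
  do.call(rbind, lapply(xs, function(a) matrix(a, nrow = dim(a)[1]))) -> flat
  array(flat, dim = c(nrow(flat), n, 3))
}

#' Quality report of a pulling run
#'
#' Protein-bead RMSD (mass-weighted Kabsch fit over protein beads) versus a
#' reference per recorded frame, and the maximum absolute CV tracking error
#' per pulling step.
#'
#' @param pull_res a [pull()] result.
#' @param sys the `system_model`.
#' @param reference reference coordinates (default: the pose used to start
#'   the pull is not stored, so the system reference pose).
#' @return list of class `pull_quality_report`: `protein_rmsd` (per frame),
#'   `time_ps`, `cv_tracking_error` (per step, max |xi - target|),
#'   `max_protein_rmsd`.
#' @export
pull_quality <- function(pull_res, sys, reference = sys$reference_pose) {
  fr <- pull_res$quality$frames
  if (is.null(fr) || nrow(fr) == 0) {
    return(structure(list(protein_rmsd = numeric(0), time_ps = numeric(0),
                          cv_tracking_error = numeric(0),
                          max_protein_rmsd = NA_real_),
                     class = "pull_quality_report"))
  }
  prot <- which(sys$beads$role == "protein")
  masses <- sys$beads$mass
  fc <- pull_res$quality$frame_coords
  rmsd <- vapply(seq_len(dim(fc)[1]), function(f) {
    X <- fc[f, , ]
    if (length(prot) >= 3) {
      fitted <- .kabsch_apply(X, reference, prot, masses)
    } else {
      fitted <- X
    }
    d <- fitted[prot, , drop = FALSE] - reference[prot, , drop = FALSE]
    sqrt(mean(rowSums(d^2)))
  }, numeric(1))
  err <- abs(fr$cv_A - pull_res$quality$frame_target)
  per_step <- tapply(err, pull_res$quality$frame_target, max)
  structure(list(protein_rmsd = rmsd, time_ps = fr$time_ps,
                 cv_tracking_error = as.numeric(per_step),
                 max_protein_rmsd = max(rmsd)),
            class = "pull_quality_report")
}

#' Forward + reverse pulling to build a window manifest
#'
#' Runs a forward pull from the bound pose and a reverse pull starting at
#' the final forward conformation, and returns both conformation sets
#' indexed by target.
#'
#' @param sys a `system_model`.
#' @param targets CV targets (increasing), Angstrom.
#' @param k_pull,step_ps,protein_restraint_k see [pull_schedule()].
#' @param seed master seed (reverse pull uses `seed + 1`).
#' @param cv CV definition.
#' @param dyn a [dynamics_params()] template.
#' @return list with `forward`, `reverse` ([pull()] results) and `manifest`
#'   (data.frame: window, target, achieved_forward, achieved_reverse).
#' @export
dual_pull <- function(sys, targets, k_pull = 4, step_ps = 30,
                      protein_restraint_k = 1, seed = 1L,
                      cv = sys$cv_default, dyn = dynamics_params()) {
  fwd <- pull(sys, sys$reference_pose,
              pull_schedule(targets, k_pull, step_ps, "forward",
                            protein_restraint_k), seed = seed, cv = cv,
              dyn = dyn)
  rev_sched <- pull_schedule(rev(targets), k_pull, step_ps, "reverse",
                             protein_restraint_k)
  bwd <- pull(sys, fwd$conformations[[length(targets)]], rev_sched,
              seed = seed + 1L, cv = cv, dyn = dyn)
  manifest <- data.frame(
    window = seq_along(targets), target = targets,
    achieved_forward = fwd$achieved_cv,
    achieved_reverse = rev(bwd$achieved_cv))
  list(forward = fwd, reverse = bwd, manifest = manifest)
}
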