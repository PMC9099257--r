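# Shared fixtures: systems are deterministic, so build each once per session.
.sys_cache <- new.env(parent = emptyenv())

get_sys <- function(preset, seed = 1L, overrides = list()) {
  key <- paste(preset, seed,
               paste(names(overrides), unlist(overrides), collapse = "_"))
  if (is.null(.sys_cache[[key]])) {
    .sys_cache[[key]] <- build_system(preset, seed = seed,
                                      overrides = overrides)
  }
  .sys_cache[[key]]
}

# central-difference gradient of the scaled total energy
numeric_forces <- function(sys, coords, scaling = scaling_params(),
                           restraints = NULL, h = 1e-5) {
  g <- coords * 0
  for (i in seq_len(nrow(coords))) {
    for (d in 1:3) {
      xp <- coords; xm <- coords
      xp[i, d] <- xp[i, d] + h
      xm[i, d] <- xm[i, d] - h
      g[i, d] <- -(energy(sys, xp, scaling, restraints)$scaled_total -
                     energy(sys, xm, scaling, restraints)$scaled_total) /
        (2 * h)
    }
  }
  g
}

# random rigid motion (rotation + translation) applied to all coordinates
rigid_motion <- function(coords, seed = 1) {
  set.seed(seed)
  ang <- runif(3, 0, 2 * pi)
  Rx <- rbind(c(1, 0, 0), c(0, cos(ang[1]), -sin(ang[1])),
              c(0, sin(ang[1]), cos(ang[1])))
  Ry <- rbind(c(cos(ang[2]), 0, sin(ang[2])), c(0, 1, 0),
              c(-sin(ang[2]), 0, cos(ang[2])))
  Rz <- rbind(c(cos(ang[3]), -sin(ang[3]), 0),
              c(sin(ang[3]), cos(ang[3]), 0), c(0, 0, 1))
  R <- Rx %*% Ry %*% Rz
  sweep(coords %*% t(R), 2, runif(3, -5, 5), "+")
}

# a tiny hand-made system with one term of each gREST class:
# bead 1: protein, not solute, tethered (vv); beads 2-3: ligand, solute,
# bonded (uu); bond 1-2 crosses the partition (uv).
three_class_system <- function(k_uu = 10, k_uv = 4, k_vv = 7) {
  beads <- data.frame(
    role = c("protein", "ligand", "ligand"),
    solute = c(FALSE, TRUE, TRUE),
    mass = c(50, 12, 12), frozen = FALSE,
    tether_x = c(5, NA, NA), tether_y = c(5, NA, NA), tether_z = c(5, NA, NA),
    tether_k = c(k_vv, 0, 0))
  bonds <- data.frame(i = c(2L, 1L), j = c(3L, 2L), k = c(k_uu, k_uv),
                      r0 = c(0, 0))
  pose <- rbind(c(5, 5, 5), c(7, 5, 5), c(7, 6, 5))
  system_model(beads, bonds = bonds, box = cbind(rep(0, 3), rep(20, 3)),
               kwall = 10, reference_pose = pose, preset = "custom")
}

# Memoized full temperature-tuning history on pocket_small (M = 6, target
# 0.2, seed 42): shared between the tuning unit tests and the acceptance
# suite, which reuse the tuned ladder.
get_tuning_history <- function() {
  if (is.null(.sys_cache$tuning_history)) {
    sys <- get_sys("pocket_small")
    .sys_cache$tuning_history <- tune_temperatures(
      sys, geometric_ladder(6, 310, 663), states = c(3, 7.5, 12),
      rounds = 5, target = 0.2, seed = 42)
  }
  .sys_cache$tuning_history
}

# Memoized 1D-REUS trial + window-tuning round on pocket_small starting from
# 8 even windows at uniform k = 2 over the bound-to-unbound span (shared by
# the window-tuner and production-carry-over acceptance checks).
get_window_tuning <- function() {
  if (is.null(.sys_cache$window_tuning)) {
    sys <- get_sys("pocket_small")
    win0 <- even_windows(sys$cv_default, sys$cv_range[1], sys$cv_range[2],
                         K = 8, k = 2)
    trial <- reus_trial(sys, win0, n_attempts = 400, segment_ps = 2.1,
                        equil_ps = 20, seed = 5, stride = 30)
    wrep <- tune_windows(win0, trial$cv_series, trial$acceptance)
    .sys_cache$window_tuning <- list(win0 = win0, trial = trial, wrep = wrep)
  }
  .sys_cache$window_tuning
}

expect_between <- function(x, lo, hi) {
  expect_gte(x, lo)
  expect_lte(x, hi)
}
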