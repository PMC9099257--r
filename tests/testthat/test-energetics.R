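test_that("energy breakdown components sum to the unscaled total", {
  sys <- get_sys("pocket_small")
  set.seed(4)
  x <- sys$reference_pose + matrix(rnorm(36, 0, 0.4), ncol = 3)
  restr <- list(umbrella_restraint(sys$cv_default, 5, 2),
                positional_restraint(1:2, sys$reference_pose, 1))
  e <- energy(sys, x, scaling_params(310, 500), restr)
  expect_equal(e$total_unscaled,
               e$E_uu + e$E_uv + e$E_vv + e$E_restraint,
               tolerance = 1e-10)
})

test_that("gREST scaling follows lambda E_uu + sqrt(lambda) E_uv + E_vv", {
  # three-term system engineered to E_uu = 10, E_uv = 4, E_vv = 7
  sys <- three_class_system(k_uu = 10, k_uv = 4, k_vv = 7)
  x <- rbind(c(5, 5, 6), c(6, 5, 5), c(6, 6, 5))  # tether d=1, uv bond r=sqrt(2)...
  # place exactly: tether displacement 1, uu bond length 1, uv bond length 1
  x <- rbind(c(5, 5, 6), c(6, 5, 6), c(6, 6, 6))
  e1 <- energy(sys, x, scaling_params(310, 310))
  expect_equal(e1$E_uu, 10)
  expect_equal(e1$E_uv, 4)
  expect_equal(e1$E_vv, 7)
  expect_equal(e1$scaled_total, e1$total_unscaled)  # lambda = 1 identity
  e <- energy(sys, x, scaling_params(310, 1240))    # lambda = 0.25
  expect_equal(e$scaled_total, 0.25 * 10 + 0.5 * 4 + 7)  # 2.5 + 2 + 7 = 11.5
})

test_that("lambda arithmetic matches the ladder endpoints", {
  expect_equal(scaling_params(310, 620)$lambda, 0.5)
  expect_equal(scaling_params(310, 692)$lambda, 310 / 692)
  expect_equal(scaling_params(310, 692)$lambda, 0.44798, tolerance = 1e-4)
  expect_error(scaling_params(310, 300), "Tm >= T0")
})

test_that("restraint energies are never scaled by lambda", {
  sys <- get_sys("pocket_small")
  x <- conformation_at_cv(sys, 6)
  restr <- list(umbrella_restraint(sys$cv_default, 5, 2),
                positional_restraint(1:2, sys$reference_pose + 0.5, 3))
  e_lo <- energy(sys, x, scaling_params(310, 310), restr)
  e_hi <- energy(sys, x, scaling_params(310, 1000), restr)
  expect_equal(e_lo$E_restraint, e_hi$E_restraint)
  expect_gt(e_lo$E_restraint, 0)
  # scaled totals differ only through the solute terms
  lam <- 310 / 1000
  expect_equal(e_hi$scaled_total - e_lo$scaled_total,
               (lam - 1) * e_lo$E_uu + (sqrt(lam) - 1) * e_lo$E_uv,
               tolerance = 1e-10)
})

test_that("a single harmonic tether with k = 1 displaced by (1,0,0) pulls
           back with force (-2,0,0) under the E = k d^2 convention", {
  beads <- data.frame(role = "protein", solute = FALSE, mass = 12,
                      frozen = FALSE, tether_x = 5, tether_y = 5,
                      tether_z = 5, tether_k = 1)
  sys <- system_model(beads, box = cbind(rep(0, 3), rep(10, 3)), kwall = 10,
                      reference_pose = matrix(c(5, 5, 5), 1), preset = "custom")
  f <- forces(sys, matrix(c(6, 5, 5), 1))
  expect_equal(f[1, ], c(-2, 0, 0))
  expect_equal(energy(sys, matrix(c(6, 5, 5), 1))$total_unscaled, 1)
})

test_that("analytic forces match central differences on random
           configurations of both pocket presets", {
  for (preset in c("pocket_small", "pocket_flexible")) {
    sys <- get_sys(preset)
    set.seed(11)
    x <- sys$reference_pose +
      matrix(rnorm(length(sys$reference_pose), 0, 0.25), ncol = 3)
    restr <- list(umbrella_restraint(sys$cv_default, 4, 2),
                  positional_restraint(1:2, sys$reference_pose, 1))
    sc <- scaling_params(310, 620)
    f <- forces(sys, x, sc, restr)
    fn <- numeric_forces(sys, x, sc, restr)
    expect_lt(max(abs(f - fn)) / max(abs(f)), 1e-5, label = preset)
  }
})

test_that("flat_channel interior is force-free", {
  sys <- get_sys("flat_channel")
  coords <- sys$reference_pose
  coords[3, ] <- c(17.2, 2, 2)
  expect_identical(max(abs(forces(sys, coords))), 0)
})

test_that("propagate with n_steps = 0 is the identity and records nothing", {
  sys <- get_sys("pocket_small")
  st <- replica_state(sys, seed = 2)
  out <- propagate(st, sys, params = dynamics_params(n_steps = 0, seed = 2))
  expect_identical(out$state$coords, st$coords)
  expect_identical(out$state$vels, st$vels)
  expect_equal(nrow(out$frames), 0)
})

test_that("propagation is deterministic given (state, seed) and the noise
           stream survives a parameter change", {
  sys <- get_sys("pocket_small")
  dp <- dynamics_params(n_steps = 500, seed = 9)
  a <- propagate(replica_state(sys, seed = 9), sys, params = dp)
  b <- propagate(replica_state(sys, seed = 9), sys, params = dp)
  expect_identical(a$state$coords, b$state$coords)
  # replica id enters the stream: a different replica diverges
  c_ <- propagate(replica_state(sys, seed = 9, replica_id = 2), sys,
                  params = dp)
  expect_false(identical(a$state$coords, c_$state$coords))
})

test_that("equipartition: mean kinetic energy per dof is kB T / 2", {
  sys <- get_sys("pocket_small")
  st <- replica_state(sys, seed = 5)
  ke <- numeric(120)
  for (i in seq_along(ke)) {
    st <- propagate(st, sys, params = dynamics_params(n_steps = 500,
                                                      seed = 5))$state
    ke[i] <- kinetic_per_dof(sys, st$vels)
  }
  ke <- ke[-(1:20)]
  se <- sd(ke) / sqrt(length(ke))
  expect_lt(abs(mean(ke) - kB * 310 / 2), 3 * se + 1e-4)
})

test_that("umbrella-restrained CV has the closed-form stationary variance
           kB T / (2 k)", {
  sys <- get_sys("flat_channel")
  st <- replica_state(sys, seed = 3, coords = conformation_at_cv(sys, 8))
  out <- propagate(st, sys,
                   restraints = list(umbrella_restraint(sys$cv_default, 8, 2)),
                   params = dynamics_params(n_steps = 3e5, seed = 3),
                   stride = 100)
  x <- out$frames$cv_A[-(1:200)]
  v_expect <- kB * 310 / (2 * 2)
  expect_equal(v_expect, 0.15401, tolerance = 1e-4)
  expect_lt(abs(var(x) - v_expect) / v_expect, 0.05)
})

test_that("Boltzmann sampling of a solute tether: effective spring is
           lambda k at reduced lambda", {
  beads <- data.frame(role = c("protein", "ligand"), solute = c(TRUE, FALSE),
                      mass = c(12, 12), frozen = c(FALSE, TRUE),
                      tether_x = c(5, NA), tether_y = c(5, NA),
                      tether_z = c(5, NA), tether_k = c(1, 0))
  sys <- system_model(beads, box = cbind(rep(0, 3), rep(10, 3)), kwall = 10,
                      reference_pose = rbind(c(5, 5, 5), c(1, 1, 1)),
                      preset = "custom")
  for (lam in c(1, 0.5)) {
    out <- propagate(replica_state(sys, seed = 13), sys,
                     scaling_params(310, 310 / lam),
                     params = dynamics_params(n_steps = 2e5, seed = 13),
                     stride = 200, cv = NULL, record_coords = TRUE)
    xs <- out$frame_coords[-(1:100), 1, 1] - 5
    ks <- suppressWarnings(
      stats::ks.test(xs, "pnorm", 0, sqrt(kB * 310 / (2 * lam * 1))))
    expect_gt(ks$p.value, 0.01, label = sprintf("lambda = %.1f", lam))
  }
})

test_that("free diffusion in the channel samples the box interior
           uniformly", {
  sys <- get_sys("flat_channel", overrides = list(box_x = 10))
  st <- replica_state(sys, seed = 21, coords = {
    x <- sys$reference_pose; x[3, ] <- c(5, 2, 2); x
  })
  out <- propagate(st, sys, params = dynamics_params(n_steps = 3e6,
                                                     gamma = 2, seed = 21),
                   stride = 600, cv = NULL, record_coords = TRUE)
  xs <- out$frame_coords[, 3, 1]
  xs <- xs[xs > 0 & xs < 10]   # condition on the interior
  ks <- suppressWarnings(stats::ks.test(xs, "punif", 0, 10))
  expect_gt(ks$p.value, 0.01)
})

test_that("coordinate/bead-count mismatches are rejected", {
  sys <- get_sys("pocket_small")
  expect_error(energy(sys, sys$reference_pose[-1, ]), "mismatch")
  expect_error(forces(sys, sys$reference_pose[, -1]), "mismatch")
})
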