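test_that("metropolis criterion: always accept non-positive delta, accept
           positive delta with probability exp(-delta)", {
  expect_true(metropolis(0, 0.999999))
  expect_true(metropolis(-8.1, 0.999))
  p <- exp(-5.8438)
  expect_equal(p, 0.00289, tolerance = 5e-3)
  expect_true(metropolis(5.8438, p * 0.99))
  expect_false(metropolis(5.8438, p * 1.01))
  expect_error(metropolis(1, 1), "\\[0, 1\\)")
})

test_that("grest_delta reproduces the hand-computed pure-solute case and is
           antisymmetric", {
  bi <- list(E_uu = 20, E_uv = 0)
  bj <- list(E_uu = 10, E_uv = 0)
  # E_m(x_i)=20, E_n(x_i)=10, E_m(x_j)=10, E_n(x_j)=5:
  # (10 + 10) - (20 + 5) = -5 kcal/mol; beta0 = 1/(kB 310)
  d <- grest_delta(bi, bj, lambda_m = 1, lambda_n = 0.5, T0 = 310)
  expect_equal(d, -5 / (0.0019872041 * 310), tolerance = 1e-10)
  expect_equal(d, -8.116, tolerance = 1e-3)
  expect_equal(grest_delta(bj, bi, 1, 0.5, T0 = 310), -d, tolerance = 1e-12)
  expect_equal(grest_delta(bi, bj, 0.7, 0.7), 0)
})

test_that("reus_delta reproduces the hand-computed window case", {
  cv <- cv_definition(1L, 2L)
  wm <- umbrella_window(5.0, 2, cv)
  wn <- umbrella_window(6.0, 2, cv)
  # (1.28 + 2.42) - (0.08 + 0.02) = 3.60 kcal/mol -> delta = 5.8438
  d <- reus_delta(5.2, 6.1, wm, wn, T0 = 310)
  expect_equal(d, 3.6 / (0.0019872041 * 310), tolerance = 1e-10)
  expect_equal(d, 5.8438, tolerance = 1e-4)
  expect_equal(reus_delta(4.4, 4.4, wm, wn), 0)
  # each replica sitting at its own center: any swap costs energy
  expect_gt(reus_delta(5.0, 6.0, wm, wn), 0)
  cv2 <- cv_definition(1L, 2L, name = "other")
  expect_error(reus_delta(5, 6, wm, umbrella_window(6, 2, cv2)),
               "CV mismatch")
})

test_that("the alternating schedule cycles gREST/REUS with period 4", {
  expect_equal(exchange_schedule(0), list(dimension = "gREST",
                                          parity = "even"))
  expect_equal(exchange_schedule(5), list(dimension = "REUS",
                                          parity = "even"))
  expect_equal(exchange_schedule(2)$parity, "odd")
  expect_equal(exchange_schedule(3), list(dimension = "REUS", parity = "odd"))
  # single-dimension runs alternate parity with period 2
  expect_equal(exchange_schedule(0, "gREST")$parity, "even")
  expect_equal(exchange_schedule(1, "gREST")$parity, "odd")
})

test_that("over 4 consecutive attempts every adjacent pair in both dimensions
           is attempted exactly once (M = 3, K = 4)", {
  sys <- get_sys("flat_channel")
  cvd <- sys$cv_default
  wins <- even_windows(cvd, 6, 12, K = 4, k = 2)
  grid <- replica_grid(sys, c(310, 400, 520), wins,
                       init_coords = lapply(wins, function(w) {
                         conformation_at_cv(sys, w$center)
                       }), seed = 3)
  res <- run_2d(grid, segment_ps = 0.2, n_attempts = 4)
  att <- res$log$attempts
  # gREST: pairs (1,2) and (2,3) at each of 4 windows = 8 attempts
  # REUS: pairs (1,2),(2,3),(3,4) at each of 3 temperatures = 9 attempts
  expect_equal(nrow(att), 17)
  key <- paste(att$dimension, att$pair_a, att$other_index)
  expect_false(anyDuplicated(key) > 0)
  expect_equal(sum(att$dimension == "gREST"), 8)
  expect_equal(sum(att$dimension == "REUS"), 9)
})

test_that("degenerate runs: zero attempts and 1x1 grids complete cleanly", {
  sys <- get_sys("flat_channel")
  w <- umbrella_window(8, 2, sys$cv_default)
  g0 <- replica_grid(sys, 310, list(w),
                     init_coords = conformation_at_cv(sys, 8), seed = 1)
  r0 <- run_2d(g0, segment_ps = 0.2, n_attempts = 0)
  expect_equal(nrow(r0$log$attempts), 0)
  r1 <- run_2d(g0, segment_ps = 0.2, n_attempts = 6)
  expect_equal(nrow(r1$log$attempts), 0)   # no pairs to attempt
  expect_equal(nrow(r1$log$snapshots), 7)  # initial + one per attempt phase
})

test_that("the replica -> (temperature, window) mapping stays a bijection at
           every snapshot", {
  sys <- get_sys("flat_channel")
  wins <- even_windows(sys$cv_default, 7, 10, K = 3, k = 2)
  grid <- replica_grid(sys, c(310, 420), wins,
                       init_coords = lapply(wins, function(w) {
                         conformation_at_cv(sys, w$center)
                       }), seed = 5)
  res <- run_2d(grid, segment_ps = 0.5, n_attempts = 40)
  snaps <- res$log$snapshots
  full <- sort(paste(rep(1:2, times = 3), rep(1:3, each = 2)))
  for (a in unique(snaps$attempt)) {
    s <- snaps[snaps$attempt == a, ]
    expect_identical(sort(paste(s$temp_index, s$window_index)), full)
  }
  # coordinates stay with replica identities across exchanges: the final
  # mapping is a permutation, not a copy
  expect_equal(sort(res$log$snapshots$replica[snaps$attempt == 40]), 1:6)
})

test_that("gREST exchanges on a zero-solute-energy system accept with
           probability exactly 1", {
  sys <- get_sys("flat_channel")
  grid <- replica_grid(sys, c(310, 500, 700),
                       list(umbrella_window(8, 2, sys$cv_default)),
                       init_coords = conformation_at_cv(sys, 8), seed = 2)
  res <- run_2d(grid, segment_ps = 0.5, n_attempts = 30, dims = "gREST")
  expect_true(all(res$log$attempts$delta == 0))
  expect_true(all(res$log$attempts$accepted))
})

test_that("acceptance ratios replay exactly from logged (delta, u) pairs", {
  sys <- get_sys("flat_channel")
  wins <- even_windows(sys$cv_default, 8, 10, K = 3, k = 2)
  grid <- replica_grid(sys, 310, wins,
                       init_coords = lapply(wins, function(w) {
                         conformation_at_cv(sys, w$center)
                       }), seed = 8)
  res <- run_2d(grid, segment_ps = 1, n_attempts = 120, dims = "REUS")
  expect_identical(acceptance_profile(res$log), replay_acceptance(res$log))
})

test_that("empirical REUS acceptance between overlapping flat-channel windows
           matches the closed-form double integral", {
  sys <- get_sys("flat_channel")
  cvd <- sys$cv_default
  k <- 2; cm <- 8; cn <- 8.8
  wins <- list(umbrella_window(cm, k, cvd), umbrella_window(cn, k, cvd))
  grid <- replica_grid(sys, 310, wins,
                       init_coords = list(conformation_at_cv(sys, cm),
                                          conformation_at_cv(sys, cn)),
                       seed = 31)
  res <- run_2d(grid, segment_ps = 2.1, n_attempts = 1200, equil_ps = 10,
                dims = "REUS")
  ap <- acceptance_profile(res$log)
  beta <- 1 / (kB * 310)
  s <- sqrt(kB * 310 / (2 * k))
  g <- seq(cm - 6 * s, cn + 6 * s, length.out = 301)
  f <- outer(g, g, function(xi, xj) {
    d <- beta * k * ((xi - cn)^2 + (xj - cm)^2 - (xi - cm)^2 - (xj - cn)^2)
    pmin(1, exp(-d)) * dnorm(xi, cm, s) * dnorm(xj, cn, s)
  })
  acc_th <- sum(f) * diff(g)[1]^2
  se <- sqrt(acc_th * (1 - acc_th) / ap$attempted)
  expect_lt(abs(ap$ratio - acc_th), 3 * se)
})
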