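# a hand-buildable exchange log
fake_log <- function(attempts, snapshots, M = 2, K = 2) {
  structure(list(attempts = attempts, snapshots = snapshots, M = M, K = K,
                 dims = c("gREST", "REUS"), segment_ps = 1, equil_ps = 0,
                 seed = 1L, T0 = 310, ladder = seq(310, by = 50,
                                                   length.out = M),
                 centers = seq(4, by = 1, length.out = K),
                 ks = rep(2, K), version = 1L),
            class = "exchange_log")
}

test_that("acceptance_profile counts attempted/accepted per pair and marks
           unattempted pairs as undefined", {
  att <- data.frame(attempt = 1:10, dimension = "gREST", parity = "even",
                    pair_a = 1L, pair_b = 2L, other_index = 1L,
                    replica_i = 1L, replica_j = 2L, delta = 0.5,
                    u = runif(10), accepted = c(rep(TRUE, 2), rep(FALSE, 8)))
  snaps <- data.frame(attempt = 0L, replica = 1:4,
                      temp_index = c(1L, 2L, 1L, 2L),
                      window_index = c(1L, 1L, 2L, 2L))
  log <- fake_log(att, snaps)
  ap <- acceptance_profile(log)
  g <- ap[ap$dimension == "gREST", ]
  expect_equal(g$ratio, 0.2)
  expect_equal(g$attempted, 10)
  r <- ap[ap$dimension == "REUS", ]
  expect_true(is.na(r$ratio))
  expect_equal(r$attempted, 0)
})

test_that("visitation matrices are row-normalized with entropy 0 for pinned
           and 1 for uniform replicas", {
  snaps <- rbind(
    data.frame(attempt = rep(0:3, each = 2), replica = rep(1:2, 4),
               temp_index = c(1L, 1L, 1L, 2L, 1L, 1L, 1L, 2L),
               window_index = 1L))
  log <- fake_log(data.frame(), snaps, M = 2, K = 1)
  v <- visitation(log)
  expect_equal(rowSums(v$grest$matrix), c(`1` = 1, `2` = 1))
  expect_equal(unname(v$grest$entropy[1]), 0)      # pinned at index 1
  expect_equal(unname(v$grest$entropy[2]), 1)      # 50/50 over 2 indices
  expect_equal(unname(v$grest$matrix[2, ]), c(0.5, 0.5))  # hand tally
})

test_that("round_trips counts completed ladder traversals", {
  mk <- function(idx) {
    data.frame(attempt = seq_along(idx) - 1L, replica = 1L,
               temp_index = 1L, window_index = as.integer(idx))
  }
  K <- 4
  log1 <- fake_log(data.frame(), mk(c(1, 2, 3, 4, 3, 2, 1)), M = 1, K = K)
  expect_equal(unname(round_trips(log1, "REUS")), 1L)
  log2 <- fake_log(data.frame(), mk(c(1, 2, 3, 4)), M = 1, K = K)
  expect_equal(unname(round_trips(log2, "REUS")), 0L)
  log3 <- fake_log(data.frame(), mk(c(2, 1, 4, 1, 4, 2, 1)), M = 1, K = K)
  expect_equal(unname(round_trips(log3, "REUS")), 2L)
})

test_that("round_trips agrees with an independent two-state automaton on
           stochastic walks", {
  automaton <- function(idx, n_idx) {
    trips <- 0L; stage <- 0L; origin <- NA_integer_
    for (v in idx) {
      at_end <- v == 1 || v == n_idx
      if (!at_end) next
      if (is.na(origin)) { origin <- v; next }
      if (stage == 0L && v != origin) stage <- 1L
      else if (stage == 1L && v == origin) { trips <- trips + 1L; stage <- 0L }
    }
    trips
  }
  set.seed(14)
  for (i in 1:50) {
    K <- sample(3:6, 1)
    idx <- pmin(pmax(cumsum(sample(c(-1L, 0L, 1L), 200, TRUE)) + 2L, 1L), K)
    log <- fake_log(data.frame(),
                    data.frame(attempt = seq_along(idx) - 1L, replica = 1L,
                               temp_index = 1L, window_index = idx),
                    M = 1, K = K)
    expect_identical(unname(round_trips(log, "REUS")), automaton(idx, K))
  }
})

test_that("hit_ratio: recounts at several cutoffs and stays monotone", {
  tab <- data.frame(initial_rmsd = c(2, 3, 1, 5),
                    min_rmsd = c(0.5, 1.2, 0.9, 3.0))
  expect_equal(hit_ratio(tab, cutoff = 1)$hit_pct, 50)
  expect_equal(hit_ratio(tab, cutoff = 0)$hit_pct, 0)     # strict inequality
  expect_equal(hit_ratio(tab, cutoff = 1.5)$hit_pct, 75)
  cuts <- seq(0, 4, by = 0.25)
  hr <- vapply(cuts, function(ct) hit_ratio(tab, ct)$hit_pct, numeric(1))
  expect_true(all(diff(hr) >= 0))
  series <- list(c(3, 0.4, 2), c(2, 1.8))
  r <- hit_ratio(series, 1)
  expect_equal(r$hit_pct, 50)
  expect_equal(r$table$initial_rmsd, c(3, 2))
  expect_equal(r$table$min_rmsd, c(0.4, 1.8))
  expect_error(hit_ratio(list()), "at least one replica")
})

test_that("reus_distribution_report: single window united equals its own
           histogram; flat-channel windows match the closed-form Gaussians", {
  sys <- get_sys("flat_channel")
  cvd <- sys$cv_default
  wins <- list(umbrella_window(8, 2, cvd), umbrella_window(9.2, 4, cvd))
  grid <- replica_grid(sys, 310, wins,
                       init_coords = list(conformation_at_cv(sys, 8),
                                          conformation_at_cv(sys, 9.2)),
                       seed = 17)
  res <- run_2d(grid, segment_ps = 2.1, n_attempts = 500, equil_ps = 10,
                dims = "REUS", stride = 30)
  rep <- reus_distribution_report(res$trajs, res$log)
  st <- rep$per_window_stats
  for (kk in 1:2) {
    mu <- st$center[kk]
    sg <- sqrt(kB * 310 / (2 * st$k[kk]))
    se_mean <- sg / sqrt(st$n[kk] / 4)   # conservative effective n
    expect_lt(abs(st$mean[kk] - mu), 3 * se_mean + 0.02)
    expect_lt(abs(st$sd[kk] - sg) / sg, 0.1)
  }
  one <- reus_distribution_report(res$trajs[res$trajs$window_index == 1, ],
                                  fake_log(data.frame(),
                                           data.frame(attempt = 0L,
                                                      replica = 1L,
                                                      temp_index = 1L,
                                                      window_index = 1L),
                                           M = 1, K = 1))
  expect_equal(one$united$prob, one$histograms[[1]]$prob)
})

test_that("every statistic is reproducible from the serialized log", {
  sys <- get_sys("flat_channel")
  wins <- even_windows(sys$cv_default, 8, 10, K = 3, k = 2)
  grid <- replica_grid(sys, c(310, 400), wins,
                       init_coords = lapply(wins, function(w) {
                         conformation_at_cv(sys, w$center)
                       }), seed = 19)
  res <- run_2d(grid, segment_ps = 1, n_attempts = 80)
  stem <- file.path(tempdir(), "diaglog")
  write_exchange_log(res$log, stem)
  log2 <- read_exchange_log(stem)
  expect_equal(acceptance_profile(log2), acceptance_profile(res$log))
  expect_identical(round_trips(log2, "REUS"), round_trips(res$log, "REUS"))
  v1 <- visitation(res$log); v2 <- visitation(log2)
  expect_equal(v1$reus$matrix, v2$reus$matrix)
})
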