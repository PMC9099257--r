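test_that("retarget_ladder is a fixed point when every pair already meets the
           target", {
  ladder <- c(310, 380, 470, 590)
  new <- retarget_ladder(ladder, rep(0.2, 3), 0.2)
  expect_equal(new, ladder, tolerance = 1e-5)
})

test_that("retarget_ladder halves the log-range when acceptances sit at
           target^2 on a geometric ladder", {
  # hand evaluation of the quantile construction: costs are uniform at
  # 2 (-log target), so the total-cost point sits at the old mid
  # temperature and the new mid lies at the half-cost point:
  # T2' = sqrt(310 * 441) = 369.76 K, T3' = 441.0 K exactly.
  ladder <- c(310, 441.0, 627.2)
  target <- 0.2
  new <- retarget_ladder(ladder, rep(target^2, 2), target)
  expect_equal(new[3], 441.0, tolerance = 1e-6)
  expect_equal(new[2], sqrt(310 * 441.0), tolerance = 1e-3)
  # log-range halved (exact for an exactly geometric ladder; 441.0 is the
  # printed 4-figure mid temperature, hence the 1e-3 tolerance)
  expect_equal(log(new[3] / new[1]) / log(627.2 / 310), 0.5,
               tolerance = 1e-3)
})

test_that("zero-acceptance pairs are floored and the result stays finite and
           monotone", {
  ladder <- c(310, 400, 500, 640)
  new <- retarget_ladder(ladder, c(0.2, 0, 0.3), 0.2, eps = 1e-3)
  expect_true(all(is.finite(new)))
  expect_false(is.unsorted(new, strictly = TRUE))
  expect_equal(new[1], 310)
})

test_that("retarget_ladder preserves the bottom temperature and strict
           monotonicity for random acceptance vectors", {
  set.seed(99)
  for (i in 1:200) {
    M <- sample(2:8, 1)
    ladder <- 310 * cumprod(c(1, runif(M - 1, 1.02, 1.6)))
    acc <- runif(M - 1, 0, 1)
    target <- runif(1, 0.05, 0.6)
    new <- retarget_ladder(ladder, acc, target)
    expect_identical(new[1], ladder[1])
    expect_length(new, M)
    expect_false(is.unsorted(new, strictly = TRUE))
  }
})

test_that("top-only mode moves just the top temperature", {
  ladder <- c(310, 400, 500)
  new <- retarget_ladder(ladder, c(0.05, 0.05), 0.2, move = "top")
  expect_identical(new[1:2], ladder[1:2])
  expect_lt(new[3], ladder[3])
})

test_that("idempotence at target on an analytic Gaussian-energy model", {
  # Gaussian-overlap toy: acceptance between adjacent rungs with equal
  # log-spacing w is erfc(alpha w).  Choose w* so the analytic acceptance
  # equals the target; feeding those acceptances back moves every
  # temperature by < 1%.
  target <- 0.2
  alpha <- 3.1
  wstar <- stats::uniroot(function(w) {
    2 * pnorm(-sqrt(2) * alpha * w) - target
  }, c(1e-4, 2))$root
  ladder <- 310 * exp(wstar * 0:4)
  acc <- rep(2 * pnorm(-sqrt(2) * alpha * wstar), 4)
  new <- retarget_ladder(ladder, acc, target)
  expect_true(all(abs(new - ladder) / ladder < 0.01))
})

test_that("tune_temperatures runs one round per state and averages the final
           ladders element-wise", {
  sys <- get_sys("double_well_1d")
  th <- tune_temperatures(sys, c(310, 400, 520), states = c(5, 12),
                          rounds = 1, target = 0.3, round_ps = 10,
                          equil_ps = 1, seed = 4)
  expect_equal(nrow(th$rounds), 2)
  expect_equal(th$states_used, c(5, 12))
  expect_equal(th$final_ladder, colMeans(th$per_state_final))
  expect_identical(th$final_ladder[1], 310)
})

test_that("overlap_coefficient: identical = 1, disjoint = 0, two equal-width
           Gaussians 2 sigma apart = 2 Phi(-1)", {
  br <- cv_breaks(0, 20, 0.02)
  a <- cv_histogram(rep(c(4, 5), 50), br)
  expect_equal(overlap_coefficient(a, a), 1)
  b <- cv_histogram(rep(c(14, 15), 50), br)
  expect_equal(overlap_coefficient(a, b), 0)
  mids <- (br[-1] + br[-length(br)]) / 2
  g1 <- list(breaks = br, prob = diff(pnorm(br, 8, 1)))
  g2 <- list(breaks = br, prob = diff(pnorm(br, 10, 1)))
  expect_equal(overlap_coefficient(g1, g2), 2 * pnorm(-1), tolerance = 1e-3)
  expect_equal(2 * pnorm(-1), 0.3173, tolerance = 1e-4)
  expect_error(overlap_coefficient(a, cv_histogram(1, cv_breaks(0, 5, 0.1))),
               "binning mismatch")
})

test_that("tune_windows proposes nothing when overlaps, acceptances and
           coverage are all healthy", {
  cv <- cv_definition(1L, 2L)
  wins <- lapply(c(4, 5, 6), umbrella_window, k = 2, cv = cv)
  set.seed(1)
  series <- lapply(c(4, 5, 6), function(c0) rnorm(4000, c0, 0.55))
  rep <- tune_windows(wins, series, acceptance = c(0.3, 0.3))
  expect_equal(nrow(rep$proposals), 0)
  expect_equal(length(rep$new_windows), 3)
  expect_equal(nrow(rep$flagged_gaps), 0)
})

test_that("a zero-density interval between windows 3 and 4 triggers exactly
           one midpoint insertion with escalated k = 3", {
  cv <- cv_definition(1L, 2L)
  centers <- c(3, 4, 5, 8, 9)
  wins <- lapply(centers, umbrella_window, k = 2, cv = cv)
  set.seed(2)
  series <- lapply(centers, function(c0) rnorm(4000, c0, 0.45))
  # pairs all healthy by acceptance; the 5 -> 8 stretch has a density hole
  rep <- tune_windows(wins, series, acceptance = c(0.3, 0.3, 0.25, 0.3))
  expect_equal(nrow(rep$proposals), 1)
  expect_equal(rep$proposals$center, (5 + 8) / 2)
  expect_equal(rep$proposals$k, 3)
  expect_equal(length(rep$new_windows), 6)
})

test_that("tune_windows never removes windows and only raises force
           constants", {
  cv <- cv_definition(1L, 2L)
  set.seed(3)
  for (i in 1:20) {
    K <- sample(3:8, 1)
    centers <- sort(3 + cumsum(runif(K, 0.5, 2.5)))
    ks <- sample(c(2, 3), K, replace = TRUE)
    wins <- Map(umbrella_window, centers, ks, MoreArgs = list(cv = cv))
    series <- lapply(centers, function(c0) rnorm(500, c0, runif(1, 0.2, 0.8)))
    acc <- runif(K - 1, 0, 0.5)
    rep <- tune_windows(wins, series, acc)
    expect_gte(length(rep$new_windows), K)
    new_centers <- vapply(rep$new_windows, `[[`, numeric(1), "center")
    new_ks <- vapply(rep$new_windows, `[[`, numeric(1), "k")
    expect_true(all(centers %in% new_centers))
    for (j in seq_len(K)) {
      expect_gte(new_ks[match(centers[j], new_centers)], ks[j])
    }
  }
})

test_that("tune_windows rejects empty trial data", {
  cv <- cv_definition(1L, 2L)
  wins <- lapply(c(4, 5), umbrella_window, k = 2, cv = cv)
  expect_error(tune_windows(wins, list(numeric(0), numeric(0)), 0.3),
               "empty trial data")
})

test_that("multi-round temperature tuning converges on the seeded pocket
           system (changes shrink by the late rounds)", {
  th <- get_tuning_history()
  chg <- function(r1, r2) {
    max(vapply(unique(th$rounds$state), function(s) {
      rr <- th$rounds[th$rounds$state == s, ]
      max(abs(rr$new_ladder[[r2]] - rr$new_ladder[[r1]]) / rr$new_ladder[[r1]])
    }, numeric(1)))
  }
  expect_lt(chg(4, 5), 0.3)
  expect_lt(chg(4, 5), chg(1, 2) / 3)
})
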