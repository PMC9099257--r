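#' Default geometric solute-temperature ladder
#'
#' @param M replica count.
#' @param T0 bottom (thermostat) temperature, K.
#' @param top initial top solute temperature, K.
#' @return strictly increasing ladder of length M.
#' @export
geometric_ladder <- function(M = 6L, T0 = 310, top = 663) {
  T0 * (top / T0)^(seq(0, 1, length.out = M))
}

#' Evenly spaced umbrella windows at uniform force constant
#'
#' @param cv a [cv_definition()].
#' @param cv_min,cv_max span, Angstrom.
#' @param K window count.
#' @param k uniform force constant, kcal/mol/A^2.
#' @return list of [umbrella_window()]s.
#' @export
even_windows <- function(cv, cv_min, cv_max, K = 8L, k = 2) {
  lapply(equidistant_targets(cv_min, cv_max, K), umbrella_window, k = k,
         cv = cv)
}

#' Run the full protocol on a configuration
#'
#' Stages, in protocol order: build the system and verify the bound pose;
#' dual-direction pulling for initial window structures; solute-temperature
#' tuning at bound/intermediate/unbound states; one round of umbrella-window
#' tuning from a 1D-REUS trial; the 2D gREST/REUS production run; and the
#' efficiency analysis.  Each stage's artifact is written under
#' `cfg$output$directory` when set.
#'
#' @param cfg a `run_config` (see [read_run_config()]) or a list with the
#'   same shape.
#' @param stages subset of stages to run (later stages require earlier ones).
#' @param progress print stage banners.
#' @return list with the artifacts of every executed stage: `sys`,
#'   `pose_check`, `pulls`, `tuning`, `window_report`, `run`, `report`.
#' @export
run_pipeline <- function(cfg, stages = c("build", "pull", "tune-temps",
                                         "tune-windows", "run2d", "analyze"),
                         progress = FALSE) {
  say <- function(...) if (progress) message(sprintf(...))
  out_dir <- cfg$output$directory
  save_to <- function(fn, name, ...) {
    if (!is.null(out_dir)) {
      dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
      fn(..., file.path(out_dir, name))
    }
  }
  res <- list()
  seed <- as.integer(cfg$seed)

  say("[build] preset %s", cfg$system$preset)
  sys <- build_system(cfg$system$preset, seed = seed,
                      overrides = if (length(cfg$system$overrides)) {
                        cfg$system$overrides
                      } else list())
  res$sys <- sys
  res$pose_check <- verify_bound_pose(sys)
  save_to(function(s, p) write_system_yaml(s, p), "system.yaml", sys)
  if (!"pull" %in% stages) return(res)

  cvdef <- sys$cv_default
  span <- sys$cv_range
  targets <- equidistant_targets(span[1], span[2], cfg$windows$K)
  say("[pull] %d targets over %.1f-%.1f A", length(targets), span[1], span[2])
  pulls <- dual_pull(sys, targets, k_pull = cfg$pulling$k_pull,
                     step_ps = cfg$pulling$step_ps,
                     protein_restraint_k = cfg$pulling$protein_restraint_k,
                     seed = seed, cv = cvdef)
  res$pulls <- pulls
  if (!is.null(out_dir)) {
    write_xyz(pulls$forward$conformations, sys,
              file.path(out_dir, "pull_forward.xyz"),
              comment = sprintf("target %.3f A", targets))
  }
  if (!"tune-temps" %in% stages) return(res)

  ladder0 <- geometric_ladder(cfg$ladder$M, cfg$ladder$T0, cfg$ladder$top)
  states <- c(span[1], mean(span), span[2])
  say("[tune-temps] M=%d rounds=%d target=%.2f", cfg$ladder$M,
      cfg$tuning$rounds, cfg$ladder$target)
  tuning <- tune_temperatures(sys, ladder0, states,
                              rounds = cfg$tuning$rounds,
                              target = cfg$ladder$target,
                              window_k = cfg$windows$k,
                              round_ps = cfg$tuning$round_ps,
                              seed = seed, T0 = cfg$ladder$T0)
  res$tuning <- tuning
  save_to(function(x, p) write_report_json(x, p), "tuning_history.json",
          tuning)
  if (!"tune-windows" %in% stages) return(res)

  win0 <- even_windows(cvdef, span[1], span[2], cfg$windows$K,
                       cfg$windows$k)
  init <- pulls$forward$conformations
  say("[tune-windows] trial with K=%d", length(win0))
  trial <- reus_trial(sys, win0, n_attempts = cfg$run$n_attempts,
                      segment_ps = cfg$run$segment_ps,
                      equil_ps = cfg$run$equil_ps, init_coords = init,
                      seed = seed + 17L, T0 = cfg$ladder$T0)
  wrep <- tune_windows(win0, trial$cv_series, trial$acceptance)
  res$window_report <- wrep
  save_to(function(x, p) write_report_json(x, p), "window_tuning.json",
          list(overlaps = wrep$overlaps, acceptance = wrep$acceptance,
               proposals = wrep$proposals, flagged_gaps = wrep$flagged_gaps))
  if (!"run2d" %in% stages) return(res)

  windows <- wrep$new_windows
  centers <- vapply(windows, `[[`, numeric(1), "center")
  init2 <- lapply(centers, function(cc) {
    pulls$forward$conformations[[which.min(abs(pulls$manifest$target - cc))]]
  })
  say("[run2d] M=%d K=%d attempts=%d", length(tuning$final_ladder),
      length(windows), cfg$run$n_attempts)
  grid <- replica_grid(sys, tuning$final_ladder, windows,
                       init_coords = init2, seed = seed + 23L,
                       T0 = cfg$ladder$T0)
  run <- run_2d(grid, segment_ps = cfg$run$segment_ps,
                n_attempts = cfg$run$n_attempts,
                equil_ps = cfg$run$equil_ps,
                stride = cfg$run$stride, record_coords = TRUE)
  res$run <- run
  if (!is.null(out_dir)) {
    write_exchange_log(run$log, file.path(out_dir, "run2d"))
    write_trajectory_tsv(run$trajs, file.path(out_dir, "run2d_frames.tsv"))
  }
  if (!"analyze" %in% stages) return(res)

  say("[analyze]")
  res$report <- efficiency_report(run, sys)
  save_to(function(x, p) write_report_json(x, p), "efficiency.json",
          list(acceptance = res$report$acceptance,
               round_trips = res$report$round_trips,
               hit_pct = if (!is.null(res$report$hits)) {
                 res$report$hits$hit_pct
               } else NA_real_))
  res
}
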