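#' Construct a bead-model system
#'
#' Low-level constructor for a coarse-grained protein-ligand system.  Most
#' users should call [build_system()] with a named preset instead.
#'
#' A system is a set of beads (protein or ligand) with optional harmonic
#' tethers (E = k d^2), bonded terms (bonds, angles, dihedrals), nonbonded
#' pair terms (attractive Gaussian well -eps exp(-r^2 / 2 w^2) plus a smooth
#' soft-core repulsion A (sigma^2 / (r^2 + sigma^2))^6, finite at r = 0), and
#' a cuboid box with half-harmonic reflecting walls.  Beads marked `frozen`
#' are excluded from the dynamics (fixed reference sites, as in fixed-atom MD
#' setups).  Beads marked `solute` participate in solute tempering: energy
#' terms whose beads are all solute are "uu" terms (scaled by lambda), terms
#' with no solute bead are "vv", mixed terms are "uv" (scaled by
#' sqrt(lambda)).  Box walls always count as "vv" (they model the container).
#'
#' @param beads data.frame with columns `role` ("protein"/"ligand"), `solute`
#'   (logical), `mass` (amu), `frozen` (logical), `tether_x/y/z` (Angstrom, NA
#'   if untethered), `tether_k` (kcal/mol/A^2, 0 if untethered).
#' @param bonds data.frame `i, j, k, r0` (may be empty).
#' @param angles data.frame `i, j, k, ka, theta0` (theta0 in rad).
#' @param dihedrals data.frame `i, j, k, l, kd, mult, phase`.
#' @param pairs data.frame `i, j, eps, width, A, sigma`.
#' @param box 3 x 2 matrix of per-dimension (lo, hi) wall planes, Angstrom.
#' @param kwall wall force constant, kcal/mol/A^2.
#' @param reference_pose n x 3 matrix, the designed bound conformation.
#' @param cv_default a [cv_definition()] suggested for this system.
#' @param anchor_candidates list of integer vectors: candidate anchor sets.
#' @param cv_range length-2 numeric: the designed bound-to-unbound CV span.
#' @param preset,seed,overrides provenance metadata.
#' @return An object of class `system_model`.
#' @export
system_model <- function(beads, bonds = NULL, angles = NULL, dihedrals = NULL,
                         pairs = NULL, box, kwall = 10, reference_pose,
                         cv_default = NULL, anchor_candidates = list(),
                         cv_range = c(3, 10), preset = "custom", seed = 1L,
                         overrides = list()) {
  empty <- function(cols) {
    df <- as.data.frame(setNames(rep(list(numeric(0)), length(cols)), cols))
    df
  }
  if (is.null(bonds)) bonds <- empty(c("i", "j", "k", "r0"))
  if (is.null(angles)) angles <- empty(c("i", "j", "k", "ka", "theta0"))
  if (is.null(dihedrals)) {
    dihedrals <- empty(c("i", "j", "k", "l", "kd", "mult", "phase"))
  }
  if (is.null(pairs)) pairs <- empty(c("i", "j", "eps", "width", "A", "sigma"))
  sys <- structure(list(
    beads = beads, bonds = bonds, angles = angles, dihedrals = dihedrals,
    pairs = pairs, box = box, kwall = kwall,
    reference_pose = as.matrix(reference_pose), cv_default = cv_default,
    anchor_candidates = anchor_candidates, cv_range = cv_range,
    preset = preset, seed = as.integer(seed), overrides = overrides,
    version = 1L
  ), class = "system_model")
  validate_system(sys)
  sys
}

#' Validate a system_model's invariants
#'
#' Checks index validity, positive masses, non-negative tether constants,
#' that ligand beads carry no tether, that no nonbonded pair is duplicated,
#' and that the reference pose has one row per bead.
#'
#' @param sys a `system_model`.
#' @return `sys`, invisibly; errors on violation.
#' @export
validate_system <- function(sys) {
  b <- sys$beads
  n <- nrow(b)
  stopifnot(all(b$role %in% c("protein", "ligand")))
  if (any(b$mass <= 0)) stop("bead masses must be positive")
  if (any(b$tether_k < 0)) stop("tether_k must be >= 0")
  if (any(b$tether_k > 0 & b$role == "ligand")) {
    stop("ligand beads must not be tethered")
  }
  idx <- c(sys$bonds$i, sys$bonds$j, sys$angles$i, sys$angles$j, sys$angles$k,
           sys$dihedrals$i, sys$dihedrals$j, sys$dihedrals$k, sys$dihedrals$l,
           sys$pairs$i, sys$pairs$j)
  if (length(idx) && (any(idx < 1) || any(idx > n))) {
    stop("term refers to an invalid bead index")
  }
  if (nrow(sys$pairs)) {
    key <- paste(pmin(sys$pairs$i, sys$pairs$j), pmax(sys$pairs$i, sys$pairs$j))
    if (anyDuplicated(key)) stop("duplicated nonbonded pair term")
  }
  if (nrow(sys$reference_pose) != n || ncol(sys$reference_pose) != 3) {
    stop("reference_pose must have one 3-vector per bead")
  }
  if (!all(dim(sys$box) == c(3, 2)) || any(sys$box[, 2] < sys$box[, 1])) {
    stop("box must be a 3 x 2 (lo, hi) matrix with hi >= lo")
  }
  invisible(sys)
}

# gREST term class from the solute flags of the participating beads:
# 0 = uu (all solute), 1 = uv (mixed), 2 = vv (none)
.term_class <- function(solute_flags) {
  if (all(solute_flags)) 0L else if (!any(solute_flags)) 2L else 1L
}

# Pack a system_model into the flat 0-based representation the C++ engine
# consumes; the result is cached on the object's environment-free attribute.
.compile_system <- function(sys) {
  cached <- attr(sys, ".compiled", exact = TRUE)
  if (!is.null(cached)) return(cached)
  b <- sys$beads
  sol <- b$solute
  mk <- function(df, idx_cols, cls_of) {
    if (!nrow(df)) return(matrix(numeric(0), 0, length(df) + 1))
    m <- as.matrix(df)
    cls <- vapply(seq_len(nrow(df)), function(r) {
      .term_class(sol[unlist(df[r, idx_cols])])
    }, integer(1))
    m[, idx_cols] <- m[, idx_cols] - 1
    cbind(m, cls = cls)
  }
  teth_rows <- which(b$tether_k > 0)
  tethers <- if (length(teth_rows)) {
    cbind(teth_rows - 1,
          b$tether_x[teth_rows], b$tether_y[teth_rows], b$tether_z[teth_rows],
          b$tether_k[teth_rows],
          vapply(teth_rows, function(i) .term_class(sol[i]), integer(1)))
  } else matrix(numeric(0), 0, 6)
  list(
    mass = b$mass,
    frozen = as.integer(b$frozen),
    tethers = tethers,
    bonds = mk(sys$bonds, c("i", "j"), sol),
    angles = mk(sys$angles, c("i", "j", "k"), sol),
    dihedrals = mk(sys$dihedrals, c("i", "j", "k", "l"), sol),
    pairs = mk(sys$pairs, c("i", "j"), sol),
    box = sys$box,
    kwall = sys$kwall
  )
}

# attach the compiled cache (returns modified copy)
.with_compiled <- function(sys) {
  if (is.null(attr(sys, ".compiled", exact = TRUE))) {
    attr(sys, ".compiled") <- .compile_system(sys)
  }
  sys
}

.bead_df <- function(role, solute, mass, frozen, tether, tether_k) {
  data.frame(
    role = role, solute = solute, mass = mass, frozen = frozen,
    tether_x = tether[, 1], tether_y = tether[, 2], tether_z = tether[, 3],
    tether_k = tether_k, stringsAsFactors = FALSE
  )
}

.preset_defaults <- list(
  pocket_small = list(
    well_eps = 1.0, well_width = 2, trap_eps = 0.9, rep_A = 2, rep_sigma = 1.5,
    tether_k = 1, kwall = 10, box_len = 26, protein_mass = 100,
    ligand_mass = 30
  ),
  pocket_flexible = list(
    well_eps = 1.0, well_width = 2, trap_eps = 0.9, rep_A = 2, rep_sigma = 1.5,
    tether_k = 1, kwall = 10, box_len = 26, protein_mass = 100,
    ligand_mass = 14, bond_k = 100, bond_r0 = 1.5, angle_k = 10,
    angle_theta0 = 2 * pi / 3, dihedral_k = 1, dihedral_mult = 3
  ),
  flat_channel = list(
    box_x = 40, ligand_mass = 10, kwall = 10, ligand_x = 8
  ),
  double_well_1d = list(
    eps1 = 2.5, eps2 = 1.2, well_width = 1.5, site2_x = 12, box_x = 20,
    ligand_mass = 10, kwall = 10
  )
)

.override_ranges <- list(
  well_eps = c(0.1, 20), well_width = c(0.5, 6), trap_eps = c(0, 10),
  rep_A = c(0, 50), rep_sigma = c(0.5, 5), tether_k = c(0.01, 100),
  kwall = c(0.5, 1000), box_len = c(15, 200), protein_mass = c(1, 1e4),
  ligand_mass = c(1, 1e4), bond_k = c(1, 1e3), bond_r0 = c(0.5, 5),
  angle_k = c(0.1, 1e3), angle_theta0 = c(0.5, pi), dihedral_k = c(0, 50),
  dihedral_mult = c(1, 6), box_x = c(5, 500), ligand_x = c(1, 490),
  eps1 = c(0.1, 20), eps2 = c(0, 20), site2_x = c(3, 490)
)

.apply_overrides <- function(preset, overrides) {
  p <- .preset_defaults[[preset]]
  for (nm in names(overrides)) {
    if (!nm %in% names(p)) {
      stop(sprintf("unknown override '%s' for preset '%s'", nm, preset))
    }
    rng <- .override_ranges[[nm]]
    v <- overrides[[nm]]
    if (!is.numeric(v) || length(v) != 1 || v < rng[1] || v > rng[2]) {
      stop(sprintf("override '%s' = %s outside documented range [%g, %g]",
                   nm, format(v), rng[1], rng[2]))
    }
    p[[nm]] <- v
  }
  p
}

# ring of 4 beads of radius r around the x axis at (x, c, c)
.ring4 <- function(x, r, c0) {
  rbind(c(x, c0 + r, c0), c(x, c0 - r, c0), c(x, c0, c0 + r), c(x, c0, c0 - r))
}

.build_pocket <- function(preset, p, seed) {
  c0 <- 13
  prot_xyz <- rbind(
    c(3, c0 - 1, c0), c(3, c0 + 1, c0),   # anchor/base pair (back wall)
    .ring4(5, 2, c0),                      # ring A (binding-site, solute)
    .ring4(7, 2, c0),                      # ring B (binding-site, solute)
    c(12, c0 - 3, c0)                      # off-axis intermediate trap site
  )
  np <- nrow(prot_xyz)
  flexible <- identical(preset, "pocket_flexible")
  if (flexible) {
    # 4-bead zig-zag chain entering the pocket head-first
    dx <- p$bond_r0 * sin(p$angle_theta0 / 2) * 2 / 2  # planar zig-zag step
    dy <- p$bond_r0 * cos(p$angle_theta0 / 2)
    lig_xyz <- rbind(
      c(6, c0, c0), c(6 + dx, c0 + dy, c0),
      c(6 + 2 * dx, c0, c0), c(6 + 3 * dx, c0 + dy, c0)
    )
  } else {
    lig_xyz <- matrix(c(6, c0, c0), 1, 3)
  }
  nl <- nrow(lig_xyz)
  beads <- .bead_df(
    role = c(rep("protein", np), rep("ligand", nl)),
    solute = c(FALSE, FALSE, rep(TRUE, 8), FALSE, rep(TRUE, nl)),
    mass = c(rep(p$protein_mass, np), rep(p$ligand_mass, nl)),
    frozen = FALSE,
    tether = rbind(prot_xyz, matrix(NA_real_, nl, 3)),
    tether_k = c(rep(p$tether_k, np), rep(0, nl))
  )
  ring_ids <- 3:10
  trap_id <- 11L
  lig_ids <- np + seq_len(nl)
  head_id <- lig_ids[1]
  # attractive wells: pocket rings to the ligand head (and half-strength to
  # the second bead of a flexible ligand); trap site to the head bead
  pr <- data.frame(i = integer(0), j = integer(0), eps = numeric(0),
                   width = numeric(0), A = numeric(0), sigma = numeric(0))
  add_pair <- function(df, i, j, eps, width, A, sigma) {
    rbind(df, data.frame(i = i, j = j, eps = eps, width = width, A = A,
                         sigma = sigma))
  }
  for (r in ring_ids) {
    pr <- add_pair(pr, r, head_id, p$well_eps, p$well_width, p$rep_A,
                   p$rep_sigma)
    if (flexible) {
      pr <- add_pair(pr, r, lig_ids[2], p$well_eps / 2, p$well_width, p$rep_A,
                     p$rep_sigma)
    }
  }
  pr <- add_pair(pr, trap_id, head_id, p$trap_eps, p$well_width, p$rep_A,
                 p$rep_sigma)
  # soft-core repulsion for the remaining protein-ligand combinations
  for (i in seq_len(np)) {
    for (j in lig_ids) {
      key_have <- any(pr$i == i & pr$j == j)
      if (!key_have) {
        pr <- add_pair(pr, i, j, 0, 1, p$rep_A, p$rep_sigma)
      }
    }
  }
  bonds <- angles <- dihedrals <- NULL
  if (flexible) {
    bonds <- data.frame(i = lig_ids[1:3], j = lig_ids[2:4], k = p$bond_k,
                        r0 = p$bond_r0)
    angles <- data.frame(i = lig_ids[1:2], j = lig_ids[2:3], k = lig_ids[3:4],
                         ka = p$angle_k, theta0 = p$angle_theta0)
    dihedrals <- data.frame(i = lig_ids[1], j = lig_ids[2], k = lig_ids[3],
                            l = lig_ids[4], kd = p$dihedral_k,
                            mult = p$dihedral_mult, phase = 0)
  }
  box <- cbind(rep(0, 3), rep(p$box_len, 3))
  cv <- cv_definition(anchor_beads = c(1L, 2L), ligand_beads = lig_ids,
                      name = "base2-ligall")
  system_model(
    beads = beads, bonds = bonds, angles = angles, dihedrals = dihedrals,
    pairs = pr, box = box, kwall = p$kwall,
    reference_pose = rbind(prot_xyz, lig_xyz), cv_default = cv,
    anchor_candidates = list(base2 = c(1L, 2L), ringA4 = 3:6,
                             rings8 = 3:10),
    cv_range = c(3, 12), preset = preset, seed = seed
  )
}

.build_flat_channel <- function(p, seed) {
  prot_xyz <- rbind(c(0, 1.5, 2), c(0, 2.5, 2))
  lig_xyz <- matrix(c(p$ligand_x, 2, 2), 1, 3)
  beads <- .bead_df(
    role = c("protein", "protein", "ligand"),
    solute = c(FALSE, FALSE, TRUE),
    mass = c(100, 100, p$ligand_mass),
    frozen = c(TRUE, TRUE, FALSE),
    tether = matrix(NA_real_, 3, 3), tether_k = c(0, 0, 0)
  )
  box <- rbind(c(0, p$box_x), c(2, 2), c(2, 2))
  cv <- cv_definition(anchor_beads = c(1L, 2L), ligand_beads = 3L,
                      name = "channel")
  system_model(
    beads = beads, box = box, kwall = p$kwall,
    reference_pose = rbind(prot_xyz, lig_xyz), cv_default = cv,
    anchor_candidates = list(base2 = c(1L, 2L)),
    cv_range = c(3, p$box_x - 5), preset = "flat_channel", seed = seed
  )
}

.build_double_well <- function(p, seed) {
  prot_xyz <- rbind(c(0, 1.5, 2), c(0, 2.5, 2), c(5, 2, 2),
                    c(p$site2_x, 2, 2))
  lig_xyz <- matrix(c(5, 2, 2), 1, 3)
  beads <- .bead_df(
    role = c(rep("protein", 4), "ligand"),
    solute = c(FALSE, FALSE, FALSE, FALSE, TRUE),
    mass = c(100, 100, 100, 100, p$ligand_mass),
    frozen = c(TRUE, TRUE, TRUE, TRUE, FALSE),
    tether = matrix(NA_real_, 5, 3), tether_k = rep(0, 5)
  )
  pr <- data.frame(i = c(3L, 4L), j = c(5L, 5L), eps = c(p$eps1, p$eps2),
                   width = p$well_width, A = 0, sigma = 1)
  box <- rbind(c(0, p$box_x), c(2, 2), c(2, 2))
  cv <- cv_definition(anchor_beads = c(1L, 2L), ligand_beads = 5L,
                      name = "channel")
  system_model(
    beads = beads, pairs = pr, box = box, kwall = p$kwall,
    reference_pose = rbind(prot_xyz, lig_xyz), cv_default = cv,
    anchor_candidates = list(base2 = c(1L, 2L)),
    cv_range = c(3, p$box_x - 4), preset = "double_well_1d", seed = seed
  )
}

#' Build a synthetic bead-model binding system from a named preset
#'
#' Presets:
#' \describe{
#'   \item{`pocket_small`}{11 tethered protein beads forming a binding pocket
#'     (two anchor/base beads, two 4-bead binding-site rings flagged as gREST
#'     solute, one off-axis intermediate trap site) plus a single-bead ligand.
#'     The bound minimum sits near CV = 3 Angstrom from the base-bead anchor
#'     COM; the intermediate trap basin lies near CV = 9, and interactions are
#'     negligible beyond CV = 11-12 (so `cv_range` spans 3-12 Angstrom, the
#'     designed bound-to-unbound range), while the box admits CV values above
#'     20 Angstrom.}
#'   \item{`pocket_flexible`}{the same pocket with a 4-bead bonded ligand
#'     chain (bonds, angles, one dihedral), emulating a larger flexible
#'     inhibitor whose tail can reorient at fixed CV.}
#'   \item{`flat_channel`}{an exactly solvable oracle: one free ligand bead in
#'     a long channel with frozen anchor beads, zero interaction terms, and
#'     a degenerate (lo = hi) box in y and z so the CV is effectively the x
#'     coordinate.  The interior potential is identically zero.}
#'   \item{`double_well_1d`}{a 1D two-state oracle: two frozen attractor
#'     sites of unequal depth along the channel.}
#' }
#'
#' Pocket presets run a built-in local minimization (L-BFGS-B on the unscaled
#' potential with analytic gradients) so that `reference_pose` is a genuine
#' stationary point; see [verify_bound_pose()].
#'
#' Construction is fully deterministic given `(preset, overrides, seed)`; the
#' seed is carried as provenance for downstream runs.
#'
#' @param preset one of `"pocket_small"`, `"pocket_flexible"`,
#'   `"flat_channel"`, `"double_well_1d"`.
#' @param seed integer seed recorded in the model.
#' @param overrides named list of numeric parameter overrides; unknown names
#'   or out-of-range values are errors.
#' @return A `system_model`.
#' @export
build_system <- function(preset = c("pocket_small", "pocket_flexible",
                                    "flat_channel", "double_well_1d"),
                         seed = 1L, overrides = list()) {
  if (!is.character(preset) || !preset[1] %in% names(.preset_defaults)) {
    stop(sprintf("unknown preset name '%s'", preset[1]))
  }
  preset <- preset[1]
  p <- .apply_overrides(preset, overrides)
  sys <- switch(preset,
    pocket_small = .build_pocket(preset, p, seed),
    pocket_flexible = .build_pocket(preset, p, seed),
    flat_channel = .build_flat_channel(p, seed),
    double_well_1d = .build_double_well(p, seed)
  )
  sys$overrides <- overrides
  if (preset != "flat_channel") sys <- minimize_pose(sys)
  sys
}

#' Relax the reference pose to the nearest local minimum
#'
#' Runs L-BFGS-B on the unscaled potential (lambda = 1, no restraints) over
#' all non-frozen beads, starting from the current `reference_pose`, and
#' stores the minimized coordinates back into the model.
#'
#' @param sys a `system_model`.
#' @param maxit iteration cap.
#' @return The system with an updated `reference_pose`.
#' @export
minimize_pose <- function(sys, maxit = 2000L) {
  free <- !sys$beads$frozen
  x0 <- as.vector(t(sys$reference_pose[free, , drop = FALSE]))
  full <- sys$reference_pose
  csys <- .compile_system(sys)
  fn <- function(x) {
    full[free, ] <- matrix(x, ncol = 3, byrow = TRUE)
    .energy_cpp(full, csys, 1, list(), FALSE)$total_unscaled
  }
  gr <- function(x) {
    full[free, ] <- matrix(x, ncol = 3, byrow = TRUE)
    -as.vector(t(.energy_cpp(full, csys, 1, list(), TRUE)$forces[free, ,
                                                                 drop = FALSE]))
  }
  fit <- optim(x0, fn, gr, method = "L-BFGS-B",
               control = list(maxit = maxit, factr = 10, pgtol = 1e-8))
  full[free, ] <- matrix(fit$par, ncol = 3, byrow = TRUE)
  sys$reference_pose <- full
  attr(sys, ".compiled") <- NULL
  sys
}

#' Check that the reference pose is a stationary point of the potential
#'
#' Computes the analytic gradient of the unscaled potential (lambda = 1, no
#' restraints) at `reference_pose` over the non-frozen beads and the CV value
#' at the pose.
#'
#' @param sys a `system_model`.
#' @param tol_force pass threshold on the gradient Euclidean norm,
#'   kcal/mol/A.
#' @return list with `gradient_norm`, `cv_at_pose`, `pass`.
#' @export
verify_bound_pose <- function(sys, tol_force = 1e-3) {
  csys <- .compile_system(sys)
  res <- .energy_cpp(sys$reference_pose, csys, 1, list(), TRUE)
  free <- !sys$beads$frozen
  gnorm <- sqrt(sum(res$forces[free, , drop = FALSE]^2))
  cvv <- if (!is.null(sys$cv_default)) {
    com_distance(sys$reference_pose, sys$cv_default, sys$beads$mass)
  } else NA_real_
  list(gradient_norm = gnorm, cv_at_pose = cvv, pass = gnorm <= tol_force)
}

#' Scan the unscaled potential along the CV by rigid ligand translation
#'
#' Translates all ligand beads rigidly along the anchor-to-ligand COM
#' direction of the reference pose and evaluates the unscaled potential at
#' each displaced CV value.  Used to verify the designed binding funnel
#' (bound minimum location, barrier to the unbound plateau).
#'
#' @param sys a `system_model`.
#' @param cv_values CV values (Angstrom) at which to evaluate.
#' @param cv the CV definition (defaults to the preset's).
#' @return data.frame with `cv` and `energy` (kcal/mol).
#' @export
scan_cv_profile <- function(sys, cv_values, cv = sys$cv_default) {
  csys <- .compile_system(sys)
  m <- sys$beads$mass
  pose <- sys$reference_pose
  ra <- .com(pose, cv$anchor_beads, m)
  rl <- .com(pose, cv$ligand_beads, m)
  u <- (rl - ra) / sqrt(sum((rl - ra)^2))
  cv0 <- com_distance(pose, cv, m)
  vapply(cv_values, function(v) {
    x <- pose
    shift <- (v - cv0) * u
    x[cv$ligand_beads, ] <- sweep(x[cv$ligand_beads, , drop = FALSE], 2,
                                  shift, "+")
    .energy_cpp(x, csys, 1, list(), FALSE)$total_unscaled
  }, numeric(1)) -> e
  data.frame(cv = cv_values, energy = e)
}

#' Displace the ligand rigidly to a target CV value
#'
#' Deterministic helper used to seed tuning runs at chosen window centers:
#' translates the ligand beads along the reference anchor-to-ligand axis so
#' the COM-distance CV equals `target`.
#'
#' @param sys a `system_model`.
#' @param target desired CV value, Angstrom.
#' @param cv the CV definition (defaults to the preset's).
#' @param coords starting conformation (defaults to the reference pose).
#' @return an n x 3 coordinate matrix.
#' @export
conformation_at_cv <- function(sys, target, cv = sys$cv_default,
                               coords = sys$reference_pose) {
  m <- sys$beads$mass
  ra <- .com(coords, cv$anchor_beads, m)
  rl <- .com(coords, cv$ligand_beads, m)
  d <- sqrt(sum((rl - ra)^2))
  u <- if (d > 1e-9) (rl - ra) / d else c(1, 0, 0)
  x <- coords
  x[cv$ligand_beads, ] <- sweep(x[cv$ligand_beads, , drop = FALSE], 2,
                                (target - d) * u, "+")
  x
}
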