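#' Define a multi-anchor COM-distance collective variable
#'
#' The CV is the Euclidean distance between the mass-weighted centers of mass
#' of a protein anchor-bead group and a ligand-bead subset.  Multiple anchor
#' sites and multi-bead ligand selections reduce the number of ligand
#' conformations compatible with a given CV value, which is what
#' [score_cv_candidates()] quantifies.
#'
#' @param anchor_beads integer ids of protein anchor beads.
#' @param ligand_beads integer ids of ligand beads used for the ligand COM.
#' @param name label, e.g. `"2site-allheavy"`.
#' @return list of class `cv_definition`.
#' @export
cv_definition <- function(anchor_beads, ligand_beads, name = "cv") {
  if (!length(anchor_beads) || !length(ligand_beads)) {
    stop("anchor and ligand selections must be nonempty")
  }
  structure(list(anchor_beads = as.integer(anchor_beads),
                 ligand_beads = as.integer(ligand_beads), name = name),
            class = "cv_definition")
}

#' Validate a CV definition against a system
#'
#' @param sys a `system_model`.
#' @param cv a [cv_definition()].
#' @return `cv`, invisibly; errors if a selection is empty, out of range, or
#'   crosses bead roles.
#' @export
validate_cv <- function(sys, cv) {
  n <- nrow(sys$beads)
  if (any(cv$anchor_beads < 1 | cv$anchor_beads > n) ||
      any(cv$ligand_beads < 1 | cv$ligand_beads > n)) {
    stop("CV selection out of range")
  }
  if (!all(sys$beads$role[cv$anchor_beads] == "protein")) {
    stop("anchor beads must be protein beads")
  }
  if (!all(sys$beads$role[cv$ligand_beads] == "ligand")) {
    stop("ligand selection must contain only ligand beads")
  }
  invisible(cv)
}

.com <- function(coords, ids, masses) {
  w <- masses[ids] / sum(masses[ids])
  colSums(coords[ids, , drop = FALSE] * w)
}

#' Mass-weighted COM distance
#'
#' @param coords n x 3 coordinates.
#' @param cv a [cv_definition()].
#' @param masses bead masses, amu.
#' @return distance in Angstrom.
#' @export
com_distance <- function(coords, cv, masses) {
  if (!length(cv$anchor_beads) || !length(cv$ligand_beads)) {
    stop("empty selection")
  }
  sqrt(sum((.com(coords, cv$anchor_beads, masses) -
            .com(coords, cv$ligand_beads, masses))^2))
}

#' Reference pose for ligand RMSD
#'
#' @param coordinates n x 3 reference coordinates (the bound pose).
#' @param fit_beads protein bead ids used for superposition.
#' @param rmsd_beads ligand bead ids over which the RMSD is taken.
#' @return list of class `pose_reference`.
#' @export
pose_reference <- function(coordinates, fit_beads, rmsd_beads) {
  if (!length(fit_beads) || !length(rmsd_beads)) stop("empty selections")
  if (length(intersect(fit_beads, rmsd_beads))) {
    stop("fit and rmsd selections must be disjoint")
  }
  structure(list(coordinates = as.matrix(coordinates),
                 fit_beads = as.integer(fit_beads),
                 rmsd_beads = as.integer(rmsd_beads)),
            class = "pose_reference")
}

# Mass-weighted Kabsch superposition: returns P mapped onto Q using the
# rotation/translation that minimizes the weighted RMSD over the given rows.
.kabsch_apply <- function(P, Q, fit_rows, w) {
  wf <- w[fit_rows] / sum(w[fit_rows])
  cp <- colSums(P[fit_rows, , drop = FALSE] * wf)
  cq <- colSums(Q[fit_rows, , drop = FALSE] * wf)
  Pc <- sweep(P[fit_rows, , drop = FALSE], 2, cp)
  Qc <- sweep(Q[fit_rows, , drop = FALSE], 2, cq)
  H <- t(Pc * wf) %*% Qc
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  if (d == 0) d <- 1
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  sweep(sweep(P, 2, cp) %*% t(R), 2, cq, "+")
}

.check_fit_beads <- function(coords, fit_beads) {
  if (length(fit_beads) < 3) stop("need at least 3 non-collinear fit beads")
  X <- coords[fit_beads, , drop = FALSE]
  Xc <- sweep(X, 2, colMeans(X))
  sv <- svd(Xc)$d
  if (sv[2] < 1e-8) stop("need at least 3 non-collinear fit beads")
}

#' Ligand RMSD to a bound pose after protein-frame superposition
#'
#' Rigid-body (mass-weighted Kabsch) superposition of `coords` onto the
#' reference over `fit_beads`, followed by the root-mean-square deviation
#' over `rmsd_beads` without further fitting: the standard bound-pose RMSD.
#'
#' @param coords n x 3 coordinates.
#' @param ref a [pose_reference()].
#' @param masses bead masses (used as superposition weights).
#' @return RMSD in Angstrom.
#' @export
ligand_rmsd <- function(coords, ref, masses) {
  .check_fit_beads(ref$coordinates, ref$fit_beads)
  fitted <- .kabsch_apply(as.matrix(coords), ref$coordinates, ref$fit_beads,
                          masses)
  d <- fitted[ref$rmsd_beads, , drop = FALSE] -
    ref$coordinates[ref$rmsd_beads, , drop = FALSE]
  sqrt(mean(rowSums(d^2)))
}

#' RMSF of the anchor-site COM over a trajectory
#'
#' Each frame is superposed (mass-weighted Kabsch) on all protein beads onto
#' the reference structure; the root-mean-square fluctuation of the
#' anchor-bead COM is then taken relative to its position in the reference:
#' RMSF = sqrt(mean ||com_t - com_ref||^2).
#'
#' @param traj_coords array frames x beads x 3, or a list of n x 3 matrices.
#' @param anchor_beads integer anchor bead ids.
#' @param reference n x 3 reference coordinates.
#' @param masses bead masses.
#' @param protein_beads protein bead ids used for superposition.
#' @return RMSF in Angstrom.
#' @export
anchor_com_rmsf <- function(traj_coords, anchor_beads, reference, masses,
                            protein_beads) {
  frames <- .as_frame_list(traj_coords)
  if (!length(frames)) stop("empty trajectory")
  if (length(frames) < 2) stop("need at least 2 frames")
  ref <- as.matrix(reference)
  .check_fit_beads(ref, protein_beads)
  com_ref <- .com(ref, anchor_beads, masses)
  dev2 <- vapply(frames, function(X) {
    fitted <- .kabsch_apply(X, ref, protein_beads, masses)
    sum((.com(fitted, anchor_beads, masses) - com_ref)^2)
  }, numeric(1))
  sqrt(mean(dev2))
}

.as_frame_list <- function(traj_coords) {
  if (is.list(traj_coords)) return(lapply(traj_coords, as.matrix))
  if (is.array(traj_coords) && length(dim(traj_coords)) == 3) {
    return(lapply(seq_len(dim(traj_coords)[1]),
                  function(f) traj_coords[f, , ]))
  }
  stop("trajectory must be a list of matrices or a frames x beads x 3 array")
}

#' Score candidate CV definitions on trial trajectories
#'
#' For each candidate CV, computes over all trial replicas: (a) the
#' conditional spread of the ligand RMSD given the CV (mean interquartile
#' range of RMSD over CV bins of width `bin_width`); (b) the bound-pose
#' probability (percentage of replicas whose RMSD drops below `hit_cutoff` at
#' least once); (c) the anchor-COM RMSF.  A good CV gives a narrow, nearly
#' linear RMSD-vs-CV relation and a stable anchor site.  Candidates are
#' ranked by hit percentage (descending), ties broken by conditional spread
#' (ascending).
#'
#' @param trial_trajs list of per-replica coordinate trajectories (each an
#'   array frames x beads x 3 or list of matrices).
#' @param candidates list of [cv_definition()]s.
#' @param ref a [pose_reference()].
#' @param sys the `system_model` (for masses and protein selection).
#' @param bin_width CV bin width for the conditional spread, Angstrom.
#' @param hit_cutoff bound-pose RMSD cutoff, Angstrom.
#' @return data.frame of class `cv_score_report`: one row per candidate with
#'   `name`, `cond_spread_A`, `hit_pct`, `anchor_rmsf_A`, `rank`, ordered by
#'   rank.
#' @export
score_cv_candidates <- function(trial_trajs, candidates, ref, sys,
                                bin_width = 1, hit_cutoff = 1) {
  if (!length(trial_trajs)) stop("no replicas provided")
  masses <- sys$beads$mass
  protein_beads <- which(sys$beads$role == "protein")
  frames_by_rep <- lapply(trial_trajs, .as_frame_list)
  rows <- lapply(candidates, function(cand) {
    cvv <- numeric(0); rmsd <- numeric(0); hits <- logical(0)
    for (fr in frames_by_rep) {
      r <- vapply(fr, ligand_rmsd, numeric(1), ref = ref, masses = masses)
      v <- vapply(fr, com_distance, numeric(1), cv = cand, masses = masses)
      cvv <- c(cvv, v); rmsd <- c(rmsd, r)
      hits <- c(hits, any(r < hit_cutoff))
    }
    bins <- floor(cvv / bin_width)
    iqrs <- tapply(rmsd, bins, function(x) {
      if (length(x) < 4) NA_real_ else unname(diff(quantile(x, c(0.25, 0.75))))
    })
    rmsf <- mean(vapply(frames_by_rep, function(fr) {
      anchor_com_rmsf(fr, cand$anchor_beads, ref$coordinates, masses,
                      protein_beads)
    }, numeric(1)))
    data.frame(name = cand$name,
               cond_spread_A = mean(iqrs, na.rm = TRUE),
               hit_pct = 100 * mean(hits),
               anchor_rmsf_A = rmsf, stringsAsFactors = FALSE)
  })
  rep_df <- do.call(rbind, rows)
  ord <- order(-rep_df$hit_pct, rep_df$cond_spread_A)
  rep_df <- rep_df[ord, , drop = FALSE]
  rep_df$rank <- seq_len(nrow(rep_df))
  rownames(rep_df) <- NULL
  class(rep_df) <- c("cv_score_report", "data.frame")
  rep_df
}
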