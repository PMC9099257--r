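#' Write a system model to a YAML file
#'
#' The format is a versioned key-value document (`format: grestreus-system`,
#' `format_version: 1`); [read_system_yaml()] refuses files with a different
#' version.
#'
#' @param sys a `system_model`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_system_yaml <- function(sys, path) {
  doc <- list(
    format = "grestreus-system", format_version = 1L,
    preset = sys$preset, seed = sys$seed, overrides = sys$overrides,
    kwall = sys$kwall, cv_range = sys$cv_range,
    box = list(lo = unname(sys$box[, 1]), hi = unname(sys$box[, 2])),
    beads = lapply(seq_len(nrow(sys$beads)), function(i) {
      b <- sys$beads[i, ]
      out <- list(role = b$role, solute = b$solute, mass = b$mass,
                  frozen = b$frozen)
      if (b$tether_k > 0) {
        out$tether_point <- c(b$tether_x, b$tether_y, b$tether_z)
        out$tether_k <- b$tether_k
      }
      out
    }),
    bonds = unname(apply(sys$bonds, 1, as.list)),
    angles = unname(apply(sys$angles, 1, as.list)),
    dihedrals = unname(apply(sys$dihedrals, 1, as.list)),
    pairs = unname(apply(sys$pairs, 1, as.list)),
    reference_pose = unname(apply(sys$reference_pose, 1, function(r) {
      as.list(unname(r))
    })),
    cv_default = if (!is.null(sys$cv_default)) {
      list(anchor_beads = sys$cv_default$anchor_beads,
           ligand_beads = sys$cv_default$ligand_beads,
           name = sys$cv_default$name)
    },
    anchor_candidates = sys$anchor_candidates
  )
  yaml::write_yaml(doc, path, precision = 17L)
  invisible(path)
}

#' Read a system model from a YAML file written by [write_system_yaml()]
#'
#' @param path input file path.
#' @return a `system_model`.
#' @export
read_system_yaml <- function(path) {
  doc <- yaml::read_yaml(path)
  if (!identical(doc$format, "grestreus-system")) {
    stop("not a grestreus system file")
  }
  if (!identical(as.integer(doc$format_version), 1L)) {
    stop(sprintf("unsupported system format version %s", doc$format_version))
  }
  nb <- length(doc$beads)
  tether <- matrix(NA_real_, nb, 3)
  tk <- numeric(nb)
  for (i in seq_len(nb)) {
    if (!is.null(doc$beads[[i]]$tether_k)) {
      tether[i, ] <- unlist(doc$beads[[i]]$tether_point)
      tk[i] <- doc$beads[[i]]$tether_k
    }
  }
  beads <- .bead_df(
    role = vapply(doc$beads, `[[`, character(1), "role"),
    solute = vapply(doc$beads, `[[`, logical(1), "solute"),
    mass = vapply(doc$beads, `[[`, numeric(1), "mass"),
    frozen = vapply(doc$beads, `[[`, logical(1), "frozen"),
    tether = tether, tether_k = tk)
  df_of <- function(lst, cols) {
    if (!length(lst)) return(NULL)
    out <- as.data.frame(do.call(rbind, lapply(lst, function(r) {
      unlist(r)[cols]
    })))
    names(out) <- cols
    out
  }
  pose <- do.call(rbind, lapply(doc$reference_pose, unlist))
  cvd <- if (!is.null(doc$cv_default)) {
    cv_definition(unlist(doc$cv_default$anchor_beads),
                  unlist(doc$cv_default$ligand_beads), doc$cv_default$name)
  }
  sys <- system_model(
    beads = beads,
    bonds = df_of(doc$bonds, c("i", "j", "k", "r0")),
    angles = df_of(doc$angles, c("i", "j", "k", "ka", "theta0")),
    dihedrals = df_of(doc$dihedrals, c("i", "j", "k", "l", "kd", "mult",
                                       "phase")),
    pairs = df_of(doc$pairs, c("i", "j", "eps", "width", "A", "sigma")),
    box = cbind(unlist(doc$box$lo), unlist(doc$box$hi)), kwall = doc$kwall,
    reference_pose = pose, cv_default = cvd,
    anchor_candidates = lapply(doc$anchor_candidates, as.integer),
    cv_range = unlist(doc$cv_range), preset = doc$preset, seed = doc$seed,
    overrides = if (length(doc$overrides)) doc$overrides else list())
  sys
}

#' Write coordinates as an XYZ file
#'
#' Standard XYZ: atom count, comment, then `element x y z` lines (Angstrom).
#' Protein beads are written as carbon, ligand beads as nitrogen, so viewers
#' color the two roles differently.
#'
#' @param coords n x 3 matrix or list of matrices (multi-frame XYZ).
#' @param sys the `system_model` (for roles).
#' @param path output file path.
#' @param comment per-frame comment string(s).
#' @return `path`, invisibly.
#' @export
write_xyz <- function(coords, sys, path, comment = "grestreus frame") {
  frames <- if (is.list(coords)) coords else list(coords)
  if (length(comment) == 1) comment <- rep(comment, length(frames))
  elem <- ifelse(sys$beads$role == "protein", "C", "N")
  con <- file(path, "w")
  on.exit(close(con))
  for (f in seq_along(frames)) {
    X <- frames[[f]]
    writeLines(as.character(nrow(X)), con)
    writeLines(comment[f], con)
    writeLines(sprintf("%s %.6f %.6f %.6f", elem, X[, 1], X[, 2], X[, 3]),
               con)
  }
  invisible(path)
}

#' Read an XYZ file written by [write_xyz()]
#'
#' @param path input file path.
#' @return list of n x 3 coordinate matrices (one per frame).
#' @export
read_xyz <- function(path) {
  lines <- readLines(path)
  frames <- list()
  i <- 1
  while (i <= length(lines)) {
    n <- suppressWarnings(as.integer(lines[i]))
    if (is.na(n)) stop("malformed XYZ: expected atom count at line ", i)
    if (i + 1 + n > length(lines)) {
      stop("truncated XYZ file: frame starting at line ", i)
    }
    body <- lines[(i + 2):(i + 1 + n)]
    xyz <- do.call(rbind, lapply(strsplit(body, "\\s+"), function(p) {
      as.numeric(p[2:4])
    }))
    frames[[length(frames) + 1L]] <- xyz
    i <- i + 2 + n
  }
  frames
}

#' Write coordinates as a minimal PDB file
#'
#' 1-based atom serials, Angstrom; protein beads as CA/PRO, ligand beads as
#' N1/LIG (HETATM).
#'
#' @param coords n x 3 matrix.
#' @param sys the `system_model`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(coords, sys, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(coords))) {
    prot <- sys$beads$role[i] == "protein"
    writeLines(sprintf(
      "%-6s%5d %-4s %-3s %s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f",
      if (prot) "ATOM" else "HETATM", i, if (prot) "CA" else "N1",
      if (prot) "PRO" else "LIG", if (prot) "A" else "B", i,
      coords[i, 1], coords[i, 2], coords[i, 3], 1.0, 0.0), con)
  }
  writeLines("END", con)
  invisible(path)
}

.tsv_header <- function(kind) {
  c(sprintf("#! grestreus %s", kind), "#! format_version 1")
}

.check_tsv_header <- function(lines, kind, path) {
  if (length(lines) < 2 || !identical(lines[1], sprintf("#! grestreus %s", kind))) {
    stop(sprintf("'%s' is not a grestreus %s file", path, kind))
  }
  if (!identical(lines[2], "#! format_version 1")) {
    stop(sprintf("unsupported %s format version in '%s'", kind, path))
  }
}

#' Write a trajectory frame table as versioned TSV
#'
#' Columns: step, time_ps, cv_A, E_uu, E_uv, E_vv, E_restraint,
#' total_unscaled, scaled_total (plus any extra tag columns present).  A
#' `#! frames N` header allows [read_trajectory_tsv()] to detect truncation.
#'
#' @param frames frame data.frame (from [propagate()] or [run_2d()]).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_trajectory_tsv <- function(frames, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(.tsv_header("trajectory"),
               sprintf("#! frames %d", nrow(frames))), con)
  write.table(frames, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a trajectory TSV written by [write_trajectory_tsv()]
#'
#' @param path input file path.
#' @return the frame data.frame; errors on version mismatch or truncation
#'   (reporting the last good frame index).
#' @export
read_trajectory_tsv <- function(path) {
  lines <- readLines(path)
  .check_tsv_header(lines, "trajectory", path)
  n_declared <- as.integer(sub("#! frames ", "", lines[3], fixed = TRUE))
  body <- lines[-(1:3)]
  df <- read.table(text = body, header = TRUE, sep = "\t")
  if (nrow(df) != n_declared) {
    stop(sprintf(
      "truncated trajectory file '%s': declared %d frames, last good frame %d",
      path, n_declared, nrow(df)))
  }
  df
}

#' Write an exchange log as two versioned TSV streams
#'
#' `<stem>_attempts.tsv` holds one row per exchange attempt (attempt,
#' dimension, parity, pair, other-dimension index, replicas, delta, u,
#' accepted); `<stem>_snapshots.tsv` holds the replica -> (temp_index,
#' window_index) mapping after every attempt.  Grid metadata (M, K, ladder,
#' window centers and force constants, seed) rides in header lines so a
#' reader can reconstruct both per-replica walks and per-parameter
#' occupancies.
#'
#' @param log an `exchange_log`.
#' @param stem output path stem (without suffix).
#' @return character vector of the two paths, invisibly.
#' @export
write_exchange_log <- function(log, stem) {
  meta <- c(
    sprintf("#! M %d", log$M), sprintf("#! K %d", log$K),
    sprintf("#! dims %s", paste(log$dims, collapse = ",")),
    sprintf("#! segment_ps %.17g", log$segment_ps),
    sprintf("#! equil_ps %.17g", log$equil_ps),
    sprintf("#! seed %d", log$seed), sprintf("#! T0 %.17g", log$T0),
    sprintf("#! ladder %s", paste(sprintf("%.17g", log$ladder),
                                  collapse = ",")),
    sprintf("#! centers %s", paste(sprintf("%.17g", log$centers),
                                   collapse = ",")),
    sprintf("#! ks %s", paste(sprintf("%.17g", log$ks), collapse = ",")))
  pa <- paste0(stem, "_attempts.tsv")
  ps <- paste0(stem, "_snapshots.tsv")
  con <- file(pa, "w")
  writeLines(c(.tsv_header("exchange-attempts"), meta,
               sprintf("#! rows %d", nrow(log$attempts))), con)
  write.table(format(log$attempts, digits = 17, scientific = FALSE,
                     trim = TRUE),
              con, sep = "\t", quote = FALSE, row.names = FALSE)
  close(con)
  con <- file(ps, "w")
  writeLines(c(.tsv_header("exchange-snapshots"), meta,
               sprintf("#! rows %d", nrow(log$snapshots))), con)
  write.table(log$snapshots, con, sep = "\t", quote = FALSE,
              row.names = FALSE)
  close(con)
  invisible(c(pa, ps))
}

.parse_meta <- function(lines) {
  kv <- list()
  for (ln in grep("^#! ", lines, value = TRUE)) {
    parts <- strsplit(sub("^#! ", "", ln), " ", fixed = TRUE)[[1]]
    kv[[parts[1]]] <- paste(parts[-1], collapse = " ")
  }
  kv
}

#' Read an exchange log written by [write_exchange_log()]
#'
#' @param stem path stem used at write time.
#' @return an `exchange_log`.
#' @export
read_exchange_log <- function(stem) {
  pa <- paste0(stem, "_attempts.tsv")
  ps <- paste0(stem, "_snapshots.tsv")
  la <- readLines(pa)
  ls_ <- readLines(ps)
  .check_tsv_header(la, "exchange-attempts", pa)
  .check_tsv_header(ls_, "exchange-snapshots", ps)
  meta <- .parse_meta(la)
  read_body <- function(lines, path) {
    hdr <- grep("^#! ", lines)
    n_declared <- as.integer(meta_of(lines, "rows"))
    body <- lines[-hdr]
    df <- read.table(text = body, header = TRUE, sep = "\t")
    if (nrow(df) != n_declared) {
      stop(sprintf("truncated file '%s': declared %d rows, last good row %d",
                   path, n_declared, nrow(df)))
    }
    df
  }
  meta_of <- function(lines, key) {
    .parse_meta(lines)[[key]]
  }
  att <- read_body(la, pa)
  att$accepted <- as.logical(att$accepted)
  snaps <- read_body(ls_, ps)
  num_list <- function(key) as.numeric(strsplit(meta[[key]], ",")[[1]])
  structure(list(
    attempts = att, snapshots = snaps,
    M = as.integer(meta$M), K = as.integer(meta$K),
    dims = strsplit(meta$dims, ",")[[1]],
    segment_ps = as.numeric(meta$segment_ps),
    equil_ps = as.numeric(meta$equil_ps), seed = as.integer(meta$seed),
    T0 = as.numeric(meta$T0), ladder = num_list("ladder"),
    centers = num_list("centers"), ks = num_list("ks"), version = 1L),
    class = "exchange_log")
}

#' Write a report object as JSON
#'
#' Serializes tuning histories, window-tuning reports, efficiency reports and
#' other list-like results with a format/version envelope.
#'
#' @param x report object (list-like).
#' @param path output file path.
#' @param kind format tag recorded in the envelope.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(x, path, kind = class(x)[1]) {
  env <- list(format = paste0("grestreus-", kind), format_version = 1L,
              payload = .jsonable(x))
  jsonlite::write_json(env, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

.jsonable <- function(x) {
  if (is.data.frame(x)) return(x)
  if (is.list(x)) return(lapply(unclass(x), .jsonable))
  if (is.matrix(x)) return(unclass(x))
  x
}

#' Read a JSON report written by [write_report_json()]
#'
#' @param path input file path.
#' @return the payload list.
#' @export
read_report_json <- function(path) {
  env <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(env$format) || !startsWith(env$format, "grestreus-")) {
    stop("not a grestreus report file")
  }
  if (!identical(as.integer(env$format_version), 1L)) {
    stop("unsupported report format version")
  }
  env$payload
}

#' Read and validate a run configuration
#'
#' YAML schema (all blocks optional unless stated):
#' \preformatted{
#' system:    preset (required), seed, overrides: {...}
#' cv:        candidates: [{name, anchor_beads, ligand_beads}, ...]
#' ladder:    M, T0, top, target
#' windows:   K, cv_min, cv_max, k
#' pulling:   k_pull, step_ps, protein_restraint_k
#' run:       equil_ps, segment_ps, n_attempts, stride
#' tuning:    rounds, round_ps, states
#' seed:      master seed (required)
#' output:    directory
#' }
#' Numeric sanity checks name the offending key on failure.
#'
#' @param path YAML config path.
#' @return validated config list of class `run_config`.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  fail <- function(key, why) stop(sprintf("config error at '%s': %s", key, why))
  if (is.null(cfg$system$preset)) fail("system.preset", "missing")
  if (!cfg$system$preset %in% names(.preset_defaults)) {
    fail("system.preset", "unknown preset")
  }
  if (is.null(cfg$seed)) fail("seed", "missing (explicit seeds are required)")
  defaults <- list(
    ladder = list(M = 6L, T0 = 310, top = 663, target = 0.2),
    windows = list(K = 8L, k = 2),
    pulling = list(k_pull = 4, step_ps = 30, protein_restraint_k = 1),
    run = list(equil_ps = 10, segment_ps = 2.1, n_attempts = 200L,
               stride = 0L),
    tuning = list(rounds = 5L, round_ps = 120))
  for (blk in names(defaults)) {
    for (key in names(defaults[[blk]])) {
      if (is.null(cfg[[blk]][[key]])) cfg[[blk]][[key]] <- defaults[[blk]][[key]]
    }
  }
  chk_pos <- function(blk, key) {
    v <- cfg[[blk]][[key]]
    if (!is.numeric(v) || length(v) != 1 || v <= 0) {
      fail(paste(blk, key, sep = "."), "must be a positive number")
    }
  }
  for (k in c("M", "T0", "top", "target")) chk_pos("ladder", k)
  if (cfg$ladder$target >= 1) fail("ladder.target", "must be below 1")
  if (cfg$ladder$top <= cfg$ladder$T0) fail("ladder.top", "must exceed T0")
  for (k in c("K", "k")) chk_pos("windows", k)
  for (k in c("k_pull", "step_ps")) chk_pos("pulling", k)
  if (cfg$pulling$protein_restraint_k < 0) {
    fail("pulling.protein_restraint_k", "must be >= 0")
  }
  for (k in c("segment_ps")) chk_pos("run", k)
  if (cfg$run$n_attempts < 0) fail("run.n_attempts", "must be >= 0")
  if (cfg$run$equil_ps < 0) fail("run.equil_ps", "must be >= 0")
  if (cfg$tuning$rounds < 1) fail("tuning.rounds", "must be >= 1")
  structure(cfg, class = "run_config")
}
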