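# grestreus file formats (version 1)

All artifacts are plain text and carry an explicit format tag and version so
readers can refuse files they do not understand.  Units everywhere: Angstrom,
kcal/mol, ps, K, amu.  Harmonic energies use the E = k x^2 convention.

## System model (`*.yaml`)

YAML document with `format: grestreus-system`, `format_version: 1`.  Keys:

- `preset`, `seed`, `overrides`: provenance of the generator call.
- `box`: `{lo: [x,y,z], hi: [x,y,z]}` wall planes; `kwall`: wall constant.
- `beads`: list of `{role: protein|ligand, solute: bool, mass, frozen: bool,
  tether_point: [x,y,z], tether_k}` (tether keys absent when untethered).
- `bonds` (`i j k r0`), `angles` (`i j k ka theta0`), `dihedrals`
  (`i j k l kd mult phase`), `pairs` (`i j eps width A sigma`): 1-based bead
  indices; pair energy is `-eps exp(-r^2/(2 width^2)) +
  A (sigma^2/(r^2+sigma^2))^6`.
- `reference_pose`: list of `[x, y, z]` rows, one per bead.
- `cv_default`, `anchor_candidates`, `cv_range`: CV metadata.

Writer: `write_system_yaml()`; reader: `read_system_yaml()` (round-trip
equality of all numeric content; errors on unknown `format_version`).

## Coordinates

- XYZ (`write_xyz()`/`read_xyz()`): standard multi-frame XYZ, Angstrom;
  protein beads as `C`, ligand beads as `N`.  Truncated frames are an error
  reporting the offending line.
- PDB (`write_pdb()`): minimal ATOM/HETATM records, 1-based serials,
  Angstrom; for visualization only.

## Trajectory table (`*.tsv`)

Header lines:

    #! grestreus trajectory
    #! format_version 1
    #! frames N

then a tab-separated table with columns `step, time_ps, cv_A, E_uu, E_uv,
E_vv, E_restraint, total_unscaled, scaled_total` plus optional tag columns
(`replica`, `temp_index`, `window_index`).  `read_trajectory_tsv()` errors on
a row count different from the declared `frames` (reporting the last good
frame index).

## Exchange log (`<stem>_attempts.tsv`, `<stem>_snapshots.tsv`)

Both files share header metadata (`M`, `K`, `dims`, `segment_ps`, `equil_ps`,
`seed`, `T0`, `ladder`, `centers`, `ks`, `rows`).

- Attempts: one row per exchange attempt: `attempt, dimension
  (gREST|REUS), parity (even|odd), pair_a, pair_b, other_index, replica_i,
  replica_j, delta, u, accepted`.  Replaying `metropolis(delta, u)`
  reproduces `accepted` exactly.
- Snapshots: replica -> (temp_index, window_index) mapping after every
  attempt (attempt 0 is the initial mapping).  Each snapshot is a bijection
  onto the M x K grid.

Writer: `write_exchange_log()`; reader: `read_exchange_log()` (truncation
detected against the declared row count).

## Reports (`*.json`)

`write_report_json()` wraps any report (tuning history, window-tuning
report, efficiency report, CV scores) as

    {"format": "grestreus-<kind>", "format_version": 1, "payload": ...}

with full double precision (`digits = NA`).

## Run configuration (`*.yaml`)

See `read_run_config()`; unknown presets, missing `seed`, or non-positive
numeric fields are rejected with the offending key named in the error.
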