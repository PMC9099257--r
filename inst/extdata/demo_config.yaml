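# Demo configuration for the grestreus CLI: a scaled-down full protocol run
# on the single-bead pocket system.  See read_run_config() for the schema.
system:
  preset: pocket_small
seed: 21
ladder:
  M: 4
  T0: 310
  top: 663
  target: 0.2
windows:
  K: 8
  k: 2
pulling:
  k_pull: 4
  step_ps: 30
  protein_restraint_k: 1
run:
  equil_ps: 10
  segment_ps: 2.1
  n_attempts: 400
  stride: 0
tuning:
  rounds: 3
output:
  directory: grestreus_demo_out
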