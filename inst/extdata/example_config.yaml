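# Example run configuration for the cgresin pipeline (desk-scale sizes).
# Stages: pack -> minimize -> equilibrate -> polymerize -> sweep -> analyze
formulation:
  w_bisgma: 0.5
  mass_basis: 90          # TEGDMA-equivalents; 1000 reproduces the study boxes
packing:
  n_active: 4
  target_density: 0.8     # g/cm^3 initial guess; NPT sets the real density
ensemble:
  temperature: 298
  pressure: 1
  timestep_fs: 10         # 20 fs is the study value; 10 fs is gentler for
  tau_t: 0.2              # Bis-GMA-containing desk-scale boxes (see vignette)
  tau_p: 3
equilibration:
  n_steps: 4000
schedule:
  bonding_cutoff_A: 5.5
  bonds_per_relaxation: 10
  relax_steps: 400
  retry_steps: 200
  max_failed_attempts: 8
sweep:
  T_start: 150
  T_end: 500
  n_steps: 4800
  n_windows: 12
run:
  seed: 1
  outdir: cgresin-run
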