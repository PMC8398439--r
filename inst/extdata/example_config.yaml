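# Example Transwell dissolution run: 23 ug of a synthetic dry-powder
# formulation (lognormal APSD, MMAD 3.7 um, GSD 1.8, discretized onto NGI
# stage cut-offs; see synthetic_formulation_stages.csv) dissolving in
# 0.5% Tween 80 at the small-volume bench setup.
run:
  initial_amount: 23        # ug deposited in the donor at t = 0
  donor_volume: 0.58        # mL
  receptor_volume: 1.5      # mL (hydrostatically matched pair)
  correction_factor: 0.0244 # calibrated Nernst-Brunner correction F
  stage_table: synthetic_formulation_stages.csv
drug:
  permeability: 0.289          # cm/h across the stirred PC membrane
  diffusion_coefficient: 0.022284  # cm^2/h
  density: 1.37                # g/cm^3
  shape_factor: 1
medium:
  solubility: 5.3           # ug/mL
  label: "0.5% Tween 80"
schedule:
  times: [10, 20, 30, 45, 60, 90, 120, 180, 240, 360, 480, 720, 1440]
  sample_volume: 0.5        # mL withdrawn and replaced at each timepoint
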