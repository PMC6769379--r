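# Demonstration pipeline configuration: every stage runs on synthetic
# inputs with known ground truth, at desk scale.
seed: 7
outdir: kgate_out
stages:
  binding:
    kd_mM: 8          # generator dissociation constant
    concentration_M: 1
    k_off: 1          # 1/us
    duration_us: 10
    dt_us: 0.001
    n_monomers: 6
    n_boot: 200
  pathflux:
    rates: demo       # relay-biased demonstration network
    source: apo
    sink: K1
    n_paths: 2
  alchemy:
    dg: 19.7          # kJ/mol
    sigma: 4
    n: 250
    n_boot: 500
  gating:
    p_closed: 0.59
    n_windows: 44
    force_constant: 1000   # kJ/mol/nm^2
    n_per_window: 2000
    n_boot: 30
  charge:
    q_p0: 2           # e0
    C0: 0.5           # e0/mV
    noise_sd: 0.05
    n_replicates: 5
    n_boot: 300
  mst:
    kd_mM: 30
    n_curves: 5
    noise_sd: 0.01
    n_boot: 1000
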