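# Default run configuration: the sedentary-breathing study conditions.
geometry:
  trachea:
    diameter_cm: 1.56
    posterior_cut_cm: 0.65
    length_cm: 10.0
  rings:
    step_p_mm: 5.4
    width_L_mm: 3.5
    depth_d_mm: 0.45
    fillet_r_mm: 0.3
    enabled: true
  bifurcation:
    x_n: 3.0
    c_c: 0.1
    transition_fraction: 0.8
  upper_airway:
    trachea_ref_diameter_cm: 1.9
    scale_mode: match_trachea
flow:
  gas:
    density_kg_m3: 1.225
    viscosity_kg_ms: 1.7894e-5
  cycle:
    period_s: 4.0
    mean_inspiratory_lpm: 6.0
  losses:
    pedley: true
    pedley_C: 1.85
    # K_bifurcation is calibrated once so the network reproduces the
    # reference 4.5 Pa trachea-to-generation-6 drop at the inspiratory peak
    K_bifurcation: 2.2
    K_larynx: 1.0
  dt_s: 0.01
particles:
  density_kg_m3: 998.2
  cunningham_Cc: 1.0
  sizes_um: [3, 7, 10, 25]
  injection:
    n_particles: 2720
    disk_diameter_cm: 2.16
    spacing_s: 0.2
deposition:
  oral: {form: ip_exp, a: 1.0e-4}
  pharynx: {form: ip_exp, a: 1.5e-4}
  larynx: {form: ip_exp, a: 4.0e-4}
  trachea: {form: stokes_exp, a: 1.2, b: 1.25}
  bif1: {form: stokes_exp, a: 4.0, b: 1.3}
  bif2: {form: stokes_exp, a: 4.5, b: 1.25}
  bif3: {form: stokes_exp, a: 5.0, b: 1.2}
  peripheral: {form: stokes_exp, a: 5.5, b: 1.15}
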