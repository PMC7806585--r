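# Per-region deposition-efficiency correlation constants.
#
# Upper-airway regions use the impaction-parameter form
#     DE = 1 - exp(-a * IP),        IP = rho[g/cm^3] * dp[um]^2 * Q[L/min]
# consistent with oral-airway cast impaction fits; tracheobronchial regions
# use the Stokes-number form
#     DE = 1 - exp(-a * St^b),      St = rho_p dp^2 U Cc / (36 mu R0)
# consistent with bifurcation-cast impaction fits (exponents slightly above
# one: impaction-dominated, convex in St).
#
# These constants are model configuration, not measurements: they set a
# plausible characteristic magnitude for each region at sedentary flow and
# are fully overridable through a user config file.
deposition:
  oral:
    form: ip_exp
    a: 1.0e-4
    source: "oral-cavity impaction fit, cast-replica style"
  pharynx:
    form: ip_exp
    a: 1.5e-4
    source: "pharyngeal impaction fit, cast-replica style"
  larynx:
    form: ip_exp
    a: 4.0e-4
    source: "glottal-jet impaction fit, cast-replica style"
  trachea:
    form: stokes_exp
    a: 1.2
    b: 1.25
    source: "tracheal impaction fit, ringed-wall cast style"
  bif1:
    form: stokes_exp
    a: 4.0
    b: 1.3
    source: "main-bifurcation impaction fit, TB-cast style"
  bif2:
    form: stokes_exp
    a: 4.5
    b: 1.25
    source: "second-generation impaction fit, TB-cast style"
  bif3:
    form: stokes_exp
    a: 5.0
    b: 1.2
    source: "third-generation impaction fit, TB-cast style"
  peripheral:
    form: stokes_exp
    a: 5.5
    b: 1.15
    source: "small-airway impaction fit, TB-cast style"
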