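Package: airwaydep
Title: Reduced-Order Airflow and Aerosol Deposition in the Conducting Airways
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Builds a characteristic human airway geometry (elliptical upper
    airway, C-shaped ringed trachea, asymmetric bifurcating tracheobronchial
    tree to generation 6), solves quasi-steady laminar Poiseuille network flow
    over a sedentary sinusoidal breathing cycle, and transports inhaled aerosol
    boluses with Stokes-number and impaction-parameter deposition-efficiency
    correlations. Reports regional and total deposition efficiency,
    injection-time sweeps over the inhalation phase, and per-lobe escape
    accounting, with deterministic fractional-bolus and seeded Monte-Carlo
    transport modes.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    yaml,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
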