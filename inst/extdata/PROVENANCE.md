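# Fixture provenance

## characteristic_tree.csv

Generated by `make_characteristic_table(tree_recipe())` (deterministic; no
random numbers). 127 branches, generations 0-6, 64 peripheral outlets
carrying all five lobe labels. This is a synthetic characteristic geometry,
an emulation of a cast-derived digital airway model, not a copy of one.

Tuning note (done once, frozen): the named central airways use fixed
anatomical anchors — trachea 1.56 cm diameter / 10 cm long with the
posterior cut at 0.65 cm; right main bronchus 1.30 / 2.2 cm; left main
bronchus 1.17 / 5.0 cm; bronchus intermedius 1.00 / 2.5 cm; right-lower
lobar root 0.90 cm. The remaining four lobar-root diameters are derived in
closed form (`characteristic_dimensions()`) so that the equal-pressure
Poiseuille flow split reproduces the reference lobar ventilation fractions
RUL 19 / RML 9 / RLL 29 / LUL 26 / LLL 17 percent (right lung 57%) by
construction. Below each lobar root the tree is a symmetric x_n = 3
subdivision with length = 3 x diameter.

Content checksum (md5): 675031d7e91e69e4c645a9629bedf904

The packaged file and the generator output are byte-identical; a regression
test asserts this, so the fixture is content-addressed.

## deposition_correlations.yaml / default_config.yaml

Model configuration defaults (see file comments). The per-region
deposition constants are plausible impaction-fit magnitudes, not
measurements; K_bifurcation = 2.2 is calibrated once so the loss model
reproduces the reference 4.5 Pa trachea-to-generation-6 pressure drop at
the sedentary inspiratory peak.
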