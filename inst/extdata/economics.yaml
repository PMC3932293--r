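# Economic inputs: acute fracture costs (EUR 2009, DRG-tariff based),
# health-state utilities, discounting, and the base-case cohort.
discount:
  annual_rate: 0.03
  cycle_length_years: 0.5
cohort:
  start_age: 65
  max_age: 110
unit_costs_eur:
  hip: 8206.0
  vertebral: 2476.0
  other:
    pelvis_other_femoral: 4575.0
    forearm: 2831.0
    ribs_sternum: 1022.0
    scapula_clavicle: 2962.0
    proximal_humerus: 4575.0
    tibia_fibula: 4929.0
# Weights pooling the other-fracture sub-table into a single state cost.
# Not published; chosen to reflect the typical osteoporotic site mix
# (forearm/wrist most frequent, humerus and pelvis next).
other_mix:
  pelvis_other_femoral: 0.15
  forearm: 0.35
  ribs_sternum: 0.10
  scapula_clavicle: 0.05
  proximal_humerus: 0.15
  tibia_fibula: 0.20
utilities:
  healthy: 1.0
  hip:
    first_year: 0.700
    subsequent: 0.800
  vertebral:
    first_year: 0.590
    subsequent: 0.929
  other:
    first_year: 0.902
  wrist:
    first_year: 0.956
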