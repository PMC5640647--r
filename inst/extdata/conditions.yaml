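# Condition registry for multi-condition comparisons.
#
# Two packaged series:
#   headspace      - sealed-tube cultures, 48 h, headspace volume 20-80%
#                    (larger headspace = more O2): biomass rises with O2,
#                    magnetic response collapses (C_mag 2.0 -> ~1), PHA stain
#                    (Pyr-546 FL1 location) falls with O2, and the PG-SK
#                    signal is lowest (most quenched = most chelatable iron)
#                    at 80% headspace.
#   medium_shift   - O2-limited bioreactor culture shifted to aerobic flasks
#                    in iron-replete (FSM) or iron-free (FSM-Fe-) medium;
#                    FSM cultures burn PHA (>3-fold Pyr-546 drop by 24 h) and
#                    accumulate iron (PG-SK drop), iron-free cultures barely
#                    grow and keep most of their PHA (65% of pre-shift).
#
# cmag parameters feed generate_od_pairs(); the implied noiseless C_mag is
# 1 + alignment_contrast * magnetic_fraction. pyr546_mu / pgsk_mu are log10
# FL1 locations (sigma 0.25) for the stained-sample scenarios; viability
# fractions parameterise the BOX/PI scenario.
sets:
  headspace: [headspace_20, headspace_40, headspace_60, headspace_80]
  medium_shift: [preshift_0h, fsm_24h, fsm_48h, fsm_noiron_24h, fsm_noiron_48h]

conditions:
  headspace_20:
    description: 20% headspace, most O2-limited; strongly magnetic, PHA-rich
    od565: 0.40
    cmag: {magnetic_fraction: 1.00, alignment_contrast: 1.0, noise_cv: 0.01}
    viability: {healthy: 0.88, injured: 0.065, dead: 0.035, anomalous: 0.02}
    pyr546_mu: 3.60
    pgsk_mu: 3.30
  headspace_40:
    description: 40% headspace
    od565: 0.55
    cmag: {magnetic_fraction: 0.60, alignment_contrast: 1.0, noise_cv: 0.01}
    viability: {healthy: 0.80, injured: 0.12, dead: 0.06, anomalous: 0.02}
    pyr546_mu: 3.30
    pgsk_mu: 3.20
  headspace_60:
    description: 60% headspace; very weakly magnetic
    od565: 0.70
    cmag: {magnetic_fraction: 0.10, alignment_contrast: 1.0, noise_cv: 0.01}
    viability: {healthy: 0.70, injured: 0.18, dead: 0.10, anomalous: 0.02}
    pyr546_mu: 3.00
    pgsk_mu: 3.00
  headspace_80:
    description: 80% headspace, most aerobic; highest biomass, highest iron uptake
    od565: 0.85
    cmag: {magnetic_fraction: 0.02, alignment_contrast: 1.0, noise_cv: 0.01}
    viability: {healthy: 0.60, injured: 0.22, dead: 0.16, anomalous: 0.02}
    pyr546_mu: 2.70
    pgsk_mu: 2.50

  preshift_0h:
    description: O2-limited bioreactor culture at the point of transfer
    od565: 1.20
    cmag: {magnetic_fraction: 0.71, alignment_contrast: 1.0, noise_cv: 0.01}
    viability: {healthy: 0.88, injured: 0.065, dead: 0.035, anomalous: 0.02}
    pyr546_mu: 3.60
    pgsk_mu: 3.30
  fsm_24h:
    description: 24 h after shift to aerobic iron-replete FSM
    od565: 1.60
    cmag: {magnetic_fraction: 0.84, alignment_contrast: 1.0, noise_cv: 0.01}
    viability: {healthy: 0.88, injured: 0.065, dead: 0.035, anomalous: 0.02}
    pyr546_mu: 3.00
    pgsk_mu: 3.00
  fsm_48h:
    description: 48 h after shift to aerobic iron-replete FSM
    od565: 2.10
    cmag: {magnetic_fraction: 0.46, alignment_contrast: 1.0, noise_cv: 0.01}
    viability: {healthy: 0.85, injured: 0.09, dead: 0.04, anomalous: 0.02}
    pyr546_mu: 2.95
    pgsk_mu: 2.80
  fsm_noiron_24h:
    description: 24 h after shift to aerobic iron-free FSM-Fe-
    od565: 0.30
    cmag: {magnetic_fraction: 0.40, alignment_contrast: 1.0, noise_cv: 0.01}
    viability: {healthy: 0.70, injured: 0.18, dead: 0.10, anomalous: 0.02}
    pyr546_mu: 3.41
    pgsk_mu: 3.30
  fsm_noiron_48h:
    description: 48 h after shift to aerobic iron-free FSM-Fe-
    od565: 0.35
    cmag: {magnetic_fraction: 0.20, alignment_contrast: 1.0, noise_cv: 0.01}
    viability: {healthy: 0.60, injured: 0.22, dead: 0.16, anomalous: 0.02}
    pyr546_mu: 3.41
    pgsk_mu: 3.30
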