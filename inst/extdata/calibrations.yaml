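# Packaged OD565 -> concentration proportionality constants for MSR-1.
# These are published equivalences, not fits performed by this package, so
# n_points is 0 and r2 is null with the context in `provenance`.
calibrations:
  fcm_unstained:
    mode: FCM
    slope: 1.16e+09
    r2: null
    n_points: 0
    provenance: >
      Published equivalence for unstained MSR-1 suspensions counted
      volumetrically by flow cytometry (auto-calibration, 35 uL/min):
      1 OD565 = 1.16e9 cells/mL; correlation reported as R2 > 0.95.
  fcm_syto62:
    mode: FCM
    slope: 1.03e+09
    r2: null
    n_points: 0
    provenance: >
      Published equivalence for Syto62-stained MSR-1 events (DNA-dye gate
      excludes noise particles): 1 OD565 = 1.03e9 cells/mL.
  cfu:
    mode: CFU
    slope: 3.3e+08
    r2: null
    n_points: 0
    provenance: >
      Published plate-count equivalence for MSR-1: 1 OD565 = 3.3e8 CFU/mL.
      Lower than the cytometric constant because viable-but-non-culturable
      cells form no colonies.
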