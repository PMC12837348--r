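# Packaged default Pain-Track configuration for the thirteen heat stress
# scenarios (acute CCI category x chronic ATL risk class).
#
# - Phase durations (I: initial stress, II: overload, III: recovery) and the
#   daily totals are the packaged per-scenario estimates; totals are metadata
#   only - the phase intervals drive all computation, and a mismatch between
#   their sum and the total is surfaced as a warning, not reconciled.
# - The M-M intensity probabilities are the published worked example
#   (phase-structured: overload is the most severe phase).
# - The other twelve scenarios' probability matrices are PACKAGE STAND-INS,
#   not published values: each scenario uses one severity profile across all
#   three phases, calibrated so that hurtful and disabling discomfort-hours
#   are non-decreasing along both scenario axes (more acute stress, or more
#   chronic load, never yields fewer severe hours), which is what the shade
#   comparison relies on. Excruciating mass appears only in extreme-danger
#   scenarios and never exceeds 0.05. Override freely via
#   load_paintrack_config().
scenarios:
  M-M:
    total: [5, 7]
    phases:
      I:
        duration: [1, 2]
        probs: {none: 0.10, annoying: 0.60, hurtful: 0.30, disabling: 0.00, excruciating: 0.00}
      II:
        duration: [2, 3]
        probs: {none: 0.00, annoying: 0.10, hurtful: 0.80, disabling: 0.10, excruciating: 0.00}
      III:
        duration: [1, 2]
        probs: {none: 0.30, annoying: 0.60, hurtful: 0.10, disabling: 0.00, excruciating: 0.00}
  M-H:
    total: [7, 9]
    phases:
      I:
        duration: [1.5, 2.5]
        probs: &mh {none: 0.06, annoying: 0.44, hurtful: 0.42, disabling: 0.08, excruciating: 0.00}
      II:
        duration: [3, 4]
        probs: *mh
      III:
        duration: [2, 2.5]
        probs: *mh
  M-VH:
    total: [9, 11]
    phases:
      I:
        duration: [2, 2.5]
        probs: &mvh {none: 0.03, annoying: 0.38, hurtful: 0.45, disabling: 0.14, excruciating: 0.00}
      II:
        duration: [4, 5]
        probs: *mvh
      III:
        duration: [3, 3.5]
        probs: *mvh
  M-E:
    total: [10, 12]
    phases:
      I:
        duration: [2, 3]
        probs: &me {none: 0.00, annoying: 0.33, hurtful: 0.47, disabling: 0.20, excruciating: 0.00}
      II:
        duration: [5, 6]
        probs: *me
      III:
        duration: [3, 3.5]
        probs: *me
  S-M:
    total: [5, 7]
    phases:
      I:
        duration: [1, 1.5]
        probs: &sm {none: 0.04, annoying: 0.42, hurtful: 0.46, disabling: 0.08, excruciating: 0.00}
      II:
        duration: [2.5, 3.5]
        probs: *sm
      III:
        duration: [1.5, 2]
        probs: *sm
  S-H:
    total: [8, 10]
    phases:
      I:
        duration: [1.5, 2]
        probs: &sh {none: 0.02, annoying: 0.38, hurtful: 0.46, disabling: 0.14, excruciating: 0.00}
      II:
        duration: [4, 5]
        probs: *sh
      III:
        duration: [2.5, 3]
        probs: *sh
  S-VH:
    total: [10, 12]
    phases:
      I:
        duration: [2, 2.5]
        probs: &svh {none: 0.00, annoying: 0.38, hurtful: 0.45, disabling: 0.17, excruciating: 0.00}
      II:
        duration: [5, 6]
        probs: *svh
      III:
        duration: [3, 3.5]
        probs: *svh
  S-E:
    total: [11, 13]
    phases:
      I:
        duration: [2.5, 3]
        probs: &se {none: 0.00, annoying: 0.32, hurtful: 0.46, disabling: 0.22, excruciating: 0.00}
      II:
        duration: [6, 7]
        probs: *se
      III:
        duration: [2.5, 3]
        probs: *se
  E-H:
    total: [7, 9]
    phases:
      I:
        duration: [0.5, 1]
        probs: &eh {none: 0.00, annoying: 0.27, hurtful: 0.53, disabling: 0.20, excruciating: 0.00}
      II:
        duration: [3, 4]
        probs: *eh
      III:
        duration: [3.5, 4]
        probs: *eh
  E-VH:
    total: [9, 11]
    phases:
      I:
        duration: [0.5, 1]
        probs: &evh {none: 0.00, annoying: 0.26, hurtful: 0.51, disabling: 0.23, excruciating: 0.00}
      II:
        duration: [4, 5]
        probs: *evh
      III:
        duration: [4.5, 5]
        probs: *evh
  E-E:
    total: [10, 12]
    phases:
      I:
        duration: [0.5, 1]
        probs: &ee {none: 0.00, annoying: 0.22, hurtful: 0.52, disabling: 0.26, excruciating: 0.00}
      II:
        duration: [4.5, 5.5]
        probs: *ee
      III:
        duration: [5, 5.5]
        probs: *ee
  ED-VH:
    total: [8, 10]
    phases:
      I:
        duration: [0.25, 0.5]
        probs: &edvh {none: 0.00, annoying: 0.07, hurtful: 0.59, disabling: 0.30, excruciating: 0.04}
      II:
        duration: [3, 4]
        probs: *edvh
      III:
        duration: [4.75, 5.5]
        probs: *edvh
  ED-E:
    total: [10, 12]
    phases:
      I:
        duration: [0.25, 0.5]
        probs: &ede {none: 0.00, annoying: 0.08, hurtful: 0.56, disabling: 0.32, excruciating: 0.04}
      II:
        duration: [3.5, 4.5]
        probs: *ede
      III:
        duration: [6.25, 7]
        probs: *ede
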