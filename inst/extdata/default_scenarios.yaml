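# Default seasonal scenarios for the honeybee colony demographic model.
#
# These numeric values are calibrated implementer defaults, NOT values
# from a published per-season parameter table (none is publicly
# deposited).  They encode the qualitative season descriptions --
# summer: high food availability, high extrinsic mortality, high
# nurse-to-forager transition; spring/fall: intermediate food and
# extrinsic mortality, high transition; winter: near-zero food, low
# extrinsic mortality, low transition -- and are calibrated so that
# (a) expected adult worker lifespan is 2-6 weeks in summer and at most
# 20 weeks in winter, and (b) the six qualitative orderings of the
# seasonal elasticity comparison hold (see the package vignette).
#
# Shared across seasons: stage durations, brood survival s_b, brood food
# requirement c, and the age-dependent hazard components (alpha, beta)
# of both roles.  Seasonal: extrinsic mortality (gamma) of both roles,
# food availability p, and transition rate g (summer = spring_fall > winter
# for g; summer > spring_fall > winter for gamma and p).
scenarios:
  - label: summer
    provenance_note: calibrated implementer default (no deposited table)
    params:
      structure: {brood_days: 21, nurse_max_days: 120, forager_max_days: 19}
      s_b: 0.97
      g: 0.06
      p: 1.0
      c: 1.0
      nurse_gm: {alpha: 2.0e-4, beta: 0.004, gamma: 0.008}
      forager_gm: {alpha: 2.0e-3, beta: 0.22, gamma: 0.30}
  - label: spring_fall
    provenance_note: calibrated implementer default (no deposited table)
    params:
      structure: {brood_days: 21, nurse_max_days: 120, forager_max_days: 19}
      s_b: 0.97
      g: 0.06
      p: 0.65
      c: 1.0
      nurse_gm: {alpha: 2.0e-4, beta: 0.004, gamma: 6.8e-3}
      forager_gm: {alpha: 2.0e-3, beta: 0.22, gamma: 0.18}
  - label: winter
    provenance_note: calibrated implementer default (no deposited table)
    params:
      structure: {brood_days: 21, nurse_max_days: 120, forager_max_days: 19}
      s_b: 0.97
      g: 0.012
      p: 0.02
      c: 1.0
      nurse_gm: {alpha: 2.0e-4, beta: 0.004, gamma: 8.0e-4}
      forager_gm: {alpha: 2.0e-3, beta: 0.22, gamma: 1.5e-3}
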