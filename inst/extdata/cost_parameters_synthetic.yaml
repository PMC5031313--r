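# Default cost-parameter configuration (synthetic).
#
# mean_annual_cost: mean annual direct medical cost per patient, USD/year.
# distribution:    uncertainty used by the probabilistic sensitivity
#                  analysis: gamma (needs se) or uniform (+/-20% of mean).
# delta_mn:        proportional excess annual cost of a malnourished
#                  patient relative to a non-malnourished patient with the
#                  same disease; global = one shared value across diseases.
#
# The dementia mean ($36,397/yr) is the published literature value; the
# remaining means, the standard errors and the delta_mn distribution are
# synthetic, literature-plausible defaults for testing and simulation.
delta_mn:
  value: 0.5
  distribution: gamma
  se: 0.1
  global: true
diseases:
  stroke:
    mean_annual_cost: 10000
    distribution: gamma
    se: 1000
  copd:
    mean_annual_cost: 9800
    distribution: gamma
    se: 900
  chf:
    mean_annual_cost: 12000
    distribution: gamma
    se: 1200
  colorectal_cancer:
    mean_annual_cost: 14000
    distribution: uniform
  breast_cancer:
    mean_annual_cost: 13000
    distribution: uniform
  dementia:
    mean_annual_cost: 36397
    distribution: gamma
    se: 3500
  musculoskeletal:
    mean_annual_cost: 8000
    distribution: uniform
  depression:
    mean_annual_cost: 11000
    distribution: gamma
    se: 1100
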