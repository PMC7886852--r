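# Zhaoshu Island 2017 assessment configuration.
# Raw pressure/support values were mostly not published for this case
# study; each pair is materialised as (pressure, support) = (1 - d, 1),
# which reproduces the published per-indicator surplus ratio d exactly.
# Note: the source table prints degree 5 for environmental protection
# investment alongside ratio 0.08; the degree consistent with the ratio
# is 8 and that is what the assessment reports.
name: Zhaoshu Island 2017
warning_width: 0.10
dimensions:
  - id: resources
    name: Resources supply
    mode: flat
    factors:
      - id: land
        name: Land resources
        indicators:
          - id: land
            name: Land resources
            units: km2
            pressure: 0.62
            support: 1.0
      - id: water
        name: Water resources
        indicators:
          - id: water
            name: Water resources
            units: t/a
            pressure: 0.56
            support: 1.0
  - id: assimilation
    name: Environmental assimilation
    mode: flat
    factors:
      - id: water_assim
        name: Water assimilation
        indicators:
          - id: water_assim
            name: Water assimilation capacity
            units: t/a
            pressure: 0.13
            support: 1.0
  - id: ecosystem
    name: Ecosystem services
    mode: nested
    factors:
      - id: terrestrial
        name: Terrestrial ecosystem services
        indicators:
          - id: sum_lai
            name: Sum LAI
            units: m2/m2
            pressure: 1.04
            support: 1.0
      - id: coral_reef
        name: Coral reef ecosystem services
        indicators:
          - id: hcc
            name: Hard corals coverage
            units: "%"
            pressure: 2.45
            support: 1.0
          - id: coral_spp
            name: Species number of hard corals
            pressure: 0.86
            support: 1.0
          - id: fish_density
            name: Coral reef fishes density
            units: fish/m2
            pressure: 1.67
            support: 1.0
          - id: fish_spp
            name: Species number of coral reef fishes
            pressure: 0.86
            support: 1.0
  - id: socioeconomic
    name: Socio-economic supporting
    mode: flat
    factors:
      - id: development
        name: Socio-economic development
        indicators:
          - id: gdp
            name: GDP per capita
            units: Yuan
            pressure: 0.96
            support: 1.0
      - id: protection
        name: Protective initiatives
        indicators:
          - id: env_invest
            name: Environmental protection investment
            units: "%"
            pressure: 0.92
            support: 1.0
          - id: rnd
            name: R&D expenditures
            units: "%"
            pressure: 1.60
            support: 1.0
land_suitability:
  weights: [0.25, 0.25, 0.25, 0.25]
  thresholds: [2, 4]
pollutant_combine: min
seed: 1
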