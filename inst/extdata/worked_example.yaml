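# Minimal worked example: one cause, one preventive intervention.
# 10 000 diarrhea deaths; a vaccine 50% effective against diarrhea mortality
# scaled from 0% to 50% coverage leaves 7 500 deaths.
causes:
  - id: diarrhea
    name: Diarrhea
    baseline_deaths: 10000
interventions:
  - id: vaccine
    name: New rotavirus vaccine
    category: preventive
    stage: childhood
    effectiveness:
      diarrhea: 0.5
demography:
  base_year: 2010
  base_births: 100000
  growth_rate: 0.0
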