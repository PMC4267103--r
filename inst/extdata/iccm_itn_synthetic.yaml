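# SYNTHETIC example world: an iCCM package (antimalarials, pneumonia case
# management, ORS+zinc) rolled out alongside an ITN (bednet) campaign.
# Baseline cause-of-death structure and effectiveness values are invented
# (no country is represented); they are chosen so the joint scale-up yields
# per-intervention percent mortality reductions that display, at one
# decimal, as ITN 3.7, antimalarials 2.1, pneumonia case management 2.7,
# ORS+zinc 2.4 (total 10.9) -- the classic prevention-before-cure pattern in
# which a curative intervention is worth less wherever a preventive one is
# scaled up on the same cause.
causes:
  - id: malaria
    name: Malaria
    baseline_deaths: 13214
  - id: pneumonia
    name: Pneumonia
    baseline_deaths: 30000
  - id: diarrhea
    name: Diarrhea
    baseline_deaths: 30000
  - id: other
    name: Other causes
    baseline_deaths: 26786
interventions:
  - id: itn
    name: Insecticide-treated bednets
    category: preventive
    stage: childhood
    effectiveness:
      malaria: 0.56
  - id: antimalarials
    name: Antimalarials (ACT)
    category: curative
    stage: childhood
    effectiveness:
      malaria: 0.439
  - id: pneumo_cm
    name: Case management of pneumonia
    category: curative
    stage: childhood
    effectiveness:
      pneumonia: 0.18
  - id: ors_zinc
    name: ORS + zinc for diarrhea
    category: curative
    stage: childhood
    effectiveness:
      diarrhea: 0.16
demography:
  base_year: 2010
  base_births: 100000
  growth_rate: 0.0
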