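# Example run configuration for the classification pipeline.
paths:
  cultures: blood_cultures.csv
  contacts: contacts.csv
  assessments: assessments.csv
  followup: followup.csv
output_dir: results
windows:
  episode_span: 2          # days: index date and the day after
  contamination_window: 5  # repeat-growth screen for skin commensals
  hca_window: 30           # prior-contact window for healthcare association
  attach_window: 30        # unassessed-culture attachment to reference episodes
  incident_lookback: 365   # lag lookback for the incident flag
lexicon:
  genus_patterns: [Propionibacterium, Bacillus, Micrococcus, Corynebacterium]
  exact_labels: [coagulase-negative staphylococcus, coryneform rod]
  cons_species:
    - Staphylococcus epidermidis
    - Staphylococcus hominis
    - Staphylococcus haemolyticus
    - Staphylococcus capitis
    - Staphylococcus warneri
    - Staphylococcus saprophyticus
    - Staphylococcus lugdunensis
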