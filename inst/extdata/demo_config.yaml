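# Demonstration pipeline configuration: a two-region synthetic study with a
# dopamine receptor-signaling module planted in the hippocampus, a matching
# dopamine increase, and serotonin configured undetectable.
seed: 11
simulation:
  nProteins: 500
  regions: [Hip, Ctx]
  plantedSets:
    - name: "DA receptor signaling"
      regions: [Hip]
      direction: 1
  plantedAnalyteEffects:
    - analyte: DA
      region: Hip
      genotype: TG
      direction: 1
      fold: 2
  absentAnalytes: [5HT]
enrichment:
  nPerm: 200
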