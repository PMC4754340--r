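# Demonstration pipeline configuration.  Paths are resolved relative to
# `outputDir` passed to runPipeline(); every stochastic stage carries an
# explicit seed.
stages:
  - stage: simulate
    params:
      freq_causal: 0.35
      freq_tag: 0.40
      r2_target: 0.6
      n_hap: 2000
      odds_ratio: 1.5
      n_case: 300
      n_control: 700
      seed: 11
    outputs:
      panel_vcf: panel.vcf
      dosage_tsv: dosages.tsv
      phenotype_tsv: phenotypes.tsv
  - stage: qc
    inputs:
      dosage_tsv: dosages.tsv
      phenotype_tsv: phenotypes.tsv
    outputs:
      dosage_tsv: dosages_qc.tsv
      report_json: qc_report.json
  - stage: assoc
    inputs:
      dosage_tsv: dosages_qc.tsv
      phenotype_tsv: phenotypes.tsv
    outputs:
      assoc_tsv: assoc.tsv
  - stage: finemap_sim
    params:
      causal: snpA
      tag: snpB
      b: 500
      seed: 12
    inputs:
      panel_vcf: panel.vcf
      dosage_tsv: dosages_qc.tsv
      phenotype_tsv: phenotypes.tsv
      assoc_tsv: assoc.tsv
    outputs:
      report_json: finemap_sim.json
      replicate_tsv: finemap_replicates.tsv
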