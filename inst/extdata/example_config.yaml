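# Example isoTP run configuration (schema version 1).
# Exactly one data source: 'data: <csv path>' or 'simulate: {...}'.
version: 1
seed: 42
simulate:
  n_hauls: 10
  haul_sd_fraction: 0.3
outdir: isoTP-report
models:
  - method: bulk
    consumer: Champsocephalus gunnari
    baseline: POM
    lambda: 1
    tef: {mean: 3.4, sd: 0.51}
    label: gunnari bulk
  - method: csia
    consumer: Champsocephalus gunnari
    pair: [Glx, Phe]
    tef: {mean: 7.6, sd: 1.2}
    beta: {mean: 3.4, sd: 0}
    label: gunnari Glx-Phe
  - method: csia
    consumer: Euphausia superba
    pair: [Glx, Phe]
    tef: {mean: 7.6, sd: 1.2}
    beta: {mean: 3.4, sd: 0}
    label: superba Glx-Phe
comparisons:
  - a: gunnari Glx-Phe
    b: superba Glx-Phe
    expected_dtp: 1
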