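# Demonstration run: simulate a small hexaploid GBS population end-to-end,
# estimate variance components by EM-REML, and validate by forward prediction.
seed: 42
output_dir: gbsblup_demo
simulation:
  n_mothers: 60
  n_markers: 150
  n_families: 6
  n_years: 8
  progeny_per_mother: 2
  records_per_progeny: 2
  replicated_mothers: 4
filters:
  maf: 0.05
  min_depth: 5
  max_depth: 300
  call_rate: 0.5
grm:
  method: betabinomial
  ploidy: 6
model:
  mode: single
  vc: reml
  reml:
    tol: 1.0e-05
    max_iter: 100
validation:
  strategy: forward
  cutoff_year: 2006
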