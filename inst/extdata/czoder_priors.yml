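# Uniform prior bounds for the Czech Oder origin scenarios (same
# conventions as sazava_priors.yml).
params:
  - {name: N_ODR,  min: 10,   max: 2000}    # present Ne of CZODER
  - {name: N_NMO,  min: 100,  max: 10000}   # present Ne of NMORAV
  - {name: N_POL,  min: 100,  max: 10000}   # present Ne of POLRIV
  - {name: N_ANC,  min: 100,  max: 10000}   # ancestral Ne
  - {name: t_fnd,  min: 1,    max: 2000}    # founding time of CZODER
  - {name: t_anc,  min: 200,  max: 20000}   # NMORAV/POLRIV split (> t_fnd)
  - {name: r_nmo,  min: 0.05, max: 0.95}    # admixture fraction from NMORAV
  - {name: N_bot,  min: 2,    max: 100}     # founding bottleneck Ne
  - {name: d_bot,  min: 0,    max: 30}      # bottleneck duration (< t_fnd)
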