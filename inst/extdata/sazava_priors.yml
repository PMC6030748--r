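# Uniform prior bounds for the Sazava origin scenarios. Synthetic package
# defaults chosen to bracket plausible values for small lowland fish
# populations (times in generations = years; Ne in diploid individuals);
# edit freely and pass through sazava_models().
params:
  - {name: N_SAZ,  min: 10,   max: 2000}    # present Ne of SAZAVA
  - {name: N_WMO,  min: 100,  max: 10000}   # present Ne of WMORAV
  - {name: N_ELB,  min: 100,  max: 10000}   # present Ne of CZELBE
  - {name: N_ANC,  min: 100,  max: 10000}   # ancestral Ne
  - {name: t_adm,  min: 1,    max: 2000}    # founding time of SAZAVA
  - {name: t_anc,  min: 200,  max: 10000}   # CZELBE/WMORAV split (> t_adm)
  - {name: r_wmo,  min: 0.05, max: 0.95}    # admixture fraction from WMORAV
  - {name: N_bot,  min: 2,    max: 100}     # founding bottleneck Ne
  - {name: d_bot,  min: 0,    max: 30}      # bottleneck duration (< t_adm)
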