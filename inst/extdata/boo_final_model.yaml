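# Final fitted demographic model of the Bolshoy Oleni Ostrov (BOO) lineage
# and its North Eurasian context. Times in years ago; ne are diploid
# effective sizes; alpha is the forward-time admixture fraction arriving in
# `dest` from `source`. Entries marked `assumed: true` were not estimated:
# they are conventional values required to complete the model and can be
# overridden via set_parameter().
generation_time: 29
mutation_rate: 1.25e-8
populations:
  - {name: YRI, ne: 10000, assumed: true}
  - {name: Loschbour, ne: 10000, assumed: true}
  - {name: CHB, ne: 10000, assumed: true}
  - {name: EEHG, ne: 2470}
  - {name: EasternSiberiaLNBA, ne: 1690}
  - {name: BOO, ne: 235}
splits:
  - {time_ya: 87790, child: Loschbour, parent: YRI}
  - {time_ya: 53010, child: CHB, parent: Loschbour}
  - {time_ya: 30000, child: EEHG, parent: Loschbour, assumed: true}
  - {time_ya: 21580, child: EasternSiberiaLNBA, parent: CHB}
  - {time_ya: 5000, child: BOO, parent: EEHG, assumed: true}
pulses:
  - {time_ya: 25000, source: CHB, dest: EEHG, alpha: 0.094, assumed: true}
  - {time_ya: 19000, source: EEHG, dest: EasternSiberiaLNBA, alpha: 0.125, assumed: true}
  - {time_ya: 4086, source: EasternSiberiaLNBA, dest: BOO, alpha: 0.398}
samples:
  - {population: YRI, n_haploids: 4, time_ya: 0}
  - {population: CHB, n_haploids: 4, time_ya: 0}
  - {population: Loschbour, n_haploids: 4, time_ya: 8000, assumed: true}
  - {population: EEHG, n_haploids: 4, time_ya: 11000, assumed: true}
  - {population: EasternSiberiaLNBA, n_haploids: 4, time_ya: 4500, assumed: true}
  # 4086 ya admixture minus 17.98 generations (521 y) at 29 y/generation:
  # the sampling age implied by the model's own dating arithmetic
  - {population: BOO, n_haploids: 4, time_ya: 3565, assumed: true}
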