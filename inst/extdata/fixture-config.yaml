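# Packaged tiny-fixture configuration: a 2-catchment x 2-stream survey with
# the default effect structure, used for fast end-to-end runs.
seed: 20161025
simulate:
  design:
    n_catchments: 2
    streams_per_catchment: 2
    replicates_per_zone: 3
  effects: default
  noise_free: false
nmds:
  n_starts: 50
n_perm: 999
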