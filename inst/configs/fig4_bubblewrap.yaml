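# low-dimensional trajectory -> streaming mixture-HMM prediction
actors:
  source:
    impl: trajectory_source
    params: {frames: 2000, dims: 3, noise: 0.05, seed: 1}
  bubblewrap:
    impl: bubblewrap_model
    params: {tiles: 50, init_points: 20, seed: 42}
  sink:
    impl: count_sink
connections:
  - source.out -> bubblewrap.in
  - bubblewrap.out -> sink.in
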