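# behavior video -> proSVD subspace -> streaming ridge readout of neural traces
actors:
  video:
    impl: behavior_pair_source
    params: {frames: 300, seed: 1}
  model:
    impl: prosvd_ridge
    params: {k: 10, init_frames: 10, lambda: 1.0e-5}
  sink:
    impl: count_sink
connections:
  - video.out -> model.in
  - model.out -> sink.in
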