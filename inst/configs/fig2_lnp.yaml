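# streaming LNP characterization: simulated calcium-derived spikes with a
# visual motion protocol, fit online one frame at a time
actors:
  acquirer:
    impl: lnp_spike_source
    params: {n_neurons: 10, repetitions: 2, seed: 1}
  lnp:
    impl: lnp_model
    params: {window: 100, track_every: 25}
  sink:
    impl: count_sink
connections:
  - acquirer.out -> lnp.in
  - lnp.out -> sink.in
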