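# closed-loop stimulus optimization: the optimizer and the stimulus actor
# exchange messages around a cycle until every neuron's peak is found
actors:
  trigger:
    impl: trigger_source
  optimizer:
    impl: bo_optimizer
    params: {n_neurons: 20, n_max: 30, rng_seed: 1337}
  stimuli:
    impl: visual_stimuli
    params: {n_neurons: 20, seed: 1, noise_sd: 0.2}
connections:
  - trigger.out -> optimizer.in
  - optimizer.out -> stimuli.in
  - stimuli.out -> optimizer.in
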