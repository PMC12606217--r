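# characterization -> phase switch -> adaptive photostimulation targeting
actors:
  trigger:
    impl: trigger_source
  controller:
    impl: photostim_controller
    params: {n_neurons: 20, n_targets: 5, seed: 1}
  sink:
    impl: count_sink
connections:
  - trigger.out -> controller.in
  - controller.out -> sink.in
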