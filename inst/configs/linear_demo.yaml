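# minimal 3-actor linear pipeline used by examples and tests
actors:
  acquirer:
    impl: count_source
  processor:
    impl: passthrough
  analyzer:
    impl: collect_sink
connections:
  - acquirer.out -> processor.in
  - processor.out -> analyzer.in
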