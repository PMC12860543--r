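# Heavy shared fixture: the desk-scale observer study (trains the
# segmentation network once and reconstructs every test sample under all
# three arms).  Built lazily and reused by the acceptance tests.

deskStudy <- function() {
  fixture("deskStudy", function() {
    cfg <- deskStudyConfig(seed = 20260901L)
    runExperiment(cfg, verbose = FALSE)
  })
}
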