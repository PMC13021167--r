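# The end-to-end desk run is expensive; compute it once per test session and
# share it between the evaluation and robustness property suites.
.demo_cache <- new.env(parent = emptyenv())

demo_artifacts <- function() {
  if (is.null(.demo_cache$art)) {
    cfg <- pipeline_config("desk", seed = 1L)
    .demo_cache$art <- run_pipeline(cfg, stages = c("phantom", "crops", "folds",
                                                    "train", "evaluate",
                                                    "robustness"))
  }
  .demo_cache$art
}
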