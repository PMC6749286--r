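# The desk-scale ensemble + distillation study is the costly part of the
# suite; compute it once per test run and share it across files.
.study_cache <- new.env(parent = emptyenv())

get_desk_study <- function() {
  if (is.null(.study_cache$study)) {
    .study_cache$study <- run_distillation_study(seed = 1)
  }
  .study_cache$study
}
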