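# Shared configuration for the numbered analysis drivers. Each driver runs
# one stage of the pipeline against the same artifact directory, so they
# can be run in sequence (01 ... 06) or re-run individually.

library(poleward)

analysis_seed <- 1L
artifact_dir <- file.path("results", "pipeline")

analysis_config <- function() {
  pipeline_config(out_dir = artifact_dir,
                  transect = transect_config(seed = analysis_seed),
                  seed = analysis_seed)
}
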