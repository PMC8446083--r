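#!/usr/bin/env Rscript
# Stage 4: weighted co-occurrence networks. Soft-power adjacency (power 11
# for the combined 16S+18S taxa, 12 for Pfams), topological overlap,
# module detection by average-linkage clustering on 1 - TOM, module
# eigengenes and their correlation with the environment.

source(file.path("analysis", "00_config.R"))

cfg <- analysis_config()
rep <- run_pipeline(cfg, "network")

for (tag in c("taxa", "pfam")) {
  r <- rep$network[[tag]]
  cat(sprintf("%s network: %d module(s); sizes %s\n", tag, r$n_modules,
              paste(unlist(r$module_sizes), collapse = ", ")))
  if (!is.null(r$temperature_r)) {
    cat("  eigengene ~ temperature r:",
        paste(sprintf("%.2f", unlist(r$temperature_r)), collapse = ", "),
        "\n")
  }
}
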