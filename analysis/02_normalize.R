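#!/usr/bin/env Rscript
# Stage 2: copy-number-aware normalization. 16S counts are divided by
# taxonomy-averaged rRNA operon copy numbers (species averages propagated
# up the tree, missing values imputed from the nearest valued ancestor);
# 18S counts by copy numbers predicted from the genome-size power law
# fitted on the reference table; all tables are then rescaled to hits per
# million.

source(file.path("analysis", "00_config.R"))

cfg <- analysis_config()
rep <- run_pipeline(cfg, "normalize")

m <- rep$normalize$copy_model
cat(sprintf("18S copy-number law: log10(copies) = %.3f log10(Mbp) + %.3f (R2 %.2f, n %d)\n",
            m$slope, m$intercept, m$r_squared, m$n))
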