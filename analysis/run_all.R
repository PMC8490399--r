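#!/usr/bin/env Rscript
# Run the whole workflow (simulate -> consensus -> classify -> summarize ->
# arm calls) from one master seed. Set THROMBEVO_SEED to change it.
# Usage, from the repository root:  Rscript analysis/run_all.R

stages <- c("01_simulate.R", "02_consensus.R", "03_classify.R",
            "04_summarize.R", "05_armcall.R")
for (s in stages) {
  cat("\n==>", s, "\n")
  status <- system2("Rscript", file.path("analysis", s))
  if (status != 0L) stop("stage failed: ", s)
}
cat("\nAll stages complete; outputs under results/.\n")
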