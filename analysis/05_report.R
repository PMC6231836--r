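#!/usr/bin/env Rscript
# Step 5 — human-readable summary of the run.
#
# Formats the per-stratum tables written in step 4; every number traces back
# to a results CSV cell (the only derived statistic is the percent difference
# of the intervention-period mean over baseline).

suppressMessages(library(stepincentives))

for (ap in c("any", "completer", "imputed")) {
  cat("\n")
  report_summary("results/run", ap)
}
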