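#!/usr/bin/env Rscript

# Render the final summary: one table per feature-set mode with the six
# bootstrapped metrics formatted as "mean [lo-hi]".

library(ocatscreen)

txt <- render_report("results")
cat(txt, sep = "\n")
cat("\nwrote results/report.txt\n")
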