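#!/usr/bin/env Rscript
# Runs the whole analysis sequence. Each step is independent (every script
# regenerates its inputs deterministically from fixed seeds), so they can
# also be run one at a time.
for (script in sprintf("analysis/%02d_%s.R", 1:7,
                       c("simulate", "occupancy_classes",
                         "accessibility_signal", "methylation_dynamics",
                         "footprints_cooccurrence", "expression_clusters",
                         "dependency"))) {
  message("==> ", script)
  source(script, echo = FALSE)
}
message("all analysis steps complete; tables under results/analysis/")
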