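#!/usr/bin/env Rscript
# Per-1000-patient comparison of surveillance strategies: colonoscopy for
# all, parallel VOC+FIT, and serial VOC-then-FIT, with colonoscopy demand
# and number needed to scope.

suppressPackageStartupMessages(library(polyptriage))
dir.create("results", showWarnings = FALSE)

voc <- test_spec("VOC", 0.94, 0.69)
fit10 <- test_spec("FIT10", 0.54, 0.79)
par_test <- test_spec("VOC||FIT", 0.97, 0.11)

tab <- flow_table(1000, 0.26, first = voc, second = fit10,
                  parallel = par_test)
write.csv(tab, "results/strategy_comparison_per_1000.csv",
          row.names = FALSE)
print(tab[, c("strategy", "test_positives", "test_negatives",
              "detected_in_positives", "missed_in_negatives",
              "colonoscopies", "number_needed_to_scope")])

ser <- flow_serial(1000, 0.26, voc, fit10)
cat(sprintf(paste0("\nSerial testing: %d colonoscopies per 1000 patients ",
                   "(%d + %d), %d findings\ndetected, %d missed; %d ",
                   "colonoscopies per finding detected, against %d for\n",
                   "colonoscopy-for-all.\n"),
            ser$summary$colonoscopies, ser$stages$test_positives[1],
            ser$stages$test_positives[2], ser$summary$detected,
            ser$summary$missed, ser$summary$number_needed_to_scope,
            flow_colonoscopy_all(1000, 0.26)$number_needed_to_scope))
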