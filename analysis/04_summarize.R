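#!/usr/bin/env Rscript
# Stage 4: cohort summary and recovery against simulation truth.
# Reads labels from results/classify/ and the truth table from
# results/cohort/, writes the cohort summary tables (TSV + JSON) under
# results/summary/ and reports how well the classified labels recover the
# generating scenarios.

suppressPackageStartupMessages(library(thrombevo))

labels <- utils::read.table("results/classify/labels.tsv", sep = "\t",
                            header = TRUE, stringsAsFactors = FALSE)
truth <- utils::read.table("results/cohort/truth.tsv", sep = "\t",
                           header = TRUE, stringsAsFactors = FALSE)

s <- summarize_patterns(labels)
write_cohort_summary(s, "results/summary")
print(s)

f <- fraction_with_additional_drivers(labels)
cat(sprintf("\nAdditional TT drivers: %d of %d multi-TT patients (%s%%)\n",
            f$n_true, f$n, f$percent_int))

rec <- label_recovery(labels, truth)
cat(sprintf("Recovery vs truth (n=%d): pattern %.1f%%, topology %.1f%%\n",
            rec$n, 100 * rec$pattern_recovery, 100 * rec$topology_recovery))
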