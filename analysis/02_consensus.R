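#!/usr/bin/env Rscript
# Stage 2: multi-caller merge, 3-of-7 consensus retention, variant-class
# filter, and per-patient driver-matrix construction. Reads the cohort from
# results/cohort/ and writes retained calls plus one matrix TSV per patient
# under results/consensus/.

suppressPackageStartupMessages(library(thrombevo))

indir <- "results/cohort"
outdir <- "results/consensus"
dir.create(file.path(outdir, "matrices"), showWarnings = FALSE, recursive = TRUE)

calls <- read_calls_tsv(file.path(indir, "caller_calls.tsv"))
roles <- utils::read.table(file.path(indir, "sample_roles.tsv"), sep = "\t",
                           header = TRUE, stringsAsFactors = FALSE)

retained <- consensus_calls(calls, min_callers = 3L, verbose = TRUE)
utils::write.table(retained, file.path(outdir, "retained_calls.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)

matrices <- build_mutation_matrices(retained, driver_gene_pool(), roles)
for (pid in names(matrices))
  write_mutation_matrix(matrices[[pid]],
                        file.path(outdir, "matrices", paste0(pid, ".tsv")))

cat(sprintf("Retained %d of %d merged calls; wrote %d matrices to %s\n",
            nrow(retained), nrow(merge_caller_calls(calls)),
            length(matrices), outdir))
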