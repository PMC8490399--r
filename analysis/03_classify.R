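#!/usr/bin/env Rscript
# Stage 3: per-patient evolution-pattern classification and clone trees.
# Reads the matrices from results/consensus/, classifies every patient, and
# writes labels.tsv plus one Newick clone tree per patient under
# results/classify/.

suppressPackageStartupMessages(library(thrombevo))

indir <- "results/consensus/matrices"
outdir <- "results/classify"
dir.create(file.path(outdir, "trees"), showWarnings = FALSE, recursive = TRUE)

paths <- list.files(indir, pattern = "\\.tsv$", full.names = TRUE)
matrices <- lapply(paths, read_mutation_matrix, driver_list = driver_gene_pool())
names(matrices) <- vapply(matrices, `[[`, character(1), "patient_id")

labels <- classify_cohort(matrices)
utils::write.table(labels, file.path(outdir, "labels.tsv"), sep = "\t",
                   quote = FALSE, row.names = FALSE)
for (pid in names(matrices))
  clone_tree_newick(build_clone_tree(matrices[[pid]]),
                    file.path(outdir, "trees", paste0(pid, ".nwk")))

cat(sprintf("Classified %d patients; labels and %d clone trees in %s\n",
            nrow(labels), length(matrices), outdir))
print(table(labels$pt_tt_pattern))
print(table(labels$tt_topology))
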