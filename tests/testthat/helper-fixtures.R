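# Shared fixtures: tiny call tables and mutation matrices built in code.

# one long-format call row per caller in `callers`
make_calls <- function(callers, patient = "P1", sample = "S1",
                       chrom = "chr3", pos = 10191L, ref = "C", alt = "T",
                       gene = "VHL", vclass = "nonsynonymous_SNV") {
  data.frame(patient_id = patient, sample_id = sample, caller = callers,
             chrom = chrom, pos = pos, ref = ref, alt = alt, gene = gene,
             variant_class = vclass, stringsAsFactors = FALSE)
}

# build a mutation_matrix from named gene-set profiles; roles parallel to
# profiles (defaults: first sample PT, the rest TT)
matrix_from_profiles <- function(profiles, roles = NULL, patient = "P1") {
  if (is.null(roles))
    roles <- c("PT", rep("TT", length(profiles) - 1L))
  genes <- sort(unique(unlist(profiles)))
  calls <- do.call(rbind, lapply(names(profiles), function(s) {
    p <- profiles[[s]]
    if (length(p) == 0L) return(NULL)
    i <- match(p, genes)
    data.frame(patient_id = patient, sample_id = s,
               chrom = paste0("chr", i), pos = 1000L + i,
               ref = "A", alt = "G", gene = p,
               variant_class = "nonsynonymous_SNV", stringsAsFactors = FALSE)
  }))
  if (is.null(calls)) calls <- thrombevo:::empty_call_table()
  role_tab <- data.frame(sample_id = names(profiles), role = roles,
                         stringsAsFactors = FALSE)
  build_mutation_matrix(calls, driver_list = if (length(genes)) genes else "VHL",
                        roles = role_tab, granularity = "gene")
}

# random family of subset-structured profiles over a small alphabet
random_profiles <- function(n_samples, alphabet = LETTERS[1:8],
                            p_member = 0.4) {
  profs <- lapply(seq_len(n_samples), function(i) {
    alphabet[stats::runif(length(alphabet)) < p_member]
  })
  stats::setNames(profs, paste0("S", seq_len(n_samples)))
}
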