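#' Run the full analysis chain on a simulated cohort
#'
#' Chains the pipeline stages end to end: multi-caller merge, K-of-N
#' consensus retention, variant-class filtering, driver-matrix
#' construction, per-patient pattern/topology classification and cohort
#' summary. Operates on a `sim_cohort` (or any object with `caller_calls`
#' and `sample_roles` tables plus a driver list in its config).
#'
#' @param cohort a [simulate_cohort()] result.
#' @param min_callers consensus threshold (default 3).
#' @param granularity profile granularity for matrices and classification.
#' @param use_truth_calls classify from the noise-free truth calls instead
#'   of the noisy per-caller tables (consensus is skipped); used for
#'   recovery checks at noise level zero.
#' @param verbose log per-stage counts.
#' @return list with `retained` (call table after consensus and class
#'   filter), `matrices`, `labels` (per-patient classification), `summary`
#'   (a `cohort_summary`) and `additional_tt` (output of
#'   [fraction_with_additional_drivers()]).
#' @examples
#' co <- simulate_cohort(sim_config(seed = 11), 6)
#' res <- run_pipeline(co)
#' res$labels
#' @export
run_pipeline <- function(cohort, min_callers = 3L,
                         granularity = c("variant", "gene"),
                         use_truth_calls = FALSE, verbose = FALSE) {
  granularity <- match.arg(granularity)
  retained <- if (use_truth_calls) {
    filter_variant_classes(cohort$truth_calls)
  } else {
    consensus_calls(cohort$caller_calls, min_callers = min_callers,
                    verbose = verbose)
  }
  matrices <- build_mutation_matrices(
    retained, cohort$config$driver_list, cohort$sample_roles, granularity)
  labels <- classify_cohort(matrices)
  list(retained = retained, matrices = matrices, labels = labels,
       summary = summarize_patterns(labels),
       additional_tt = fraction_with_additional_drivers(labels))
}

#' Label recovery against simulation truth
#'
#' Joins classified labels with a cohort's truth table and reports the
#' fraction of patients whose PT-TT pattern, and (where defined) thrombus
#' topology, were recovered.
#'
#' @param labels classified label table.
#' @param truth cohort truth table (`patient_id`, `true_pt_tt_pattern`,
#'   `true_tt_topology`).
#' @return list: `n`, `pattern_recovery`, `topology_recovery`,
#'   `both_recovery` (fractions in \[0, 1\]), and the joined table.
#' @export
label_recovery <- function(labels, truth) {
  joined <- merge(labels, truth, by = "patient_id")
  stopifnot(nrow(joined) == nrow(labels))
  pat_ok <- joined$pt_tt_pattern == joined$true_pt_tt_pattern
  topo_ok <- joined$tt_topology == joined$true_tt_topology
  list(n = nrow(joined),
       pattern_recovery = mean(pat_ok),
       topology_recovery = mean(topo_ok),
       both_recovery = mean(pat_ok & topo_ok),
       table = joined)
}
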