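# Rule-based classification of clonal-evolution patterns.
#
# Patterns are formalized as set-containment relations between the
# patient-level primary-tumor profile P (union over PT samples) and the
# thrombus profile T (union over TT samples):
#
#   coevolution  P == T (non-empty)  - identical driver profiles
#   private_pt   T strictly within P - drivers private to the primary
#   private_tt   P strictly within T - drivers private to the thrombus
#   divergent    both P\T and T\P non-empty - independent driver acquisition
#   no_driver    P and T both empty
#
# Thrombus topology, for patients with >= 2 TT samples, from the set D of
# distinct TT sample profiles:
#
#   linear_homogeneous    |D| == 1
#   linear_heterogeneous  |D| >= 2, totally ordered by inclusion
#   branched_heterogeneous some pair in D incomparable under inclusion
#
# The narrative descriptions in the literature are figure-level; these
# containment rules are the minimal formalization consistent with them.

set_equal <- function(a, b) length(a) == length(b) && setequal(a, b)
is_subset <- function(a, b) all(a %in% b)

#' Classify the PT-TT clonal-evolution pattern of one patient
#'
#' Compares the union driver profile of the primary tumor (P) with that of
#' the tumor thrombus (T) under set containment; see the package vignette
#' for the exact rules.
#'
#' @param matrix a [build_mutation_matrix()] result with at least one PT
#'   and one TT sample.
#' @param granularity profile granularity (defaults to the matrix's own).
#' @return one of `"divergent"`, `"private_pt"`, `"private_tt"`,
#'   `"coevolution"`, `"no_driver"`.
#' @export
classify_pt_tt <- function(matrix, granularity = NULL) {
  stopifnot(inherits(matrix, "mutation_matrix"))
  if (length(pt_samples(matrix)) == 0L) stop("patient has no PT sample")
  if (length(tt_samples(matrix)) == 0L) stop("patient has no TT sample")
  P <- pt_profile(matrix, granularity)
  T_ <- tt_profile(matrix, granularity)
  if (length(P) == 0L && length(T_) == 0L) return("no_driver")
  if (set_equal(P, T_)) return("coevolution")
  if (is_subset(T_, P)) return("private_pt")
  if (is_subset(P, T_)) return("private_tt")
  "divergent"
}

#' Classify the thrombus topology of one patient
#'
#' Inspects the distinct driver profiles of the TT samples. All identical:
#' linear homogeneous. Distinct but totally ordered by set inclusion
#' (stepwise accumulation): linear heterogeneous. Any incomparable pair
#' (distinct private mutations on separate branches): branched
#' heterogeneous. Patients with fewer than two TT samples are labeled
#' `"undefined"`, not an error.
#'
#' Spatial order along the thrombus (adjacent, middle, distal) is not
#' required to coincide with the inclusion order; only the inclusion
#' structure matters.
#'
#' @inheritParams classify_pt_tt
#' @return one of `"branched_heterogeneous"`, `"linear_homogeneous"`,
#'   `"linear_heterogeneous"`, `"undefined"`.
#' @export
classify_tt_topology <- function(matrix, granularity = NULL) {
  stopifnot(inherits(matrix, "mutation_matrix"))
  ids <- tt_samples(matrix)
  if (length(ids) < 2L) return("undefined")
  profiles <- lapply(ids, sample_profile, matrix = matrix,
                     granularity = granularity)
  D <- unique(profiles)
  if (length(D) == 1L) return("linear_homogeneous")
  for (i in seq_along(D)) for (j in seq_along(D)) {
    if (i < j && !is_subset(D[[i]], D[[j]]) && !is_subset(D[[j]], D[[i]]))
      return("branched_heterogeneous")
  }
  "linear_heterogeneous"
}

#' Does the thrombus carry drivers absent from the primary?
#'
#' TRUE when the union TT profile contains any element missing from the
#' union PT profile. With `relative_to = "adjacent"` the comparison is
#' against the thrombus sample adjacent to the primary (TT_A) instead of
#' the primary itself.
#'
#' @inheritParams classify_pt_tt
#' @param relative_to `"pt"` (default) or `"adjacent"`.
#' @return logical.
#' @export
flag_additional_tt_drivers <- function(matrix, granularity = NULL,
                                       relative_to = c("pt", "adjacent")) {
  relative_to <- match.arg(relative_to)
  stopifnot(inherits(matrix, "mutation_matrix"))
  T_ <- tt_profile(matrix, granularity)
  base <- if (relative_to == "pt") {
    pt_profile(matrix, granularity)
  } else {
    adj <- matrix$samples$sample_id[matrix$samples$role == "TT_A"]
    if (length(adj) == 0L) stop("no TT_A sample for relative_to = 'adjacent'")
    sort(unique(unlist(lapply(adj, sample_profile, matrix = matrix,
                              granularity = granularity))))
  }
  length(setdiff(T_, base)) > 0L
}

#' Classify one patient into its full evolution-pattern label
#'
#' @inheritParams classify_pt_tt
#' @return one-row data.frame: `patient_id`, `pt_tt_pattern`,
#'   `tt_topology`, `has_additional_tt_drivers`, `n_tt_samples`.
#' @export
classify_patient <- function(matrix, granularity = NULL) {
  data.frame(
    patient_id = matrix$patient_id,
    pt_tt_pattern = classify_pt_tt(matrix, granularity),
    tt_topology = classify_tt_topology(matrix, granularity),
    has_additional_tt_drivers = flag_additional_tt_drivers(matrix, granularity),
    n_tt_samples = length(tt_samples(matrix)),
    stringsAsFactors = FALSE)
}

#' Classify every patient of a cohort
#'
#' @param matrices list of `mutation_matrix` (see
#'   [build_mutation_matrices()]).
#' @inheritParams classify_pt_tt
#' @return data.frame of per-patient labels (one row per patient).
#' @export
classify_cohort <- function(matrices, granularity = NULL) {
  out <- do.call(rbind, lapply(matrices, classify_patient, granularity = granularity))
  rownames(out) <- NULL
  out
}
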