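# Consensus retention of somatic variants across a caller ensemble.
#
# A candidate somatic mutation is kept only when at least `min_callers` of
# the ensemble report it (default 3 of 7). Variant identity for consensus is
# the exact key (chrom, pos, ref, alt) within a sample; no indel
# normalization or fuzzy matching is attempted.

variant_key <- function(chrom, pos, ref, alt) {
  paste(chrom, pos, ref, alt, sep = ":")
}

check_call_columns <- function(calls, need_caller = FALSE) {
  need <- c("patient_id", "sample_id", "chrom", "pos", "ref", "alt",
            "gene", "variant_class", if (need_caller) "caller")
  miss <- setdiff(need, names(calls))
  if (length(miss))
    stop("call table is missing columns: ", paste(miss, collapse = ", "))
  if (nrow(calls) > 0L) {
    if (any(calls$pos < 1L)) stop("positions must be 1-based (pos >= 1)")
    if (any(calls$ref == calls$alt)) stop("ref and alt alleles must differ")
  }
  invisible(calls)
}

#' Merge per-caller call tables into one table with supporting-caller sets
#'
#' Takes the union of all per-caller calls and accumulates, for each unique
#' variant key `(patient, sample, chrom, pos, ref, alt)`, the set of callers
#' that reported it. If callers disagree on the gene or variant-class
#' annotation of the same key, the first-seen annotation wins and a warning
#' is issued.
#'
#' @param calls per-caller call table (long format, one row per caller per
#'   call) with columns `patient_id, sample_id, caller, chrom, pos, ref,
#'   alt, gene, variant_class`; or a list of such tables, which are
#'   concatenated first.
#' @return merged call table, one row per unique variant key, with
#'   `supporting_callers` (semicolon-joined caller names) and `n_callers`
#'   columns in place of `caller`.
#' @examples
#' calls <- data.frame(patient_id = "P1", sample_id = "S1",
#'                     caller = c("MuTect", "Strelka"), chrom = "chr3",
#'                     pos = 10191, ref = "C", alt = "T",
#'                     gene = "VHL", variant_class = "nonsynonymous_SNV")
#' merge_caller_calls(calls)$n_callers
#' @export
merge_caller_calls <- function(calls) {
  if (is.list(calls) && !is.data.frame(calls))
    calls <- do.call(rbind, calls)
  if (is.null(calls)) calls <- empty_call_table(with_caller = TRUE)
  check_call_columns(calls, need_caller = TRUE)
  out_cols <- c("patient_id", "sample_id", "chrom", "pos", "ref", "alt",
                "gene", "variant_class", "supporting_callers", "n_callers")
  if (nrow(calls) == 0L) {
    out <- calls[, c("patient_id", "sample_id", "chrom", "pos", "ref",
                     "alt", "gene", "variant_class")]
    out$supporting_callers <- character()
    out$n_callers <- integer()
    return(out[, out_cols])
  }
  if (anyDuplicated(calls[, c("patient_id", "sample_id", "caller",
                              "chrom", "pos", "ref", "alt")]))
    calls <- calls[!duplicated(calls[, c("patient_id", "sample_id", "caller",
                                         "chrom", "pos", "ref", "alt")]), ]
  key <- paste(calls$patient_id, calls$sample_id,
               variant_key(calls$chrom, calls$pos, calls$ref, calls$alt),
               sep = "\r")
  first <- !duplicated(key)
  merged <- calls[first, c("patient_id", "sample_id", "chrom", "pos",
                           "ref", "alt", "gene", "variant_class")]
  # annotation conflicts: same key, different gene/class than first-seen
  ann <- paste(calls$gene, calls$variant_class, sep = "\r")
  first_ann <- ann[first][match(key, key[first])]
  if (any(ann != first_ann))
    warning(sum(ann != first_ann & !duplicated(paste(key, ann))),
            " conflicting gene/class annotation(s); first-seen kept")
  support <- split(calls$caller, factor(key, levels = key[first]))
  merged$supporting_callers <- vapply(
    support, function(s) paste(sort(unique(s)), collapse = ";"), character(1))
  merged$n_callers <- vapply(support, function(s) length(unique(s)), integer(1))
  rownames(merged) <- NULL
  merged[, out_cols]
}

#' Retain variants called by at least K callers
#'
#' The consensus retention rule: a mutation is kept when it was reported by
#' at least `min_callers` of the ensemble (default 3, against the 7-caller
#' panel). Row order is preserved.
#'
#' @param merged output of [merge_caller_calls()].
#' @param min_callers minimum supporting-caller count (>= 1).
#' @param caller_count optional ensemble size; when `min_callers` exceeds
#'   it, a warning is issued and the result is empty.
#' @return the retained subset of `merged`.
#' @export
retain_consensus <- function(merged, min_callers = 3L, caller_count = NULL) {
  min_callers <- as.integer(min_callers)
  if (is.na(min_callers) || min_callers < 1L) stop("min_callers must be >= 1")
  if (!"n_callers" %in% names(merged))
    stop("input must be a merged call table (see merge_caller_calls)")
  if (!is.null(caller_count) && min_callers > caller_count) {
    warning("min_callers (", min_callers, ") exceeds ensemble size (",
            caller_count, "); no variant can be retained")
  }
  out <- merged[merged$n_callers >= min_callers, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Filter calls to the retained variant classes
#'
#' Keeps only calls whose `variant_class` is in the inclusion list
#' (default [retained_variant_classes()]): frameshift/non-frameshift
#' substitutions, stop gain/loss, splicing, non-synonymous SNVs and known
#' mutations. Class labels outside the recognized vocabulary are reported
#' via a message and treated as not allowed.
#'
#' @param calls a call table with a `variant_class` column.
#' @param allowed_classes non-empty character vector of class labels to keep.
#' @return the filtered table.
#' @export
filter_variant_classes <- function(calls,
                                   allowed_classes = retained_variant_classes()) {
  if (length(allowed_classes) == 0L) stop("allowed_classes must be non-empty")
  if (!"variant_class" %in% names(calls)) stop("missing variant_class column")
  unknown <- setdiff(unique(calls$variant_class), variant_class_vocabulary())
  if (length(unknown))
    message("unrecognized variant class label(s), dropped: ",
            paste(unknown, collapse = ", "))
  out <- calls[calls$variant_class %in% allowed_classes, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Run the full consensus stage
#'
#' Convenience wrapper chaining [merge_caller_calls()], [retain_consensus()]
#' and [filter_variant_classes()], logging in/out counts per stage.
#'
#' @inheritParams merge_caller_calls
#' @inheritParams retain_consensus
#' @inheritParams filter_variant_classes
#' @param verbose print per-stage counts.
#' @return retained, class-filtered call table.
#' @export
consensus_calls <- function(calls, min_callers = 3L,
                            allowed_classes = retained_variant_classes(),
                            verbose = FALSE) {
  merged <- merge_caller_calls(calls)
  kept <- retain_consensus(merged, min_callers)
  filtered <- filter_variant_classes(kept, allowed_classes)
  if (verbose)
    message(sprintf("consensus: %d raw -> %d merged -> %d retained (>=%d callers) -> %d class-filtered",
                    nrow(calls), nrow(merged), nrow(kept), min_callers,
                    nrow(filtered)))
  stopifnot(nrow(merged) >= nrow(kept), nrow(kept) >= nrow(filtered))
  filtered
}
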