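#' Driver-gene pool and shared vocabularies
#'
#' The evolution-pattern analysis is restricted to a curated list of 332
#' cancer driver genes. The full published list lives in controlled-access
#' supplementary material, so the bundled pool is synthetic: its first
#' entries are the clear-cell RCC drivers that are named in the literature
#' (VHL, PBRM1, BAP1, SETD2, ...) and the remainder are placeholder symbols
#' \code{DRV013 ... DRV332}. Any character vector of gene symbols can be
#' supplied instead wherever a \code{driver_list} argument is accepted.
#'
#' @param n pool size (default 332).
#' @return character vector of \code{n} gene symbols.
#' @examples
#' head(driver_gene_pool(), 15)
#' @export
driver_gene_pool <- function(n = 332L) {
  n <- as.integer(n)
  stopifnot(n >= 1L)
  seed_genes <- c("VHL", "PBRM1", "BAP1", "SETD2", "TP53", "PTEN",
                  "MTOR", "KDM5C", "TSC1", "TSC2", "ARID1A", "CSMD3")
  if (n <= length(seed_genes)) return(seed_genes[seq_len(n)])
  c(seed_genes, sprintf("DRV%03d", seq.int(length(seed_genes) + 1L, n)))
}

#' Default somatic caller panel
#'
#' The seven-caller ensemble used for consensus retention. If more than
#' seven simulated callers are requested the panel is extended with
#' generic names.
#'
#' @param n number of callers.
#' @return character vector of caller names.
#' @export
caller_panel <- function(n = 7L) {
  n <- as.integer(n)
  stopifnot(n >= 1L)
  base <- c("MuTect", "VarScan", "Shimmer", "SpeedSeq",
            "Manta", "Strelka", "Lofreq")
  if (n <= length(base)) return(base[seq_len(n)])
  c(base, sprintf("Caller%02d", seq.int(length(base) + 1L, n)))
}

#' Variant classes retained for driver-matrix construction
#'
#' The inclusion list used when building mutation matrices: frameshift and
#' non-frameshift substitutions, stop gain/loss, splicing mutations,
#' non-synonymous SNVs, and annotated known mutations. "known" is a
#' pass-through label taken from the input annotation, not computed from a
#' hotspot database.
#'
#' @return character vector of class labels.
#' @export
retained_variant_classes <- function() {
  c("frameshift_substitution", "nonframeshift_substitution",
    "stopgain", "stoploss", "splicing", "nonsynonymous_SNV", "known")
}

# Full vocabulary of class labels the pipeline recognizes; anything outside
# it in an input table is reported as unknown (and never retained).
variant_class_vocabulary <- function() {
  c(retained_variant_classes(), "synonymous_SNV", "UTR", "intronic")
}

#' Sample-role vocabulary
#'
#' Roles used in multi-region sampling: primary tumor (PT, possibly
#' multi-sampled), directional tumor-thrombus samples (TT_A adjacent,
#' TT_M middle, TT_D distal, plus generic TT), metastasis (MET) and
#' matched normal (NORMAL).
#'
#' @return character vector of role labels.
#' @export
sample_roles <- function() {
  c("PT", "TT_A", "TT_M", "TT_D", "TT", "MET", "NORMAL")
}

# role predicates used throughout classification
is_pt_role <- function(role) role == "PT"
is_tt_role <- function(role) grepl("^TT", role)

#' PT-TT clonal-evolution pattern labels
#' @return character vector of the recognized pattern labels.
#' @export
pt_tt_patterns <- function() {
  c("divergent", "private_pt", "private_tt", "coevolution", "no_driver")
}

#' Tumor-thrombus topology labels
#' @return character vector of the recognized topology labels.
#' @export
tt_topologies <- function() {
  c("branched_heterogeneous", "linear_homogeneous",
    "linear_heterogeneous", "undefined")
}
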