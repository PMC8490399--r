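# Interchange formats. Two equivalent representations of per-caller calls
# are supported: one consolidated TSV (long format, one row per caller per
# call) and a minimal VCF 4.2 subset (one file per sample per caller, with
# patient/sample/caller carried in header meta-lines and gene / variant
# class in the INFO keys GENE= and VCLASS=). Coordinates are 1-based
# throughout.

#' Write per-caller calls as a consolidated TSV
#'
#' @param calls long-format call table (`patient_id, sample_id, caller,
#'   chrom, pos, ref, alt, gene, variant_class`).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_calls_tsv <- function(calls, path) {
  check_call_columns(calls, need_caller = TRUE)
  cols <- c("patient_id", "sample_id", "caller", "chrom", "pos", "ref",
            "alt", "gene", "variant_class")
  utils::write.table(calls[, cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_calls_tsv
#' @export
read_calls_tsv <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           colClasses = c(pos = "integer"),
                           stringsAsFactors = FALSE)
  check_call_columns(tab, need_caller = TRUE)
  tab
}

#' Write one sample's calls from one caller as minimal VCF 4.2
#'
#' Emits `##fileformat=VCFv4.2` with `##patient=`, `##sample=` and
#' `##caller=` meta-lines, INFO keys `GENE=` and `VCLASS=`, and the
#' standard 8 columns.
#'
#' @param calls call table for a single (patient, sample, caller).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_variant_vcf <- function(calls, path) {
  check_call_columns(calls, need_caller = TRUE)
  stopifnot(nrow(calls) >= 1L,
            length(unique(calls$sample_id)) == 1L,
            length(unique(calls$caller)) == 1L)
  header <- c(
    "##fileformat=VCFv4.2",
    paste0("##patient=", calls$patient_id[[1]]),
    paste0("##sample=", calls$sample_id[[1]]),
    paste0("##caller=", calls$caller[[1]]),
    "##INFO=<ID=GENE,Number=1,Type=String,Description=\"Gene symbol\">",
    "##INFO=<ID=VCLASS,Number=1,Type=String,Description=\"Variant class\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO"),
          collapse = "\t"))
  calls <- calls[order(calls$chrom, calls$pos), , drop = FALSE]
  body <- paste(calls$chrom, calls$pos, ".", calls$ref, calls$alt, ".",
                "PASS",
                paste0("GENE=", calls$gene, ";VCLASS=", calls$variant_class),
                sep = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}

#' @rdname write_variant_vcf
#' @return `read_variant_vcf` returns the call table reconstructed from the
#'   file.
#' @export
read_variant_vcf <- function(path) {
  lines <- readLines(path)
  meta <- lines[startsWith(lines, "##")]
  get_meta <- function(key) {
    m <- meta[startsWith(meta, paste0("##", key, "="))]
    if (length(m) != 1L) stop("missing ##", key, "= meta-line in ", path)
    sub(paste0("^##", key, "="), "", m)
  }
  body <- lines[!startsWith(lines, "#")]
  info_field <- function(info, key) {
    vapply(strsplit(info, ";", fixed = TRUE), function(kv) {
      hit <- kv[startsWith(kv, paste0(key, "="))]
      if (length(hit)) sub(paste0("^", key, "="), "", hit[[1]]) else NA_character_
    }, character(1))
  }
  if (length(body) == 0L) return(empty_call_table(with_caller = TRUE))
  parts <- do.call(rbind, strsplit(body, "\t", fixed = TRUE))
  info <- parts[, 8]
  data.frame(
    patient_id = get_meta("patient"),
    sample_id = get_meta("sample"),
    caller = get_meta("caller"),
    chrom = parts[, 1],
    pos = as.integer(parts[, 2]),
    ref = parts[, 4],
    alt = parts[, 5],
    gene = info_field(info, "GENE"),
    variant_class = info_field(info, "VCLASS"),
    stringsAsFactors = FALSE)
}

#' Write a simulated cohort to disk
#'
#' Emits the per-caller calls (one VCF per sample per caller, plus one
#' consolidated TSV), the sample-role table and the truth table of a
#' [simulate_cohort()] result.
#'
#' @param cohort a `sim_cohort`.
#' @param dir output directory.
#' @param vcf also write the per-sample-per-caller VCFs (default TRUE).
#' @return invisibly, the output directory.
#' @export
write_cohort <- function(cohort, dir, vcf = TRUE) {
  stopifnot(inherits(cohort, "sim_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_calls_tsv(cohort$caller_calls, file.path(dir, "caller_calls.tsv"))
  utils::write.table(cohort$sample_roles, file.path(dir, "sample_roles.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(cohort$truth, file.path(dir, "truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (vcf) {
    vdir <- file.path(dir, "vcf")
    dir.create(vdir, showWarnings = FALSE)
    cc <- cohort$caller_calls
    for (grp in split(cc, list(cc$sample_id, cc$caller), drop = TRUE)) {
      if (nrow(grp) == 0L) next
      write_variant_vcf(
        grp, file.path(vdir, paste0(grp$sample_id[[1]], ".",
                                    grp$caller[[1]], ".vcf")))
    }
  }
  invisible(dir)
}
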