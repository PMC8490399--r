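# Arm-level copy number from gene-level copy ratios.
#
# Gene-level log2 copy ratios (CNVkit-style gene metrics, with bin-derived
# weights) are converted to absolute copy numbers against a diploid
# reference, cn = 2 * 2^log2_ratio, and averaged per chromosome arm with the
# gene weights. The arm estimate is clipped to [0, 4] (normal = 2). Two
# calling rules are provided: the threshold rule on the arm-level estimate
# (loss <= 1, gain >= 3, both inclusive) and the fraction rule (call when
# more than 50% of the arm's weight sits in gained/lost genes).

check_gene_copy <- function(records) {
  need <- c("gene", "arm", "weight", "log2_ratio")
  miss <- setdiff(need, names(records))
  if (length(miss))
    stop("gene copy table is missing columns: ", paste(miss, collapse = ", "))
  if (nrow(records) > 0L) {
    if (any(records$weight < 0)) stop("weights must be >= 0")
    if (!all(grepl("^(chr)?[0-9XY]+[pq]$", records$arm)))
      stop("arm labels must look like 3p / 5q / 14q")
  }
  invisible(records)
}

#' Gene copy number from log2 ratio
#'
#' `cn = 2 * 2^log2_ratio`: the standard diploid-reference conversion of a
#' log2 copy ratio to an absolute copy number.
#'
#' @param log2_ratio numeric vector of log2 copy ratios.
#' @return numeric vector of copy numbers (>= 0).
#' @export
gene_copy_number <- function(log2_ratio) 2 * 2^log2_ratio

#' Arm-level copy number by weighted averaging
#'
#' For the gene records of one sample and one chromosome arm, the arm-level
#' copy number is the weight-averaged gene copy number,
#' `sum(w * cn) / sum(w)`, clipped to the reportable range \[0, 4\]
#' (normal = 2). The unclipped value is returned as an attribute for
#' diagnostics.
#'
#' @param records data.frame with columns `gene, arm, weight, log2_ratio`
#'   (one sample, one arm).
#' @return arm copy number in \[0, 4\], with attribute `raw` (unclipped);
#'   `NA` with a warning when the total weight is zero (no-call).
#' @examples
#' arm_copy_number(data.frame(gene = c("VHL", "PBRM1"), arm = "3p",
#'                            weight = c(1, 3), log2_ratio = c(-Inf, 0)))
#' @export
arm_copy_number <- function(records) {
  check_gene_copy(records)
  if (nrow(records) == 0L || sum(records$weight) <= 0) {
    warning("zero total weight: arm reported as no-call")
    return(structure(NA_real_, raw = NA_real_))
  }
  if (length(unique(records$arm)) > 1L)
    stop("records span multiple arms; call per arm (see arm_copy_table)")
  cn <- gene_copy_number(records$log2_ratio)
  raw <- sum(records$weight * cn) / sum(records$weight)
  structure(min(4, max(0, raw)), raw = raw)
}

#' Threshold rule: loss/neutral/gain from the arm-level estimate
#'
#' Loss is called when the arm-level copy number is <= 1 and gain when it is
#' >= 3 (both boundaries inclusive); otherwise neutral.
#'
#' @param cn_arm numeric vector of arm-level copy numbers.
#' @return character vector in `{loss, neutral, gain}` (`NA` propagates).
#' @export
call_arm_threshold <- function(cn_arm) {
  out <- ifelse(cn_arm <= 1, "loss", ifelse(cn_arm >= 3, "gain", "neutral"))
  out[is.na(cn_arm)] <- NA_character_
  out
}

#' Fraction rule: call when >50% of the arm is gained or lost
#'
#' Each gene is first called individually (gain if its copy number >= 3,
#' loss if <= 1). The arm is called gained (lost) when strictly more than
#' half of the arm's total gene weight is in gained (lost) genes; ties and
#' everything else are neutral.
#'
#' @inheritParams arm_copy_number
#' @return one of `"loss"`, `"neutral"`, `"gain"`, or `NA` on zero total
#'   weight (no-call, with a warning).
#' @export
call_arm_fraction <- function(records) {
  check_gene_copy(records)
  w <- sum(records$weight)
  if (nrow(records) == 0L || w <= 0) {
    warning("zero total weight: arm reported as no-call")
    return(NA_character_)
  }
  cn <- gene_copy_number(records$log2_ratio)
  frac_gain <- sum(records$weight[cn >= 3]) / w
  frac_loss <- sum(records$weight[cn <= 1]) / w
  if (frac_gain > 0.5) "gain" else if (frac_loss > 0.5) "loss" else "neutral"
}

#' Arm-level copy-number table for one or more samples
#'
#' Applies [arm_copy_number()] and both calling rules to every
#' (sample, arm) group of a gene-level table.
#'
#' @param records data.frame with columns `sample_id, gene, arm, weight,
#'   log2_ratio`.
#' @param rule which rule supplies the `call` column: `"threshold"`
#'   (default) or `"fraction"`.
#' @return data.frame with one row per (sample, arm): `cn_arm`,
#'   `cn_arm_raw` (unclipped), `frac_gain`, `frac_loss`, `call`,
#'   `rule_used`.
#' @export
arm_copy_table <- function(records, rule = c("threshold", "fraction")) {
  rule <- match.arg(rule)
  if (!"sample_id" %in% names(records)) stop("missing sample_id column")
  check_gene_copy(records)
  groups <- split(records, list(records$sample_id, records$arm), drop = TRUE)
  rows <- lapply(groups, function(g) {
    w <- sum(g$weight)
    if (w <= 0) {
      cn <- NA_real_; raw <- NA_real_; fg <- NA_real_; fl <- NA_real_
      call <- NA_character_
      warning("zero total weight for ", g$sample_id[[1]], " ", g$arm[[1]],
              ": no-call")
    } else {
      cn_g <- gene_copy_number(g$log2_ratio)
      raw <- sum(g$weight * cn_g) / w
      cn <- min(4, max(0, raw))
      fg <- sum(g$weight[cn_g >= 3]) / w
      fl <- sum(g$weight[cn_g <= 1]) / w
      call <- if (rule == "threshold") call_arm_threshold(cn)
              else if (fg > 0.5) "gain" else if (fl > 0.5) "loss" else "neutral"
    }
    data.frame(sample_id = g$sample_id[[1]], arm = g$arm[[1]],
               cn_arm = cn, cn_arm_raw = raw, frac_gain = fg, frac_loss = fl,
               call = call, rule_used = rule, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$sample_id, out$arm), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Cohort arm-call matrix and alteration frequencies
#'
#' Pivots per-sample arm calls into an arm-by-sample matrix and computes,
#' per arm, the fraction of informative samples (non-missing call) carrying
#' each alteration.
#'
#' @param estimates output of [arm_copy_table()] (possibly concatenated
#'   over samples).
#' @return list with `calls` (arm x sample character matrix) and
#'   `frequencies` (data.frame: arm, n_samples, frac_loss, frac_neutral,
#'   frac_gain).
#' @export
cohort_arm_matrix <- function(estimates) {
  if (nrow(estimates) == 0L)
    return(list(calls = matrix(character(), 0, 0),
                frequencies = data.frame(arm = character(),
                                         n_samples = integer(),
                                         frac_loss = numeric(),
                                         frac_neutral = numeric(),
                                         frac_gain = numeric())))
  arms <- sort(unique(estimates$arm))
  samples <- sort(unique(estimates$sample_id))
  calls <- matrix(NA_character_, length(arms), length(samples),
                  dimnames = list(arms, samples))
  calls[cbind(match(estimates$arm, arms),
              match(estimates$sample_id, samples))] <- estimates$call
  freq <- do.call(rbind, lapply(arms, function(a) {
    v <- calls[a, ]
    v <- v[!is.na(v)]
    n <- length(v)
    data.frame(arm = a, n_samples = n,
               frac_loss = if (n) mean(v == "loss") else NA_real_,
               frac_neutral = if (n) mean(v == "neutral") else NA_real_,
               frac_gain = if (n) mean(v == "gain") else NA_real_,
               stringsAsFactors = FALSE)
  }))
  rownames(freq) <- NULL
  list(calls = calls, frequencies = freq)
}
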