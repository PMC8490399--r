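# Cohort-level summaries: evolution-pattern proportions and PT/TT grade
# discordance. Percentages are reported both at one decimal and rounded to
# the nearest integer; the denominator is always carried alongside, because
# topology percentages run over the subset of patients with >= 2 TT samples
# while PT-TT pattern percentages run over all classified patients.

count_table <- function(x, levels, denom) {
  n <- as.integer(table(factor(x, levels = levels)))
  data.frame(category = levels, n = n,
             denominator = denom,
             percent = round(100 * n / denom, 1),
             percent_int = as.integer(round(100 * n / denom)),
             stringsAsFactors = FALSE)
}

#' Summarize evolution-pattern labels over a cohort
#'
#' Tabulates the PT-TT patterns over all classified patients and the
#' thrombus topologies over the patients for which a topology is defined
#' (>= 2 TT samples). Counts are checked to sum to the respective
#' denominators.
#'
#' @param labels per-patient label table (see [classify_cohort()]); columns
#'   `pt_tt_pattern` and `tt_topology` are required.
#' @return object of class `cohort_summary`: list with `n_patients`,
#'   `n_topology` (patients with defined topology), `pt_tt` and
#'   `tt_topology` count/percent tables.
#' @examples
#' labels <- data.frame(
#'   pt_tt_pattern = c("divergent", "private_tt", "coevolution"),
#'   tt_topology = c("branched_heterogeneous", "linear_homogeneous",
#'                   "undefined"))
#' summarize_patterns(labels)
#' @export
summarize_patterns <- function(labels) {
  if (nrow(labels) == 0L) stop("empty label table")
  stopifnot(all(c("pt_tt_pattern", "tt_topology") %in% names(labels)))
  bad <- setdiff(labels$pt_tt_pattern, pt_tt_patterns())
  if (length(bad)) stop("unknown pattern label(s): ", paste(bad, collapse = ", "))
  bad <- setdiff(labels$tt_topology, tt_topologies())
  if (length(bad)) stop("unknown topology label(s): ", paste(bad, collapse = ", "))

  n <- nrow(labels)
  pt_tt <- count_table(labels$pt_tt_pattern, pt_tt_patterns(), n)
  topo <- labels$tt_topology[labels$tt_topology != "undefined"]
  n_topo <- length(topo)
  topo_tab <- if (n_topo > 0L) {
    count_table(topo, setdiff(tt_topologies(), "undefined"), n_topo)
  } else {
    count_table(character(), setdiff(tt_topologies(), "undefined"), NA_integer_)[0, ]
  }
  stopifnot(sum(pt_tt$n) == n, n_topo == 0L || sum(topo_tab$n) == n_topo)
  structure(list(n_patients = n, n_topology = n_topo,
                 pt_tt = pt_tt, tt_topology = topo_tab),
            class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat(sprintf("Cohort of %d classified patients (%d with defined TT topology)\n",
              x$n_patients, x$n_topology))
  cat("\nPT-TT patterns:\n"); print(x$pt_tt, row.names = FALSE)
  if (nrow(x$tt_topology)) {
    cat("\nTT topologies:\n"); print(x$tt_topology, row.names = FALSE)
  }
  invisible(x)
}

#' PT versus TT grade crosstab and discordance
#'
#' Grades are WHO/ISUP 1-4, taken as the highest-grade area of each
#' compartment. For each PT grade the discordance percent is the share of
#' patients whose thrombus is of strictly lower grade than the primary.
#'
#' @param grades data.frame with columns `patient_id`, `pt_grade`,
#'   `tt_grade` (integers 1-4).
#' @return list with `crosstab` (PT grade x TT grade contingency table) and
#'   `discordance` (per PT grade: n, n_tt_lower, percent, percent_int).
#' @examples
#' grade_discordance(data.frame(patient_id = c("a", "b", "c"),
#'                              pt_grade = c(3, 3, 4),
#'                              tt_grade = c(2, 3, 2)))$discordance
#' @export
grade_discordance <- function(grades) {
  if (nrow(grades) == 0L) stop("empty grade table")
  stopifnot(all(c("pt_grade", "tt_grade") %in% names(grades)))
  if (!all(grades$pt_grade %in% 1:4) || !all(grades$tt_grade %in% 1:4))
    stop("grades must be integers in 1..4")
  crosstab <- table(pt_grade = factor(grades$pt_grade, levels = 1:4),
                    tt_grade = factor(grades$tt_grade, levels = 1:4))
  disc <- do.call(rbind, lapply(1:4, function(g) {
    sub <- grades[grades$pt_grade == g, , drop = FALSE]
    n <- nrow(sub)
    k <- sum(sub$tt_grade < g)
    data.frame(pt_grade = g, n = n, n_tt_lower = k,
               percent = if (n) round(100 * k / n, 1) else NA_real_,
               percent_int = if (n) as.integer(round(100 * k / n)) else NA_integer_)
  }))
  list(crosstab = crosstab, discordance = disc)
}

#' Fraction of multi-TT patients whose thrombus gained drivers
#'
#' Over patients with a defined thrombus topology (>= 2 TT samples), the
#' percentage with any driver mutation in the thrombus that is absent from
#' the primary.
#'
#' @param labels label table with `tt_topology` and
#'   `has_additional_tt_drivers` columns.
#' @return list: `n` (denominator), `n_true`, `percent` (one decimal),
#'   `percent_int`.
#' @export
fraction_with_additional_drivers <- function(labels) {
  stopifnot(all(c("tt_topology", "has_additional_tt_drivers") %in% names(labels)))
  sub <- labels[labels$tt_topology != "undefined", , drop = FALSE]
  n <- nrow(sub)
  if (n == 0L) stop("no patients with >= 2 TT samples")
  k <- sum(sub$has_additional_tt_drivers)
  list(n = n, n_true = k, percent = round(100 * k / n, 1),
       percent_int = as.integer(round(100 * k / n)))
}

#' Write a cohort summary as TSV and JSON
#'
#' @param summary a `cohort_summary`.
#' @param dir output directory (created if absent).
#' @return invisibly, the paths written.
#' @export
write_cohort_summary <- function(summary, dir) {
  stopifnot(inherits(summary, "cohort_summary"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p1 <- file.path(dir, "pt_tt_patterns.tsv")
  p2 <- file.path(dir, "tt_topologies.tsv")
  p3 <- file.path(dir, "cohort_summary.json")
  utils::write.table(summary$pt_tt, p1, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(summary$tt_topology, p2, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  jsonlite::write_json(
    list(n_patients = summary$n_patients, n_topology = summary$n_topology,
         pt_tt = summary$pt_tt, tt_topology = summary$tt_topology),
    p3, auto_unbox = TRUE, digits = NA)
  invisible(c(p1, p2, p3))
}
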