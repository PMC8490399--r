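# Per-patient driver-mutation matrix: samples x driver genes, each cell
# holding the set of distinct retained variant keys in that gene.

#' Build a per-patient driver-mutation matrix
#'
#' Restricts retained, class-filtered calls to the driver-gene list and
#' organizes them as a samples-by-genes presence structure for one patient.
#' Cells hold the distinct variant keys (`chrom:pos:ref:alt`) observed for
#' that (sample, gene); an empty cell means no retained driver mutation.
#'
#' Sample profiles can be read off at two granularities: `"variant"`
#' (elements are `gene|chrom:pos:ref:alt` keys, the default) or `"gene"`
#' (multiple variants in one gene collapse to the gene symbol, the
#' granularity at which clone trees are usually drawn).
#'
#' @param calls retained call table for a single patient (see
#'   [consensus_calls()]); a `caller`/`supporting_callers` column is ignored.
#' @param driver_list character vector of driver gene symbols; calls in
#'   other genes are excluded.
#' @param roles data.frame with columns `sample_id`, `role` (see
#'   [sample_roles()]); defines the patient's sample set, including samples
#'   with no retained calls. NORMAL samples are dropped.
#' @param granularity default profile granularity, `"variant"` or `"gene"`.
#' @return an object of class `mutation_matrix`.
#' @export
build_mutation_matrix <- function(calls, driver_list, roles,
                                  granularity = c("variant", "gene")) {
  granularity <- match.arg(granularity)
  if (!all(c("sample_id", "role") %in% names(roles)))
    stop("roles needs sample_id and role columns")
  roles <- roles[!roles$role %in% "NORMAL", , drop = FALSE]
  if (nrow(roles) == 0L) stop("patient has no tumor samples")
  if (anyDuplicated(roles$sample_id))
    stop("duplicate sample_id in roles: ",
         paste(unique(roles$sample_id[duplicated(roles$sample_id)]),
               collapse = ", "))
  if (!all(roles$role %in% sample_roles()))
    stop("unknown sample role(s): ",
         paste(setdiff(roles$role, sample_roles()), collapse = ", "))
  check_call_columns(calls)
  patient_id <- unique(c(calls$patient_id,
                         if ("patient_id" %in% names(roles)) roles$patient_id))
  if (length(patient_id) > 1L)
    stop("build_mutation_matrix expects a single patient; got: ",
         paste(patient_id, collapse = ", "))
  if (length(patient_id) == 0L) patient_id <- NA_character_
  if (!all(calls$sample_id %in% roles$sample_id))
    stop("calls reference samples absent from roles: ",
         paste(setdiff(calls$sample_id, roles$sample_id), collapse = ", "))

  keep <- calls$gene %in% driver_list
  calls <- calls[keep, , drop = FALSE]
  entries <- if (nrow(calls) > 0L) {
    key <- variant_key(calls$chrom, calls$pos, calls$ref, calls$alt)
    agg <- stats::aggregate(
      list(variant_keys = key),
      by = list(sample_id = calls$sample_id, gene = calls$gene),
      FUN = function(k) paste(sort(unique(k)), collapse = ";"))
    agg[order(agg$sample_id, agg$gene), , drop = FALSE]
  } else {
    data.frame(sample_id = character(), gene = character(),
               variant_keys = character(), stringsAsFactors = FALSE)
  }
  rownames(entries) <- NULL

  structure(list(
    patient_id = patient_id,
    samples = roles[, c("sample_id", "role")],
    genes = sort(unique(entries$gene)),
    driver_list = driver_list,
    entries = entries,
    granularity = granularity), class = "mutation_matrix")
}

#' @export
print.mutation_matrix <- function(x, ...) {
  cat(sprintf("Mutation matrix for patient %s: %d samples, %d mutated driver genes (%s-level profiles)\n",
              x$patient_id, nrow(x$samples), length(x$genes), x$granularity))
  invisible(x)
}

#' Mutation profile of one sample
#'
#' The set of mutated elements in a sample at the requested granularity.
#'
#' @param matrix a `mutation_matrix`.
#' @param sample_id sample identifier (must appear in the matrix).
#' @param granularity `"variant"` or `"gene"`; defaults to the matrix's own.
#' @return sorted character vector (possibly empty).
#' @export
sample_profile <- function(matrix, sample_id, granularity = NULL) {
  stopifnot(inherits(matrix, "mutation_matrix"))
  if (!sample_id %in% matrix$samples$sample_id)
    stop("unknown sample: ", sample_id)
  granularity <- granularity %||% matrix$granularity
  e <- matrix$entries[matrix$entries$sample_id == sample_id, , drop = FALSE]
  if (nrow(e) == 0L) return(character())
  if (granularity == "gene") return(sort(unique(e$gene)))
  keys <- mapply(function(g, vk) {
    paste(g, strsplit(vk, ";", fixed = TRUE)[[1]], sep = "|")
  }, e$gene, e$variant_keys, SIMPLIFY = FALSE)
  sort(unique(unlist(keys)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# union profile over samples matching a role predicate
role_union_profile <- function(matrix, pred, granularity = NULL) {
  ids <- matrix$samples$sample_id[pred(matrix$samples$role)]
  sort(unique(unlist(lapply(ids, sample_profile, matrix = matrix,
                            granularity = granularity))))
}

#' Patient-level PT and TT profiles
#'
#' The primary-tumor profile is the union over all PT samples; the thrombus
#' profile is the union over all TT samples (TT_A/TT_M/TT_D/TT).
#'
#' @inheritParams sample_profile
#' @return sorted character vector.
#' @export
pt_profile <- function(matrix, granularity = NULL)
  role_union_profile(matrix, is_pt_role, granularity)

#' @rdname pt_profile
#' @export
tt_profile <- function(matrix, granularity = NULL)
  role_union_profile(matrix, is_tt_role, granularity)

# sample ids by role group
pt_samples <- function(matrix) matrix$samples$sample_id[is_pt_role(matrix$samples$role)]
tt_samples <- function(matrix) matrix$samples$sample_id[is_tt_role(matrix$samples$role)]

#' Build mutation matrices for every patient in a call table
#'
#' @param calls retained multi-patient call table.
#' @param driver_list driver gene symbols.
#' @param roles sample-role table with `patient_id`, `sample_id`, `role`.
#' @inheritParams build_mutation_matrix
#' @return named list of `mutation_matrix`, one per patient in `roles`.
#' @export
build_mutation_matrices <- function(calls, driver_list, roles,
                                    granularity = c("variant", "gene")) {
  granularity <- match.arg(granularity)
  stopifnot("patient_id" %in% names(roles))
  pids <- unique(roles$patient_id)
  out <- lapply(pids, function(p) {
    build_mutation_matrix(
      calls[calls$patient_id == p, , drop = FALSE], driver_list,
      roles[roles$patient_id == p, , drop = FALSE], granularity)
  })
  stats::setNames(out, pids)
}

#' Write / read a mutation matrix as TSV
#'
#' One row per (patient, sample, gene) with semicolon-joined variant keys;
#' samples without driver mutations are carried as rows with an empty gene
#' so the sample set round-trips losslessly.
#'
#' @param matrix a `mutation_matrix`.
#' @param path file path.
#' @return `write_mutation_matrix` returns `path` invisibly;
#'   `read_mutation_matrix` returns a `mutation_matrix`.
#' @export
write_mutation_matrix <- function(matrix, path) {
  stopifnot(inherits(matrix, "mutation_matrix"))
  e <- matrix$entries
  covered <- unique(e$sample_id)
  extra <- matrix$samples[!matrix$samples$sample_id %in% covered, , drop = FALSE]
  rows <- rbind(
    if (nrow(e)) data.frame(
      patient_id = matrix$patient_id, sample_id = e$sample_id,
      role = matrix$samples$role[match(e$sample_id, matrix$samples$sample_id)],
      gene = e$gene, variant_keys = e$variant_keys, stringsAsFactors = FALSE),
    if (nrow(extra)) data.frame(
      patient_id = matrix$patient_id, sample_id = extra$sample_id,
      role = extra$role, gene = "", variant_keys = "",
      stringsAsFactors = FALSE))
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_mutation_matrix
#' @param driver_list driver list to attach on read (defaults to the genes
#'   present in the file).
#' @param granularity profile granularity to attach on read.
#' @export
read_mutation_matrix <- function(path, driver_list = NULL,
                                 granularity = c("variant", "gene")) {
  granularity <- match.arg(granularity)
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           colClasses = "character", na.strings = NULL)
  stopifnot(all(c("patient_id", "sample_id", "role", "gene",
                  "variant_keys") %in% names(tab)))
  pid <- unique(tab$patient_id)
  stopifnot(length(pid) == 1L)
  roles <- unique(tab[, c("sample_id", "role")])
  has_mut <- nzchar(tab$gene)
  entries <- tab[has_mut, c("sample_id", "gene", "variant_keys")]
  entries <- entries[order(entries$sample_id, entries$gene), , drop = FALSE]
  rownames(entries) <- NULL
  structure(list(
    patient_id = pid,
    samples = roles,
    genes = sort(unique(entries$gene)),
    driver_list = driver_list %||% sort(unique(entries$gene)),
    entries = entries,
    granularity = granularity), class = "mutation_matrix")
}
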