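# Synthetic multi-region patient generator.
#
# Each patient is built from a scenario template: a truncal driver set shared
# by all regions, plus pattern/topology-specific private driver blocks. The
# template guarantees that, in the absence of caller noise, the emitted
# sample profiles classify exactly to the requested scenario. Caller noise is
# then layered on top: each of the simulated callers reports each true
# variant independently with probability `caller_sensitivity` and adds
# Poisson false calls in non-driver filler genes at fresh loci.

# Poisson draw conditioned to be >= min_n; for a zero rate the conditional
# law is degenerate and the minimum itself is returned.
rpois_min <- function(lambda, min_n) {
  if (min_n <= 0L) return(stats::rpois(1L, lambda))
  if (lambda <= 0) return(min_n)
  repeat {
    k <- stats::rpois(1L, lambda)
    if (k >= min_n) return(k)
  }
}

# deterministic 31-bit hash of a string, for per-patient RNG streams
string_hash <- function(x) {
  codes <- utf8ToInt(x)
  h <- 0
  for (cc in codes) h <- (h * 131 + cc) %% 2147483629
  h
}

patient_stream_seed <- function(seed, patient_id) {
  as.integer((as.numeric(seed) %% 2147483629 * 48271 +
                string_hash(patient_id)) %% 2147483629)
}

# toy genome: one locus per driver-pool index, unique per gene
gene_locus <- function(gene, driver_list) {
  i <- match(gene, driver_list)
  if (is.na(i)) stop("gene not in driver pool: ", gene)
  list(chrom = paste0("chr", (i - 1L) %% 22L + 1L), pos = i * 1500L + 7L)
}

empty_call_table <- function(with_caller = FALSE) {
  df <- data.frame(patient_id = character(), sample_id = character(),
                   chrom = character(), pos = integer(),
                   ref = character(), alt = character(),
                   gene = character(), variant_class = character(),
                   stringsAsFactors = FALSE)
  if (with_caller) df <- cbind(df, data.frame(caller = character()))
  df
}

#' Simulate one multi-region patient with known truth
#'
#' Generates a clone genealogy under the configured scenario, assigns driver
#' mutations from the pool, lays clones out over one or more primary-tumor
#' (PT) samples and a directional chain of tumor-thrombus (TT) samples, and
#' emits both the noise-free variant table and per-caller tables with
#' detection noise.
#'
#' Generation is deterministic in `(config, patient_id)`: the RNG stream is
#' derived from the master seed and the patient identifier, so cohorts are
#' reproducible and order-independent.
#'
#' @param config a [sim_config()].
#' @param patient_id patient identifier string.
#' @return an object of class `sim_patient`: a list with elements
#'   `truth` (clone tree, per-sample true gene profiles, scenario labels),
#'   `truth_calls` (noise-free variant table), `caller_calls` (per-caller
#'   variant tables with noise, one row per call), `sample_roles`
#'   (sample annotation table) and `config`.
#' @examples
#' p <- simulate_patient(sim_config(pattern = "private_tt", seed = 7), "P01")
#' p$truth$true_pt_tt_pattern
#' head(p$truth_calls)
#' @export
simulate_patient <- function(config, patient_id) {
  validate_sim_config(config)
  set.seed(patient_stream_seed(config$seed, patient_id))

  pool <- sample(config$driver_list)  # patient-specific allocation order
  cursor <- 0L
  take_genes <- function(k) {
    if (k == 0L) return(character())
    if (cursor + k > length(pool))
      stop("driver pool exhausted; increase driver_pool_size")
    out <- pool[seq.int(cursor + 1L, cursor + k)]
    cursor <<- cursor + k
    out
  }

  trunk <- take_genes(rpois_min(config$truncal_rate, 1L))
  lp <- config$private_rate
  n_tt <- config$n_tt_samples

  # --- TT sample profiles by topology -----------------------------------
  # tt_min_gain: does the pattern require the TT union to strictly exceed
  # the trunk (private_tt, divergent)?
  tt_needs_gain <- config$pattern %in% c("private_tt", "divergent")
  tt_profiles <- vector("list", n_tt)
  if (config$topology == "linear_hom") {
    gain0 <- take_genes(rpois_min(lp, if (tt_needs_gain) 1L else 0L))
    base <- c(trunk, gain0)
    for (i in seq_len(n_tt)) tt_profiles[[i]] <- base
  } else if (config$topology == "linear_het") {
    # stepwise accumulation along the chain; at least one step must gain
    steps <- integer(n_tt - 1L)
    repeat {
      steps <- vapply(seq_len(n_tt - 1L),
                      function(i) stats::rpois(1L, lp), integer(1))
      if (sum(steps) >= 1L) break
      if (lp <= 0) { steps[1L] <- 1L; break }
    }
    prof <- trunk
    tt_profiles[[1L]] <- prof
    for (i in seq_len(n_tt - 1L)) {
      prof <- c(prof, take_genes(steps[[i]]))
      tt_profiles[[i + 1L]] <- prof
    }
  } else { # branched_het: two branches with obligatory distinct gains
    for (i in seq_len(n_tt)) {
      k <- rpois_min(lp, if (i <= 2L) 1L else 0L)
      tt_profiles[[i]] <- c(trunk, take_genes(k))
    }
  }

  # --- PT profile by pattern --------------------------------------------
  tt_union <- unique(unlist(tt_profiles))
  pt_profile <- switch(config$pattern,
    coevolution = tt_union,
    private_pt = c(tt_union, take_genes(rpois_min(lp, 1L))),
    private_tt = trunk,
    divergent  = c(trunk, take_genes(rpois_min(lp, 1L)))
  )

  # --- samples ----------------------------------------------------------
  pt_ids <- paste0(patient_id, "-PT", seq_len(config$n_pt_samples))
  tt_local <- c("TTA", "TTM", "TTD",
                if (n_tt > 3L) paste0("TT", seq.int(4L, n_tt)))[seq_len(n_tt)]
  tt_ids <- paste0(patient_id, "-", tt_local)
  tt_roles <- c("TT_A", "TT_M", "TT_D", rep("TT", max(0L, n_tt - 3L)))[seq_len(n_tt)]
  roles <- data.frame(
    patient_id = patient_id,
    sample_id = c(pt_ids, tt_ids),
    role = c(rep("PT", config$n_pt_samples), tt_roles),
    stringsAsFactors = FALSE)

  sample_profiles <- c(
    stats::setNames(rep(list(sort(pt_profile)), config$n_pt_samples), pt_ids),
    stats::setNames(lapply(tt_profiles, sort), tt_ids))

  # --- planted variants: one locus per mutated gene ---------------------
  mutated <- sort(unique(c(pt_profile, tt_union)))
  bases <- c("A", "C", "G", "T")
  var_info <- lapply(mutated, function(g) {
    loc <- gene_locus(g, config$driver_list)
    ref <- sample(bases, 1L)
    alt <- sample(setdiff(bases, ref), 1L)
    cls <- sample(retained_variant_classes(), 1L,
                  prob = c(1, 1, 1, 0.2, 1, 6, 0.5))
    data.frame(chrom = loc$chrom, pos = loc$pos, ref = ref, alt = alt,
               gene = g, variant_class = cls, stringsAsFactors = FALSE)
  })
  var_info <- do.call(rbind, var_info)
  rownames(var_info) <- var_info$gene

  truth_calls <- do.call(rbind, c(list(empty_call_table()), lapply(
    names(sample_profiles), function(s) {
      genes <- sample_profiles[[s]]
      if (length(genes) == 0L) return(empty_call_table())
      cbind(data.frame(patient_id = patient_id, sample_id = s,
                       stringsAsFactors = FALSE),
            var_info[genes, , drop = FALSE])
    })))
  rownames(truth_calls) <- NULL

  # --- caller noise ------------------------------------------------------
  callers <- caller_panel(config$caller_count)
  fp_counter <- 0L
  caller_calls <- list()
  for (cal in callers) {
    if (nrow(truth_calls) > 0L) {
      keep <- stats::runif(nrow(truth_calls)) <= config$caller_sensitivity
      tp <- truth_calls[keep, , drop = FALSE]
    } else tp <- truth_calls
    fps <- list()
    for (s in names(sample_profiles)) {
      nfp <- stats::rpois(1L, config$caller_fp_rate)
      if (nfp == 0L) next
      for (k in seq_len(nfp)) {
        fp_counter <- fp_counter + 1L
        ref <- sample(bases, 1L)
        fps[[length(fps) + 1L]] <- data.frame(
          patient_id = patient_id, sample_id = s,
          chrom = paste0("chr", (fp_counter - 1L) %% 22L + 1L),
          pos = 9000000L + fp_counter * 13L,
          ref = ref, alt = sample(setdiff(bases, ref), 1L),
          gene = sprintf("FILLER%04d", fp_counter),
          variant_class = sample(variant_class_vocabulary(), 1L),
          stringsAsFactors = FALSE)
      }
    }
    tab <- do.call(rbind, c(list(tp), fps))
    if (nrow(tab) > 0L) tab$caller <- cal else tab <- empty_call_table(TRUE)
    caller_calls[[cal]] <- tab
  }
  caller_calls <- do.call(rbind, caller_calls)
  rownames(caller_calls) <- NULL

  truth <- list(
    patient_id = patient_id,
    scenario = scenario_string(config$pattern, config$topology),
    true_pt_tt_pattern = config$pattern,
    true_tt_topology = topology_label(config$topology),
    sample_profiles = sample_profiles,
    clone_tree = profile_clone_tree(sample_profiles),
    true_variants = var_info)

  structure(list(truth = truth, truth_calls = truth_calls,
                 caller_calls = caller_calls, sample_roles = roles,
                 config = config),
            class = "sim_patient")
}

# clone genealogy over the distinct true profiles: clone per profile,
# parent = containment ancestor (shared machinery with build_clone_tree)
profile_clone_tree <- function(sample_profiles) {
  build_clone_tree_from_profiles(sample_profiles)
}

#' Simulate a cohort of multi-region patients
#'
#' Draws a scenario per patient from `scenario_mix` (multinomial under the
#' master seed), then generates each patient with its own derived RNG
#' stream. Scenario names are `"pattern/topology"` strings (see
#' [all_scenarios()]); a bare topology name such as `"linear_hom"` is
#' accepted and defaults the pattern to `private_tt`.
#'
#' @param config a [sim_config()]; its `pattern`/`topology` are overridden
#'   per patient by the drawn scenario.
#' @param n_patients number of patients (>= 1).
#' @param scenario_mix named numeric vector of scenario proportions summing
#'   to 1.
#' @return an object of class `sim_cohort`: list with `patients` (list of
#'   `sim_patient`), `truth` (one row per patient: scenario and true
#'   labels), concatenated `caller_calls`, `truth_calls` and `sample_roles`
#'   tables, and `config`.
#' @examples
#' co <- simulate_cohort(sim_config(seed = 3), 4,
#'                       c("coevolution/linear_hom" = 0.5, "linear_het" = 0.5))
#' co$truth
#' @export
simulate_cohort <- function(config, n_patients,
                            scenario_mix = stats::setNames(
                              rep(1 / 12, 12), all_scenarios())) {
  validate_sim_config(config)
  n_patients <- as.integer(n_patients)
  if (is.na(n_patients) || n_patients < 1L)
    stop("n_patients must be a positive integer")
  if (length(scenario_mix) == 0L) stop("scenario_mix must be non-empty")
  if (is.null(names(scenario_mix)) || any(!nzchar(names(scenario_mix))))
    stop("scenario_mix must be a named vector")
  if (any(scenario_mix < 0)) stop("scenario proportions must be >= 0")
  if (abs(sum(scenario_mix) - 1) > 1e-9)
    stop("scenario proportions must sum to 1")
  parsed <- lapply(names(scenario_mix), parse_scenario)  # validates names

  set.seed(config$seed)
  drawn <- sample(seq_along(scenario_mix), n_patients, replace = TRUE,
                  prob = scenario_mix)

  patients <- vector("list", n_patients)
  truth_rows <- vector("list", n_patients)
  for (i in seq_len(n_patients)) {
    sc <- parsed[[drawn[[i]]]]
    cfg_i <- config
    cfg_i$pattern <- sc$pattern
    cfg_i$topology <- sc$topology
    pid <- sprintf("SIM%03d", i)
    patients[[i]] <- simulate_patient(cfg_i, pid)
    truth_rows[[i]] <- data.frame(
      patient_id = pid,
      scenario = scenario_string(sc$pattern, sc$topology),
      true_pt_tt_pattern = sc$pattern,
      true_tt_topology = topology_label(sc$topology),
      stringsAsFactors = FALSE)
  }

  structure(list(
    patients = patients,
    truth = do.call(rbind, truth_rows),
    caller_calls = do.call(rbind, lapply(patients, `[[`, "caller_calls")),
    truth_calls = do.call(rbind, lapply(patients, `[[`, "truth_calls")),
    sample_roles = do.call(rbind, lapply(patients, `[[`, "sample_roles")),
    config = config), class = "sim_cohort")
}

#' @export
print.sim_cohort <- function(x, ...) {
  cat(sprintf("Synthetic cohort: %d patients, %d calls across %d callers\n",
              length(x$patients), nrow(x$caller_calls), x$config$caller_count))
  print(table(x$truth$scenario))
  invisible(x)
}
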