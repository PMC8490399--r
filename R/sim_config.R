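#' Simulation configuration for the synthetic multi-region cohort
#'
#' Bundles every knob of the synthetic-patient generator. A scenario is the
#' pair (PT-TT pattern, TT topology); the generator guarantees by template
#' construction that the noise-free output of a patient classifies exactly
#' to its scenario.
#'
#' Defaults describe a typical multi-region ccRCC thrombus study: a small
#' truncal driver load (VHL plus a couple of others), about one private
#' driver per subclone, one PT sample and three directional TT samples
#' (adjacent / middle / distal), and a seven-caller ensemble with 90%
#' per-caller sensitivity and on average one false call per sample per
#' caller.
#'
#' @param driver_pool_size size of the driver-gene pool (default 332).
#' @param truncal_rate Poisson mean of truncal drivers per patient
#'   (conditioned to be >= 1).
#' @param private_rate Poisson mean of private drivers per subclone
#'   (re-drawn where the scenario template requires a non-empty gain).
#' @param n_pt_samples,n_tt_samples samples per patient; `n_tt_samples`
#'   must be >= 2 when a TT topology scenario is requested.
#' @param pattern PT-TT pattern to simulate: one of `"divergent"`,
#'   `"private_pt"`, `"private_tt"`, `"coevolution"`.
#' @param topology TT topology to simulate: one of `"branched_het"`,
#'   `"linear_hom"`, `"linear_het"`.
#' @param caller_count number of simulated callers (default 7).
#' @param caller_sensitivity per-caller probability of reporting a true
#'   variant, in \[0, 1\].
#' @param caller_fp_rate expected false calls per sample per caller
#'   (Poisson mean), planted in non-driver filler genes at fresh loci.
#' @param seed integer master seed; identical (config, seed) yields
#'   byte-identical output. Per-patient streams are derived from it so
#'   cohort generation is order-independent.
#' @param driver_list optional explicit driver pool (overrides
#'   `driver_pool_size`).
#' @return an object of class `sim_config`.
#' @seealso [simulate_patient()], [simulate_cohort()]
#' @export
sim_config <- function(driver_pool_size = 332L,
                       truncal_rate = 2,
                       private_rate = 1,
                       n_pt_samples = 1L,
                       n_tt_samples = 3L,
                       pattern = "private_tt",
                       topology = "branched_het",
                       caller_count = 7L,
                       caller_sensitivity = 0.9,
                       caller_fp_rate = 1,
                       seed = 1L,
                       driver_list = NULL) {
  if (is.null(driver_list)) driver_list <- driver_gene_pool(driver_pool_size)
  cfg <- structure(list(
    driver_list = driver_list,
    truncal_rate = truncal_rate,
    private_rate = private_rate,
    n_pt_samples = as.integer(n_pt_samples),
    n_tt_samples = as.integer(n_tt_samples),
    pattern = pattern,
    topology = topology,
    caller_count = as.integer(caller_count),
    caller_sensitivity = caller_sensitivity,
    caller_fp_rate = caller_fp_rate,
    seed = as.integer(seed)
  ), class = "sim_config")
  validate_sim_config(cfg)
  cfg
}

sim_patterns <- function() c("divergent", "private_pt", "private_tt", "coevolution")
sim_topologies <- function() c("branched_het", "linear_hom", "linear_het")

# map short simulation topology names to classifier labels
topology_label <- function(short) {
  c(branched_het = "branched_heterogeneous",
    linear_hom = "linear_homogeneous",
    linear_het = "linear_heterogeneous")[[short]]
}

validate_sim_config <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (!is.character(cfg$driver_list) || length(cfg$driver_list) < 1L ||
      anyDuplicated(cfg$driver_list))
    stop("driver_list must be a non-empty character vector without duplicates")
  if (cfg$truncal_rate < 0 || cfg$private_rate < 0 || cfg$caller_fp_rate < 0)
    stop("rates must be >= 0")
  if (cfg$caller_sensitivity < 0 || cfg$caller_sensitivity > 1)
    stop("caller_sensitivity must be in [0, 1]")
  if (cfg$n_pt_samples < 1L) stop("need at least one PT sample")
  if (cfg$caller_count < 1L) stop("need at least one caller")
  if (!cfg$pattern %in% sim_patterns())
    stop("unknown scenario pattern: ", cfg$pattern)
  if (!cfg$topology %in% sim_topologies())
    stop("unknown scenario topology: ", cfg$topology)
  if (cfg$n_tt_samples < 2L)
    stop("a TT topology scenario requires n_tt_samples >= 2")
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Synthetic multi-region cohort configuration\n")
  cat(sprintf("  scenario: %s / %s\n", x$pattern, x$topology))
  cat(sprintf("  driver pool: %d genes; truncal rate %.2f, private rate %.2f\n",
              length(x$driver_list), x$truncal_rate, x$private_rate))
  cat(sprintf("  samples: %d PT + %d TT\n", x$n_pt_samples, x$n_tt_samples))
  cat(sprintf("  callers: %d, sensitivity %.2f, fp rate %.2f/sample\n",
              x$caller_count, x$caller_sensitivity, x$caller_fp_rate))
  cat(sprintf("  seed: %d\n", x$seed))
  invisible(x)
}

# Parse a scenario string: "pattern/topology", or a bare topology name
# (pattern defaults to private_tt, the modal case in which the thrombus
# gains drivers beyond the primary), or a bare pattern name (topology
# defaults to branched_het).
parse_scenario <- function(scenario) {
  parts <- strsplit(scenario, "/", fixed = TRUE)[[1]]
  if (length(parts) == 2L) {
    out <- list(pattern = parts[[1]], topology = parts[[2]])
  } else if (length(parts) == 1L && parts %in% sim_topologies()) {
    out <- list(pattern = "private_tt", topology = parts)
  } else if (length(parts) == 1L && parts %in% sim_patterns()) {
    out <- list(pattern = parts, topology = "branched_het")
  } else {
    stop("unknown scenario name: ", scenario)
  }
  if (!out$pattern %in% sim_patterns())
    stop("unknown scenario pattern: ", out$pattern)
  if (!out$topology %in% sim_topologies())
    stop("unknown scenario topology: ", out$topology)
  out
}

scenario_string <- function(pattern, topology) paste(pattern, topology, sep = "/")

#' All twelve simulation scenarios
#'
#' The cross of the four PT-TT patterns with the three TT topologies,
#' as `"pattern/topology"` strings.
#' @return character vector of length 12.
#' @export
all_scenarios <- function() {
  as.vector(outer(sim_patterns(), sim_topologies(), scenario_string))
}
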