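# Multi-caller merge, K-of-N consensus retention, class filter, matrices.

test_that("merging accumulates supporting-caller sets without loss or duplication", {
  two <- merge_caller_calls(make_calls(c("MuTect", "Strelka")))
  expect_identical(nrow(two), 1L)
  expect_identical(two$n_callers, 2L)
  expect_identical(two$supporting_callers, "MuTect;Strelka")

  seven <- merge_caller_calls(make_calls(caller_panel(7)))
  expect_identical(nrow(seven), 1L)
  expect_identical(seven$n_callers, 7L)

  # list-of-tables input, distinct variants stay distinct
  lst <- list(make_calls("MuTect"), make_calls("VarScan", pos = 999L))
  m <- merge_caller_calls(lst)
  expect_identical(nrow(m), 2L)
  expect_identical(sort(m$n_callers), c(1L, 1L))

  empty <- merge_caller_calls(list())
  expect_identical(nrow(empty), 0L)
  expect_true(all(c("supporting_callers", "n_callers") %in% names(empty)))
})

test_that("conflicting gene annotations keep the first seen with a warning", {
  calls <- rbind(make_calls("MuTect", gene = "VHL"),
                 make_calls("Strelka", gene = "WRONG"))
  expect_warning(m <- merge_caller_calls(calls), "conflicting")
  expect_identical(m$gene, "VHL")
  expect_identical(m$n_callers, 2L)
})

test_that("retention matches the popcount oracle over every support subset of 7 callers", {
  panel <- caller_panel(7)
  subsets <- lapply(seq_len(2^7) - 1L, function(m) panel[bitwAnd(m, 2^(0:6)) > 0])
  calls <- do.call(rbind, lapply(seq_along(subsets), function(i) {
    if (length(subsets[[i]]) == 0L) return(NULL)
    make_calls(subsets[[i]], pos = 1000L + i)
  }))
  merged <- merge_caller_calls(calls)
  for (k in 1:8) {
    kept <- suppressWarnings(retain_consensus(merged, k))
    oracle <- sum(lengths(subsets) >= k & lengths(subsets) > 0L)
    expect_identical(nrow(kept), as.integer(oracle))
  }
  # the printed 3-of-7 rule: 99 of the 128 subsets survive
  expect_identical(nrow(retain_consensus(merged, 3L)),
                   as.integer(sum(choose(7, 3:7))))
  expect_identical(sum(choose(7, 3:7)), 99)
})

test_that("raising min_callers never adds a variant and min_callers = 1 is the identity", {
  set.seed(42)
  for (rep in 1:25) {
    n <- sample(1:30, 1)
    calls <- do.call(rbind, lapply(seq_len(n), function(i) {
      make_calls(sample(caller_panel(7), sample(1:7, 1)), pos = 100L * i)
    }))
    merged <- merge_caller_calls(calls)
    expect_identical(retain_consensus(merged, 1L), merged)
    prev <- merged
    for (k in 2:8) {
      cur <- suppressWarnings(retain_consensus(merged, k))
      expect_true(all(cur$pos %in% prev$pos))
      expect_lte(nrow(cur), nrow(prev))
      prev <- cur
    }
  }
})

test_that("min_callers above the ensemble size warns and returns nothing", {
  merged <- merge_caller_calls(make_calls(c("MuTect", "Strelka")))
  expect_warning(out <- retain_consensus(merged, 3L, caller_count = 2L),
                 "exceeds ensemble size")
  expect_identical(nrow(out), 0L)
  expect_error(retain_consensus(merged, 0L), "min_callers")
})

test_that("the variant-class filter keeps the inclusion list and drops the rest", {
  calls <- rbind(
    make_calls("MuTect", pos = 1L, vclass = "nonsynonymous_SNV"),
    make_calls("MuTect", pos = 2L, vclass = "synonymous_SNV"),
    make_calls("MuTect", pos = 3L, vclass = "stopgain"),
    make_calls("MuTect", pos = 4L, vclass = "known"),
    make_calls("MuTect", pos = 5L, vclass = "splicing"))
  out <- filter_variant_classes(calls)
  expect_setequal(out$pos, c(1L, 3L, 4L, 5L))
  expect_identical(nrow(filter_variant_classes(calls[0, ])), 0L)
  expect_message(
    none <- filter_variant_classes(make_calls("MuTect", vclass = "weird")),
    "unrecognized")
  expect_identical(nrow(none), 0L)
  expect_error(filter_variant_classes(calls, character()), "non-empty")
})

test_that("the mutation matrix holds exactly the retained driver calls", {
  roles <- data.frame(sample_id = c("S1", "S2"), role = c("PT", "TT_A"))
  calls <- rbind(
    make_calls("x", sample = "S1", gene = "VHL", pos = 10L),
    make_calls("x", sample = "S2", gene = "VHL", pos = 10L),
    make_calls("x", sample = "S2", gene = "FILLER01", pos = 20L))
  calls$caller <- NULL
  mm <- build_mutation_matrix(calls, c("VHL", "PBRM1"), roles)
  expect_s3_class(mm, "mutation_matrix")
  expect_identical(mm$genes, "VHL")
  expect_identical(sample_profile(mm, "S1", "gene"), "VHL")
  expect_identical(sample_profile(mm, "S2", "gene"), "VHL")
  expect_identical(sample_profile(mm, "S1"), "VHL|chr3:10:C:T")

  expect_error(build_mutation_matrix(calls, "VHL", roles[0, ]), "no tumor samples")
  expect_error(build_mutation_matrix(calls, "VHL", rbind(roles, roles[1, ])),
               "duplicate sample_id")
  expect_error(
    build_mutation_matrix(make_calls("x", sample = "S9"), "VHL", roles),
    "absent from roles")
})

test_that("matrices round-trip through the TSV writer losslessly", {
  cfg <- sim_config(seed = 21, caller_sensitivity = 1, caller_fp_rate = 0)
  p <- simulate_patient(cfg, "P1")
  mm <- build_mutation_matrix(filter_variant_classes(p$truth_calls),
                              cfg$driver_list, p$sample_roles)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_mutation_matrix(mm, path)
  back <- read_mutation_matrix(path, driver_list = cfg$driver_list)
  expect_identical(back$entries, mm$entries)
  expect_setequal(back$samples$sample_id, mm$samples$sample_id)
  for (s in mm$samples$sample_id)
    expect_identical(sample_profile(back, s), sample_profile(mm, s))
})

test_that("noise-free matrix profiles equal the true per-sample clone sets", {
  for (seed in c(1, 19)) {
    cfg <- sim_config(seed = seed, pattern = "divergent",
                      topology = "branched_het",
                      caller_sensitivity = 1, caller_fp_rate = 0)
    p <- simulate_patient(cfg, "P1")
    retained <- consensus_calls(p$caller_calls)
    mm <- build_mutation_matrix(retained, cfg$driver_list, p$sample_roles)
    for (s in names(p$truth$sample_profiles))
      expect_identical(sample_profile(mm, s, "gene"),
                       p$truth$sample_profiles[[s]])
  }
})
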