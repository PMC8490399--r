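# PT-TT pattern classification, TT topology, and clone-tree construction.

test_that("PT-TT pattern follows the containment rules on canonical profiles", {
  pt_tt <- function(P, T1, T2 = NULL) {
    profs <- c(list(PT = P, TT1 = T1), if (!is.null(T2)) list(TT2 = T2))
    classify_pt_tt(matrix_from_profiles(profs))
  }
  expect_identical(pt_tt(c("VHL", "PBRM1"), c("VHL", "PBRM1")), "coevolution")
  expect_identical(pt_tt("VHL", c("VHL", "BAP1")), "private_tt")
  expect_identical(pt_tt(c("VHL", "PBRM1"), "VHL"), "private_pt")
  expect_identical(pt_tt(c("VHL", "PBRM1"), c("VHL", "SETD2")), "divergent")
  expect_identical(pt_tt(character(), character()), "no_driver")
  # union semantics over multiple TT samples
  expect_identical(pt_tt(c("VHL", "PBRM1"), "VHL", c("VHL", "PBRM1")),
                   "coevolution")
  expect_error(
    classify_pt_tt(matrix_from_profiles(list(A = "VHL", B = "VHL"),
                                        roles = c("PT", "PT"))),
    "no TT sample")
})

test_that("TT topology distinguishes homogeneous, ordered, and branched profile families", {
  topo <- function(...) {
    profs <- list(...)
    names(profs) <- paste0("TT", seq_along(profs))
    m <- matrix_from_profiles(c(list(PT = unique(unlist(profs))), profs))
    classify_tt_topology(m)
  }
  expect_identical(topo("VHL", "VHL", "VHL"), "linear_homogeneous")
  expect_identical(topo("VHL", c("VHL", "SETD2"), c("VHL", "SETD2", "TP53")),
                   "linear_heterogeneous")
  expect_identical(topo(c("VHL", "BAP1"), c("VHL", "SETD2")),
                   "branched_heterogeneous")
  # single TT sample: undefined, not an error
  m1 <- matrix_from_profiles(list(PT = "VHL", TT1 = "VHL"))
  expect_identical(classify_tt_topology(m1), "undefined")
})

test_that("topology agrees with a brute-force pairwise-inclusion oracle on random families", {
  oracle <- function(profiles) {
    D <- unique(lapply(profiles, sort))
    if (length(D) == 1L) return("linear_homogeneous")
    for (i in seq_along(D)) for (j in seq_along(D)) {
      if (i != j && !all(D[[i]] %in% D[[j]]) && !all(D[[j]] %in% D[[i]]))
        return("branched_heterogeneous")
    }
    "linear_heterogeneous"
  }
  set.seed(99)
  for (rep in 1:200) {
    profs <- random_profiles(sample(2:5, 1))
    m <- matrix_from_profiles(
      c(list(PT = LETTERS[1:8]), profs),
      roles = c("PT", rep("TT", length(profs))))
    expect_identical(classify_tt_topology(m), oracle(profs))
  }
})

test_that("classification is invariant to sample order and duplication", {
  set.seed(17)
  for (rep in 1:40) {
    profs <- random_profiles(4)
    roles <- c("PT", "TT_A", "TT_M", "TT_D")
    m <- matrix_from_profiles(profs, roles = roles)
    base <- classify_patient(m)
    perm <- sample(seq_along(profs))
    m2 <- matrix_from_profiles(profs[perm], roles = roles[perm])
    expect_identical(classify_pt_tt(m2), base$pt_tt_pattern)
    # duplicating a TT sample changes nothing
    dup <- c(profs, list(S9 = profs[[2]]))
    m3 <- matrix_from_profiles(dup, roles = c(roles, "TT"))
    expect_identical(classify_pt_tt(m3), base$pt_tt_pattern)
    expect_identical(classify_tt_topology(m3), base$tt_topology)
  }
})

test_that("additional-TT-driver flag is the non-empty difference of union profiles", {
  m <- matrix_from_profiles(list(PT = "VHL", TT1 = c("VHL", "BAP1")))
  expect_true(flag_additional_tt_drivers(m))
  m2 <- matrix_from_profiles(list(PT = c("VHL", "BAP1"),
                                  TT1 = c("VHL", "BAP1")))
  expect_false(flag_additional_tt_drivers(m2))
  # against the adjacent TT sample instead of the primary
  m3 <- matrix_from_profiles(
    list(PT = "VHL", TTA = c("VHL", "BAP1"), TTD = c("VHL", "BAP1")),
    roles = c("PT", "TT_A", "TT_D"))
  expect_true(flag_additional_tt_drivers(m3))
  expect_false(flag_additional_tt_drivers(m3, relative_to = "adjacent"))
})

test_that("clone trees attach profiles by containment with gained-mutation edges", {
  m <- matrix_from_profiles(list(S1 = "V", S2 = c("V", "A"), S3 = c("V", "B")),
                            roles = c("PT", "TT_A", "TT_M"))
  tr <- build_clone_tree(m)
  expect_identical(nrow(tr$nodes), 3L)
  root <- tr$nodes[tr$nodes$node_id == tr$root_id, ]
  expect_identical(root$profile, "V")
  kids <- tr$nodes[!is.na(tr$nodes$parent_id), ]
  expect_true(all(kids$parent_id == tr$root_id))
  expect_setequal(kids$gained, c("A", "B"))

  # single profile: one node, no edges
  tr1 <- build_clone_tree(matrix_from_profiles(list(S1 = c("V", "A"))))
  expect_identical(nrow(tr1$nodes), 1L)
  expect_true(is.na(tr1$nodes$parent_id))

  # disjoint profiles hang off a virtual empty root
  tr2 <- build_clone_tree_from_profiles(list(S1 = "A", S2 = "B"))
  expect_identical(nrow(tr2$nodes), 3L)
  expect_identical(tr2$nodes$profile[tr2$nodes$node_id == tr2$root_id], "")
})

test_that("every sample profile replays from the root on random families", {
  set.seed(31)
  for (rep in 1:300) {
    profs <- random_profiles(sample(1:6, 1))
    tr <- build_clone_tree_from_profiles(profs)
    expect_true(replay_clone_tree(tr))
    # each sample profile sits at exactly one node
    keys <- vapply(tr$profiles, paste, character(1), collapse = ",")
    for (s in names(profs)) {
      hits <- sum(keys == paste(sort(unique(profs[[s]])), collapse = ","))
      expect_identical(hits, 1L)
    }
  }
})

test_that("ambiguous-ancestor families still yield a sound, deterministic tree", {
  # {a}, {b}, {a,b,c}: the meet-closed family leaves {a,b,c} with two
  # maximal subset ancestors; the tie-break must pick one deterministically
  profs <- list(S1 = "a", S2 = "b", S3 = c("a", "b", "c"))
  tr <- build_clone_tree_from_profiles(profs)
  tr2 <- build_clone_tree_from_profiles(profs)
  expect_identical(tr$nodes, tr2$nodes)
  expect_true(replay_clone_tree(tr))
  big <- tr$nodes[tr$nodes$profile == "a;b;c", ]
  parent_prof <- tr$nodes$profile[tr$nodes$node_id == big$parent_id]
  expect_identical(parent_prof, "a")  # largest, then lexicographic
})

test_that("Newick export is parseable and preserves the tree shape", {
  skip_if_not_installed("ape")
  cfg <- sim_config(seed = 13, pattern = "divergent", topology = "branched_het",
                    caller_sensitivity = 1, caller_fp_rate = 0)
  p <- simulate_patient(cfg, "P1")
  mm <- build_mutation_matrix(filter_variant_classes(p$truth_calls),
                              cfg$driver_list, p$sample_roles, "gene")
  tr <- build_clone_tree(mm)
  nwk <- clone_tree_newick(tr)
  expect_match(nwk, ";$")
  expect_match(nwk, "\\[&gained=")
  stripped <- gsub("\\[[^]]*\\]", "", nwk)
  ph <- ape::read.tree(text = stripped)
  expect_s3_class(ph, "phylo")
  # as many tips as leaf clones
  n_leaves <- sum(!tr$nodes$node_id %in% tr$nodes$parent_id)
  expect_identical(length(ph$tip.label), n_leaves)

  path <- withr::local_tempfile(fileext = ".nwk")
  clone_tree_newick(tr, path)
  expect_identical(readLines(path), nwk)
})
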