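# Clone-tree construction from sample mutation profiles.
#
# Each distinct profile (set of mutated elements) is a clone; the root is
# the truncal profile, i.e. the intersection of all sample profiles (an
# empty virtual root when nothing is shared). The profile family is closed
# under pairwise intersection so every branching point corresponds to a
# node, and each node is attached to a maximal proper-subset ancestor.
# Where that ancestor is not unique (possible even in a meet-closed
# family), the tie is broken deterministically: largest ancestor profile
# first, then lexicographic order. Edge labels carry the mutations gained
# relative to the parent; by construction the gains along any root-to-node
# path are disjoint and union to the node's profile.

profile_key <- function(p) paste(sort(p), collapse = ",")

#' Build a clone tree from a mutation matrix
#'
#' @param matrix a `mutation_matrix`.
#' @param granularity profile granularity (defaults to the matrix's own).
#' @return an object of class `clone_tree`; see
#'   [build_clone_tree_from_profiles()] for the structure.
#' @export
build_clone_tree <- function(matrix, granularity = NULL) {
  stopifnot(inherits(matrix, "mutation_matrix"))
  ids <- matrix$samples$sample_id
  if (length(ids) == 0L) stop("patient has no samples")
  profiles <- stats::setNames(
    lapply(ids, sample_profile, matrix = matrix, granularity = granularity),
    ids)
  tr <- build_clone_tree_from_profiles(profiles)
  tr$patient_id <- matrix$patient_id
  tr
}

#' Build a clone tree from named sample profiles
#'
#' Workhorse behind [build_clone_tree()], usable directly on a named list
#' of sample profiles (character-vector sets).
#'
#' @param profiles named list, sample id -> character vector of mutated
#'   elements.
#' @return object of class `clone_tree`: list with `nodes` (data.frame:
#'   `node_id`, `parent_id` (NA for root), `profile`, `gained`,
#'   `samples` — the latter three semicolon-joined), `root_id`, and
#'   `profiles` (list of profile vectors per node, named by node id).
#' @export
build_clone_tree_from_profiles <- function(profiles) {
  stopifnot(length(profiles) >= 1L, !is.null(names(profiles)))
  profiles <- lapply(profiles, function(p) sort(unique(as.character(p))))

  root <- Reduce(intersect, profiles)
  fam <- unique(c(list(root), unname(profiles)))
  # meet closure: add pairwise intersections until stable
  repeat {
    added <- FALSE
    keys <- vapply(fam, profile_key, character(1))
    for (i in seq_along(fam)) for (j in seq_along(fam)) {
      if (i < j) {
        m <- intersect(fam[[i]], fam[[j]])
        if (!profile_key(m) %in% keys) {
          fam[[length(fam) + 1L]] <- m
          keys <- c(keys, profile_key(m))
          added <- TRUE
        }
      }
    }
    if (!added) break
  }

  sizes <- lengths(fam)
  ord <- order(sizes, vapply(fam, profile_key, character(1)))
  fam <- fam[ord]
  keys <- vapply(fam, profile_key, character(1))
  node_ids <- paste0("C", seq_along(fam))

  parent <- rep(NA_character_, length(fam))
  gained <- vector("list", length(fam))
  for (i in seq_along(fam)) {
    if (identical(fam[[i]], root)) { gained[[i]] <- root; next }
    # candidate ancestors: proper subsets; pick largest, tie-break on key
    cand <- which(vapply(seq_along(fam), function(j) {
      j != i && length(fam[[j]]) < length(fam[[i]]) &&
        is_subset(fam[[j]], fam[[i]])
    }, logical(1)))
    cand <- cand[order(-lengths(fam[cand]), keys[cand])]
    p <- cand[[1L]]  # root is always a subset, so cand is never empty
    parent[[i]] <- node_ids[[p]]
    gained[[i]] <- setdiff(fam[[i]], fam[[p]])
  }

  sample_at <- split(names(profiles),
                     factor(vapply(profiles, profile_key, character(1)),
                            levels = keys))
  nodes <- data.frame(
    node_id = node_ids,
    parent_id = parent,
    profile = vapply(fam, function(p) paste(p, collapse = ";"), character(1)),
    gained = vapply(gained, function(g) paste(sort(g), collapse = ";"),
                    character(1)),
    samples = vapply(sample_at, function(s) paste(sort(s), collapse = ";"),
                     character(1)),
    stringsAsFactors = FALSE)
  rownames(nodes) <- NULL

  structure(list(nodes = nodes,
                 root_id = node_ids[[which(vapply(fam, identical, logical(1),
                                                  y = root))[1]]],
                 profiles = stats::setNames(fam, node_ids)),
            class = "clone_tree")
}

#' @export
print.clone_tree <- function(x, ...) {
  cat(sprintf("Clone tree%s: %d clones, root %s (truncal: %s)\n",
              if (!is.null(x$patient_id)) paste0(" for ", x$patient_id) else "",
              nrow(x$nodes), x$root_id,
              if (nzchar(x$nodes$profile[x$nodes$node_id == x$root_id]))
                x$nodes$profile[x$nodes$node_id == x$root_id] else "<empty>"))
  invisible(x)
}

#' Replay a clone tree: reconstruct each node's profile from edge gains
#'
#' Accumulates the gained-mutation sets from the root down each path and
#' checks the result against the stored node profiles. Used as the tree
#' soundness check: every sample profile must be reconstructible this way.
#'
#' @param tree a `clone_tree`.
#' @return TRUE invisibly; stops if any profile fails to replay.
#' @export
replay_clone_tree <- function(tree) {
  stopifnot(inherits(tree, "clone_tree"))
  nodes <- tree$nodes
  acc <- list()
  split_field <- function(x) if (nzchar(x)) strsplit(x, ";", fixed = TRUE)[[1]] else character()
  # nodes are emitted in non-decreasing size order, so parents come first
  for (i in seq_len(nrow(nodes))) {
    id <- nodes$node_id[[i]]
    g <- split_field(nodes$gained[[i]])
    base <- if (is.na(nodes$parent_id[[i]])) character() else acc[[nodes$parent_id[[i]]]]
    if (length(intersect(base, g)) > 0L)
      stop("gain set overlaps inherited mutations at ", id)
    acc[[id]] <- sort(c(base, g))
    if (!identical(acc[[id]], sort(split_field(nodes$profile[[i]]))))
      stop("profile of ", id, " does not replay from root")
  }
  invisible(TRUE)
}

#' Serialize a clone tree as Newick
#'
#' Writes the genealogy in Newick form with node labels of the form
#' `nodeid.sampleA+sampleB` and a bracket comment `[&gained=m1,m2]` after
#' each label carrying the mutations gained on the edge into that node.
#' Comments follow the Newick convention (square brackets) and can be
#' stripped for consumption by standard parsers.
#'
#' @param tree a `clone_tree`.
#' @param path optional file to write to.
#' @return the Newick string (invisibly when `path` is given).
#' @export
clone_tree_newick <- function(tree, path = NULL) {
  stopifnot(inherits(tree, "clone_tree"))
  nodes <- tree$nodes
  children <- split(nodes$node_id, nodes$parent_id)
  label <- function(i) {
    s <- nodes$samples[[i]]
    lab <- nodes$node_id[[i]]
    if (nzchar(s)) lab <- paste0(lab, ".", gsub(";", "+", s, fixed = TRUE))
    g <- nodes$gained[[i]]
    paste0(lab, "[&gained=", gsub(";", ",", g, fixed = TRUE), "]")
  }
  rec <- function(id) {
    i <- match(id, nodes$node_id)
    kids <- children[[id]]
    if (is.null(kids) || length(kids) == 0L) return(label(i))
    paste0("(", paste(vapply(kids, rec, character(1)), collapse = ","), ")",
           label(i))
  }
  nwk <- paste0(rec(tree$root_id), ";")
  if (!is.null(path)) {
    writeLines(nwk, path)
    return(invisible(nwk))
  }
  nwk
}
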