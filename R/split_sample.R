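# Chemical-series-aware splitting and controlled balanced subsampling.
#
# Compounds are clustered at Tanimoto 0.8 with Butina (leader) clustering,
# train/test splits keep whole clusters on one side so near-duplicate
# analogs never straddle the split, and small balanced training subsets of
# fixed sizes are drawn for the low-data benchmark.

#' Butina (leader) clustering of fingerprints
#'
#' Greedy leader clustering at a similarity cutoff: compounds are processed
#' in descending order of neighbor count (neighbors = other compounds with
#' Tanimoto >= cutoff; ties broken by ascending compound id). Each
#' unassigned compound in that order becomes a centroid and absorbs every
#' still-unassigned compound within the cutoff. Deterministic.
#'
#' @param fingerprints Named list of `fingerprint` objects (names are
#'   compound ids).
#' @param cutoff Similarity cutoff in (0, 1], default 0.8.
#' @return A `cluster_assignment`: list with `assignment` (named integer
#'   vector, compound id -> cluster index) and `centroids` (character
#'   vector, cluster index -> centroid compound id).
#' @export
butina_cluster <- function(fingerprints, cutoff = 0.8) {
  if (!is_scalar_number(cutoff) || cutoff <= 0 || cutoff > 1) {
    abort("cutoff must be in (0, 1]", "dti_config_error")
  }
  n <- length(fingerprints)
  if (!n) {
    return(structure(list(assignment = integer(0), centroids = character(0)),
                     class = "cluster_assignment"))
  }
  ids <- names(fingerprints)
  if (is.null(ids) || anyDuplicated(ids)) {
    abort("fingerprints must be uniquely named by compound id",
          "dti_config_error")
  }
  sim <- tanimoto_matrix(fingerprints)
  neighbor_counts <- rowSums(sim >= cutoff) - 1L
  order_idx <- order(-neighbor_counts, ids)

  assignment <- integer(n)
  names(assignment) <- ids
  assigned <- logical(n)
  centroids <- character(0)
  k <- 0L
  for (i in order_idx) {
    if (assigned[i]) next
    k <- k + 1L
    members <- which(!assigned & sim[i, ] >= cutoff)
    members <- union(i, members)
    assignment[members] <- k
    assigned[members] <- TRUE
    centroids[k] <- ids[i]
  }
  structure(list(assignment = assignment, centroids = centroids),
            class = "cluster_assignment")
}

#' Cluster-disjoint train/test split
#'
#' Whole clusters are assigned greedily to the test partition -- largest
#' first, with a seeded shuffle among clusters of equal size -- until the
#' test partition reaches `test_fraction` of the data; the remainder is
#' train. The split may overshoot the fraction by at most one cluster;
#' clusters are never broken.
#'
#' @param compound_ids Character vector of compound ids (a data.frame with
#'   a `compound_id` column is also accepted).
#' @param clusters A `cluster_assignment` covering every compound.
#' @param test_fraction Target test fraction (default 1/6, matching the
#'   typical test share of the family datasets).
#' @param seed Integer seed for the equal-size shuffle.
#' @return A `dataset_split`.
#' @export
cluster_split <- function(compound_ids, clusters, test_fraction = 1 / 6,
                          seed = 1L) {
  if (is.data.frame(compound_ids)) compound_ids <- compound_ids$compound_id
  compound_ids <- as.character(compound_ids)
  stopifnot(inherits(clusters, "cluster_assignment"))
  if (!is_scalar_number(test_fraction) || test_fraction <= 0 ||
      test_fraction >= 1) {
    abort("test_fraction must be in (0, 1)", "dti_config_error")
  }
  unclustered <- setdiff(compound_ids, names(clusters$assignment))
  if (length(unclustered)) {
    abort(sprintf("compound(s) not clustered: %s",
                  paste(utils::head(unclustered, 5L), collapse = ", ")),
          "dti_precondition_error")
  }
  memb <- clusters$assignment[compound_ids]
  sizes <- table(memb)
  if (length(sizes) == 1L) {
    abort("all compounds fall in a single cluster; a cluster-disjoint split with non-empty train and test partitions is impossible",
          "dti_split_error")
  }
  cluster_ids <- names(sizes)
  shuffled <- local_seed(seed, sample(cluster_ids))
  ord <- shuffled[order(-as.integer(sizes[shuffled]))]

  n <- length(compound_ids)
  target <- test_fraction * n
  test_clusters <- character(0)
  got <- 0L
  for (cl in ord) {
    if (got >= target) break
    if (got + sizes[[cl]] >= n) next  # never empty the train partition
    test_clusters <- c(test_clusters, cl)
    got <- got + as.integer(sizes[[cl]])
  }
  in_test <- memb %in% as.integer(test_clusters)
  dataset_split(train_ids = compound_ids[!in_test],
                test_ids = compound_ids[in_test],
                seed = seed, test_fraction = test_fraction)
}

#' Specification of the controlled training-subset grid
#'
#' @param sizes Even subset sizes (default the benchmark grid
#'   2, 6, 12, 48, 96, 400, 1000, 4000).
#' @param repeats Number of independent subset draws per size (default 20).
#' @param seed Master seed for the draws.
#' @return A `subset_spec`; subsets are always class-balanced.
#' @export
subset_spec <- function(sizes = c(2L, 6L, 12L, 48L, 96L, 400L, 1000L, 4000L),
                        repeats = 20L, seed = 1L) {
  sizes <- as.integer(sizes)
  if (any(sizes < 2L) || any(sizes %% 2L != 0L)) {
    abort("subset sizes must be even and >= 2", "dti_config_error")
  }
  if (repeats < 1L) abort("repeats must be >= 1", "dti_config_error")
  structure(list(sizes = sizes, balanced = TRUE,
                 repeats = as.integer(repeats), seed = as.integer(seed)),
            class = "subset_spec")
}

#' Draw a balanced training subset
#'
#' Uniform seeded draw without replacement of `size/2` actives and
#' `size/2` inactives from a curated training set.
#'
#' @param train Data.frame of labeled compounds (needs a `label` column
#'   with values `"active"`/`"inactive"`).
#' @param size Even subset size.
#' @param seed Integer seed; equal seeds give identical draws.
#' @return A data.frame subset of `train` with exactly `size/2` rows per
#'   class.
#' @export
balanced_subset <- function(train, size, seed = 1L) {
  size <- as.integer(size)
  if (size < 2L || size %% 2L != 0L) {
    abort("subset size must be even and >= 2", "dti_config_error")
  }
  half <- size %/% 2L
  act <- which(train$label == "active")
  ina <- which(train$label == "inactive")
  if (length(act) < half || length(ina) < half) {
    abort(sprintf(
      "cannot draw %d per class: %d active / %d inactive available",
      half, length(act), length(ina)),
      "dti_sampling_error", needed = half,
      available = c(active = length(act), inactive = length(ina)))
  }
  picked <- local_seed(seed, {
    c(sample(act, half), sample(ina, half))
  })
  out <- train[picked, , drop = FALSE]
  rownames(out) <- NULL
  out
}
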