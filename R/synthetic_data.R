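# Synthetic multi-family task generator.
#
# Families are linear-threshold tasks over 300-d standard-normal features
# whose weight vectors share a controllable fraction of a common
# direction: w_f = normalize(sqrt(rho) * w0 + sqrt(1 - rho) * u_f). With
# rho near 1 the families' decision rules coincide and transfer from one
# family to another is maximally useful; with rho = 0 they are unrelated.
# Labels are the sign of the margin, flipped with probability eps. This
# reproduces the statistical regime the transfer benchmark needs (a
# data-rich source family related to a data-poor target family) without
# any chemistry.

#' Synthetic task configuration
#'
#' @param n_per_family Compounds per family (scalar, or named vector to
#'   give families different sizes).
#' @param dimension Feature dimension (default 300, the classifier input).
#' @param overlap Cross-family signal overlap rho in `[0, 1]`.
#' @param signal_strength Stretch factor applied to features along the
#'   family weight vector after labeling (default 1 = no stretch; labels
#'   are unaffected).
#' @param label_noise Label-flip probability eps in `[0, 0.5)`.
#' @param n_clusters Planted clusters for pseudo-fingerprint generation.
#' @param n_families Number of families when `family_names` not given.
#' @param family_names Optional family names.
#' @param seed Master seed.
#' @return A `synthetic_config`.
#' @export
synthetic_config <- function(n_per_family = 2000L, dimension = 300L,
                             overlap = 0.8, signal_strength = 1,
                             label_noise = 0.1, n_clusters = 10L,
                             n_families = 2L, family_names = NULL,
                             seed = 1L) {
  if (!is_scalar_number(overlap) || overlap < 0 || overlap > 1) {
    abort("overlap must be in [0, 1]", "dti_config_error")
  }
  if (!is_scalar_number(label_noise) || label_noise < 0 || label_noise >= 0.5) {
    abort("label_noise must be in [0, 0.5)", "dti_config_error")
  }
  if (!is_scalar_number(signal_strength) || signal_strength <= 0) {
    abort("signal_strength must be positive", "dti_config_error")
  }
  if (is.null(family_names)) {
    family_names <- paste0("family_", seq_len(n_families))
  }
  structure(list(n_per_family = n_per_family,
                 dimension = as.integer(dimension),
                 overlap = overlap, signal_strength = signal_strength,
                 label_noise = label_noise,
                 n_clusters = as.integer(n_clusters),
                 family_names = family_names,
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

unit_vector <- function(d) {
  v <- stats::rnorm(d)
  v / sqrt(sum(v^2))
}

#' Generate related synthetic families
#'
#' Draws a shared unit direction `w0` and per-family unit directions
#' `u_f`, sets each family's weight vector to
#' `normalize(sqrt(rho) w0 + sqrt(1-rho) u_f)`, samples standard-normal
#' features, labels by the sign of the margin and flips each label with
#' probability `label_noise`. When `n_per_family >= 4` a redraw guarantees
#' both classes are present. Seeded-deterministic.
#'
#' @param config A [synthetic_config()].
#' @return Named list of `synthetic_family` objects, each with `family`,
#'   `x` (features), `y` (0/1 labels), `labels`
#'   (`"active"`/`"inactive"`), and the ground-truth `w`.
#' @export
generate_families <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  fams <- config$family_names
  sizes <- config$n_per_family
  if (length(sizes) == 1L) {
    sizes <- stats::setNames(rep(as.integer(sizes), length(fams)), fams)
  } else if (is.null(names(sizes))) {
    stopifnot(length(sizes) == length(fams))
    sizes <- stats::setNames(as.integer(sizes), fams)
  }
  d <- config$dimension
  rho <- config$overlap
  local_seed(config$seed, {
    w0 <- unit_vector(d)
    out <- lapply(fams, function(f) {
      u <- unit_vector(d)
      w <- sqrt(rho) * w0 + sqrt(1 - rho) * u
      w <- w / sqrt(sum(w^2))
      n <- sizes[[f]]
      for (try in 1:100) {
        x <- matrix(stats::rnorm(n * d), n, d)
        margin <- drop(x %*% w)
        y <- as.integer(margin > 0)
        flip <- stats::runif(n) < config$label_noise
        y[flip] <- 1L - y[flip]
        if (n < 4L || length(unique(y)) == 2L) break
      }
      if (config$signal_strength != 1) {
        x <- x + (config$signal_strength - 1) * tcrossprod(margin, w)
      }
      ids <- sprintf("%s_c%05d", f, seq_len(n))
      rownames(x) <- ids
      structure(list(family = f, compound_id = ids, x = x, y = y,
                     labels = ifelse(y == 1L, "active", "inactive"),
                     w = w),
                class = "synthetic_family")
    })
    stats::setNames(out, fams)
  })
}

#' Source/target benchmark data at desk scale
#'
#' Generates one source and one target family from a shared
#' [synthetic_config()] and splits the target family into train and test.
#' Defaults are the package's desk-scale benchmark conditions: source
#' n = 5000, target train n = 2000, target test n = 1000, overlap 0.8,
#' label noise 0.1.
#'
#' @param config A [synthetic_config()]; `n_per_family` is ignored in
#'   favor of the explicit sizes.
#' @param n_source,n_target_train,n_target_test Family sizes.
#' @return List with `source`, `target_train`, `target_test` (each a list
#'   with `x`, `y`, `family`) and the two `synthetic_family` objects.
#' @export
synthetic_benchmark_data <- function(config = synthetic_config(),
                                     n_source = 5000L,
                                     n_target_train = 2000L,
                                     n_target_test = 1000L) {
  cfg <- config
  cfg$family_names <- c("source", "target")
  cfg$n_per_family <- c(source = as.integer(n_source),
                        target = as.integer(n_target_train + n_target_test))
  fams <- generate_families(cfg)
  tgt <- fams$target
  split_idx <- local_seed(cfg$seed + 1L,
                          sample.int(nrow(tgt$x), n_target_train))
  list(
    source = list(x = fams$source$x, y = fams$source$y, family = "source"),
    target_train = list(x = tgt$x[split_idx, , drop = FALSE],
                        y = tgt$y[split_idx], family = "target"),
    target_test = list(x = tgt$x[-split_idx, , drop = FALSE],
                       y = tgt$y[-split_idx], family = "target"),
    families = fams
  )
}

#' Fixed 12-row toy activity table
#'
#' A hand-constructed curation fixture exercising every attribute filter:
#' 8 fully conforming records (among them one compound-target pair
#' measured twice, at pChEMBL 6.0 and 8.0, whose median 7.0 labels active
#' under the >= convention), plus one functional-assay record, one
#' non-human record, one record without a pChEMBL value and one with a
#' disallowed standard type. Values are fixed; the `seed` argument is
#' accepted for interface uniformity and ignored.
#'
#' @param seed Ignored; the fixture is deterministic by construction.
#' @return A 12-row activity-record data.frame.
#' @export
generate_toy_activity_table <- function(seed = 1L) {
  conforming <- function(id, smiles, target, pchembl, family,
                         assay = "binding", tax = "human",
                         ttype = "SINGLE PROTEIN", stype = "IC50") {
    data.frame(compound_id = id, smiles = smiles, target_id = target,
               target_type = ttype, taxonomy = tax, assay_type = assay,
               standard_type = stype, pchembl = pchembl, family = family,
               stringsAsFactors = FALSE)
  }
  rbind(
    conforming("C01", "CCO", "T1", 6.0, "transporter"),
    conforming("C01", "CCO", "T1", 8.0, "transporter", stype = "Ki"),
    conforming("C02", "c1ccccc1O", "T1", 8.2, "transporter"),
    conforming("C03", "CCN", "T1", 6.1, "transporter", stype = "EC50"),
    conforming("C04", "CC(=O)O", "T2", 7.0, "kinase", stype = "Kd"),
    conforming("C05", "c1ccncc1", "T2", 5.5, "kinase", stype = "AC50"),
    conforming("C06", "CCCC", "T2", 9.1, "kinase", stype = "Potency"),
    conforming("C07", "CC(C)O", "T2", 6.9, "kinase"),
    conforming("C08", "COC", "T1", 8.5, "transporter", assay = "functional"),
    conforming("C09", "CCS", "T1", 7.4, "transporter", tax = "mouse"),
    conforming("C10", "CCCl", "T2", NA_real_, "kinase"),
    conforming("C11", "CBr", "T2", 7.9, "kinase", stype = "other")
  )
}

#' Pseudo-fingerprints with planted cluster structure
#'
#' Each cluster gets a random centroid bit set; members copy the centroid,
#' dropping each bit with probability `flip_rate` and adding a small
#' Poisson number of random extra bits. With the defaults, intra-cluster
#' Tanimoto stays >= 0.8 and inter-cluster similarity stays far below it
#' with high probability, so leader clustering recovers the planted
#' partition.
#'
#' @param n_clusters Number of planted clusters (>= 1).
#' @param cluster_size Members per cluster (scalar or vector).
#' @param nbits Fingerprint length (default 2048).
#' @param n_bits_on Centroid bit count (default 96).
#' @param flip_rate Per-bit drop probability (default 0.02; two members
#'   drop bits independently, so the expected member-to-member Tanimoto is
#'   roughly `(1 - flip_rate)^2 / (1 + 2 * flip_rate)` and the default
#'   keeps it near 0.93, safely above the 0.8 cutoff).
#' @param seed Seed.
#' @return List with `fingerprints` (named list of `fingerprint`) and
#'   `clusters` (named integer vector: the planted ground truth).
#' @export
generate_pseudo_fingerprints <- function(n_clusters = 5L, cluster_size = 10L,
                                         nbits = 2048L, n_bits_on = 96L,
                                         flip_rate = 0.02, seed = 1L) {
  if (n_clusters < 1L) abort("n_clusters must be >= 1", "dti_config_error")
  sizes <- rep(as.integer(cluster_size), length.out = n_clusters)
  local_seed(seed, {
    fps <- list()
    truth <- integer(0)
    for (k in seq_len(n_clusters)) {
      centroid <- sample.int(nbits, n_bits_on) - 1L
      for (m in seq_len(sizes[k])) {
        keep <- centroid[stats::runif(n_bits_on) >= flip_rate]
        extra_n <- stats::rpois(1L, flip_rate * n_bits_on)
        extras <- if (extra_n > 0L) {
          sample(setdiff(seq_len(nbits) - 1L, keep), min(extra_n, nbits - length(keep)))
        } else {
          integer(0)
        }
        id <- sprintf("cl%02d_m%03d", k, m)
        fps[[id]] <- fingerprint(c(keep, extras), nbits = nbits)
        truth[id] <- k
      }
    }
    list(fingerprints = fps, clusters = truth)
  })
}

#' Export a synthetic family as an activity table and embedding file
#'
#' Writes the family's compounds as a curated-style activity table (with a
#' placeholder SMILES column, since synthetic compounds have no chemistry)
#' and its feature vectors as an embedding TSV, so the file-based pipeline
#' can be exercised end-to-end.
#'
#' @param family A `synthetic_family`.
#' @param dir Output directory.
#' @param threshold pChEMBL threshold used to synthesize consistent
#'   pChEMBL values from the labels (actives at 7.5, inactives at 6.5
#'   around the 7.0 threshold).
#' @return Invisibly, the two paths written.
#' @export
write_synthetic_family <- function(family, dir, threshold = 7.0) {
  stopifnot(inherits(family, "synthetic_family"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tab <- data.frame(
    compound_id = family$compound_id,
    smiles = "*",
    target_id = family$family,
    target_type = "SINGLE PROTEIN",
    taxonomy = "human",
    assay_type = "binding",
    standard_type = "IC50",
    pchembl = ifelse(family$y == 1L, threshold + 0.5, threshold - 0.5),
    family = "other",
    stringsAsFactors = FALSE
  )
  table_path <- file.path(dir, paste0(family$family, "_activity.csv"))
  write_activity_table(tab, table_path)
  emb_path <- file.path(dir, paste0(family$family, "_embeddings.tsv"))
  write_embeddings(embedding_table(family$x), emb_path)
  invisible(c(table_path, emb_path))
}
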