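test_that("full overlap gives identical family weight vectors", {
  fams <- generate_families(synthetic_config(n_per_family = 50L,
                                             overlap = 1, label_noise = 0,
                                             n_families = 3L, seed = 2L))
  expect_equal(fams[[1]]$w, fams[[2]]$w, tolerance = 1e-12)
  expect_equal(fams[[1]]$w, fams[[3]]$w, tolerance = 1e-12)
  # noise-free labels equal the sign of the margin
  f <- fams[[1]]
  expect_equal(f$y, as.integer(drop(f$x %*% f$w) > 0))
})

test_that("zero overlap gives near-orthogonal weight vectors", {
  dots <- vapply(1:20, function(s) {
    fams <- generate_families(synthetic_config(n_per_family = 4L,
                                               overlap = 0, seed = s))
    abs(sum(fams[[1]]$w * fams[[2]]$w))
  }, numeric(1))
  # independent random unit vectors in 300-d: |<u,v>| ~ 1/sqrt(300) = 0.06
  expect_lt(mean(dots), 0.15)
})

test_that("weight vectors are unit length and interpolate with overlap", {
  for (rho in c(0, 0.3, 0.8, 1)) {
    fams <- generate_families(synthetic_config(n_per_family = 4L,
                                               overlap = rho, seed = 6L))
    for (f in fams) expect_equal(sum(f$w^2), 1, tolerance = 1e-12)
  }
  # same seed: higher overlap -> more similar family vectors
  sim_at <- function(rho) {
    fams <- generate_families(synthetic_config(n_per_family = 4L,
                                               overlap = rho, seed = 8L))
    sum(fams[[1]]$w * fams[[2]]$w)
  }
  expect_gt(sim_at(0.9), sim_at(0.3))
})

test_that("generation is seeded-deterministic with balanced classes", {
  cfg <- synthetic_config(n_per_family = 2000L, overlap = 0.8,
                          label_noise = 0.1, seed = 19L)
  a <- generate_families(cfg)
  b <- generate_families(cfg)
  expect_identical(a, b)
  balance <- mean(a[[1]]$y)
  expect_gt(balance, 0.45)
  expect_lt(balance, 0.55)
  expect_equal(dim(a[[1]]$x), c(2000L, 300L))
  expect_equal(a[[1]]$labels, ifelse(a[[1]]$y == 1L, "active", "inactive"))
})

test_that("both classes are present whenever n >= 4", {
  for (s in 1:10) {
    fams <- generate_families(synthetic_config(n_per_family = 4L,
                                               label_noise = 0, seed = s))
    for (f in fams) expect_equal(sort(unique(f$y)), c(0L, 1L))
  }
})

test_that("label noise flips approximately the requested fraction", {
  cfg <- synthetic_config(n_per_family = 5000L, label_noise = 0.1, seed = 23L)
  f <- generate_families(cfg)[[1]]
  clean <- as.integer(drop(f$x %*% f$w) > 0)
  flip_rate <- mean(clean != f$y)
  expect_gt(flip_rate, 0.08)
  expect_lt(flip_rate, 0.12)
})

test_that("signal strength stretches features without changing labels", {
  base <- generate_families(synthetic_config(n_per_family = 100L,
                                             label_noise = 0, seed = 3L))
  stretched <- generate_families(synthetic_config(n_per_family = 100L,
                                                  label_noise = 0,
                                                  signal_strength = 3,
                                                  seed = 3L))
  f0 <- base[[1]]; f3 <- stretched[[1]]
  expect_identical(f0$y, f3$y)
  expect_equal(drop(f3$x %*% f3$w), 3 * drop(f0$x %*% f0$w),
               tolerance = 1e-10)
  # off-signal directions are untouched
  resid0 <- f0$x - tcrossprod(drop(f0$x %*% f0$w), f0$w)
  resid3 <- f3$x - tcrossprod(drop(f3$x %*% f3$w), f3$w)
  expect_equal(resid0, resid3, tolerance = 1e-10)
})

test_that("configuration validation rejects out-of-range parameters", {
  expect_error(synthetic_config(overlap = 1.2), class = "dti_config_error")
  expect_error(synthetic_config(overlap = -0.1), class = "dti_config_error")
  expect_error(synthetic_config(label_noise = 0.5), class = "dti_config_error")
  expect_error(synthetic_config(signal_strength = 0),
               class = "dti_config_error")
})

test_that("the desk-scale benchmark data partitions the target family", {
  data <- synthetic_benchmark_data(
    synthetic_config(dimension = 20L, seed = 4L),
    n_source = 100L, n_target_train = 60L, n_target_test = 40L
  )
  expect_equal(nrow(data$source$x), 100L)
  expect_equal(nrow(data$target_train$x), 60L)
  expect_equal(nrow(data$target_test$x), 40L)
  expect_length(intersect(rownames(data$target_train$x),
                          rownames(data$target_test$x)), 0)
  expect_setequal(c(rownames(data$target_train$x),
                    rownames(data$target_test$x)),
                  data$families$target$compound_id)
})

test_that("pseudo-fingerprints with zero flip rate are exact copies", {
  gen <- generate_pseudo_fingerprints(n_clusters = 3L, cluster_size = 4L,
                                      flip_rate = 0, seed = 12L)
  for (k in 1:3) {
    members <- gen$fingerprints[gen$clusters == k]
    for (m in members) {
      expect_equal(tanimoto(members[[1]], m), 1)
    }
  }
})

test_that("pseudo-fingerprint clusters separate across the 0.8 cutoff", {
  gen <- generate_pseudo_fingerprints(seed = 44L)
  fps <- gen$fingerprints
  ids <- names(fps)
  same <- outer(gen$clusters, gen$clusters, "==")
  for (i in seq_along(ids)) {
    for (j in seq_len(i - 1L)) {
      s <- tanimoto(fps[[i]], fps[[j]])
      if (same[i, j]) expect_gte(s, 0.8) else expect_lt(s, 0.8)
    }
  }
})

test_that("synthetic families export to readable activity and embedding files", {
  fams <- generate_families(synthetic_config(n_per_family = 20L,
                                             dimension = 8L, seed = 9L))
  dir <- withr::local_tempdir()
  paths <- write_synthetic_family(fams[[1]], dir)
  tab <- read_activity_table(paths[1])
  expect_equal(nrow(tab), 20L)
  curated <- curate(tab)
  labels <- do.call(rbind, curated)$label
  expect_equal(sort(unique(labels)), c("active", "inactive"))
  emb <- read_embeddings(paths[2])
  expect_equal(emb$dimension, 8L)
  expect_equal(unname(emb$vectors), unname(fams[[1]]$x), tolerance = 1e-12)
})

test_that("scratch training is Bayes-consistent on noise-free data", {
  # the decision direction must be estimated from data, so "large n" means
  # large relative to the 300 dimensions: with n = 11000 the angular
  # estimation error is small enough for MCC > 0.9 on held-out data
  fams <- generate_families(synthetic_config(n_per_family = c(12000L, 4L),
                                             label_noise = 0, seed = 27L))
  f <- fams[[1]]
  train_idx <- 1:11000
  test_idx <- 11001:12000
  cfg <- fnn_config(epochs = 30L, learning_rate = 1e-3, seed = 5L)
  run <- train_fnn(init_fnn(cfg), f$x[train_idx, ], f$y[train_idx], cfg)
  pred <- predict_fnn(run$params, f$x[test_idx, ])
  mcc <- compute_metrics(f$y[test_idx], pred$labels)$mcc
  expect_gt(mcc, 0.9)
})

test_that("the transfer benefit grows with cross-family overlap", {
  gap_at <- function(rho) {
    data <- synthetic_benchmark_data(
      synthetic_config(overlap = rho, label_noise = 0.1, seed = 37L),
      n_source = 1500L, n_target_train = 500L, n_target_test = 500L
    )
    cfg <- fnn_config(epochs = 25L, seed = 51L)
    res <- run_benchmark(data$source, data$target_train, data$target_test,
                         spec = subset_spec(sizes = 12L, repeats = 20L,
                                            seed = 61L),
                         modes = c("mode1_full_finetune",
                                   "scratch_reference"),
                         config = cfg)
    agg <- aggregate_results(res)
    agg$mcc_mean[agg$mode == "mode1_full_finetune"] -
      agg$mcc_mean[agg$mode == "scratch_reference"]
  }
  expect_gt(gap_at(0.9), gap_at(0))
})
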