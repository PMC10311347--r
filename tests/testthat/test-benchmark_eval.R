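test_that("metrics match hand-computed confusion values", {
  # perfect predictions
  perfect <- compute_metrics(c(1, 0, 1, 0), c(1, 0, 1, 0), c(0.9, 0.1, 0.8, 0.2))
  expect_equal(perfect$mcc, 1)
  expect_equal(perfect$accuracy, 1)
  expect_equal(perfect$auroc, 1)
  # balanced confusion: TP=TN=FP=FN=1 -> numerator zero
  expect_equal(compute_metrics(c(1, 1, 0, 0), c(1, 0, 1, 0))$mcc, 0)
  # TP=40, TN=35, FP=13, FN=8, evaluated by hand from the formula
  truth <- rep(c(1, 0, 0, 1), c(40, 35, 13, 8))
  pred <- rep(c(1, 0, 1, 0), c(40, 35, 13, 8))
  m <- compute_metrics(truth, pred)
  expect_equal(m$mcc, (40 * 35 - 13 * 8) /
                 sqrt(53) / sqrt(48) / sqrt(48) / sqrt(43))
  expect_equal(m$precision, 40 / 53)
  expect_equal(m$recall, 40 / 48)
  expect_equal(m$accuracy, 75 / 96)
})

test_that("metrics agree with independent oracles on all 2^8 labelings", {
  set.seed(55)
  for (truth_bits in 0:255) {
    truth <- as.integer(intToBits(truth_bits))[1:8]
    pred <- sample(0:1, 8, replace = TRUE)
    scores <- rnorm(8)
    m <- compute_metrics(truth, pred, scores)
    expect_equal(m$mcc, oracle_mcc(truth, pred), tolerance = 1e-12)
    conf <- oracle_confusion(truth, pred)
    expect_equal(m$precision, conf$precision)
    expect_equal(m$recall, conf$recall)
    expect_equal(m$f1, conf$f1)
    expect_equal(m$accuracy, conf$accuracy)
    expect_equal(m$auroc, oracle_auroc(truth, scores))
  }
})

test_that("AUROC handles perfect, inverted, tied, and degenerate cases", {
  truth <- c(1, 1, 0, 0)
  expect_equal(compute_metrics(truth, truth, c(4, 3, 2, 1))$auroc, 1)
  expect_equal(compute_metrics(truth, truth, c(1, 2, 3, 4))$auroc, 0)
  expect_equal(compute_metrics(truth, truth, c(1, 1, 1, 1))$auroc, 0.5)
  expect_true(is.na(compute_metrics(truth, truth)$auroc))
  expect_true(is.na(compute_metrics(c(1, 1), c(1, 0), c(0.2, 0.3))$auroc))
})

test_that("metric input validation raises structured errors", {
  expect_error(compute_metrics(integer(0), integer(0)),
               class = "dti_value_error")
  expect_error(compute_metrics(c(1, 0), c(1)), class = "dti_dimension_error")
  expect_error(compute_metrics(c(1, 0), c(1, 0), 0.5),
               class = "dti_dimension_error")
})

# Fast reduced-scale benchmark setup reused by the grid-mechanics tests.
bench_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      data <- synthetic_benchmark_data(
        synthetic_config(dimension = 10L, overlap = 0.9, label_noise = 0.05,
                         seed = 41L),
        n_source = 400L, n_target_train = 200L, n_target_test = 200L
      )
      cfg <- fnn_config(input_dim = 10L, hidden_sizes = c(12L, 6L),
                        epochs = 5L, learning_rate = 1e-2, batch_size = 64L,
                        seed = 13L)
      cache <<- list(data = data, cfg = cfg)
    }
    cache
  }
})

test_that("the grid emits one record per mode, size, and repeat", {
  fx <- bench_fixture()
  res <- run_benchmark(fx$data$source, fx$data$target_train,
                       fx$data$target_test,
                       spec = subset_spec(sizes = 2L, repeats = 3L, seed = 7L),
                       modes = c("mode1_full_finetune", "scratch_reference"),
                       config = fx$cfg)
  expect_s3_class(res, "experiment_result")
  expect_equal(nrow(res), 6L)
  counts <- table(res$mode)
  expect_equal(as.integer(counts[c("mode1_full_finetune",
                                   "scratch_reference")]), c(3L, 3L))
  expect_true(all(res$mcc >= -1 & res$mcc <= 1))
  expect_true(all(lengths(res$loss) == 5L))
})

test_that("infeasible sizes are skipped with a warning, not an error", {
  fx <- bench_fixture()
  expect_warning(
    res <- run_benchmark(fx$data$source, fx$data$target_train,
                         fx$data$target_test,
                         spec = subset_spec(sizes = c(2L, 4000L),
                                            repeats = 2L, seed = 7L),
                         modes = "scratch_base", config = fx$cfg),
    "infeasible"
  )
  expect_equal(unique(res$size), 2L)
  expect_equal(nrow(res), 2L)
})

test_that("all modes within a repeat share the identical subset draw", {
  fx <- bench_fixture()
  res <- run_benchmark(fx$data$source, fx$data$target_train,
                       fx$data$target_test,
                       spec = subset_spec(sizes = 6L, repeats = 2L, seed = 3L),
                       config = fx$cfg)
  for (r in unique(res$rep)) {
    expect_length(unique(res$subset_seed[res$rep == r]), 1L)
  }
  expect_setequal(unique(res$mode),
                  c("mode1_full_finetune", "mode2_feature_transformer",
                    "mode3_shallow", "zero_shot", "scratch_reference",
                    "scratch_base"))
})

test_that("a supplied source model skips Stage I and is used as-is", {
  fx <- bench_fixture()
  src_params <- pretrain_source(fx$data$source$x, fx$data$source$y, fx$cfg)
  spec <- subset_spec(sizes = 2L, repeats = 1L, seed = 5L)
  a <- run_benchmark(fx$data$source, fx$data$target_train,
                     fx$data$target_test, spec = spec, modes = "zero_shot",
                     config = fx$cfg, source_params = src_params)
  b <- run_benchmark(fx$data$source, fx$data$target_train,
                     fx$data$target_test, spec = spec, modes = "zero_shot",
                     config = fx$cfg)
  expect_equal(a$mcc, b$mcc)
  expect_error(
    run_benchmark(fx$data$source, fx$data$target_train, fx$data$target_test,
                  spec = spec, modes = "mode7", config = fx$cfg),
    class = "dti_config_error"
  )
})

test_that("aggregation reproduces hand-computed means and sds", {
  rec <- data.frame(
    mode = "m", size = 2L, rep = 1:3,
    mcc = c(0.2, 0.4, 0.9), auroc = c(0.7, 0.8, 0.9),
    precision = 0.5, recall = 0.5, f1 = 0.5, accuracy = c(0.6, 0.6, 0.9),
    stringsAsFactors = FALSE
  )
  agg <- aggregate_results(rec)
  expect_equal(nrow(agg), 1L)
  expect_equal(agg$mcc_mean, 0.5)
  expect_equal(agg$mcc_sd, sd(c(0.2, 0.4, 0.9)))
  expect_equal(agg$accuracy_mean, 0.7)
  expect_true(agg$sd_defined)
  expect_equal(agg$n_repeats, 3L)

  single <- aggregate_results(rec[1, , drop = FALSE])
  expect_equal(single$mcc_sd, 0)
  expect_false(single$sd_defined)

  shuffled <- aggregate_results(rec[c(3, 1, 2), , drop = FALSE])
  expect_equal(shuffled, agg)
})

test_that("benchmark outputs are written and re-readable", {
  fx <- bench_fixture()
  res <- run_benchmark(fx$data$source, fx$data$target_train,
                       fx$data$target_test,
                       spec = subset_spec(sizes = 2L, repeats = 2L, seed = 9L),
                       modes = c("scratch_reference", "scratch_base"),
                       config = fx$cfg)
  dir <- withr::local_tempdir()
  paths <- write_benchmark_results(res, dir)
  expect_true(file.exists(file.path(dir, "per_repeat.csv")))
  expect_true(file.exists(file.path(dir, "summary.csv")))
  expect_true(file.exists(file.path(dir, "loss_curves.csv")))
  per <- read.csv(file.path(dir, "per_repeat.csv"))
  expect_equal(nrow(per), nrow(res))
  summ <- read.csv(file.path(dir, "summary.csv"))
  expect_equal(nrow(summ), 2L)
  curves <- read.csv(file.path(dir, "loss_curves.csv"))
  expect_equal(unique(curves$mode), "scratch_reference")
})
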