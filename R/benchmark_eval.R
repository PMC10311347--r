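# Evaluation: confusion-matrix metrics (MCC-centric) and the benchmark
# grid over transfer modes x training-subset sizes x repeats.

#' Binary classification metrics
#'
#' Computes MCC, AUROC, precision, recall, F1 and accuracy from true and
#' predicted labels plus (optionally) ranking scores. MCC follows the
#' contingency formula `(TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`
#' with 0 returned when the denominator vanishes; precision/recall/F1 use
#' the same zero-denominator convention. AUROC is the Mann-Whitney rank
#' statistic over `scores` (ties get average ranks) and is `NA` when
#' scores are missing or only one class is present.
#'
#' @param truth,pred Labels (`"active"`/`"inactive"` or 0/1), equal length.
#' @param scores Optional numeric scores, larger = more active.
#' @return Named list: `mcc`, `auroc`, `precision`, `recall`, `f1`,
#'   `accuracy`.
#' @export
compute_metrics <- function(truth, pred, scores = NULL) {
  truth <- as_binary_labels(truth)
  pred <- as_binary_labels(pred)
  if (!length(truth)) abort("empty input", "dti_value_error")
  if (length(truth) != length(pred) ||
      (!is.null(scores) && length(scores) != length(truth))) {
    abort("truth, pred and scores must have equal lengths",
          "dti_dimension_error")
  }
  tp <- sum(truth == 1L & pred == 1L)
  tn <- sum(truth == 0L & pred == 0L)
  fp <- sum(truth == 0L & pred == 1L)
  fn <- sum(truth == 1L & pred == 0L)

  denom <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  mcc <- if (denom == 0) 0 else (tp * tn - fp * fn) / denom
  precision <- if (tp + fp == 0) 0 else tp / (tp + fp)
  recall <- if (tp + fn == 0) 0 else tp / (tp + fn)
  f1 <- if (precision + recall == 0) 0 else
    2 * precision * recall / (precision + recall)
  accuracy <- (tp + tn) / length(truth)

  auroc <- NA_real_
  npos <- sum(truth == 1L)
  nneg <- sum(truth == 0L)
  if (!is.null(scores) && npos > 0L && nneg > 0L) {
    r <- rank(scores)
    auroc <- (sum(r[truth == 1L]) - npos * (npos + 1) / 2) / (npos * nneg)
  }
  list(mcc = mcc, auroc = auroc, precision = precision, recall = recall,
       f1 = f1, accuracy = accuracy)
}

METRIC_NAMES <- c("mcc", "auroc", "precision", "recall", "f1", "accuracy")

check_xy <- function(data, what) {
  if (!is.list(data) || is.null(data$x) || is.null(data$y)) {
    abort(sprintf("%s must be a list with elements x (matrix) and y (labels)",
                  what), "dti_config_error")
  }
  list(x = as.matrix(data$x), y = as_binary_labels(data$y),
       family = data$family %||% NA_character_)
}

#' Run the transfer-learning benchmark grid
#'
#' Pre-trains a source model once, then for every repeat and subset size
#' draws one balanced target training subset and trains every requested
#' mode on that same subset (paired design), evaluating all of them on the
#' fixed target test set. Sizes too large for the target training pool are
#' skipped with a warning. Fully deterministic given `spec$seed` and
#' `config$seed`.
#'
#' @param source List with `x` (matrix), `y` (labels) and optionally
#'   `family`: the source-family training data.
#' @param target_train,target_test Same structure for the target family.
#' @param spec A [subset_spec()].
#' @param modes Character vector of modes to run; any of
#'   `"mode1_full_finetune"`, `"mode2_feature_transformer"`,
#'   `"mode3_shallow"`, `"zero_shot"`, `"scratch_reference"`,
#'   `"scratch_base"`.
#' @param config An [fnn_config()] used for Stage I and all FNN training.
#' @param svm_hyper A [shallow_hyper()] for Mode 3 and the base model.
#' @param source_params Optional pre-trained source `fnn_params`; when
#'   supplied, Stage I is skipped and these weights are used.
#' @return An `experiment_result`: data.frame with one row per
#'   (mode, size, repeat) holding the metric set, the seeds used, and the
#'   per-epoch training-loss curve in the list-column `loss`.
#' @export
run_benchmark <- function(source, target_train, target_test,
                          spec = subset_spec(),
                          modes = TRANSFER_MODES,
                          config = fnn_config(),
                          svm_hyper = shallow_hyper(),
                          source_params = NULL) {
  stopifnot(inherits(spec, "subset_spec"), inherits(config, "fnn_config"))
  bad <- setdiff(modes, TRANSFER_MODES)
  if (length(bad)) {
    abort(sprintf("unknown mode(s): %s", paste(bad, collapse = ", ")),
          "dti_config_error")
  }
  src <- check_xy(source, "source")
  trn <- check_xy(target_train, "target_train")
  tst <- check_xy(target_test, "target_test")

  needs_source <- any(modes %in% c("mode1_full_finetune",
                                   "mode2_feature_transformer",
                                   "mode3_shallow", "zero_shot"))
  if (needs_source && is.null(source_params)) {
    source_params <- pretrain_source(src$x, src$y, config)
  }

  train_pool <- data.frame(
    idx = seq_along(trn$y),
    label = ifelse(trn$y == 1L, "active", "inactive"),
    stringsAsFactors = FALSE
  )

  grid_n <- spec$repeats * length(spec$sizes)
  seeds <- matrix(derive_seeds(spec$seed, grid_n * 3L), ncol = 3L)
  colnames(seeds) <- c("subset", "init", "train")

  rows <- list()
  losses <- list()
  cell <- 0L
  for (r in seq_len(spec$repeats)) {
    for (s in spec$sizes) {
      cell <- cell + 1L
      subset <- tryCatch(
        balanced_subset(train_pool, s, seed = seeds[cell, "subset"]),
        dti_sampling_error = function(e) NULL
      )
      if (is.null(subset)) {
        if (r == 1L) {
          warning(sprintf("subset size %d infeasible for the target training pool; skipped", s),
                  call. = FALSE)
        }
        next
      }
      xb <- trn$x[subset$idx, , drop = FALSE]
      yb <- trn$y[subset$idx]
      cfg_train <- config
      cfg_train$seed <- seeds[cell, "train"]

      for (mode in modes) {
        res <- switch(
          mode,
          scratch_reference = {
            cfg_init <- config
            cfg_init$seed <- seeds[cell, "init"]
            run <- train_fnn(init_fnn(cfg_init), xb, yb, cfg_train)
            new_transfer_result("scratch_reference", params = run$params,
                                record = run$record,
                                target_family = trn$family)
          },
          scratch_base = {
            model <- fit_shallow(xb, yb, svm_hyper)
            new_transfer_result("scratch_base", shallow = model,
                                target_family = trn$family)
          },
          mode1_full_finetune =
            mode1_full_finetune(source_params, xb, yb, cfg_train,
                                src$family, trn$family),
          mode2_feature_transformer =
            mode2_feature_transformer(source_params, xb, yb, cfg_train,
                                      src$family, trn$family),
          mode3_shallow =
            mode3_shallow(source_params, xb, yb, svm_hyper,
                          src$family, trn$family),
          zero_shot = zero_shot(source_params, src$family, trn$family)
        )
        pred <- predict(res, tst$x)
        met <- compute_metrics(tst$y, pred$labels, pred$scores)
        rows[[length(rows) + 1L]] <- data.frame(
          source_family = src$family, target_family = trn$family,
          mode = mode, size = s, rep = r,
          subset_seed = seeds[cell, "subset"],
          as.data.frame(met), stringsAsFactors = FALSE
        )
        losses[[length(losses) + 1L]] <-
          if (is.null(res$record)) numeric(0) else res$record$loss
      }
    }
  }
  if (!length(rows)) {
    abort("no feasible (size, repeat) cells in the benchmark grid",
          "dti_value_error")
  }
  out <- do.call(rbind, rows)
  out$loss <- losses
  rownames(out) <- NULL
  class(out) <- c("experiment_result", "data.frame")
  out
}

#' Aggregate benchmark records
#'
#' Mean and sample standard deviation of every metric per (mode, size),
#' with the repeat count. With a single repeat the sd is reported as 0 and
#' flagged via `sd_defined = FALSE`.
#'
#' @param results An `experiment_result` from [run_benchmark()].
#' @return Data.frame, one row per (mode, size), ordered by mode then
#'   size; invariant to the order of the input records.
#' @export
aggregate_results <- function(results) {
  if (!nrow(results)) abort("no records to aggregate", "dti_value_error")
  key <- interaction(results$mode, results$size, drop = TRUE)
  groups <- split(seq_len(nrow(results)), key)
  rows <- lapply(groups, function(ii) {
    block <- results[ii, , drop = FALSE]
    stats_row <- lapply(METRIC_NAMES, function(mn) {
      v <- block[[mn]]
      m <- mean(v)
      s <- if (length(v) > 1L) stats::sd(v) else 0
      stats::setNames(list(m, s), paste0(mn, c("_mean", "_sd")))
    })
    cbind(data.frame(mode = block$mode[1L], size = block$size[1L],
                     n_repeats = nrow(block),
                     sd_defined = nrow(block) > 1L,
                     stringsAsFactors = FALSE),
          as.data.frame(do.call(c, stats_row)))
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$mode, out$size), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write benchmark outputs
#'
#' Writes the long-format per-repeat records (without loss curves) and the
#' aggregated summary as CSV, plus one loss-curve CSV per FNN-trained
#' record group.
#'
#' @param results An `experiment_result`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_benchmark_results <- function(results, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  flat <- results
  flat$loss <- NULL
  class(flat) <- "data.frame"
  per_repeat <- file.path(dir, "per_repeat.csv")
  utils::write.csv(flat, per_repeat, row.names = FALSE)
  summary_path <- file.path(dir, "summary.csv")
  utils::write.csv(aggregate_results(results), summary_path,
                   row.names = FALSE)
  has_loss <- which(lengths(results$loss) > 0L)
  loss_path <- NULL
  if (length(has_loss)) {
    loss_long <- do.call(rbind, lapply(has_loss, function(i) {
      data.frame(mode = results$mode[i], size = results$size[i],
                 rep = results$rep[i],
                 epoch = seq_along(results$loss[[i]]),
                 loss = results$loss[[i]])
    }))
    loss_path <- file.path(dir, "loss_curves.csv")
    utils::write.csv(loss_long, loss_path, row.names = FALSE)
  }
  invisible(c(per_repeat, summary_path, loss_path))
}
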