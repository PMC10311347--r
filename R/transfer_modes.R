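# Stage I pre-training and the Stage II transfer modes.
#
# Mode 1 (full fine-tuning): all layers initialized from the source model
# and re-trained. Mode 2 (feature transformer): both hidden layers frozen,
# only the output layer re-trained. Mode 3 (shallow classifier): the
# output layer is replaced by an SVM fit on frozen penultimate features.
# Zero-shot: the source model is used on the target family unchanged.

TRANSFER_MODES <- c("mode1_full_finetune", "mode2_feature_transformer",
                    "mode3_shallow", "zero_shot", "scratch_reference",
                    "scratch_base")

new_transfer_result <- function(mode, params = NULL, shallow = NULL,
                                record = NULL, source_family = NA_character_,
                                target_family = NA_character_) {
  structure(list(mode = mode, params = params, shallow = shallow,
                 record = record, source_family = source_family,
                 target_family = target_family),
            class = "transfer_result")
}

#' Pre-train a source model (Stage I)
#'
#' Full no-freeze training from a seeded scratch initialization on a
#' data-rich source family.
#'
#' @param x,y Source training vectors and labels (both classes required).
#' @param config An [fnn_config()].
#' @return An `fnn_params` with provenance `"pretrained"`, carrying the
#'   training record as attribute `"record"`.
#' @export
pretrain_source <- function(x, y, config = fnn_config()) {
  yb <- as_binary_labels(y)
  if (length(unique(yb)) < 2L) {
    abort("source training data must contain both classes",
          "dti_value_error")
  }
  run <- train_fnn(init_fnn(config), x, yb, config)
  params <- run$params
  params$provenance <- "pretrained"
  attr(params, "record") <- run$record
  params
}

#' Mode 1: full fine-tuning
#'
#' Every layer starts from the pre-trained source weights and all layers
#' are re-trained on the target data. With `config$epochs = 0` the result
#' predicts exactly like the source model (zero-shot identity at
#' initialization).
#'
#' @param source Pre-trained `fnn_params`.
#' @param x,y Target training data.
#' @param config An [fnn_config()]; fine-tuning reuses the scratch
#'   hyperparameters unless overridden.
#' @param source_family,target_family Optional family tags carried through
#'   to the result.
#' @return A `transfer_result`.
#' @export
mode1_full_finetune <- function(source, x, y, config = fnn_config(),
                                source_family = NA_character_,
                                target_family = NA_character_) {
  stopifnot(inherits(source, "fnn_params"))
  run <- train_fnn(source, x, y, config, freeze = c(FALSE, FALSE, FALSE))
  new_transfer_result("mode1_full_finetune", params = run$params,
                      record = run$record, source_family = source_family,
                      target_family = target_family)
}

#' Mode 2: feature transformer
#'
#' The source model's hidden layers are frozen (bit-identical after
#' training) and only the output layer is re-trained on the target data.
#'
#' @inheritParams mode1_full_finetune
#' @return A `transfer_result`.
#' @export
mode2_feature_transformer <- function(source, x, y, config = fnn_config(),
                                      source_family = NA_character_,
                                      target_family = NA_character_) {
  stopifnot(inherits(source, "fnn_params"))
  run <- train_fnn(source, x, y, config, freeze = c(TRUE, TRUE, FALSE))
  new_transfer_result("mode2_feature_transformer", params = run$params,
                      record = run$record, source_family = source_family,
                      target_family = target_family)
}

#' Mode 3: shallow classifier on frozen features
#'
#' The source model's output layer is replaced by a shallow SVM fit on the
#' frozen penultimate-layer features of the target training compounds. The
#' source parameters are never modified.
#'
#' @param source Pre-trained `fnn_params`.
#' @param x,y Target training data (both classes required).
#' @param svm_hyper A [shallow_hyper()].
#' @param source_family,target_family Optional family tags.
#' @return A `transfer_result` whose predictor is the composite
#'   shallow-model-on-extracted-features.
#' @export
mode3_shallow <- function(source, x, y, svm_hyper = shallow_hyper(),
                          source_family = NA_character_,
                          target_family = NA_character_) {
  stopifnot(inherits(source, "fnn_params"))
  feats <- extract_features(source, x)
  model <- fit_shallow(feats, y, svm_hyper)
  new_transfer_result("mode3_shallow", params = source, shallow = model,
                      source_family = source_family,
                      target_family = target_family)
}

#' Zero-shot baseline
#'
#' The unmodified source model is used directly as the target-family
#' predictor; no target data is consumed.
#'
#' @param source Pre-trained `fnn_params`.
#' @param source_family,target_family Optional family tags.
#' @return A `transfer_result`.
#' @export
zero_shot <- function(source, source_family = NA_character_,
                      target_family = NA_character_) {
  stopifnot(inherits(source, "fnn_params"))
  new_transfer_result("zero_shot", params = source,
                      source_family = source_family,
                      target_family = target_family)
}

#' Predict from a transfer result
#'
#' @param object A `transfer_result`.
#' @param x Numeric matrix of compound vectors.
#' @param ... Unused.
#' @return List with `labels` and `scores`.
#' @export
predict.transfer_result <- function(object, x, ...) {
  if (object$mode == "mode3_shallow") {
    predict_shallow(object$shallow, extract_features(object$params, x))
  } else if (object$mode == "scratch_base") {
    predict_shallow(object$shallow, x)
  } else {
    predict_fnn(object$params, x)
  }
}
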