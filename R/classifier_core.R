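# The FNN-2 binary classifier: a feed-forward network with two hidden
# layers (300 -> 1200 -> 300 -> 2), ReLU activations, softmax output and
# cross-entropy loss, trained with Adam. Layers can be frozen
# individually, which is what the transfer modes build on. Also the
# shallow SVM used as the from-scratch base model and as the Mode-3 head.

#' Classifier configuration
#'
#' Defaults are the reference FNN-2 configuration: two hidden layers of
#' 1200 and 300 units on a 300-d input, learning rate 1e-4, 100 training
#' epochs, mini-batches of 256.
#'
#' @param input_dim Input dimension (default 300).
#' @param hidden_sizes Sizes of the two hidden layers (default 1200, 300).
#' @param learning_rate Adam step size (default 1e-4).
#' @param epochs Training epochs (default 100; 0 is allowed and performs
#'   no update, which is how zero-shot equivalence is expressed).
#' @param batch_size Mini-batch size (default 256).
#' @param seed Seed for initialization and epoch shuffling.
#' @param adam_beta1,adam_beta2,adam_eps Adam moment decay rates and
#'   stabilizer.
#' @return An `fnn_config` object.
#' @export
fnn_config <- function(input_dim = 300L, hidden_sizes = c(1200L, 300L),
                       learning_rate = 1e-4, epochs = 100L,
                       batch_size = 256L, seed = 1L,
                       adam_beta1 = 0.9, adam_beta2 = 0.999,
                       adam_eps = 1e-8) {
  if (length(hidden_sizes) != 2L || any(hidden_sizes < 1L)) {
    abort("hidden_sizes must be two positive integers", "dti_config_error")
  }
  if (input_dim < 1L || batch_size < 1L || learning_rate <= 0 || epochs < 0L) {
    abort("invalid classifier configuration", "dti_config_error")
  }
  structure(list(input_dim = as.integer(input_dim),
                 hidden_sizes = as.integer(hidden_sizes),
                 learning_rate = learning_rate,
                 epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 seed = as.integer(seed),
                 adam_beta1 = adam_beta1, adam_beta2 = adam_beta2,
                 adam_eps = adam_eps),
            class = "fnn_config")
}

#' Initialize classifier parameters
#'
#' Seeded He-normal weight initialization (sd = sqrt(2 / fan_in)), zero
#' biases. Bit-identical across calls with the same configuration.
#'
#' @param config An [fnn_config()].
#' @return An `fnn_params` object with provenance `"scratch"`.
#' @export
init_fnn <- function(config = fnn_config()) {
  stopifnot(inherits(config, "fnn_config"))
  d <- config$input_dim
  h1 <- config$hidden_sizes[1L]
  h2 <- config$hidden_sizes[2L]
  weights <- local_seed(config$seed, list(
    W1 = matrix(stats::rnorm(d * h1, sd = sqrt(2 / d)), d, h1),
    b1 = numeric(h1),
    W2 = matrix(stats::rnorm(h1 * h2, sd = sqrt(2 / h1)), h1, h2),
    b2 = numeric(h2),
    W3 = matrix(stats::rnorm(h2 * 2L, sd = sqrt(2 / h2)), h2, 2L),
    b3 = numeric(2L)
  ))
  structure(list(weights = weights,
                 dims = c(input = d, hidden1 = h1, hidden2 = h2, output = 2L),
                 provenance = "scratch", seed = config$seed,
                 epochs_trained = 0L),
            class = "fnn_params")
}

#' @keywords internal
as_binary_labels <- function(y) {
  if (is.character(y) || is.factor(y)) {
    y <- as.character(y)
    bad <- setdiff(unique(y), c("active", "inactive"))
    if (length(bad)) {
      abort(sprintf("unknown label '%s'", bad[1L]), "dti_value_error")
    }
    return(as.integer(y == "active"))
  }
  y <- as.integer(y)
  if (any(!y %in% c(0L, 1L))) {
    abort("numeric labels must be 0/1", "dti_value_error")
  }
  y
}

add_bias <- function(z, b) z + rep(b, each = nrow(z))
relu <- function(z) (z > 0) * z

check_input_dim <- function(params, x) {
  if (!is.matrix(x)) x <- as.matrix(x)
  if (ncol(x) != params$dims[["input"]]) {
    abort(sprintf("input has %d columns, classifier expects %d",
                  ncol(x), params$dims[["input"]]),
          "dti_dimension_error")
  }
  x
}

# Forward through the two hidden layers; returns the 300-d penultimate
# activations.
hidden_forward <- function(w, x) {
  h1 <- relu(add_bias(x %*% w$W1, w$b1))
  relu(add_bias(h1 %*% w$W2, w$b2))
}

# Stable softmax cross-entropy pieces from logits z (n x 2) and labels
# y (0/1): per-example loss and probability matrix.
softmax_ce <- function(z, y = NULL) {
  m <- pmax(z[, 1L], z[, 2L])
  lse <- m + log(exp(z[, 1L] - m) + exp(z[, 2L] - m))
  p <- exp(z - lse)
  loss <- if (is.null(y)) NULL else lse - z[cbind(seq_len(nrow(z)), y + 1L)]
  list(p = p, loss = loss)
}

#' Train the classifier
#'
#' Mini-batch gradient training with softmax cross-entropy and Adam, with
#' seeded epoch shuffling. Layers flagged in `freeze` are left bit-exactly
#' untouched (no gradient, no optimizer state); when both hidden layers
#' are frozen the hidden representation is computed once and only the
#' output layer is iterated, which is mathematically identical and much
#' faster. The inner loop runs in compiled code; all randomness (the
#' epoch permutations) is drawn R-side under `config$seed`.
#'
#' @param params Starting `fnn_params` (e.g. from [init_fnn()] or a
#'   pre-trained source model).
#' @param x Numeric matrix of compound vectors (one row per compound).
#' @param y Labels: `"active"`/`"inactive"` or 0/1.
#' @param config An [fnn_config()]; `config$epochs` may be 0 (no update).
#' @param freeze Logical length-3 vector for layers L1, L2, Lout.
#' @return List with `params` (trained copy) and `record` (a
#'   `train_record` holding the per-epoch mean training loss).
#' @export
train_fnn <- function(params, x, y, config = fnn_config(),
                      freeze = c(FALSE, FALSE, FALSE)) {
  stopifnot(inherits(params, "fnn_params"), inherits(config, "fnn_config"))
  freeze <- as.logical(freeze)
  if (length(freeze) != 3L) {
    abort("freeze must flag the three layers L1, L2, Lout",
          "dti_config_error")
  }
  if (all(freeze)) {
    abort("all layers frozen: nothing to train", "dti_config_error")
  }
  x <- check_input_dim(params, x)
  y <- as_binary_labels(y)
  n <- nrow(x)
  if (n == 0L) abort("no training examples", "dti_value_error")
  if (length(y) != n) {
    abort("labels and inputs have different lengths", "dti_dimension_error")
  }

  w <- params$weights
  losses <- numeric(0)
  if (config$epochs > 0L) {
    perms <- local_seed(config$seed, {
      matrix(vapply(seq_len(config$epochs), function(e) sample.int(n),
                    integer(n)),
             nrow = config$epochs, byrow = TRUE)
    })
    if (freeze[1L] && freeze[2L]) {
      h2 <- hidden_forward(w, x)
      fit <- cpp_train_softmax(h2, y, w$W3, w$b3, perms, config$batch_size,
                               config$learning_rate, config$adam_beta1,
                               config$adam_beta2, config$adam_eps)
      w$W3 <- fit$W3
      w$b3 <- as.numeric(fit$b3)
    } else {
      fit <- cpp_train_fnn(x, y, w$W1, w$b1, w$W2, w$b2, w$W3, w$b3,
                           perms, config$batch_size, config$learning_rate,
                           config$adam_beta1, config$adam_beta2,
                           config$adam_eps, freeze)
      if (!freeze[1L]) { w$W1 <- fit$W1; w$b1 <- as.numeric(fit$b1) }
      if (!freeze[2L]) { w$W2 <- fit$W2; w$b2 <- as.numeric(fit$b2) }
      if (!freeze[3L]) { w$W3 <- fit$W3; w$b3 <- as.numeric(fit$b3) }
    }
    losses <- as.numeric(fit$losses)
  }

  out <- params
  out$weights <- w
  out$epochs_trained <- params$epochs_trained + config$epochs
  if (identical(params$provenance, "pretrained") && config$epochs > 0L) {
    out$provenance <- "finetuned"
  }
  list(params = out,
       record = structure(list(loss = losses, epochs_run = config$epochs),
                          class = "train_record"))
}

#' Predict with the classifier
#'
#' @param params An `fnn_params`.
#' @param x Numeric matrix of compound vectors.
#' @return List with `labels` (`"active"`/`"inactive"`; ties go to active)
#'   and `scores` (softmax probability of the active class).
#' @export
predict_fnn <- function(params, x) {
  x <- check_input_dim(params, x)
  w <- params$weights
  z <- add_bias(hidden_forward(w, x) %*% w$W3, w$b3)
  p <- softmax_ce(z)$p
  list(labels = ifelse(p[, 2L] >= p[, 1L], "active", "inactive"),
       scores = p[, 2L])
}

#' Penultimate-layer features
#'
#' Activations of the second hidden layer (size 300 in the reference
#' configuration) under the given parameters -- the representation the
#' shallow-classifier transfer mode feeds its head.
#'
#' @param params An `fnn_params`.
#' @param x Numeric matrix of compound vectors.
#' @return Numeric matrix, `nrow(x)` x `hidden2`.
#' @export
extract_features <- function(params, x) {
  x <- check_input_dim(params, x)
  hidden_forward(params$weights, x)
}

#' Shallow-model hyperparameters
#'
#' @param kind Only `"svm"` is implemented.
#' @param kernel,cost SVM kernel and soft-margin cost.
#' @param gamma RBF width; `NULL` scales by feature variance,
#'   `1 / (d * var(x))`.
#' @return A `shallow_hyper` object.
#' @export
shallow_hyper <- function(kind = "svm", kernel = "radial", cost = 1,
                          gamma = NULL) {
  if (!identical(kind, "svm")) {
    abort(sprintf("unsupported shallow model kind '%s'", kind),
          "dti_config_error")
  }
  structure(list(kind = kind, kernel = kernel, cost = cost, gamma = gamma),
            class = "shallow_hyper")
}

#' Fit the shallow classifier
#'
#' @param features Numeric feature matrix.
#' @param y Labels (`"active"`/`"inactive"` or 0/1); both classes must be
#'   present.
#' @param hyper A [shallow_hyper()].
#' @return A `shallow_model`.
#' @export
fit_shallow <- function(features, y, hyper = shallow_hyper()) {
  stopifnot(inherits(hyper, "shallow_hyper"))
  if (!is.matrix(features)) features <- as.matrix(features)
  y <- as_binary_labels(y)
  if (length(unique(y)) < 2L) {
    abort("shallow model needs both classes in the training data",
          "dti_fit_error")
  }
  gamma <- hyper$gamma
  if (is.null(gamma)) {
    v <- stats::var(as.vector(features))
    gamma <- if (is.finite(v) && v > 0) 1 / (ncol(features) * v)
             else 1 / ncol(features)
  }
  yfac <- factor(ifelse(y == 1L, "active", "inactive"),
                 levels = c("inactive", "active"))
  fit <- e1071::svm(x = features, y = yfac, kernel = hyper$kernel,
                    cost = hyper$cost, gamma = gamma, scale = FALSE)
  structure(list(kind = hyper$kind, fit = fit,
                 hyper = list(kernel = hyper$kernel, cost = hyper$cost,
                              gamma = gamma)),
            class = "shallow_model")
}

#' Predict with the shallow classifier
#'
#' @param model A `shallow_model`.
#' @param features Numeric feature matrix.
#' @return List with `labels` and `scores` (decision values oriented so
#'   larger means more active).
#' @export
predict_shallow <- function(model, features) {
  stopifnot(inherits(model, "shallow_model"))
  if (!is.matrix(features)) features <- as.matrix(features)
  pred <- stats::predict(model$fit, features, decision.values = TRUE)
  dv <- attr(pred, "decision.values")
  score <- dv[, 1L]
  # e1071 orients the decision value toward the class named first in the
  # column label ("a/b" means positive favors a).
  pos <- strsplit(colnames(dv)[1L], "/", fixed = TRUE)[[1L]][1L]
  if (!identical(pos, "active")) score <- -score
  list(labels = as.character(pred), scores = unname(score))
}
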