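# Independent reference implementations ("oracles") used to cross-check the
# package's numerics. These are deliberately written with different
# machinery than the package code paths they validate.

# MCC via the Pearson-correlation identity: the phi coefficient of two 0/1
# vectors equals the Matthews correlation coefficient whenever the
# contingency denominator is non-zero.
oracle_mcc <- function(truth, pred) {
  if (length(unique(truth)) < 2L || length(unique(pred)) < 2L) {
    tp <- sum(truth == 1 & pred == 1)
    tn <- sum(truth == 0 & pred == 0)
    fp <- sum(truth == 0 & pred == 1)
    fn <- sum(truth == 1 & pred == 0)
    num <- tp * tn - fp * fn
    den <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
    return(if (den == 0) 0 else num / den)
  }
  stats::cor(as.numeric(truth), as.numeric(pred))
}

# Confusion-matrix metrics by direct counting, written independently.
oracle_confusion <- function(truth, pred) {
  tab <- table(factor(truth, levels = c(0, 1)), factor(pred, levels = c(0, 1)))
  tn <- tab["0", "0"]; fp <- tab["0", "1"]
  fn <- tab["1", "0"]; tp <- tab["1", "1"]
  precision <- if (tp + fp > 0) tp / (tp + fp) else 0
  recall <- if (tp + fn > 0) tp / (tp + fn) else 0
  list(
    precision = precision,
    recall = recall,
    f1 = if (precision + recall > 0) {
      2 * precision * recall / (precision + recall)
    } else {
      0
    },
    accuracy = (tp + tn) / length(truth)
  )
}

# AUROC by exhaustive pair counting (ties count one half).
oracle_auroc <- function(truth, scores) {
  pos <- scores[truth == 1]
  neg <- scores[truth == 0]
  if (!length(pos) || !length(neg)) return(NA_real_)
  wins <- 0
  for (p in pos) wins <- wins + sum(p > neg) + 0.5 * sum(p == neg)
  wins / (length(pos) * length(neg))
}

# Tanimoto similarity straight from bit sets.
oracle_tanimoto <- function(bits_a, bits_b) {
  ni <- length(intersect(bits_a, bits_b))
  nu <- length(union(bits_a, bits_b))
  if (nu == 0) 1 else ni / nu
}

# Leader (Butina) clustering by literal hand execution of the procedure:
# count neighbors at the cutoff, sort by descending count with ascending-id
# tie break, sweep the list and absorb unassigned neighbors.
oracle_leader_cluster <- function(fps, cutoff) {
  ids <- names(fps)
  n <- length(ids)
  sim <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      sim[i, j] <- oracle_tanimoto(fps[[i]]$bits, fps[[j]]$bits)
    }
  }
  counts <- vapply(seq_len(n), function(i) {
    sum(sim[i, -i] >= cutoff)
  }, numeric(1))
  ord <- order(-counts, ids)
  cluster <- rep(NA_integer_, n)
  k <- 0L
  for (i in ord) {
    if (!is.na(cluster[i])) next
    k <- k + 1L
    for (j in seq_len(n)) {
      if (is.na(cluster[j]) && sim[i, j] >= cutoff) cluster[j] <- k
    }
  }
  names(cluster) <- ids
  cluster
}

# Plain-R reference trainer for the feed-forward classifier: mini-batch
# Adam on softmax cross-entropy, replicating the documented update order
# (one shared step counter, per-batch gradient averaging, seeded epoch
# shuffles) without touching the package's compiled code.
ref_train_fnn <- function(params, x, y, config, freeze = c(FALSE, FALSE, FALSE)) {
  w <- params$weights
  n <- nrow(x)
  m <- lapply(w, function(z) z * 0)
  v <- lapply(w, function(z) z * 0)
  t_step <- 0L
  b1 <- config$adam_beta1; b2 <- config$adam_beta2; eps <- config$adam_eps
  lr <- config$learning_rate

  old_seed <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  set.seed(config$seed)
  perms <- lapply(seq_len(config$epochs), function(e) sample.int(n))
  if (is.null(old_seed)) {
    rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old_seed, envir = globalenv())
  }

  adam <- function(name, grad) {
    m[[name]] <<- b1 * m[[name]] + (1 - b1) * grad
    v[[name]] <<- b2 * v[[name]] + (1 - b2) * grad^2
    w[[name]] <<- w[[name]] -
      lr * (m[[name]] / (1 - b1^t_step)) /
        (sqrt(v[[name]] / (1 - b2^t_step)) + eps)
  }

  losses <- numeric(config$epochs)
  for (e in seq_len(config$epochs)) {
    perm <- perms[[e]]
    epoch_loss <- 0
    for (start in seq(1L, n, by = config$batch_size)) {
      idx <- perm[start:min(n, start + config$batch_size - 1L)]
      xb <- x[idx, , drop = FALSE]
      yb <- y[idx]
      nb <- length(idx)
      a1 <- xb %*% w$W1 + rep(w$b1, each = nb)
      h1 <- pmax(a1, 0)
      a2 <- h1 %*% w$W2 + rep(w$b2, each = nb)
      h2 <- pmax(a2, 0)
      z <- h2 %*% w$W3 + rep(w$b3, each = nb)
      zmax <- pmax(z[, 1], z[, 2])
      lse <- zmax + log(exp(z[, 1] - zmax) + exp(z[, 2] - zmax))
      epoch_loss <- epoch_loss + sum(lse - z[cbind(seq_len(nb), yb + 1L)])
      p <- exp(z - lse)
      onehot <- cbind(1 - yb, yb)
      dz <- (p - onehot) / nb
      t_step <- t_step + 1L
      dh2 <- (dz %*% t(w$W3)) * (a2 > 0)
      dh1 <- (dh2 %*% t(w$W2)) * (a1 > 0)
      if (!freeze[3]) {
        adam("W3", t(h2) %*% dz)
        adam("b3", colSums(dz))
      }
      if (!freeze[2]) {
        adam("W2", t(h1) %*% dh2)
        adam("b2", colSums(dh2))
      }
      if (!freeze[1]) {
        adam("W1", t(xb) %*% dh1)
        adam("b1", colSums(dh1))
      }
    }
    losses[e] <- epoch_loss / n
  }
  list(weights = w, losses = losses)
}

# Small classifier configuration used by the dual-route training checks.
tiny_fnn_config <- function(epochs = 3L, seed = 42L) {
  fnn_config(input_dim = 3L, hidden_sizes = c(4L, 3L), epochs = epochs,
             batch_size = 2L, learning_rate = 1e-2, seed = seed)
}

tiny_training_data <- function(n = 7L, d = 3L, seed = 9L) {
  set.seed(seed)
  x <- matrix(rnorm(n * d), n, d)
  y <- as.integer(x[, 1] + 0.5 * x[, 2] > 0)
  list(x = x, y = y)
}
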