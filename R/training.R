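#' Label the top fraction of scores as positive
#'
#' The off-target classification task labels the most active aligned pairs
#' (highest indel frequency) as positives: exactly `round(fraction * n)`
#' samples get label 1. Ties at the cutoff are broken by stable input order,
#' so the rule is deterministic.
#'
#' @param scores Numeric vector of activity scores.
#' @param fraction Fraction labeled positive, in (0, 1); default the
#'   conventional top 20%.
#' @return Integer vector of 0/1 labels, same length as `scores`.
#' @examples
#' label_top_fraction(c(5, 1, 9, 3, 7), 0.2)  # only the 9 is positive
#' @export
label_top_fraction <- function(scores, fraction = 0.2) {
  if (length(scores) == 0) abort("`scores` is empty.")
  if (!is.numeric(scores) || anyNA(scores)) abort("`scores` must be numeric without NA.")
  if (fraction <= 0 || fraction >= 1) abort("`fraction` must be in (0, 1).")
  k <- round(fraction * length(scores))
  labels <- integer(length(scores))
  if (k > 0) {
    ord <- order(-scores, seq_along(scores))  # stable: ties by input order
    labels[ord[seq_len(k)]] <- 1L
  }
  labels
}

#' k-fold cross-validation assignment
#'
#' Randomly partitions samples into `k` folds whose sizes differ by at most
#' one.
#'
#' @param ids Vector of sample identifiers (or an integer count).
#' @param k Number of folds.
#' @param seed Integer seed.
#' @return Tibble with columns `id` and `fold` (0-based).
#' @export
kfold_split <- function(ids, k = 5, seed = 1) {
  if (length(ids) == 1 && is.numeric(ids)) ids <- seq_len(ids)
  n <- length(ids)
  if (k > n) abort(sprintf("k = %d exceeds the number of samples (%d).", k, n))
  if (k < 2) abort("`k` must be at least 2.")
  folds <- withr::with_seed(seed, sample(rep(0:(k - 1), length.out = n)))
  tibble(id = ids, fold = folds)
}

#' Leave-groups-out holdout
#'
#' Holds out every sample belonging to the given groups (e.g. all pairs of 3
#' sgRNAs, or all guides of one cell line), guaranteeing train/test group
#' disjointness.
#'
#' @param ids Sample identifiers (parallel to `groups`).
#' @param groups Group identifier per sample.
#' @param held_out Either the group ids to hold out, or an integer number of
#'   groups to sample (with `seed`).
#' @param seed Seed used when `held_out` is a count.
#' @return List with `train` and `test` integer index vectors and
#'   `held_out_groups`.
#' @export
leave_groups_out <- function(ids, groups, held_out, seed = 1) {
  stopifnot(length(ids) == length(groups))
  ug <- unique(groups)
  if (is.numeric(held_out) && length(held_out) == 1 && !held_out %in% ug) {
    if (held_out >= length(ug)) abort("Cannot hold out every group.")
    held_out <- withr::with_seed(seed, sample(ug, held_out))
  }
  if (!all(held_out %in% ug)) {
    abort(sprintf("Unknown group '%s'.", setdiff(held_out, ug)[1]))
  }
  test <- which(groups %in% held_out)
  train <- which(!groups %in% held_out)
  if (length(test) == 0 || length(train) == 0) {
    abort("Holdout leaves an empty train or test set.")
  }
  stopifnot(length(intersect(groups[train], groups[test])) == 0)
  list(train = train, test = test, held_out_groups = held_out)
}

#' Class-balanced mini-batches by positive oversampling
#'
#' For heavily imbalanced off-target data, each training mini-batch draws half
#' its slots from the negatives (each negative visited exactly once per epoch)
#' and fills the other half with positives sampled with replacement, so every
#' batch holds a similar number of positives and negatives. Evaluation never
#' uses these batches; metrics are always computed on the unresampled data.
#'
#' @param labels Integer 0/1 vector.
#' @param batch_size Total batch size.
#' @param seed Integer seed.
#' @return List of integer index vectors (one epoch of batches).
#' @export
balanced_batches <- function(labels, batch_size = 32, seed = 1) {
  pos <- which(labels == 1L)
  neg <- which(labels == 0L)
  if (length(pos) == 0 || length(neg) == 0) {
    abort("Balanced sampling needs at least one positive and one negative sample.")
  }
  half <- max(1L, batch_size %/% 2L)
  withr::with_seed(seed, {
    neg <- sample(neg)
    starts <- seq(1L, length(neg), by = half)
    lapply(starts, function(s) {
      nb <- neg[s:min(s + half - 1L, length(neg))]
      pb <- sample(pos, length(nb), replace = TRUE)
      sample(c(nb, pb))
    })
  })
}

#' Train a model
#'
#' Runs mini-batch gradient descent with Adam. Classification uses the
#' negative log-likelihood on log-softmax outputs with positive-oversampled
#' balanced batches; regression uses mean squared error with plain shuffled
#' batches. Training stops early when the validation loss has not improved
#' for `patience` epochs.
#'
#' @param model A `crispr_model` (modified in place and returned).
#' @param tokens Integer token matrix, rows = samples.
#' @param y Labels (0/1 integers) or numeric responses.
#' @param extra Optional numeric matrix of extra features (raw scale). It is
#'   standardized with the training-set mean and standard deviation; the
#'   statistics are stored on the model and reapplied at prediction time.
#' @param epochs Maximum epochs.
#' @param batch_size Mini-batch size.
#' @param lr Adam learning rate.
#' @param val_frac Fraction of samples held aside (after `val_idx`) to monitor
#'   validation loss; 0 disables early stopping.
#' @param val_idx Explicit validation indices (overrides `val_frac`).
#' @param patience Early-stopping patience in epochs.
#' @param balanced Use [balanced_batches()] (classification default).
#' @param seed Integer seed covering batch order, dropout and validation split.
#' @param verbose Print per-epoch losses.
#' @return The trained model, invisibly; `model$history` holds the loss curve
#'   as a tibble (`epoch`, `split`, `loss`).
#' @export
train_model <- function(model, tokens, y, extra = NULL,
                        epochs = 20, batch_size = 64, lr = 1e-3,
                        val_frac = 0.1, val_idx = NULL, patience = 10,
                        balanced = NULL, seed = 1, verbose = FALSE) {
  cfg <- model$config
  classify <- cfg$task == "classify"
  balanced <- balanced %||% classify
  if (!is.matrix(tokens)) tokens <- token_matrix(tokens)
  n <- nrow(tokens)
  stopifnot(length(y) == n)
  if (classify) y <- as.integer(y)
  if (!is.null(extra)) {
    extra <- as.matrix(extra)
    ctr <- colMeans(extra)
    scl <- apply(extra, 2, sd)
    scl[scl == 0 | !is.finite(scl)] <- 1
    model$extra_center <- ctr
    model$extra_scale <- scl
    extra <- scale(extra, center = ctr, scale = scl)
  }

  withr::with_seed(seed, {
    if (is.null(val_idx) && val_frac > 0) {
      val_idx <- sample(n, max(1L, round(val_frac * n)))
    }
    train_idx <- setdiff(seq_len(n), val_idx)

    eval_loss <- function(idx) {
      out <- model_forward(model, tokens[idx, , drop = FALSE],
                           if (is.null(extra)) NULL else extra[idx, , drop = FALSE],
                           training = FALSE)
      if (classify) nll_from_logits(out, y[idx])$loss
      else mse_loss(as.numeric(out), y[idx])$loss
    }

    history <- list()
    best <- Inf
    best_params <- NULL
    stall <- 0L
    step <- 0L
    for (ep in seq_len(epochs)) {
      batches <- if (balanced && classify) {
        balanced_batches(y[train_idx], batch_size, seed = seed + ep)
      } else {
        perm <- sample(train_idx)
        split(perm, ceiling(seq_along(perm) / batch_size))
      }
      if (balanced && classify) {
        batches <- lapply(batches, function(b) train_idx[b])
      }
      ep_loss <- 0
      for (b in batches) {
        nn_zero_grads(model$layers)
        out <- model_forward(model, tokens[b, , drop = FALSE],
                             if (is.null(extra)) NULL else extra[b, , drop = FALSE],
                             training = TRUE)
        ls <- if (classify) nll_from_logits(out, y[b]) else {
          mse_loss(as.numeric(out), y[b])
        }
        if (!is.finite(ls$loss)) {
          abort(sprintf(
            "Training diverged (non-finite loss) at epoch %d; lower `lr` or check inputs.",
            ep))
        }
        grad <- if (classify) ls$grad else matrix(ls$grad, ncol = 1)
        model_backward(model, grad)
        step <- step + 1L
        nn_adam_step(model$layers, lr = lr, t = step)
        ep_loss <- ep_loss + ls$loss * length(b)
      }
      ep_loss <- ep_loss / sum(lengths(batches))
      history[[length(history) + 1]] <- tibble(epoch = ep, split = "train",
                                               loss = ep_loss)
      if (length(val_idx) > 0) {
        vl <- eval_loss(val_idx)
        history[[length(history) + 1]] <- tibble(epoch = ep, split = "validation",
                                                 loss = vl)
        if (verbose) message(sprintf("epoch %d: train %.4f val %.4f", ep, ep_loss, vl))
        if (vl < best - 1e-6) {
          best <- vl
          stall <- 0L
          best_params <- lapply(nn_leaves(model$layers), function(l) l$params)
        } else {
          stall <- stall + 1L
          if (stall >= patience) break
        }
      } else if (verbose) {
        message(sprintf("epoch %d: train %.4f", ep, ep_loss))
      }
    }
    if (!is.null(best_params)) {
      leaves <- nn_leaves(model$layers)
      for (i in seq_along(leaves)) leaves[[i]]$params <- best_params[[i]]
    }
    model$history <- bind_rows(history)
  })
  model$trained <- TRUE
  invisible(model)
}
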