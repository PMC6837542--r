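#' Fit an off-target specificity classifier on aligned pairs
#'
#' End-to-end convenience wrapper: canonicalizes and encodes aligned
#' sgRNA-DNA pairs as base-pair tokens, derives binary labels from activity
#' scores when needed (top fraction = positive), splits the data, trains the
#' attention+CNN classifier with balanced mini-batches, and evaluates AUC-ROC
#' and PR-AUC on the untouched held-out samples.
#'
#' @param pairs Data frame with columns `sgrna`, `dna` and either `label`
#'   (0/1) or `score` (activity, labeled via [label_top_fraction()]).
#' @param config Optional [model_config()]; defaults are derived from the data
#'   (classification task, `max_len` = alignment length).
#' @param split `"holdout"` (single stratified holdout of `holdout_frac`) or
#'   `"cv"` (k-fold cross-validation).
#' @param holdout_frac,k Holdout fraction / number of folds.
#' @param label_fraction Top fraction labeled positive when `label` is absent.
#' @param groups Optional group id per row (e.g. the sgRNA); with
#'   `held_out_groups`, evaluation is leave-groups-out instead.
#' @param held_out_groups Groups (or a count of groups) to hold out.
#' @param epochs,batch_size,lr,patience Passed to [train_model()].
#' @param seed Integer seed for splitting, initialization and training.
#' @return A `crispr_fit` object; see [tidy.crispr_fit()], [glance.crispr_fit()].
#' @export
fit_offtarget_model <- function(pairs, config = NULL,
                                split = c("holdout", "cv"),
                                holdout_frac = 0.2, k = 5,
                                label_fraction = 0.2,
                                groups = NULL, held_out_groups = NULL,
                                epochs = 15, batch_size = 64, lr = 1e-3,
                                patience = 5, seed = 1) {
  split <- match.arg(split)
  tokens <- token_matrix(encode_base_pairs(pairs))
  y <- if ("label" %in% names(pairs)) {
    as.integer(pairs$label)
  } else if ("score" %in% names(pairs)) {
    label_top_fraction(pairs$score, label_fraction)
  } else {
    abort("`pairs` needs a `label` or `score` column.")
  }
  cfg <- config %||% model_config(task = "classify", max_len = ncol(tokens),
                                  seed = seed)
  if (cfg$task != "classify") abort("Off-target fitting needs a classification config.")

  fit_one <- function(train, test) {
    model <- attn_to_mismatch(cfg)
    train_model(model, tokens[train, , drop = FALSE], y[train],
                epochs = epochs, batch_size = batch_size, lr = lr,
                patience = patience, seed = seed)
    scores <- predict(model, tokens[test, , drop = FALSE], type = "prob")
    list(model = model, metrics = evaluate_classifier(y[test], scores),
         predictions = tibble(row = test, truth = y[test], score = scores))
  }
  .run_fit(fit_one, n = nrow(tokens), y = y, split = split,
           holdout_frac = holdout_frac, k = k, seed = seed,
           groups = groups, held_out_groups = held_out_groups,
           task = "offtarget", config = cfg)
}

#' Fit an on-target efficiency regressor on guide records
#'
#' Encodes guide sequences as dimer tokens, optionally augments each guide
#' with its NetExpress score (computed from a gene network and an expression
#' profile for the guide's cell line) and copy number, z-scores the extra
#' features on the training fold, trains the requested regressor with MSE
#' loss, and reports Spearman/Pearson/MSE on held-out guides.
#'
#' @param guides Data frame with columns `seq`, `efficiency`, and optionally
#'   `gene`, `cell_line`, `copy_number`.
#' @param model `"attn_crispr"` (transformer + CNN) or `"seq_crispr"`
#'   (CNN parallel LSTM).
#' @param network,expression Passed to [netexpress()] when
#'   `use_netexpress = TRUE`; expression may carry a `cell_line` column
#'   matching the guides'.
#' @param use_netexpress Include the NetExpress score as an extra feature.
#' @param use_copy_number Include `copy_number` as an extra feature.
#' @param config Optional [model_config()].
#' @inheritParams fit_offtarget_model
#' @return A `crispr_fit` object.
#' @export
fit_ontarget_model <- function(guides, model = c("attn_crispr", "seq_crispr"),
                               network = NULL, expression = NULL,
                               use_netexpress = !is.null(network),
                               use_copy_number = "copy_number" %in% names(guides),
                               config = NULL,
                               split = c("holdout", "cv"),
                               holdout_frac = 0.2, k = 5,
                               groups = NULL, held_out_groups = NULL,
                               epochs = 15, batch_size = 64, lr = 1e-3,
                               patience = 5, seed = 1) {
  model <- match.arg(model)
  split <- match.arg(split)
  tokens <- token_matrix(encode_dimers(guides))
  y <- guides$efficiency
  if (is.null(y) || !all(is.finite(y))) abort("`guides$efficiency` must be finite.")

  extra <- NULL
  extra_names <- character()
  if (use_netexpress) {
    if (is.null(network) || is.null(expression)) {
      abort("`use_netexpress = TRUE` requires both `network` and `expression`.")
    }
    if (!"gene" %in% names(guides)) abort("`guides` needs a `gene` column for NetExpress.")
    nx <- netexpress(network, expression)
    key_fit <- if ("cell_line" %in% names(nx)) {
      if (!"cell_line" %in% names(guides)) {
        abort("`expression` is per cell line but `guides` has no `cell_line` column.")
      }
      match(paste(guides$gene, guides$cell_line),
            paste(nx$gene, nx$cell_line))
    } else {
      match(guides$gene, nx$gene)
    }
    nx_score <- nx$score[key_fit]
    if (anyNA(nx_score)) {
      # genes outside the network have an empty neighborhood: score 0
      inform(sprintf("NetExpress: %d guide(s) target genes absent from the network; scoring 0.",
                     sum(is.na(nx_score))))
      nx_score[is.na(nx_score)] <- 0
    }
    extra <- cbind(extra, netexpress = nx_score)
    extra_names <- c(extra_names, "netexpress")
  }
  if (use_copy_number) {
    if (!"copy_number" %in% names(guides)) abort("`guides` has no `copy_number` column.")
    extra <- cbind(extra, copy_number = guides$copy_number)
    extra_names <- c(extra_names, "copy_number")
  }

  cfg <- config %||% model_config(task = "regress", max_len = ncol(tokens),
                                  n_extra_features = length(extra_names),
                                  seed = seed)
  if (cfg$n_extra_features != length(extra_names)) {
    abort("`config$n_extra_features` does not match the requested extra features.")
  }
  builder <- switch(model, attn_crispr = attn_to_crispr, seq_crispr = seq_crispr)

  fit_one <- function(train, test) {
    m <- builder(cfg)
    m$extra_names <- extra_names
    train_model(m, tokens[train, , drop = FALSE], y[train],
                extra = if (is.null(extra)) NULL else extra[train, , drop = FALSE],
                epochs = epochs, batch_size = batch_size, lr = lr,
                patience = patience, seed = seed)
    pred <- predict(m, tokens[test, , drop = FALSE],
                    extra = if (is.null(extra)) NULL else extra[test, , drop = FALSE])
    list(model = m, metrics = evaluate_regressor(y[test], pred),
         predictions = tibble(row = test, truth = y[test], estimate = pred))
  }
  .run_fit(fit_one, n = nrow(tokens), y = y, split = split,
           holdout_frac = holdout_frac, k = k, seed = seed,
           groups = groups, held_out_groups = held_out_groups,
           task = "ontarget", config = cfg)
}

.run_fit <- function(fit_one, n, y, split, holdout_frac, k, seed,
                     groups, held_out_groups, task, config) {
  folds <- if (!is.null(held_out_groups)) {
    if (is.null(groups)) abort("`held_out_groups` requires `groups`.")
    lg <- leave_groups_out(seq_len(n), groups, held_out_groups, seed = seed)
    list(list(train = lg$train, test = lg$test))
  } else if (split == "cv") {
    fs <- kfold_split(seq_len(n), k = k, seed = seed)
    lapply(0:(k - 1), function(f) {
      list(train = fs$id[fs$fold != f], test = fs$id[fs$fold == f])
    })
  } else {
    test <- withr::with_seed(seed, sample(n, round(holdout_frac * n)))
    list(list(train = setdiff(seq_len(n), test), test = test))
  }
  results <- lapply(seq_along(folds), function(i) {
    r <- fit_one(folds[[i]]$train, folds[[i]]$test)
    r$metrics$fold <- i - 1L
    r
  })
  structure(list(
    task = task,
    config = config,
    model = results[[length(results)]]$model,
    metrics = bind_rows(lapply(results, `[[`, "metrics")),
    predictions = bind_rows(lapply(seq_along(results), function(i) {
      mutate(results[[i]]$predictions, fold = i - 1L)
    })),
    n = n,
    seed = seed
  ), class = "crispr_fit")
}

#' Tidy per-fold metrics of a fitted model
#'
#' @param x A `crispr_fit`.
#' @param ... Unused.
#' @return Tibble with `fold`, `metric`, `estimate`, `n`.
#' @method tidy crispr_fit
#' @export
tidy.crispr_fit <- function(x, ...) {
  select(x$metrics, fold, metric, estimate, n)
}

#' One-row summary of a fitted model (mean +/- sd over folds)
#'
#' @param x A `crispr_fit`.
#' @param ... Unused.
#' @return One-row tibble with `<metric>` means, `<metric>_sd` spreads,
#'   `n_folds`, `n`.
#' @method glance crispr_fit
#' @export
glance.crispr_fit <- function(x, ...) {
  agg <- x$metrics %>%
    group_by(metric) %>%
    summarise(mean = mean(estimate), sd = sd(estimate), .groups = "drop")
  out <- as.list(setNames(agg$mean, agg$metric))
  if (nrow(x$metrics) > length(unique(x$metrics$metric))) {
    out <- c(out, as.list(setNames(agg$sd, paste0(agg$metric, "_sd"))))
  }
  as_tibble(c(out, list(n_folds = length(unique(x$metrics$fold)), n = x$n)))
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
print.crispr_fit <- function(x, ...) {
  cat(sprintf("<crispr_fit: %s, %s>\n", x$task, x$model$arch))
  print(glance(x))
  invisible(x)
}

#' Plot the training loss curve of a fit
#'
#' @param object A `crispr_fit` or `crispr_model` with a training history.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot crispr_fit
#' @export
autoplot.crispr_fit <- function(object, ...) {
  hist <- object$model$history
  if (is.null(hist)) abort("No training history recorded.")
  ggplot2::ggplot(hist, ggplot2::aes(x = epoch, y = loss, colour = split)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "epoch", y = "loss", colour = NULL,
                  title = "Training curve (final fold)") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
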