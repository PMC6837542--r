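#' Shuffle-based input-feature importance
#'
#' For each input feature (one token position, or one named extra covariate),
#' the feature's column is permuted across samples — never within a sample —
#' and the model loss on the perturbed data is recorded; this is repeated
#' `n_repeats` times with fresh permutations and averaged. The average
#' post-shuffle loss is the feature's raw importance, and raw importances are
#' normalized by their sum so the scores add to 1. Note the raw score is the
#' loss after shuffling, not the loss increase over baseline; informative
#' features still rank highest because destroying them hurts the loss most,
#' and the baseline loss is reported alongside for reference.
#'
#' The loss matches the training objective: negative log-likelihood for
#' classifiers, mean squared error for regressors. The model is read-only.
#'
#' @param model A trained `crispr_model`.
#' @param tokens Integer token matrix (rows = samples, >= 2 of them).
#' @param y Labels / responses.
#' @param extra Optional extra-feature matrix (raw scale, as at fit time).
#' @param n_repeats Permutations per feature (default 40).
#' @param seed Integer seed for the permutation stream.
#' @param feature_names Optional names; defaults to `basepair_<i>` or
#'   `dimer_<i>` by task plus the model's stored extra-feature names.
#' @return An `importance_report` tibble with columns `feature`, `raw`,
#'   `normalized`, and attributes `baseline_loss`, `n_repeats`, `seed`.
#' @export
perturbation_importance <- function(model, tokens, y, extra = NULL,
                                    n_repeats = 40, seed = 1,
                                    feature_names = NULL) {
  if (!inherits(model, "crispr_model")) abort("`model` must be a crispr_model.")
  if (!isTRUE(model$trained)) abort("`model` must be trained before importance analysis.")
  if (!is.matrix(tokens)) tokens <- token_matrix(tokens)
  n <- nrow(tokens)
  if (n < 1) abort("Need at least one sample.")
  classify <- model$config$task == "classify"
  if (classify) y <- as.integer(y)
  if (!is.null(extra)) extra <- as.matrix(extra)
  n_extra <- model$config$n_extra_features
  if (n_extra > 0 && (is.null(extra) || ncol(extra) != n_extra)) {
    abort(sprintf("Model expects %d extra feature(s).", n_extra))
  }

  loss_of <- function(tok, ext) {
    if (classify) {
      lp <- predict(model, tok, ext, type = "logprob")
      -mean(lp[cbind(seq_len(nrow(tok)), y + 1L)])
    } else {
      mean((predict(model, tok, ext) - y)^2)
    }
  }

  L <- ncol(tokens)
  pos_prefix <- if (classify) "basepair_" else "dimer_"
  extra_nm <- if (n_extra > 0) {
    nm <- model$extra_names
    if (length(nm) != n_extra || any(!nzchar(nm))) nm <- paste0("extra_", seq_len(n_extra))
    nm
  } else character()
  feature_names <- feature_names %||% c(paste0(pos_prefix, 0:(L - 1)), extra_nm)
  n_feat <- L + n_extra
  stopifnot(length(feature_names) == n_feat)

  baseline <- loss_of(tokens, extra)
  raw <- withr::with_seed(seed, {
    vapply(seq_len(n_feat), function(j) {
      mean(vapply(seq_len(n_repeats), function(r) {
        perm <- sample.int(n)
        if (j <= L) {
          tok <- tokens
          tok[, j] <- tok[perm, j]
          loss_of(tok, extra)
        } else {
          ext <- extra
          ext[, j - L] <- ext[perm, j - L]
          loss_of(tokens, ext)
        }
      }, numeric(1)))
    }, numeric(1))
  })

  total <- sum(raw)
  out <- tibble(
    feature = factor(feature_names, levels = feature_names),
    raw = raw,
    normalized = if (total > 0) raw / total else rep(1 / n_feat, n_feat)
  )
  structure(out, class = c("importance_report", class(out)),
            baseline_loss = baseline, n_repeats = n_repeats, seed = seed)
}

#' Plot an importance report as a bar chart
#'
#' Bars follow feature (position) order; extra biological features appear
#' after the positional ones. The subtitle reports the number of shuffle
#' repeats and confirms the normalized scores sum to 1.
#'
#' @param object An `importance_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot importance_report
#' @export
autoplot.importance_report <- function(object, ...) {
  if (nrow(object) == 0) abort("Empty importance report.")
  ggplot2::ggplot(object, ggplot2::aes(x = feature, y = normalized)) +
    ggplot2::geom_col(fill = "#3366aa") +
    ggplot2::labs(
      x = NULL, y = "normalized importance",
      title = "Input-perturbation feature importance",
      subtitle = sprintf("%d shuffle repeats per feature; normalized scores sum to %.3f",
                         attr(object, "n_repeats"), sum(object$normalized))
    ) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60, hjust = 1))
}

#' @rdname autoplot.importance_report
#' @param report An `importance_report`.
#' @param path Optional file path; when given the figure is written there
#'   (format from the extension) and the path returned invisibly.
#' @export
plot_importance <- function(report, path = NULL) {
  p <- autoplot(report)
  if (!is.null(path)) {
    ggplot2::ggsave(path, p, width = 8, height = 4.5, dpi = 150)
    return(invisible(path))
  }
  p
}
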