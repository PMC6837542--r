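#' Save / load a model checkpoint
#'
#' The checkpoint stores the architecture name, the full configuration and all
#' weights, plus the extra-feature standardization, so a reloaded model
#' reproduces predictions exactly.
#'
#' @param model A `crispr_model`.
#' @param path Checkpoint file (`.rds`).
#' @return `save_model()` returns `path` invisibly; `load_model()` the model.
#' @export
save_model <- function(model, path) {
  leaves <- nn_leaves(model$layers)
  ckpt <- list(
    arch = model$arch,
    config = model$config,
    params = lapply(leaves, function(l) l$params),
    extra_names = model$extra_names,
    extra_center = model$extra_center,
    extra_scale = model$extra_scale,
    trained = model$trained
  )
  saveRDS(ckpt, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  ckpt <- readRDS(path)
  builder <- switch(ckpt$arch,
                    attn_mismatch = attn_to_mismatch,
                    attn_crispr = attn_to_crispr,
                    seq_crispr = seq_crispr,
                    abort(sprintf("Unknown architecture '%s'.", ckpt$arch)))
  model <- builder(ckpt$config)
  leaves <- nn_leaves(model$layers)
  stopifnot(length(leaves) == length(ckpt$params))
  for (i in seq_along(leaves)) leaves[[i]]$params <- ckpt$params[[i]]
  model$extra_names <- ckpt$extra_names
  model$extra_center <- ckpt$extra_center
  model$extra_scale <- ckpt$extra_scale
  model$trained <- ckpt$trained
  model
}

#' Run a configured end-to-end analysis
#'
#' Executes encode -> (NetExpress) -> train -> evaluate (-> importance) from a
#' YAML config or an equivalent list, writing every artifact into the output
#' directory: the exact config used (`config.yaml`, provenance), `metrics.json`,
#' `predictions.tsv`, the model checkpoint, an optional `importance.json`, and
#' a log carrying the seed and a config hash.
#'
#' Config fields: `task` ("offtarget" or "ontarget"), `seed`, `out_dir`,
#' `data` (either `simulate: {generator params}` or file paths `pairs` /
#' `guides` + optional `network`, `expression`), `model`
#' ("attn_mismatch", "attn_crispr", "seq_crispr"), `split`
#' ("holdout"/"cv", `k`, `holdout_frac`), `hyperparameters` (any
#' [model_config()] field), `train` (`epochs`, `batch_size`, `lr`,
#' `patience`), `importance` (`enabled`, `n_repeats`).
#'
#' @param config Path to a YAML file or a named list.
#' @param out_dir Output directory (overrides `config$out_dir`).
#' @return Invisibly, a list with the `crispr_fit`, metrics tibble, and paths.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config
  if (is.null(cfg$task) || !cfg$task %in% c("offtarget", "ontarget")) {
    abort("Config error: `task` must be 'offtarget' or 'ontarget'.")
  }
  seed <- cfg$seed %||% 1L
  out_dir <- out_dir %||% cfg$out_dir %||% abort("Config error: `out_dir` missing.")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(out_dir, "run.log")
  logf <- function(fmt, ...) {
    cat(sprintf(paste0(fmt, "\n"), ...), file = log_path, append = TRUE)
  }
  cfg_hash <- rlang::hash(cfg[setdiff(names(cfg), "out_dir")])
  logf("stage=init seed=%d config_hash=%s", seed, cfg_hash)
  yaml::write_yaml(cfg, file.path(out_dir, "config.yaml"))

  tr <- cfg$train %||% list()
  hp <- cfg$hyperparameters %||% list()
  sp <- cfg$split %||% list()
  split <- sp$method %||% "holdout"

  if (cfg$task == "offtarget") {
    pairs <- if (!is.null(cfg$data$simulate)) {
      logf("stage=simulate generator=offtarget")
      gen_offtarget(do.call(offtarget_sim_config,
                            c(cfg$data$simulate, list(seed = seed))))
    } else if (!is.null(cfg$data$pairs)) {
      read_pairs(cfg$data$pairs)
    } else {
      abort("Config error: `data` needs `simulate` or `pairs` for the offtarget task.")
    }
    config_obj <- do.call(model_config, c(
      list(task = "classify",
           max_len = nchar(pairs$sgrna[1]), seed = seed), hp))
    logf("stage=train model=attn_mismatch n=%d", nrow(pairs))
    fit <- fit_offtarget_model(
      pairs, config = config_obj, split = split,
      holdout_frac = sp$holdout_frac %||% 0.2, k = sp$k %||% 5,
      epochs = tr$epochs %||% 15, batch_size = tr$batch_size %||% 64,
      lr = tr$lr %||% 1e-3, patience = tr$patience %||% 5, seed = seed)
    tokens <- token_matrix(encode_base_pairs(pairs))
    y <- if ("label" %in% names(pairs)) pairs$label else label_top_fraction(pairs$score)
    extra <- NULL
  } else {
    use_nx <- FALSE
    if (!is.null(cfg$data$simulate)) {
      logf("stage=simulate generator=ontarget")
      sim <- gen_ontarget(do.call(ontarget_sim_config,
                                  c(cfg$data$simulate, list(seed = seed))))
      guides <- sim$guides
      network <- sim$network
      expression <- sim$expression
      use_nx <- TRUE
    } else if (!is.null(cfg$data$guides)) {
      guides <- read_guides(cfg$data$guides)
      use_nx <- !is.null(cfg$data$network)
      if (use_nx && is.null(cfg$data$expression)) {
        abort("Config error: field `data.expression` is required when `data.network` is set.")
      }
      network <- if (use_nx) read_network(cfg$data$network)
      expression <- if (use_nx) read_expression(cfg$data$expression)
    } else {
      abort("Config error: `data` needs `simulate` or `guides` for the ontarget task.")
    }
    model_name <- cfg$model %||% "attn_crispr"
    n_extra <- as.integer(use_nx) + as.integer("copy_number" %in% names(guides))
    config_obj <- do.call(model_config, c(
      list(task = "regress", max_len = nchar(guides$seq[1]) - 1L,
           n_extra_features = n_extra, seed = seed), hp))
    logf("stage=train model=%s n=%d netexpress=%s", model_name, nrow(guides), use_nx)
    fit <- fit_ontarget_model(
      guides, model = model_name,
      network = if (use_nx) network, expression = if (use_nx) expression,
      use_netexpress = use_nx, config = config_obj, split = split,
      holdout_frac = sp$holdout_frac %||% 0.2, k = sp$k %||% 5,
      epochs = tr$epochs %||% 15, batch_size = tr$batch_size %||% 64,
      lr = tr$lr %||% 1e-3, patience = tr$patience %||% 5, seed = seed)
    tokens <- token_matrix(encode_dimers(guides))
    y <- guides$efficiency
    extra <- .assemble_extra(fit$model, guides, network, expression, use_nx)
  }

  metrics_path <- file.path(out_dir, "metrics.json")
  jsonlite::write_json(
    list(task = cfg$task, seed = seed, config_hash = cfg_hash,
         metrics = glance(fit)),
    metrics_path, auto_unbox = TRUE, digits = NA, dataframe = "rows")
  readr::write_tsv(fit$predictions, file.path(out_dir, "predictions.tsv"))
  ckpt <- file.path(out_dir, "model.rds")
  save_model(fit$model, ckpt)
  logf("stage=evaluate metrics=%s", metrics_path)

  imp_path <- NULL
  if (isTRUE(cfg$importance$enabled)) {
    rep <- perturbation_importance(
      fit$model, tokens, y, extra = extra,
      n_repeats = cfg$importance$n_repeats %||% 40, seed = seed)
    imp_path <- file.path(out_dir, "importance.json")
    jsonlite::write_json(
      list(baseline_loss = attr(rep, "baseline_loss"),
           n_repeats = attr(rep, "n_repeats"),
           features = as.data.frame(rep)),
      imp_path, auto_unbox = TRUE, digits = NA)
    logf("stage=importance out=%s", imp_path)
  }
  logf("stage=done")
  invisible(list(fit = fit, metrics = glance(fit),
                 paths = list(out_dir = out_dir, metrics = metrics_path,
                              checkpoint = ckpt, importance = imp_path)))
}

.assemble_extra <- function(model, guides, network, expression, use_nx) {
  if (model$config$n_extra_features == 0) return(NULL)
  extra <- NULL
  if (use_nx) {
    nx <- netexpress(network, expression)
    key <- if ("cell_line" %in% names(nx)) {
      match(paste(guides$gene, guides$cell_line), paste(nx$gene, nx$cell_line))
    } else match(guides$gene, nx$gene)
    sc <- nx$score[key]
    sc[is.na(sc)] <- 0
    extra <- cbind(extra, netexpress = sc)
  }
  if ("copy_number" %in% names(guides)) {
    extra <- cbind(extra, copy_number = guides$copy_number)
  }
  extra
}
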