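# Seeded Adam training loop and the multi-run experiment driver: models are
# trained several times from different seeds and the evaluation metrics are
# averaged, since truncated-normal initialization makes single runs
# fluctuate.

#' Training configuration
#'
#' @param learning_rate Adam step size (default 5e-4).
#' @param batch_size Samples per batch (default 5000). When the training set
#'   holds fewer than 20 batches at this size, the effective batch size is
#'   scaled down proportionally (floor 64) so small corpora still see
#'   several updates per epoch.
#' @param epochs Training epochs (default 10).
#' @param n_runs Independent training runs per experiment (default 5); run
#'   `r` uses seed `base_seed + r - 1`.
#' @param base_seed Seed of the first run.
#' @param shuffle Reshuffle sample order every epoch (default `TRUE`).
#' @param patience Optional early-stopping patience in epochs on the
#'   held-out AUC (`NULL` disables early stopping).
#' @return An object of class `train_config`.
#' @export
train_config <- function(learning_rate = 5e-4, batch_size = 5000L,
                         epochs = 10L, n_runs = 5L, base_seed = 1L,
                         shuffle = TRUE, patience = NULL) {
  stopifnot(learning_rate >= 0, batch_size >= 1, epochs >= 1, n_runs >= 1)
  structure(list(learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), n_runs = as.integer(n_runs),
                 base_seed = as.integer(base_seed), shuffle = isTRUE(shuffle),
                 patience = patience),
            class = "train_config")
}

# Effective batch size: scale the configured size down (floor 64) when the
# corpus would yield fewer than 20 batches.
effective_batch_size <- function(n, batch_size) {
  if (n >= 20L * batch_size) return(batch_size)
  max(64L, min(batch_size, as.integer(ceiling(n / 20))))
}

adam_init <- function(params) {
  list(m = lapply(params, function(x) x * 0),
       v = lapply(params, function(x) x * 0), t = 0L)
}

adam_step <- function(params, grads, state, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  c1 <- 1 - beta1^state$t
  c2 <- 1 - beta2^state$t
  for (nm in names(grads)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / c1) / (sqrt(state$v[[nm]] / c2) + eps)
  }
  list(params = params, state = state)
}

#' Train the network on a labeled sample set
#'
#' Runs mini-batch Adam on the combined objective. Fully deterministic given
#' `seed`: parameter initialization and epoch shuffling both derive from it.
#'
#' @param samples Training `tcm_samples` (non-empty, with labels).
#' @param vocab The `tcm_vocabulary` sizing the embedding tables.
#' @param config A [model_config()].
#' @param tconfig A [train_config()].
#' @param seed Integer seed for this run.
#' @param validation Optional `tcm_samples` used for per-epoch AUC tracking
#'   and early stopping.
#' @param verbose Print per-epoch losses.
#' @return A list with `params` (fitted), `history` (per-epoch data frame of
#'   mean loss components and optional validation AUC) and `config`.
#' @export
train <- function(samples, vocab, config, tconfig, seed,
                  validation = NULL, verbose = FALSE) {
  n <- n_samples(samples)
  if (n == 0) stop("empty training sample set")
  restore <- local_rng(seed)
  on.exit(restore(), add = TRUE)

  params <- init_params(config, vocab)
  state <- adam_init(params)
  bs <- effective_batch_size(n, tconfig$batch_size)
  hist <- list()
  best_auc <- -Inf; stale <- 0L

  for (epoch in seq_len(tconfig$epochs)) {
    ord <- if (tconfig$shuffle) sample.int(n) else seq_len(n)
    sums <- c(total = 0, main = 0, match = 0, u = 0, v = 0)
    n_batches <- 0L
    start <- 1L
    while (start <= n) {
      idx <- ord[start:min(n, start + bs - 1L)]
      batch <- samples_subset(samples, idx)
      gb <- network_grad(params, batch, config)
      if (!is.finite(gb$losses$total)) {
        stop("training diverged (non-finite loss) at epoch ", epoch)
      }
      if (tconfig$learning_rate > 0) {
        upd <- adam_step(params, gb$grads, state, tconfig$learning_rate)
        params <- upd$params; state <- upd$state
      }
      sums <- sums + unlist(gb$losses)[names(sums)]
      n_batches <- n_batches + 1L
      start <- start + bs
    }
    row <- as.list(sums / n_batches)
    names(row) <- paste0("loss_", names(sums))
    row <- c(list(epoch = epoch), row)
    if (!is.null(validation)) {
      vs <- score_samples(params, validation, config)
      row$val_auc <- auc_score(validation$label, vs)
    }
    hist[[epoch]] <- row
    if (verbose) {
      message(sprintf("epoch %d: loss %.5f%s", epoch, row$loss_total,
                      if (!is.null(row$val_auc)) sprintf(" val AUC %.4f", row$val_auc) else ""))
    }
    if (!is.null(tconfig$patience) && !is.null(row$val_auc)) {
      if (row$val_auc > best_auc + 1e-6) {
        best_auc <- row$val_auc; stale <- 0L
      } else {
        stale <- stale + 1L
        if (stale >= tconfig$patience) break
      }
    }
  }
  history <- do.call(rbind, lapply(hist, function(r) as.data.frame(r)))
  list(params = params, history = history, config = config)
}

#' Run a full multi-run experiment on a corpus
#'
#' Splits the corpus at the case level, builds training samples under the
#' chosen negative policy and full-cross-product test samples (ranking
#' metrics need every candidate scored), trains `n_runs` models from seeds
#' `base_seed .. base_seed + n_runs - 1` and evaluates each on the test
#' split.
#'
#' @param corpus A corpus tibble.
#' @param config A [model_config()].
#' @param tconfig A [train_config()].
#' @param test_fraction Case-level test fraction (default 2/15).
#' @param split_seed Seed of the train/test split (default `base_seed`).
#' @param negative_policy,n_negatives Passed to [build_samples()] for the
#'   training side.
#' @param stat_config Optional list enabling statistical features: fields
#'   `statistics` and `include_padding` as in [featurize_samples()]. The
#'   co-occurrence tables are computed on the training split only.
#' @param shuffle_labels If `TRUE`, training labels are randomly permuted
#'   (per run seed): a negative control that should score at chance.
#' @param verbose Print progress.
#' @return A `metrics_report` averaging the runs (see [metrics_report()]),
#'   with the per-run fitted parameters in `attr(, "runs")`.
#' @export
run_experiment <- function(corpus, config, tconfig,
                           test_fraction = 2 / 15, split_seed = NULL,
                           negative_policy = "all", n_negatives = 5L,
                           stat_config = NULL, shuffle_labels = FALSE,
                           verbose = FALSE) {
  if (is.null(split_seed)) split_seed <- tconfig$base_seed
  parts <- split_cases(corpus, test_fraction, seed = split_seed)
  vocab <- build_vocabulary(parts$train)
  # The candidate catalog is fixed and known up front: make sure every
  # element observed anywhere in the corpus is scoreable.
  vocab$elements <- build_vocabulary(corpus)$elements

  train_samples <- build_samples(parts$train, vocab,
                                 negative_policy = negative_policy,
                                 n_negatives = n_negatives,
                                 seed = split_seed + 1L)
  test_samples <- build_samples(parts$test, vocab, negative_policy = "all")

  config_run <- config
  if (!is.null(stat_config)) {
    stats <- compute_stats(parts$train, vocab)
    train_samples <- featurize_samples(train_samples, parts$train, stats,
                                       statistics = stat_config$statistics,
                                       include_padding = isTRUE(stat_config$include_padding))
    test_samples <- featurize_samples(test_samples, parts$test, stats,
                                      statistics = stat_config$statistics,
                                      include_padding = isTRUE(stat_config$include_padding))
    config_run$n_stat_features <- ncol(train_samples$extra)
  }

  runs <- vector("list", tconfig$n_runs)
  reports <- vector("list", tconfig$n_runs)
  for (r in seq_len(tconfig$n_runs)) {
    seed_r <- tconfig$base_seed + r - 1L
    ts <- train_samples
    if (shuffle_labels) {
      restore <- local_rng(seed_r + 10000L)
      ts$label <- sample(ts$label)
      restore()
    }
    fit <- train(ts, vocab, config_run, tconfig, seed = seed_r,
                 verbose = verbose)
    reports[[r]] <- evaluate(fit$params, config_run, test_samples)
    runs[[r]] <- fit
    if (verbose) {
      message(sprintf("run %d/%d: test AUC %.4f", r, tconfig$n_runs,
                      reports[[r]]$auc))
    }
  }
  rep <- metrics_report(reports)
  attr(rep, "runs") <- runs
  rep
}

#' Save a model checkpoint
#'
#' Stores the flat named-parameter list together with the configuration
#' that produced it (as YAML alongside).
#'
#' @param fit A fit from [train()] (or a list with `params` and `config`).
#' @param path Checkpoint path (`.rds`); the config is written next to it
#'   as `<path>.yaml`.
#' @return The path, invisibly.
#' @export
save_checkpoint <- function(fit, path) {
  saveRDS(fit$params, path)
  yaml::write_yaml(unclass(fit$config), paste0(path, ".yaml"))
  invisible(path)
}

#' Load a model checkpoint
#'
#' Restores parameters and config, and verifies that the parameter shapes
#' are mutually consistent with the configuration.
#'
#' @param path Checkpoint path written by [save_checkpoint()].
#' @return A list with `params` and `config`.
#' @export
load_checkpoint <- function(path) {
  params <- readRDS(path)
  cfg <- yaml::read_yaml(paste0(path, ".yaml"))
  cfg$fusion <- match.arg(cfg$fusion, c("none", "auxiliary_loss",
                                        "match_as_feature", "mimic", "full"))
  config <- do.call(model_config, cfg[names(cfg) %in% names(formals(model_config))])
  if (!all(vapply(params, function(x) all(is.finite(x)), logical(1)))) {
    stop("corrupted checkpoint: non-finite parameter values")
  }
  d <- config$embedding_dim
  for (fld in symptom_fields()) {
    tab <- params[[paste0("emb.", fld)]]
    if (is.null(tab) || ncol(tab) != d) {
      stop("corrupted checkpoint: embedding table for ", fld,
           " missing or incompatible with embedding_dim ", d)
    }
  }
  list(params = params, config = config)
}

#' Desk-scale demonstration configuration
#'
#' The model and training settings used by the package's worked examples and
#' validation experiments on the default synthetic corpus (5,000 cases).
#' They scale the published large-corpus architecture down to a size a
#' single CPU trains in seconds per run: 12-dimensional embeddings, 8
#' experts of sizes 24/12, a 12-node tower, match towers of 24/12/12,
#' auxiliary-loss weight 1 and mimic weights 0.1, a wider 0.2
#' truncated-normal initialization and a higher 0.005 learning rate (small
#' corpora see far fewer optimizer updates than the published 8-million
#' sample training runs, so initialization and step size carry more of the
#' burden), batch 512, 8 epochs, and 6 sampled negatives per positive.
#'
#' @param fusion Fusion mode for the model configuration.
#' @param n_runs Training runs to average (default 5).
#' @param base_seed Seed of the first run (default 1).
#' @return A list with `model` (a [model_config()]), `training` (a
#'   [train_config()]), `negative_policy` and `n_negatives`.
#' @export
demo_configs <- function(fusion = "full", n_runs = 5L, base_seed = 1L) {
  list(
    model = model_config(embedding_dim = 12, n_experts = 8,
                         expert_layer_sizes = c(24, 12),
                         tower_layer_sizes = 12,
                         match_tower_sizes = c(24, 12, 12),
                         fusion = fusion, lambda1 = 1,
                         lambda_u = 0.1, lambda_v = 0.1, init_sd = 0.2),
    training = train_config(learning_rate = 0.005, batch_size = 512,
                            epochs = 8, n_runs = n_runs,
                            base_seed = base_seed),
    negative_policy = "sampled", n_negatives = 6L
  )
}
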