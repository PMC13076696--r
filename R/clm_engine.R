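# The chemical language model: configuration, construction, staged training
# with plateau scheduling and best-epoch restoration, and incremental
# fine-tuning across a potency split.

#' Configure a chemical language model
#'
#' Architecture: token embedding, optional batch normalization, a stack of
#' LSTM layers, optional batch normalization, and a dense projection to
#' vocabulary logits. The reference configuration uses a 64-dimensional
#' embedding with LSTM stacks of 1024/256 units (or three 1024-unit layers
#' for broader chemotype spaces); desk-scale work uses much smaller stacks.
#'
#' @param vocab A `token_vocabulary`.
#' @param embedding_dim Embedding width. Default 64.
#' @param recurrent_layers Integer vector of LSTM unit counts per layer.
#'   Default `c(1024, 256)`.
#' @param use_batchnorm Apply batch normalization after the embedding and
#'   after the last LSTM layer. Default TRUE.
#' @param dropout Dropout proportion on LSTM outputs; use 0.2 for the
#'   canonical and augmented training variants and 0 for the randomized one.
#' @param batch_size Mini-batch size. Default 128.
#' @return A `clm_config` object.
#' @export
clm_config <- function(vocab, embedding_dim = 64, recurrent_layers = c(1024, 256),
                       use_batchnorm = TRUE, dropout = 0.2, batch_size = 128) {
  stopifnot(inherits(vocab, "token_vocabulary"),
            embedding_dim >= 1, all(recurrent_layers >= 1),
            dropout >= 0, dropout < 1)
  structure(
    list(vocab = vocab,
         vocab_size = length(vocab$tokens),
         embedding_dim = as.integer(embedding_dim),
         hidden = as.integer(recurrent_layers),
         use_batchnorm = isTRUE(use_batchnorm),
         dropout = dropout,
         batch_size = as.integer(batch_size)),
    class = "clm_config"
  )
}

#' Build a freshly initialized model
#'
#' Weight initialization is seed-reproducible: embeddings uniform(-0.05,
#' 0.05), input/recurrent LSTM weights and the dense projection
#' Glorot-uniform, biases zero except the forget-gate bias (1).
#'
#' @param config A [clm_config()].
#' @param seed Integer seed for the initialization.
#' @return A `clm_model` object.
#' @export
build_clm <- function(config, seed = 1L) {
  stopifnot(inherits(config, "clm_config"))
  if (config$vocab_size < 4) stop("vocabulary is empty")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(seed)

  glorot <- function(nr, nc) {
    lim <- sqrt(6 / (nr + nc))
    matrix(stats::runif(nr * nc, -lim, lim), nr, nc)
  }
  V <- config$vocab_size; E <- config$embedding_dim
  pieces <- list(matrix(stats::runif(E * V, -0.05, 0.05), E, V))
  if (config$use_batchnorm) pieces <- c(pieces, list(rep(1, E), rep(0, E)))
  input_dim <- E
  for (H in config$hidden) {
    b <- rep(0, 4 * H)
    b[(H + 1):(2 * H)] <- 1 # forget-gate bias
    pieces <- c(pieces, list(glorot(4 * H, input_dim), glorot(4 * H, H), b))
    input_dim <- H
  }
  if (config$use_batchnorm) pieces <- c(pieces, list(rep(1, input_dim), rep(0, input_dim)))
  pieces <- c(pieces, list(glorot(V, input_dim), rep(0, V)))
  theta <- unlist(lapply(pieces, as.numeric), use.names = FALSE)
  stopifnot(length(theta) == cpp_param_length(config))

  bn_run <- if (config$use_batchnorm) {
    H <- utils::tail(config$hidden, 1)
    c(rep(0, E), rep(1, E), rep(0, H), rep(1, H))
  } else {
    numeric(0)
  }
  structure(
    list(config = config, theta = theta, bn_run = bn_run,
         adam = list(m = numeric(length(theta)), v = numeric(length(theta)), t = 0L),
         epoch = 0L, lr = NA_real_, seed = as.integer(seed)),
    class = "clm_model"
  )
}

#' @export
print.clm_model <- function(x, ...) {
  cat("<clm_model> V =", x$config$vocab_size,
      "| embedding", x$config$embedding_dim,
      "| LSTM", paste(x$config$hidden, collapse = "/"),
      "| batchnorm", x$config$use_batchnorm,
      "|", format(length(x$theta), big.mark = ","), "parameters\n")
  cat("  trained epochs:", x$epoch, " lr:", x$lr, "\n")
  invisible(x)
}

#' Number of trainable parameters
#' @param model A `clm_model`.
#' @return Integer count.
#' @export
clm_num_params <- function(model) length(model$theta)

# Encode SMILES into a padded id matrix plus lengths.
encode_batch <- function(smiles, vocab) {
  seqs <- lapply(smiles, encode_smiles, vocab = vocab)
  lens <- vapply(seqs, length, integer(1))
  ids <- matrix(0L, length(seqs), max(lens))
  for (i in seq_along(seqs)) ids[i, seq_len(lens[i])] <- seqs[[i]]
  list(ids = ids, lengths = lens)
}

#' Select the checkpoint epoch from a validation-loss trace
#'
#' Canonical and augmented variants restore the epoch with the minimum
#' validation loss; the randomized variant minimizes a trailing moving
#' average (window 10, partial windows at the start). Ties resolve to the
#' earliest epoch.
#'
#' @param val_losses Numeric vector, one entry per epoch.
#' @param variant `"canonical"`, `"augmented"`, or `"randomized"`.
#' @param window Moving-average window for the randomized variant.
#' @return The selected epoch (1-based).
#' @export
select_checkpoint_epoch <- function(val_losses, variant = "canonical", window = 10) {
  stopifnot(length(val_losses) >= 1)
  crit <- if (variant == "randomized") {
    vapply(seq_along(val_losses), function(t) {
      mean(val_losses[max(1, t - window + 1):t])
    }, numeric(1))
  } else {
    val_losses
  }
  which.min(crit) # which.min takes the earliest tie
}

#' Train a model for one stage
#'
#' Trains with Adam on categorical cross-entropy under one of three data
#' variants: `canonical` (one canonical SMILES per record), `augmented`
#' (10 randomized spellings per record, drawn once up front), `randomized`
#' (one fresh randomized spelling per record every epoch; validation
#' sequences are re-randomized too). Canonical/augmented training reduces the
#' learning rate on plateau (factor 0.5, patience 3, floor `min_lr`). The
#' returned model is restored -- weights, optimizer state, batch-norm
#' statistics and learning rate -- to the epoch selected by
#' [select_checkpoint_epoch()].
#'
#' @param model A `clm_model`.
#' @param data Character vector of standardized SMILES (or a molecule table).
#' @param variant Training variant.
#' @param epochs Number of epochs; 0 returns the input model unchanged.
#' @param initial_lr Starting learning rate; when NA, continues from the
#'   model's current rate (used between fine-tuning stages), falling back to
#'   1e-3.
#' @param val_fraction Fraction reserved for validation (default 0.1).
#' @param val_data Optional explicit validation SMILES (overrides
#'   `val_fraction`).
#' @param schedule Plateau schedule: list(factor, patience, min_lr).
#' @param n_augment Spellings per record for the augmented variant.
#' @param ma_window Moving-average window for randomized checkpointing.
#' @param holdout Optional SMILES whose mean perplexity is traced per epoch.
#' @param seed Optional integer seed (controls the split, augmentation,
#'   shuffling and dropout for this stage).
#' @return List with `model` (restored), `log` (per-epoch data.frame with
#'   train_loss, val_loss, lr, and holdout_ppl when requested).
#' @export
train_stage <- function(model, data, variant = c("canonical", "augmented", "randomized"),
                        epochs = 100, initial_lr = NA, val_fraction = 0.1,
                        val_data = NULL, schedule = list(factor = 0.5, patience = 3, min_lr = 1e-4),
                        n_augment = 10, ma_window = 10, holdout = NULL, seed = NULL) {
  variant <- match.arg(variant)
  stopifnot(inherits(model, "clm_model"))
  if (is.data.frame(data)) data <- data$smiles
  if (!length(data)) stop("no training data")
  if (!is.null(seed)) set.seed(seed)
  if (epochs == 0) {
    return(list(model = model,
                log = data.frame(epoch = integer(0), train_loss = numeric(0),
                                 val_loss = numeric(0), lr = numeric(0))))
  }

  cfg <- model$config
  vocab <- cfg$vocab
  dropout <- if (variant == "randomized") 0 else cfg$dropout

  # validation split
  if (is.null(val_data)) {
    if (val_fraction > 0) {
      n_val <- ceiling(val_fraction * length(data))
      if (length(data) - n_val < 1) {
        stop("data smaller than the validation split allows (n = ", length(data), ")")
      }
      val_idx <- sample(length(data), n_val)
      val_data <- data[val_idx]
      train_data <- data[-val_idx]
    } else {
      stop("either val_fraction > 0 or explicit val_data is required")
    }
  } else {
    train_data <- data
  }

  # assemble training sequences per variant
  graphs <- NULL
  val_graphs <- NULL
  if (variant == "canonical") {
    train_smiles <- train_data
  } else if (variant == "augmented") {
    gs <- parse_mol_graphs(train_data)
    train_smiles <- unlist(lapply(gs, function(g) {
      vapply(seq_len(n_augment), function(i) .random_dfs_smiles(g), character(1))
    }))
  } else {
    graphs <- parse_mol_graphs(train_data)
    val_graphs <- parse_mol_graphs(val_data)
  }
  val_enc <- encode_batch(val_data, vocab)
  hold_graphs <- NULL
  hold_enc <- NULL
  if (!is.null(holdout)) {
    if (variant == "randomized") {
      # score the holdout on spellings from the population the model reads
      hold_graphs <- parse_mol_graphs(holdout)
    } else {
      hold_enc <- encode_batch(holdout, vocab)
    }
  }

  lr <- if (is.na(initial_lr)) {
    if (is.na(model$lr)) 1e-3 else model$lr
  } else {
    initial_lr
  }

  theta <- model$theta
  adam <- model$adam
  bn_run <- model$bn_run
  clist <- unclass(cfg)

  log <- data.frame(epoch = seq_len(epochs), train_loss = NA_real_,
                    val_loss = NA_real_, lr = NA_real_)
  if (!is.null(holdout)) log$holdout_ppl <- NA_real_

  best <- list(crit = Inf, epoch = 0L, theta = theta, adam = adam,
               bn_run = bn_run, lr = lr)
  plateau_best <- Inf
  plateau_wait <- 0L

  if (variant != "randomized") {
    enc <- encode_batch(train_smiles, vocab)
  }

  for (ep in seq_len(epochs)) {
    if (variant == "randomized") {
      enc <- encode_batch(.randomize_each(graphs), vocab)
      val_enc <- encode_batch(.randomize_each(val_graphs), vocab)
    }
    ord <- sample(nrow(enc$ids))
    res <- cpp_train_epoch(theta, adam$m, adam$v, adam$t, bn_run, clist,
                           enc$ids, enc$lengths, ord, cfg$batch_size, lr, dropout)
    theta <- res$theta
    adam <- list(m = res$adam_m, v = res$adam_v, t = res$adam_t)
    bn_run <- res$bn_run
    val_loss <- cpp_eval_nll(theta, bn_run, clist, val_enc$ids, val_enc$lengths)
    log$train_loss[ep] <- res$train_loss
    log$val_loss[ep] <- val_loss
    log$lr[ep] <- lr
    if (!is.null(holdout)) {
      enc_h <- if (!is.null(hold_graphs)) {
        encode_batch(.randomize_each(hold_graphs), vocab)
      } else {
        hold_enc
      }
      lp <- cpp_token_logprobs(theta, bn_run, clist, enc_h$ids, enc_h$lengths)
      ppl <- exp(-rowMeans(lp, na.rm = TRUE))
      log$holdout_ppl[ep] <- mean(ppl)
    }

    # checkpoint criterion (trailing moving average for randomized)
    crit <- if (variant == "randomized") {
      mean(log$val_loss[max(1, ep - ma_window + 1):ep])
    } else {
      val_loss
    }
    if (crit < best$crit) {
      best <- list(crit = crit, epoch = ep, theta = theta, adam = adam,
                   bn_run = bn_run, lr = lr)
    }

    # plateau schedule (canonical / augmented only)
    if (variant != "randomized" && !is.null(schedule)) {
      if (val_loss < plateau_best - 1e-12) {
        plateau_best <- val_loss
        plateau_wait <- 0L
      } else {
        plateau_wait <- plateau_wait + 1L
        if (plateau_wait >= schedule$patience && lr > schedule$min_lr) {
          lr <- max(lr * schedule$factor, schedule$min_lr)
          plateau_wait <- 0L
        }
      }
    }
  }

  out <- model
  out$theta <- best$theta
  out$adam <- best$adam
  out$bn_run <- best$bn_run
  out$lr <- best$lr
  out$epoch <- model$epoch + best$epoch
  list(model = out, log = log, best_epoch = best$epoch)
}

#' Incrementally fine-tune across a potency split
#'
#' Runs [train_stage()] on each subset of the split in order of increasing
#' potency, each stage continuing from the previous stage's restored weights,
#' optimizer state and learning rate. When a holdout is supplied the per-epoch
#' mean holdout perplexity is traced through every stage.
#'
#' @param model A pretrained (naive) `clm_model`.
#' @param split A `potency_split` from [split_series()] (or a list of SMILES
#'   character vectors ordered by increasing potency).
#' @param variant Training variant for all stages.
#' @param epochs Epochs per stage (default 100).
#' @param initial_lr Learning rate entering the first stage (default 1e-4);
#'   later stages continue from the restored rate.
#' @param holdout Optional holdout SMILES for the perplexity trace.
#' @param seed Integer seed.
#' @param ... Further arguments passed to [train_stage()].
#' @return List with `model` (final state), `logs` (one per stage), and
#'   `holdout_trace` (concatenated per-epoch mean holdout perplexity, with a
#'   `stage` column) when a holdout was given.
#' @export
incremental_finetune <- function(model, split, variant = "canonical",
                                 epochs = 100, initial_lr = 1e-4,
                                 holdout = NULL, seed = NULL, ...) {
  subsets <- if (inherits(split, "potency_split")) split$subsets else split
  stopifnot(length(subsets) >= 1)
  if (!is.null(seed)) set.seed(seed)
  logs <- vector("list", length(subsets))
  traces <- NULL
  lr <- initial_lr
  for (j in seq_along(subsets)) {
    smiles_j <- if (is.data.frame(subsets[[j]])) subsets[[j]]$smiles else subsets[[j]]
    if (length(smiles_j) < 2) {
      stop("fine-tuning subset ", j, " has fewer than 2 molecules")
    }
    st <- train_stage(model, smiles_j, variant = variant, epochs = epochs,
                      initial_lr = lr, holdout = holdout, ...)
    model <- st$model
    lr <- NA # continue from the restored rate hereafter
    logs[[j]] <- st$log
    if (!is.null(holdout)) {
      traces <- rbind(traces, data.frame(stage = j, epoch = st$log$epoch,
                                         holdout_ppl = st$log$holdout_ppl))
    }
  }
  list(model = model, logs = logs, holdout_trace = traces)
}

#' Save / load model checkpoints
#'
#' The checkpoint is a serialized model object plus a small JSON sidecar
#' describing the architecture, epoch, learning rate and vocabulary digest.
#'
#' @param model A `clm_model`. @param path File path for the checkpoint.
#' @return `save_clm` returns the path invisibly; `load_clm` the model.
#' @export
save_clm <- function(model, path) {
  stopifnot(inherits(model, "clm_model"))
  saveRDS(model, path)
  sidecar <- list(
    embedding_dim = model$config$embedding_dim,
    hidden = model$config$hidden,
    use_batchnorm = model$config$use_batchnorm,
    vocab_size = model$config$vocab_size,
    vocab_digest = sum(utf8ToInt(paste(model$config$vocab$tokens, collapse = ""))),
    epoch = model$epoch,
    lr = model$lr,
    seed = model$seed,
    n_params = length(model$theta)
  )
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_clm
#' @export
load_clm <- function(path) {
  model <- readRDS(path)
  stopifnot(inherits(model, "clm_model"))
  model
}

#' Choose the pretraining epoch by sampling quality
#'
#' Samples from each candidate checkpoint, computes validity, uniqueness,
#' novelty and the descriptor-panel distributional similarity against a
#' reference sample, and returns the candidate with the highest similarity
#' among those with validity at or above `min_validity` (falling back to the
#' highest-validity candidate when none qualify; ties resolve to higher
#' validity).
#'
#' @param candidates List of `clm_model` checkpoints.
#' @param reference_sample Character vector of reference SMILES.
#' @param n_designs Samples drawn per candidate (default 10000; reduce for
#'   toy scale).
#' @param temperature Sampling temperature. @param max_len Length cap.
#' @return List with `model` (the chosen candidate), `index`, and `metrics`
#'   (one row per candidate).
#' @export
select_pretrain_epoch <- function(candidates, reference_sample, n_designs = 10000,
                                  temperature = 1.0, max_len = 140,
                                  min_validity = 0.9) {
  if (!length(candidates)) stop("no candidate checkpoints")
  metrics <- data.frame(candidate = seq_along(candidates), validity = NA_real_,
                        uniqueness = NA_real_, novelty = NA_real_, s_kl = NA_real_)
  for (k in seq_along(candidates)) {
    ds <- sample_designs(candidates[[k]], n = n_designs, temperature = temperature,
                         max_len = max_len)
    st <- tryCatch(sampling_statistics(ds, training = character(0)),
                   error = function(e) list(validity = 0, uniqueness = 0, novelty = 0))
    metrics$validity[k] <- st$validity
    metrics$uniqueness[k] <- st$uniqueness
    metrics$novelty[k] <- st$novelty
    valid_smiles <- unique(ds$samples$smiles[!is.na(ds$samples$smiles)])
    metrics$s_kl[k] <- if (length(valid_smiles) >= 10) {
      kl_similarity(valid_smiles, reference_sample)$s_kl
    } else {
      0
    }
  }
  eligible <- which(metrics$validity >= min_validity)
  if (!length(eligible)) eligible <- which.max(metrics$validity)
  ord <- eligible[order(-metrics$s_kl[eligible], -metrics$validity[eligible])]
  list(model = candidates[[ord[1]]], index = ord[1], metrics = metrics)
}
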