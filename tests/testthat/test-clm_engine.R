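# Model construction, training mechanics, checkpoint restoration and
# serialization.

test_that("model construction is seed-reproducible and shape-correct", {
  m1 <- fixture_tiny_model()
  vocab <- m1$config$vocab
  V <- length(vocab$tokens)
  probe <- encode_smiles("CCO", vocab)
  p1 <- increclm:::cpp_next_probs(m1$theta, m1$bn_run, unclass(m1$config),
                                  probe, 1.0)
  expect_length(p1, V)
  expect_equal(sum(p1), 1, tolerance = 1e-12)
  m2 <- build_clm(m1$config, seed = 7)
  p2 <- increclm:::cpp_next_probs(m2$theta, m2$bn_run, unclass(m2$config),
                                  probe, 1.0)
  expect_identical(m1$theta, m2$theta)
  expect_identical(p1, p2)
  m3 <- build_clm(m1$config, seed = 8)
  expect_false(identical(m1$theta, m3$theta))
})

test_that("the reference architecture builds at its documented shape", {
  vocab <- build_vocabulary(fixture_panel())
  cfg <- clm_config(vocab) # embedding 64, LSTM 1024/256, batchnorm
  expect_identical(cfg$hidden, c(1024L, 256L))
  n <- increclm:::cpp_param_length(unclass(cfg))
  V <- cfg$vocab_size
  expected <- 64 * V + 2 * 64 +
    4 * 1024 * (64 + 1024 + 1) +
    4 * 256 * (1024 + 256 + 1) +
    2 * 256 + V * 256 + V
  expect_equal(n, expected)
  expect_error(clm_config(vocab, dropout = 1), "dropout")
})

test_that("analytic gradients match finite differences", {
  vocab <- build_vocabulary(c("CCO", "CC(=O)O", "c1ccccc1C"))
  for (bn in c(FALSE, TRUE)) {
    cfg <- clm_config(vocab, embedding_dim = 5, recurrent_layers = c(7, 6),
                      use_batchnorm = bn, dropout = 0, batch_size = 4)
    m <- build_clm(cfg, seed = 3)
    enc <- increclm:::encode_batch(c("CCO", "CC(=O)O", "c1ccccc1C"), vocab)
    lg <- increclm:::cpp_loss_grads(m$theta, unclass(cfg), enc$ids,
                                    enc$lengths, m$bn_run, TRUE, 0)
    set.seed(5)
    idx <- sample(length(m$theta), 40)
    eps <- 1e-5
    num <- vapply(idx, function(j) {
      tp <- m$theta; tp[j] <- tp[j] + eps
      tm <- m$theta; tm[j] <- tm[j] - eps
      (increclm:::cpp_loss_grads(tp, unclass(cfg), enc$ids, enc$lengths,
                                 m$bn_run, TRUE, 0)$loss -
       increclm:::cpp_loss_grads(tm, unclass(cfg), enc$ids, enc$lengths,
                                 m$bn_run, TRUE, 0)$loss) / (2 * eps)
    }, numeric(1))
    expect_lt(max(abs(num - lg$grad[idx]) /
                    pmax(1e-4, abs(num) + abs(lg$grad[idx]))), 1e-5)
  }
})

test_that("training zero epochs returns the model unchanged", {
  m <- fixture_tiny_model()
  out <- train_stage(m, fixture_panel(), epochs = 0, seed = 1)
  expect_identical(out$model, m)
  expect_equal(nrow(out$log), 0)
})

test_that("validation loss falls over the first epochs on a small dataset", {
  m <- fixture_tiny_model()
  st <- train_stage(m, rep(fixture_panel(), 4), variant = "canonical",
                    epochs = 8, initial_lr = 3e-3, val_fraction = 0.2,
                    schedule = NULL, seed = 2)
  expect_true(all(is.finite(st$log$val_loss)))
  expect_lt(utils::tail(st$log$val_loss, 1), st$log$val_loss[1])
})

test_that("checkpoint selection restores the argmin-validation epoch", {
  expect_equal(select_checkpoint_epoch(c(1.0, 0.8, 0.9)), 2)
  expect_equal(select_checkpoint_epoch(c(0.5, 0.5, 0.5)), 1) # tie -> earliest
  # randomized: trailing 10-epoch moving average, partial windows at start
  expect_equal(select_checkpoint_epoch(rep(1, 30), "randomized"), 1)
  trace <- c(5, 4, 3, 2, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 9, 9, 9, 9)
  # plain argmin would take epoch 5; the smoothed criterion keeps falling
  # until the window is saturated with the plateau
  expect_equal(select_checkpoint_epoch(trace, "randomized", window = 10), 14)
  expect_equal(select_checkpoint_epoch(trace, "canonical"), 5)
})

test_that("the returned model is the snapshot of the best epoch", {
  m <- fixture_tiny_model()
  st <- train_stage(m, rep(fixture_panel(), 3), variant = "canonical",
                    epochs = 6, initial_lr = 3e-3, val_fraction = 0.25,
                    schedule = NULL, seed = 3)
  best <- which.min(st$log$val_loss)
  expect_equal(st$best_epoch, best)
  # re-evaluating the returned weights on the same validation data must give
  # exactly the recorded loss of that epoch (restoration is bit-for-bit)
  set.seed(3)
  n_val <- ceiling(0.25 * length(rep(fixture_panel(), 3)))
  val_idx <- sample(length(rep(fixture_panel(), 3)), n_val)
  val <- rep(fixture_panel(), 3)[val_idx]
  enc <- increclm:::encode_batch(val, m$config$vocab)
  got <- increclm:::cpp_eval_nll(st$model$theta, st$model$bn_run,
                                 unclass(m$config), enc$ids, enc$lengths)
  expect_identical(got, st$log$val_loss[best])
})

test_that("checkpoint save/load reproduces the identical sampled token stream", {
  m <- fixture_tiny_model()
  st <- train_stage(m, fixture_panel(), epochs = 3, initial_lr = 1e-3,
                    val_fraction = 0.2, seed = 4)
  path <- tempfile(fileext = ".rds")
  save_clm(st$model, path)
  expect_true(file.exists(paste0(path, ".json")))
  loaded <- load_clm(path)
  expect_identical(loaded$theta, st$model$theta)
  d1 <- sample_designs(st$model, n = 50, max_len = 60, seed = 99)
  d2 <- sample_designs(loaded, n = 50, max_len = 60, seed = 99)
  expect_identical(d1$raw, d2$raw)
})

test_that("training variants assemble the data they advertise", {
  m <- fixture_tiny_model()
  # augmented: n_augment spellings per record, fixed up front; runs clean
  st <- train_stage(m, fixture_panel()[1:6], variant = "augmented",
                    epochs = 2, initial_lr = 1e-3, val_fraction = 0.2,
                    n_augment = 3, seed = 5)
  expect_equal(nrow(st$log), 2)
  # randomized: fresh spellings each epoch; moving-average checkpointing
  st2 <- train_stage(m, fixture_panel()[1:6], variant = "randomized",
                     epochs = 4, initial_lr = 1e-3, val_fraction = 0.2,
                     seed = 6)
  expect_equal(nrow(st2$log), 4)
  expect_true(all(is.finite(st2$log$val_loss)))
})

test_that("the plateau schedule halves the rate and respects its floor", {
  m <- fixture_tiny_model()
  # force plateaus with a tiny dataset and an aggressive schedule
  st <- train_stage(m, fixture_panel(), variant = "canonical", epochs = 10,
                    initial_lr = 8e-4, val_fraction = 0.2,
                    schedule = list(factor = 0.5, patience = 1, min_lr = 2e-4),
                    seed = 7)
  lrs <- unique(st$log$lr)
  expect_true(all(diff(st$log$lr) <= 0)) # never increases
  expect_gte(min(st$log$lr), 2e-4)       # floor respected
  expect_true(all(lrs %in% c(8e-4, 4e-4, 2e-4)))
})

test_that("incremental fine-tuning carries state and errors on tiny stages", {
  m <- fixture_tiny_model()
  series <- fixture_series(12)
  split <- split_series(series, "values", k = 3)
  ft <- incremental_finetune(m, split, variant = "canonical", epochs = 2,
                             initial_lr = 1e-3, val_fraction = 0.25,
                             holdout = fixture_series(14)$smiles[13:14],
                             seed = 8)
  expect_length(ft$logs, 3)
  expect_equal(unique(ft$holdout_trace$stage), 1:3)
  expect_true(all(is.finite(ft$holdout_trace$holdout_ppl)))
  bad <- list(fixture_series(4)$smiles, fixture_series(1)$smiles)
  expect_error(
    incremental_finetune(m, bad, epochs = 1, val_fraction = 0.25, seed = 1),
    "subset 2"
  )
})

test_that("training data smaller than the validation split errors", {
  m <- fixture_tiny_model()
  expect_error(train_stage(m, "CCO", epochs = 1, val_fraction = 0.5, seed = 1),
               "validation split")
})

test_that("pretrain-epoch selection prefers valid, reference-like candidates", {
  m <- fixture_tiny_model()
  res <- select_pretrain_epoch(list(m), reference_sample = fixture_panel(),
                               n_designs = 30, max_len = 40)
  expect_identical(res$index, 1L) # single candidate returned unconditionally
  expect_equal(nrow(res$metrics), 1)
  expect_error(select_pretrain_epoch(list(), fixture_panel()), "no candidate")
})
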