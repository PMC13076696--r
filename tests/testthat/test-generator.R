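# Temperature softmax, sampling, perplexity, ranking and the filter cascade.

test_that("temperature softmax matches hand-computed values and sums to one", {
  # z = (1, 0), T = 1: q1 = e/(1+e); reference value computed by hand
  q <- softmax_temperature(c(1, 0), 1)
  expect_equal(q, c(0.731058578630005, 0.268941421369995), tolerance = 1e-9)
  expect_equal(sum(q), 1, tolerance = 1e-12)
  # equal logits are uniform at any temperature
  for (temp in c(0.1, 1, 10)) {
    expect_equal(softmax_temperature(c(2, 2, 2, 2), temp), rep(0.25, 4),
                 tolerance = 1e-12)
  }
  # limits: T large -> uniform; T small -> argmax
  z <- c(3, 1, -2)
  expect_equal(softmax_temperature(z, 1e4), rep(1 / 3, 3), tolerance = 1e-3)
  expect_gt(softmax_temperature(z, 1e-2)[1], 1 - 1e-9)
  expect_true(all(softmax_temperature(c(-100, 100), 0.5) > 0))
  expect_error(softmax_temperature(c(1, 0), 0), "temperature")
})

test_that("perplexity closed forms hold exactly", {
  expect_equal(perplexity_from_probs(c(1, 1, 1)), 1.0)
  expect_equal(perplexity_from_probs(c(0.5, 0.25, 0.25)), 32^(1 / 3),
               tolerance = 1e-12)
  V <- 21
  expect_equal(perplexity_from_probs(rep(1 / V, 7)), V, tolerance = 1e-12)
  expect_error(perplexity_from_probs(c(0.5, 0)), "probs")
})

test_that("a uniform model scores PPL = V on any sequence", {
  m <- fixture_tiny_model()
  m$theta[] <- 0 # all-zero weights: logits identically zero -> uniform
  V <- m$config$vocab_size
  ppl <- sequence_perplexity(m, c("CCO", "c1ccccc1", "CC(=O)O"))
  expect_equal(ppl, rep(V, 3), tolerance = 1e-9)
})

test_that("model perplexity is at least one and matches its own token probabilities", {
  m <- fixture_tiny_model()
  smiles <- fixture_panel()[1:5]
  ppl <- sequence_perplexity(m, smiles)
  expect_true(all(ppl >= 1))
  # independent recomputation by walking next-token distributions
  vocab <- m$config$vocab
  for (s in smiles[1:2]) {
    ids <- encode_smiles(s, vocab)
    q <- vapply(seq_len(length(ids) - 1), function(t) {
      p <- increclm:::cpp_next_probs(m$theta, m$bn_run, unclass(m$config),
                                     ids[seq_len(t)], 1.0)
      p[ids[t + 1] + 1]
    }, numeric(1))
    expect_equal(perplexity_from_probs(q), ppl[smiles == s], tolerance = 1e-8)
  }
})

test_that("sampling at T = 1 reproduces the model's first-token distribution", {
  m <- fixture_tiny_model()
  vocab <- m$config$vocab
  n <- 10000
  ds <- sample_designs(m, n = n, max_len = 3, seed = 123)
  first <- regmatches(ds$raw, regexpr("^(\\[[^]]*\\]|Cl|Br|.)", ds$raw))
  # analytic first-token distribution (pad/start masked, renormalized)
  p <- increclm:::cpp_next_probs(m$theta, m$bn_run, unclass(m$config),
                                 vocab$start_id, 1.0)
  p[1:2] <- 0
  p <- p / sum(p)
  for (tok in c("C", "c", "O", "Cl")) {
    k <- which(vocab$tokens == tok)
    phat <- mean(first == tok)
    sigma <- sqrt(p[k] * (1 - p[k]) / n)
    expect_lt(abs(phat - p[k]), 3 * sigma + 1e-9)
  }
})

test_that("sampling is seed-reproducible and aggregates duplicates", {
  m <- fixture_tiny_model()
  d1 <- sample_designs(m, n = 200, max_len = 30, seed = 11)
  d2 <- sample_designs(m, n = 200, max_len = 30, seed = 11)
  expect_identical(d1$raw, d2$raw)
  expect_identical(d1$samples, d2$samples)
  expect_equal(sum(d1$samples$frequency), d1$n_valid)
  expect_equal(d1$n_valid + d1$n_invalid, 200)
  expect_true(all(d1$samples$frequency >= 1))
})

test_that("ranking sorts by perplexity with frequency then lexicographic ties", {
  m <- fixture_tiny_model()
  ds <- sample_designs(m, n = 300, max_len = 30, seed = 21)
  ranked <- rank_designs(ds, m)
  s <- ranked$samples
  expect_true(all(diff(s$ppl) >= 0))
  expect_identical(s$rank, seq_len(nrow(s)))
  # tie rule on a constructed table under a uniform model (all PPL equal at
  # fixed length)
  mu <- m
  mu$theta[] <- 0
  ds2 <- ds
  ds2$samples <- data.frame(smiles = c("CCO", "CCC", "OCO"),
                            frequency = c(10L, 40L, 10L),
                            exemplar = c("CCO", "CCC", "OCO"),
                            stringsAsFactors = FALSE)
  r2 <- rank_designs(ds2, mu)
  expect_identical(r2$samples$smiles[1], "CCC")        # higher frequency first
  expect_identical(r2$samples$smiles[2:3], c("CCO", "OCO")) # then lexicographic
})

test_that("designs present in the fine-tuning set are removed from the ranking", {
  m <- fixture_tiny_model()
  ds <- sample_designs(m, n = 300, max_len = 30, seed = 22)
  banned <- ds$samples$smiles[1:2]
  ranked <- rank_designs(ds, m, finetune_set = banned)
  expect_false(any(banned %in% ranked$samples$smiles))
  expect_lte(nrow(ranked$samples), nrow(ds$samples))
})

test_that("the filter cascade applies rules in order with attributed removals", {
  m <- fixture_tiny_model()
  ds <- sample_designs(m, n = 400, max_len = 30, seed = 23)
  ranked <- rank_designs(ds, m)
  # empty config: only the naive floor applies
  f0 <- filter_designs(ranked, m, filter_config(min_naive_perplexity = 1.012))
  expect_true(all(f0$removals$rule == "naive-perplexity-floor"))
  kept_plus_removed <- nrow(f0$samples) + nrow(f0$removals)
  expect_equal(kept_plus_removed, nrow(ranked$samples))
  # a design's own naive perplexity decides its fate
  if (nrow(f0$samples)) {
    ppl_kept <- sequence_perplexity(m, f0$samples$smiles[1])
    expect_gte(ppl_kept, 1.012)
  }
  # an absurdly high floor removes everything by rule 1
  fall <- filter_designs(ranked, m, filter_config(min_naive_perplexity = 1e6))
  expect_equal(nrow(fall$samples), 0)
  expect_true(all(fall$removals$rule == "naive-perplexity-floor"))
})

test_that("known-set, similarity and blacklist rules remove what they should", {
  m <- fixture_tiny_model()
  ds <- sample_designs(m, n = 400, max_len = 30, seed = 24)
  ranked <- rank_designs(ds, m)
  expect_gte(nrow(ranked$samples), 5)
  victim <- ranked$samples$smiles[1]
  f <- filter_designs(ranked, NULL,
                      filter_config(min_naive_perplexity = NA,
                                    known_sets = list(victim)))
  expect_false(victim %in% f$samples$smiles)
  expect_identical(f$removals$rule[f$removals$smiles == victim],
                   "known-molecule")
  # training-similarity cap: a molecule is maximally similar to itself
  f2 <- filter_designs(ranked, NULL,
                       filter_config(min_naive_perplexity = NA,
                                     max_similarity = 0.8),
                       training = victim)
  expect_false(victim %in% f2$samples$smiles)
  expect_true("training-similarity" %in% f2$removals$rule)
  # blacklisted substructure
  f3 <- filter_designs(ranked, NULL,
                       filter_config(min_naive_perplexity = NA,
                                     substructure_blacklist = "C"),
                       training = character(0))
  if (nrow(f3$samples)) {
    expect_true(all(increclm:::ob_smarts_count(f3$samples$smiles, "C") == 0))
  }
  expect_true(all(increclm:::ob_smarts_count(
    f3$removals$smiles[f3$removals$rule == "substructure-blacklist"], "C") > 0))
})

test_that("oversized rings and prioritized substructures are handled", {
  m <- fixture_tiny_model()
  base <- sample_designs(m, n = 50, max_len = 20, seed = 25)
  big_ring <- standardize_smiles("C1CCCCCCC1")$smiles # 8-membered
  sulfonamide <- standardize_smiles("CCS(=O)(=O)NC")$smiles
  base$samples <- data.frame(
    smiles = c(big_ring, sulfonamide, "CCO"),
    frequency = c(1L, 1L, 5L),
    exemplar = c(big_ring, sulfonamide, "CCO"),
    ppl = c(1.2, 1.3, 1.1), rank = 1:3,
    stringsAsFactors = FALSE
  )
  f <- filter_designs(base, NULL,
                      filter_config(min_naive_perplexity = NA,
                                    max_ring_size = 7,
                                    priority_pattern = "S(=O)(=O)N"))
  expect_false(big_ring %in% f$samples$smiles)
  expect_identical(f$samples$smiles[1], sulfonamide) # stable prioritization
  expect_true("ring-size" %in% f$removals$rule)
})

test_that("substructure/isomer removal against the training set works", {
  m <- fixture_tiny_model()
  base <- sample_designs(m, n = 50, max_len = 20, seed = 26)
  training <- standardize_smiles("CCOC(=O)CC")$smiles
  iso <- standardize_smiles("CCC(=O)OCC")$smiles # same formula C5H10O2
  sub <- "CCO"                                   # substructure of training
  other <- standardize_smiles("c1ccncc1")$smiles
  base$samples <- data.frame(
    smiles = c(iso, sub, other), frequency = c(1L, 1L, 1L),
    exemplar = c(iso, sub, other), ppl = c(1.1, 1.2, 1.3), rank = 1:3,
    stringsAsFactors = FALSE
  )
  f <- filter_designs(base, NULL,
                      filter_config(min_naive_perplexity = NA,
                                    remove_substructures_isomers = TRUE),
                      training = training)
  expect_setequal(f$samples$smiles, other)
  expect_true(all(f$removals$rule == "training-substructure-or-isomer"))
})
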