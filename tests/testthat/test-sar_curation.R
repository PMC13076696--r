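# Reference-corpus filtering, series curation, splitting and holdout
# extraction.

test_that("corpus filtering removes similar molecules with a strict threshold", {
  series <- fixture_series(6)$smiles
  corpus <- c(series[1], fixture_panel()[1:6]) # one exact ligand + unrelated
  fp_c <- morgan_fp(corpus)
  fp_s <- morgan_fp(series)
  max_sim <- apply(increclm:::.tanimoto_cross(fp_c, fp_s), 1, max)

  res <- filter_reference_corpus(corpus, series, sim_threshold = 0.4)
  expect_true(all(max_sim[corpus %in% res$corpus] <= 0.4))
  expect_false(series[1] %in% res$corpus) # exact ligand similarity 1 > 0.4

  # strict inequality at the boundary: a molecule at exactly the threshold
  # is retained, infinitesimally below the threshold it is removed
  probe <- corpus[2]
  s <- max_sim[2]
  expect_true(s > 0) # the probe shares some bits with the series
  at <- filter_reference_corpus(corpus, series, sim_threshold = s)
  expect_true(probe %in% at$corpus)
  below <- filter_reference_corpus(corpus, series, sim_threshold = s - 1e-9)
  expect_false(probe %in% below$corpus)
  expect_equal(sum(below$report$removed),
               length(corpus) - length(below$corpus))
})

test_that("an empty target-ligand list leaves the corpus unchanged with a warning", {
  corpus <- fixture_panel()
  expect_warning(res <- filter_reference_corpus(corpus, character(0)),
                 "unchanged")
  expect_identical(res$corpus, corpus)
})

test_that("filtering removes a superset of exact ligands for any threshold < 1", {
  series <- fixture_series(5)$smiles
  corpus <- c(series, fixture_panel())
  for (th in c(0.2, 0.5, 0.9)) {
    res <- filter_reference_corpus(corpus, series, sim_threshold = th)
    expect_false(any(series %in% res$corpus))
  }
})

test_that("series curation rejects small and diverse sets per rule", {
  # 24 close analogs: below the size floor
  small <- fixture_series(24)
  rej <- curate_series(small, min_size = 25)
  expect_s3_class(rej, "series_rejection")
  expect_identical(rej$reason, "too-small")
  # 25 analogs pass
  ok <- curate_series(fixture_series(25), min_size = 25)
  expect_s3_class(ok, "sar_series")
  expect_equal(nrow(ok$records), 25)
  expect_true(ok$mean_internal_similarity >= 0.3)

  # structurally unrelated molecules: mean similarity below 0.3
  # (outlier dropping disabled to isolate the mean-similarity rule)
  diverse <- data.frame(smiles = fixture_panel(), potency = 6,
                        stringsAsFactors = FALSE)
  rej2 <- curate_series(diverse, min_size = 5, outlier_sim = 0)
  expect_s3_class(rej2, "series_rejection")
  expect_identical(rej2$reason, "too-diverse")
  expect_lt(rej2$mean_internal_similarity, 0.3)
})

test_that("a single remote outlier is dropped, the analog core is kept", {
  core <- fixture_series(26)
  outlier <- data.frame(smiles = "CCCCCCCC", potency = 5,
                        stringsAsFactors = FALSE)
  res <- curate_series(rbind(core, outlier), min_size = 25)
  expect_s3_class(res, "sar_series")
  expect_equal(nrow(res$records), 26)
  expect_identical(res$dropped, "CCCCCCCC")
  # curation is idempotent
  again <- curate_series(res$records, min_size = 25)
  expect_identical(again$records$smiles, res$records$smiles)
  expect_length(again$dropped, 0)
})

test_that("too few candidates are rejected outright", {
  one <- data.frame(smiles = "CCO", potency = 6)
  expect_s3_class(curate_series(one), "series_rejection")
  expect_identical(curate_series(one)$reason, "too-few-candidates")
})

test_that("values split gives equal potency-ordered groups", {
  rec <- fixture_random_records(20, seed = 1)
  sp <- split_series(rec, "values", k = 4)
  sizes <- vapply(sp$subsets, nrow, integer(1))
  expect_identical(sizes, rep(5L, 4))
  # monotone potency across group boundaries
  for (j in 1:3) {
    expect_lte(max(sp$subsets[[j]]$potency), min(sp$subsets[[j + 1]]$potency))
  }
})

test_that("values split spreads the remainder over the lowest-potency groups", {
  rec <- fixture_random_records(22, seed = 2)
  sp <- split_series(rec, "values", k = 4)
  expect_identical(vapply(sp$subsets, nrow, integer(1)), c(6L, 6L, 5L, 5L))
})

test_that("focused split halves group sizes toward the most potent", {
  rec <- fixture_random_records(28, seed = 3)
  sp <- split_series(rec, "focused", k = 3)
  expect_identical(vapply(sp$subsets, nrow, integer(1)), c(16L, 8L, 4L))
  for (j in 1:2) {
    expect_lte(max(sp$subsets[[j]]$potency), min(sp$subsets[[j + 1]]$potency))
  }
  # leftovers join the first (least potent) group
  sp2 <- split_series(fixture_random_records(30, seed = 4), "focused", k = 3)
  expect_identical(vapply(sp2$subsets, nrow, integer(1)), c(18L, 8L, 4L))
})

test_that("best keeps only the most active values-group; all does not split", {
  rec <- fixture_random_records(20, seed = 5)
  best <- split_series(rec, "best", k = 4)
  expect_equal(best$k, 1)
  values <- split_series(rec, "values", k = 4)
  expect_identical(best$subsets[[1]]$smiles, values$subsets[[4]]$smiles)
  all_sp <- split_series(rec, "all")
  expect_equal(all_sp$k, 1)
  expect_setequal(all_sp$subsets[[1]]$smiles, rec$smiles)
})

test_that("scaffold split trains scaffolds first, full structures second", {
  series <- fixture_series(26)
  sp <- split_series(series, "scaffold")
  expect_equal(sp$k, 2)
  # step 1 holds the unique Murcko scaffold(s) of the series
  expect_true(all(vapply(sp$subsets[[1]]$smiles, function(s) {
    !is.na(increclm:::ob_convert_smiles(s))
  }, logical(1))))
  expect_lt(nrow(sp$subsets[[1]]), nrow(series))
  expect_setequal(sp$subsets[[2]]$smiles, series$smiles)
})

test_that("every record-partitioning strategy is a true partition (fuzz)", {
  set.seed(99)
  for (i in 1:300) {
    n <- sample(5:60, 1)
    k <- sample(1:min(5, n), 1)
    strategy <- sample(c("values", "random", "focused", "all", "best"), 1)
    rec <- fixture_random_records(n, seed = i)
    sp <- tryCatch(
      split_series(rec, strategy, k = k, seed = i),
      error = function(e) NULL # focused may legitimately refuse tiny n/k
    )
    if (is.null(sp)) {
      expect_identical(strategy, "focused")
      next
    }
    got <- unlist(lapply(sp$subsets, function(s) s$smiles))
    if (strategy %in% c("values", "random", "focused", "all")) {
      expect_identical(sort(got), sort(rec$smiles)) # disjoint and exhaustive
    } else {
      expect_true(all(got %in% rec$smiles))
      expect_false(anyDuplicated(got) > 0)
    }
    if (strategy %in% c("values", "focused") && sp$k > 1) {
      for (j in seq_len(sp$k - 1)) {
        expect_lte(max(sp$subsets[[j]]$potency),
                   min(sp$subsets[[j + 1]]$potency))
      }
    }
  }
})

test_that("k larger than the series errors", {
  expect_error(split_series(fixture_random_records(5, 1), "values", k = 6),
               "exceeds")
})

test_that("holdout extraction withholds the most potent ceiling fraction", {
  rec <- fixture_random_records(40, seed = 7)
  hs <- extract_holdout(rec, 0.25)
  expect_equal(nrow(hs$holdout), 10)
  expect_equal(nrow(hs$training), 30)
  expect_gte(min(hs$holdout$potency), max(hs$training$potency))
  # ceiling rounding
  hs2 <- extract_holdout(fixture_random_records(10, 8), 0.25)
  expect_equal(nrow(hs2$holdout), 3)
})

test_that("potency ties at the holdout boundary resolve lexicographically", {
  rec <- data.frame(smiles = c("D", "B", "C", "A"), potency = 6,
                    stringsAsFactors = FALSE)
  hs <- extract_holdout(rec, 0.25)
  expect_identical(hs$holdout$smiles, "D") # lexicographically last 25%
  expect_error(extract_holdout(rec, 0.9), "fewer than 2")
})

test_that("similarity-graph clustering separates chemotypes", {
  records <- rbind(fixture_series(8),
                   data.frame(smiles = fixture_panel()[1:5], potency = 5,
                              stringsAsFactors = FALSE))
  comps <- find_sar_series(records, threshold = 0.5, min_size = 3)
  expect_gte(length(comps), 1)
  expect_setequal(comps[[1]]$smiles, fixture_series(8)$smiles)
})

test_that("split manifests serialize to JSON", {
  sp <- split_series(fixture_random_records(12, 9), "values", k = 3)
  path <- tempfile(fileext = ".json")
  write_split_manifest(sp, path)
  m <- jsonlite::read_json(path, simplifyVector = FALSE)
  expect_equal(m$strategy, "values")
  expect_length(m$subsets, 3)
})
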