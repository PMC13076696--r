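# Standardization, tokenization, vocabulary, augmentation, fingerprints and
# tabular input.

test_that("standardization strips stereochemistry and keeps the heavy-atom graph", {
  std <- standardize_smiles("C[C@H](O)c1ccccc1")
  expect_true(std$accepted)
  expect_false(grepl("[@/\\\\]", std$smiles))
  # same heavy-atom graph as the achiral spelling
  achiral <- standardize_smiles("CC(O)c1ccccc1")
  expect_identical(std$smiles, achiral$smiles)
})

test_that("salt stripping keeps the neutralized organic fragment", {
  std <- standardize_smiles("CC(=O)[O-].[Na+]")
  expect_true(std$accepted)
  expect_identical(std$smiles, standardize_smiles("CC(=O)O")$smiles)
  # no organic fragment at all
  none <- standardize_smiles("[Na+].[Cl-]")
  expect_false(none$accepted)
  expect_identical(none$reason, "empty-after-salt-strip")
})

test_that("isotopes are removed and charges on quaternary nitrogen are kept", {
  iso <- standardize_smiles("[13CH3]CO")
  expect_true(iso$accepted)
  expect_identical(iso$smiles, standardize_smiles("CCO")$smiles)
  quat <- standardize_smiles("C[N+](C)(C)C")
  expect_true(quat$accepted)
  expect_true(grepl("N\\+", quat$smiles))
})

test_that("molecules above the weight gate are rejected as overweight", {
  heavy <- paste(rep("C", 72), collapse = "") # ~1012 Da
  std <- standardize_smiles(heavy)
  expect_false(std$accepted)
  expect_identical(std$reason, "overweight")
  light <- paste(rep("C", 71), collapse = "") # ~998 Da
  expect_true(standardize_smiles(light)$accepted)
  # the gates default to the curation rules: 1000 Da and 140 tokens
  expect_equal(formals(standardize_smiles)$max_mw, 1000)
  expect_equal(formals(standardize_smiles)$max_tokens, 140)
})

test_that("token-count gate rejects overlong sequences at a strict boundary", {
  s <- "CCCCCCCCCCC" # 11 tokens
  expect_true(standardize_smiles(s, max_tokens = 11)$accepted)
  over <- standardize_smiles(s, max_tokens = 10)
  expect_false(over$accepted)
  expect_identical(over$reason, "overlong")
})

test_that("unparsable input is a rejection, never an exception", {
  bad <- standardize_smiles(c("C(((", "", NA, "xyz", "C1CC"))
  expect_false(any(bad$accepted))
  expect_true(all(bad$reason == "unparsable"))
})

test_that("standardization is idempotent", {
  std <- standardize_smiles(fixture_panel())
  expect_true(all(std$accepted))
  again <- standardize_smiles(std$smiles)
  expect_identical(again$smiles, std$smiles)
})

test_that("tokenization treats two-letter halogens and bracket atoms as single tokens", {
  expect_identical(tokenize_smiles("Clc1ccccc1"),
                   c("Cl", "c", "1", "c", "c", "c", "c", "c", "1"))
  expect_identical(tokenize_smiles("C"), "C")
  expect_identical(tokenize_smiles("[nH]"), "[nH]")
  expect_length(tokenize_smiles("BrCC[N+](C)(C)C"), 11)
  expect_error(tokenize_smiles(""), "non-empty")
})

test_that("tokenize / untokenize round-trips standardized SMILES", {
  for (s in fixture_panel()) {
    expect_identical(untokenize_smiles(tokenize_smiles(s)), s)
  }
})

test_that("vocabulary is the sorted token union plus three distinct sentinels", {
  v <- build_vocabulary(c("CC", "CO"))
  expect_length(v$tokens, 5)
  expect_setequal(v$tokens, c("<pad>", "<s>", "</s>", "C", "O"))
  expect_identical(unname(v$index[v$tokens]), 0:4)
  # duplicates in the corpus change nothing
  v2 <- build_vocabulary(c("CC", "CO", "CC", "CO", "CC"))
  expect_identical(v, v2)
  # segmentation: Cl is one token, never an l
  v3 <- build_vocabulary("ClC")
  expect_true("Cl" %in% v3$tokens)
  expect_false("l" %in% v3$tokens)
  expect_error(build_vocabulary(character(0)), "empty")
})

test_that("encoding wraps with sentinels and an unknown token is a named error", {
  v <- build_vocabulary(c("CC", "CO"))
  ids <- encode_smiles("CO", v)
  expect_identical(ids[1], v$start_id)
  expect_identical(ids[length(ids)], v$end_id)
  expect_identical(decode_ids(ids, v), "CO")
  expect_error(tokenize_smiles("CN", v), "N")
})

test_that("randomized SMILES canonicalize back to their source and are seed-reproducible", {
  s <- standardize_smiles("CC(C)Oc1ccc2nc(CC(=O)O)n(CCO)c2c1")$smiles
  r1 <- randomize_smiles(s, n = 10, seed = 42)
  expect_length(r1, 10)
  expect_true(length(unique(r1)) > 1) # actual augmentation, not copies
  can <- increclm:::ob_convert_smiles(r1)
  expect_true(all(can == increclm:::ob_convert_smiles(s)))
  r2 <- randomize_smiles(s, n = 10, seed = 42)
  expect_identical(r1, r2)
  r3 <- randomize_smiles(s, n = 10, seed = 43)
  expect_false(identical(r1, r3))
})

test_that("randomizing a single-atom molecule returns the atom itself", {
  expect_identical(randomize_smiles("C", n = 3, seed = 1), rep("C", 3))
})

test_that("randomization round-trips across a structural panel, including charges", {
  panel <- c(fixture_panel(), standardize_smiles("C[N+](C)(C)CC([O-])=O")$smiles)
  for (s in panel) {
    r <- randomize_smiles(s, n = 8, seed = 11)
    expect_length(r, 8) # round-trip enforced internally; failure would error
  }
})

test_that("fingerprint similarity is reflexive, symmetric and bounded", {
  a <- "CC(C)Oc1ccccc1"
  b <- "O=C(O)Cc1nc2ccccc2n1C"
  expect_equal(fingerprint_similarity(a, a), 1.0)
  expect_equal(fingerprint_similarity(a, b), fingerprint_similarity(b, a))
  sim <- tanimoto_matrix(fixture_panel())
  expect_true(all(sim >= 0 & sim <= 1))
  expect_equal(unname(diag(sim)), rep(1, nrow(sim)))
  # structurally unrelated small molecules share no circular environments
  expect_equal(fingerprint_similarity("CCCC", "c1ccsc1"), 0)
})

test_that("activity tables convert units to -log10 molar and collapse duplicates", {
  tmp <- tempfile(fileext = ".csv")
  writeLines(c(
    "smiles,value,unit",
    "CCOC(=O)C1CCN(C)CC1,37,nM",
    "CC(=O)O,1,uM",
    "OC(=O)C,2,uM",     # same canonical molecule, weaker
    "CCO,5,bogus",      # unit failure
    "C(((,1,nM"         # unparsable
  ), tmp)
  tab <- read_activity_table(tmp, column_map = list(smiles = "smiles",
                                                    value = "value", unit = "unit"))
  expect_equal(nrow(tab), 2)
  ester <- tab[tab$smiles == standardize_smiles("CCOC(=O)C1CCN(C)CC1")$smiles, ]
  expect_equal(ester$potency, -log10(3.7e-8), tolerance = 1e-12)
  expect_equal(round(ester$potency, 2), 7.43)
  acid <- tab[tab$smiles == standardize_smiles("CC(=O)O")$smiles, ]
  expect_equal(acid$potency, 6.0, tolerance = 1e-12) # best potency kept
  rej <- attr(tab, "rejections")
  expect_setequal(rej$reason, c("unparsable-unit", "unparsable"))
  expect_error(read_activity_table(tmp, column_map = list(smiles = "nope")),
               "SMILES column")
})

test_that("molar conversion covers the standard unit ladder", {
  expect_equal(molar_value(1, "M"), 1)
  expect_equal(molar_value(c(1, 1, 1), c("mM", "nM", "pM")),
               c(1e-3, 1e-9, 1e-12))
  expect_true(is.na(molar_value(1, "furlongs")))
})

test_that("validity audit rejects malformed and valence-damaged strings", {
  v <- smiles_validity(c("CCO", "C1CC", "c1cc1", "CC(C)Oc1ccccc1",
                         "C(((", "CCO(C)C", "FC(F)(F)F", "CC)C("))
  expect_identical(as.logical(v), c(TRUE, FALSE, FALSE, TRUE,
                                    FALSE, FALSE, TRUE, FALSE))
  expect_identical(attr(v, "canonical")[1], "CCO")
})

test_that("murcko scaffolds strip substituents down to rings and linkers", {
  s <- standardize_smiles("CC(C)Oc1ccc2nc(C)n(CC)c2c1")$smiles
  scaf <- murcko_scaffold(s)
  bare <- standardize_smiles("c1ccc2[nH]cnc2c1")$smiles
  expect_identical(scaf, bare)
  expect_true(is.na(murcko_scaffold("CCO")))
  # two molecules of one chemotype share their scaffold
  s2 <- standardize_smiles("CCCOc1ccc2nc(CC)n(C)c2c1")$smiles
  expect_identical(murcko_scaffold(s2), scaf)
})

test_that("randomization agrees with an independent canonicalizer", {
  # cross-check with a second toolkit: every randomized spelling of a
  # molecule must canonicalize to one and the same structure
  s <- standardize_smiles("CC(C)Oc1ccc2nc(CC(=O)O)n(CCO)c2c1")$smiles
  forms <- randomize_smiles(s, n = 6, seed = 2)
  script <- paste(
    "from rdkit import Chem",
    "import sys",
    "for x in sys.argv[1:]:",
    "    m = Chem.MolFromSmiles(x)",
    "    print(Chem.MolToSmiles(m) if m is not None else 'INVALID')",
    sep = "\n"
  )
  out <- suppressWarnings(
    system2("python", c("-c", shQuote(script), shQuote(c(s, forms))),
            stdout = TRUE, stderr = FALSE)
  )
  expect_length(out, 7)
  expect_false(any(out == "INVALID"))
  expect_equal(length(unique(out)), 1) # all spellings are the same molecule
})
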