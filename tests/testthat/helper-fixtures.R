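# Shared fixtures, built in code at load time. Kept deliberately small; the
# heavyweight end-to-end fixtures are constructed lazily inside the tests
# that need them and cached in this environment.

.fixtures <- new.env(parent = emptyenv())

# A small panel of diverse, valid, standardized molecules.
fixture_panel <- function() {
  if (is.null(.fixtures$panel)) {
    raw <- c(
      "CCO", "CC(=O)O", "c1ccccc1", "Cc1ccccc1O", "CC(C)Oc1ccccc1",
      "O=C(O)Cc1nc2ccccc2n1C", "N#Cc1ccc(F)cc1", "CC(C)CC(=O)NCC",
      "c1ccc2[nH]ccc2c1", "CCS(=O)(=O)NCc1ccco1", "Clc1cccc(Br)c1",
      "CCOC(=O)C1CCN(C)CC1"
    )
    std <- standardize_smiles(raw)
    stopifnot(all(std$accepted))
    .fixtures$panel <- std$smiles
  }
  .fixtures$panel
}

# Tiny vocabulary + untrained model for engine contract tests.
fixture_tiny_model <- function(use_batchnorm = FALSE) {
  key <- paste0("tiny_", use_batchnorm)
  if (is.null(.fixtures[[key]])) {
    vocab <- build_vocabulary(fixture_panel())
    cfg <- clm_config(vocab, embedding_dim = 8, recurrent_layers = 16,
                      use_batchnorm = use_batchnorm, dropout = 0,
                      batch_size = 8)
    .fixtures[[key]] <- build_clm(cfg, seed = 7)
  }
  .fixtures[[key]]
}

# A synthetic analog series: one scaffold, enumerated substituents, potency
# increasing with substituent index. Members are highly similar to each
# other and dissimilar to unrelated molecules.
fixture_series <- function(n = 30) {
  subs <- c("C", "CC", "CCC", "CCCC", "CC(C)C", "CO", "CCO", "CCCO",
            "CCN", "CCCN", "COC", "CCOC", "C(C)O", "CCCC(C)C", "CCCCO",
            "CCCCN", "CCOCC", "CC(C)O", "CC(C)N", "CCC(C)O", "CCCOC",
            "CNC", "CCNC", "CCCNC", "CC(C)OC", "CCCCC", "CCCCCC",
            "CC(C)CC", "CCC(C)C", "CCCCCO")
  stopifnot(n <= length(subs))
  raw <- paste0("CC(C)Oc1ccc2nc(", subs[seq_len(n)],
                ")n(CC(=O)O)c2c1")
  std <- standardize_smiles(raw)
  stopifnot(all(std$accepted))
  data.frame(smiles = std$smiles, potency = 6 + 0.1 * seq_len(n),
             stringsAsFactors = FALSE)
}

# A small toy universe (2 positions x 4 substituents) for fast toyworld and
# pipeline tests.
fixture_small_universe <- function(noise_sd = 0.1, seed = 5) {
  toy_universe(
    template = "c1cc2nc({R1})n(C)c2cc1{R2}",
    substituents = list(R1 = c("C", "CC", "CCC", "CO"),
                        R2 = c("F", "Cl", "OC", "C")),
    contributions = list(R1 = c("C" = 0, "CC" = 0.4, "CCC" = 0.8, "CO" = 1.2),
                         R2 = c("F" = 0, "Cl" = 0.3, "OC" = 0.9, "C" = 0.1)),
    interactions = data.frame(pos_a = "R1", frag_a = "CO", pos_b = "R2",
                              frag_b = "OC", effect = 0.5,
                              stringsAsFactors = FALSE),
    baseline = 6, noise_sd = noise_sd, seed = seed
  )
}

# Random molecule-table generator for fuzzing splitters (no chemistry
# needed beyond unique smiles strings).
fixture_random_records <- function(n, seed) {
  set.seed(seed)
  data.frame(
    smiles = paste0("M", sprintf("%04d", sample(9999, n))),
    potency = round(stats::runif(n, 4, 9), 3),
    stringsAsFactors = FALSE
  )
}
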