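# A synthetic, fully enumerable chemical space: one scaffold with substituent
# positions, an additive pseudo-potency landscape with sparse pairwise
# interactions and Gaussian noise. Every pipeline stage -- curation,
# splitting, training, sampling, rediscovery -- is testable at desk scale
# against this known ground truth.

.toy_default_substituents <- list(
  R1 = c("C", "CC", "CCC", "C(C)C", "CO", "CC(=O)O"),
  R2 = c("C", "CC", "CCO", "CCC", "CC(C)C", "CCOC"),
  R3 = c("F", "Cl", "C", "OC", "OC(C)C", "C(F)(F)F")
)

# Contribution tiers overlap across positions (gaps comparable to the noise
# scale), so every potency stratum of the enumerated space -- including the
# top quartile withheld as holdout -- shares its fragments with the strata
# below it. High-potency enumerants are then reachable by recombining
# fragments a model has seen in the lower strata, which is the recombination
# task the retrospective benchmark is meant to probe.
.toy_default_contributions <- list(
  R1 = c("C" = 0, "CC" = 0.24, "CCC" = 0.36, "CO" = 0.60, "C(C)C" = 0.72,
         "CC(=O)O" = 0.78),
  R2 = c("C" = 0, "CC" = 0.12, "CCC" = 0.30, "CC(C)C" = 0.42, "CCOC" = 0.48,
         "CCO" = 0.60),
  R3 = c("F" = 0, "C" = 0.12, "Cl" = 0.30, "C(F)(F)F" = 0.42, "OC" = 0.72,
         "OC(C)C" = 0.78)
)

# A long-range substituent interaction: the acidic head group only unfolds
# its full effect together with the distal isopropyloxy substituent.
.toy_default_interactions <- data.frame(
  pos_a = "R1", frag_a = "CC(=O)O", pos_b = "R3", frag_b = "OC(C)C",
  effect = 0.42, stringsAsFactors = FALSE
)

#' Generate a synthetic chemical universe
#'
#' Enumerates a scaffold-plus-substituent SMILES space (default: a
#' benzimidazole-like two-ring scaffold with three substitution positions)
#' and attaches a deterministic pseudo-potency to every enumerant:
#' `baseline + sum(position contributions) + sum(pairwise interactions) +
#' noise`, with the Gaussian noise drawn once per enumerant from the seed.
#'
#' @param template Scaffold SMILES with `{R1}`, `{R2}`, ... placeholders.
#' @param substituents Named list (one entry per placeholder) of fragment
#'   SMILES; at least 2 positions with at least 3 fragments each.
#' @param contributions Named list of named numeric vectors: additive potency
#'   effect (log10 units) per (position, fragment).
#' @param interactions Data frame with columns pos_a, frag_a, pos_b, frag_b,
#'   effect: sparse pairwise effects creating long-range dependencies.
#' @param baseline Baseline potency (default 6, i.e. 1 uM).
#' @param noise_sd Gaussian potency noise in log10 units (default 0.15,
#'   small enough to mostly preserve the potency ordering used for
#'   splitting).
#' @param seed Integer seed fixing the noise (default 11).
#' @return A `toy_universe`: list with the generating parameters and
#'   `molecules`, a data.frame of all enumerants (`smiles` canonical,
#'   fragment choices, `potency`, `potency_additive`).
#' @export
toy_universe <- function(template = "c1cc2nc({R1})n({R2})c2cc1{R3}",
                         substituents = .toy_default_substituents,
                         contributions = .toy_default_contributions,
                         interactions = .toy_default_interactions,
                         baseline = 6, noise_sd = 0.15, seed = 11) {
  positions <- names(substituents)
  stopifnot(length(positions) >= 2,
            all(vapply(substituents, length, integer(1)) >= 3))
  grid <- expand.grid(lapply(substituents, seq_along))
  n <- nrow(grid)

  smiles_raw <- vapply(seq_len(n), function(i) {
    s <- template
    for (p in positions) {
      s <- sub(paste0("{", p, "}"), substituents[[p]][grid[i, p]], s, fixed = TRUE)
    }
    s
  }, character(1))
  std <- standardize_smiles(smiles_raw)
  if (!all(std$accepted)) {
    stop("invalid scaffold/fragment combination, e.g.: ",
         smiles_raw[which(!std$accepted)[1]])
  }
  if (anyDuplicated(std$smiles)) {
    stop("substituent sets produce duplicate enumerants")
  }

  additive <- rep(baseline, n)
  for (p in positions) {
    contr <- contributions[[p]][substituents[[p]]]
    contr[is.na(contr)] <- 0
    additive <- additive + contr[grid[, p]]
  }
  if (!is.null(interactions) && nrow(interactions)) {
    for (k in seq_len(nrow(interactions))) {
      ia <- interactions[k, ]
      hit <- substituents[[ia$pos_a]][grid[, ia$pos_a]] == ia$frag_a &
        substituents[[ia$pos_b]][grid[, ia$pos_b]] == ia$frag_b
      additive[hit] <- additive[hit] + ia$effect
    }
  }
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  noise <- if (noise_sd > 0) stats::rnorm(n, 0, noise_sd) else rep(0, n)
  if (!is.null(old)) assign(".Random.seed", old, globalenv())

  molecules <- cbind(
    data.frame(smiles = std$smiles, stringsAsFactors = FALSE),
    stats::setNames(as.data.frame(lapply(positions, function(p) {
      substituents[[p]][grid[, p]]
    }), stringsAsFactors = FALSE), positions),
    data.frame(potency_additive = additive, potency = additive + noise)
  )
  structure(
    list(template = template, substituents = substituents,
         contributions = contributions, interactions = interactions,
         baseline = baseline, noise_sd = noise_sd, seed = seed,
         molecules = molecules),
    class = "toy_universe"
  )
}

#' @export
print.toy_universe <- function(x, ...) {
  cat("<toy_universe>", nrow(x$molecules), "enumerants |",
      length(x$substituents), "positions | potency",
      round(min(x$molecules$potency), 2), "-",
      round(max(x$molecules$potency), 2), "| noise sd", x$noise_sd, "\n")
  invisible(x)
}

#' Pseudo-potency of a universe member
#'
#' @param universe A `toy_universe`.
#' @param smiles SMILES of an enumerant (canonicalized on lookup).
#' @return Potency on the -log10 molar scale.
#' @export
toy_potency <- function(universe, smiles) {
  stopifnot(inherits(universe, "toy_universe"))
  can <- ob_convert_smiles(smiles)
  idx <- match(can, universe$molecules$smiles)
  if (anyNA(idx)) {
    stop("molecule is not a member of the universe: ", smiles[which(is.na(idx))[1]])
  }
  universe$molecules$potency[idx]
}

# Template pool for the target-ignorant background corpus: assorted ring
# systems and linkers structurally remote from the universe scaffold.
# Placeholders sit in branch or chain-end positions so every fragment
# attaches through its first atom.
.toy_corpus_templates <- c(
  "c1ccc({X})cc1{Y}", "c1cc({X})ccc1{Y}", "n1ccc({X})cc1{Y}",
  "o1ccc({X})c1{Y}", "s1ccc({X})c1{Y}", "C1CCC({X})CC1{Y}",
  "O=C({X})OC{Y}", "O=C({X})NC{Y}", "c1ccc2occc2c1{X}",
  "c1ccc2[nH]ccc2c1{X}", "c1ccc2ncccc2c1{X}", "C1CCN({X})CC1{Y}"
)

.toy_corpus_fragments <- c(
  "C", "CC", "CCC", "O", "OC", "N", "NC", "F", "Cl", "Br", "C(=O)O",
  "C(=O)OC", "C(=O)N", "S(C)(=O)=O", "C#N", "CO", "CN", "OCC", "C(C)C",
  "CC(C)C", "C(F)(F)F", "OCC(C)C", "CCN", "CCO"
)

#' Assemble a toy benchmark bundle
#'
#' Samples an SAR series from the universe spanning at least `min_span` log
#' units of pseudo-potency, builds a scaffold-disjoint target-ignorant
#' pretraining corpus (enumerated from a remote template pool, then passed
#' through [filter_reference_corpus()] so no corpus molecule has Tanimoto
#' similarity above 0.4 to any series member), and records the ground truth:
#' the top-25%-potency members of the series.
#'
#' @param universe A `toy_universe`.
#' @param series_size Series size (default 60).
#' @param corpus_size Pretraining corpus size (default 2000).
#' @param min_span Minimum potency span of the series in log units (default 2).
#' @param holdout_fraction Truth fraction (default 0.25).
#' @param seed Integer seed.
#' @return A `toy_benchmark`: list with `corpus` (character SMILES),
#'   `series` (molecule table), `truth` (most potent fraction), `training`
#'   (series minus truth), `ignorance_report`, `seed`.
#' @export
build_toy_benchmark <- function(universe, series_size = 60, corpus_size = 2000,
                                min_span = 2, holdout_fraction = 0.25, seed = 11) {
  stopifnot(inherits(universe, "toy_universe"),
            series_size <= nrow(universe$molecules))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(seed)

  # potency-stratified series draw so the span requirement is met by design
  mols <- universe$molecules[order(universe$molecules$potency,
                                   universe$molecules$smiles), , drop = FALSE]
  strata <- cut(seq_len(nrow(mols)), breaks = 4, labels = FALSE)
  per <- diff(round(seq(0, series_size, length.out = 5)))
  idx <- unlist(lapply(1:4, function(q) {
    pool <- which(strata == q)
    sample(pool, min(per[q], length(pool)))
  }))
  series <- mols[sort(idx), c("smiles", "potency")]
  rownames(series) <- NULL
  if (diff(range(series$potency)) < min_span) {
    stop("universe potency landscape too narrow for the requested span")
  }

  # background corpus from remote templates
  raw <- unlist(lapply(.toy_corpus_templates, function(tpl) {
    if (grepl("{Y}", tpl, fixed = TRUE)) {
      combos <- expand.grid(x = .toy_corpus_fragments, y = .toy_corpus_fragments,
                            stringsAsFactors = FALSE)
      vapply(seq_len(nrow(combos)), function(i) {
        sub("{Y}", combos$y[i], sub("{X}", combos$x[i], tpl, fixed = TRUE),
            fixed = TRUE)
      }, character(1))
    } else {
      vapply(.toy_corpus_fragments, function(x) {
        sub("{X}", x, tpl, fixed = TRUE)
      }, character(1), USE.NAMES = FALSE)
    }
  }))
  raw <- sample(raw, min(length(raw), ceiling(corpus_size * 1.6)))
  std <- standardize_smiles(raw)
  corpus <- unique(std$smiles[std$accepted])
  corpus <- setdiff(corpus, universe$molecules$smiles)
  filt <- filter_reference_corpus(corpus, series$smiles, sim_threshold = 0.4,
                                  radius = 2)
  corpus <- filt$corpus
  if (length(corpus) < corpus_size) {
    stop("template pool too small for a corpus of ", corpus_size)
  }
  corpus <- sort(sample(corpus, corpus_size))

  hs <- extract_holdout(series, fraction = holdout_fraction)
  structure(
    list(corpus = corpus, series = series, truth = hs$holdout,
         training = hs$training, ignorance_report = filt$report,
         universe = universe, seed = seed),
    class = "toy_benchmark"
  )
}

#' @export
print.toy_benchmark <- function(x, ...) {
  cat("<toy_benchmark> corpus", length(x$corpus), "| series", nrow(x$series),
      "| truth", nrow(x$truth), "| potency span",
      round(diff(range(x$series$potency)), 2), "log units\n")
  invisible(x)
}

#' Write a toy benchmark bundle to disk
#'
#' Emits `pretrain.smi`, `series.csv`, `holdout.smi` and `truth.json` into a
#' directory.
#'
#' @param bench A `toy_benchmark`. @param dir Output directory.
#' @return Invisibly, the directory.
#' @export
write_toy_benchmark <- function(bench, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeLines(bench$corpus, file.path(dir, "pretrain.smi"))
  utils::write.csv(bench$series, file.path(dir, "series.csv"), row.names = FALSE)
  writeLines(bench$truth$smiles, file.path(dir, "holdout.smi"))
  jsonlite::write_json(
    list(truth = bench$truth$smiles, potency = bench$truth$potency,
         seed = bench$seed),
    file.path(dir, "truth.json"), auto_unbox = TRUE, pretty = TRUE
  )
  invisible(dir)
}
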