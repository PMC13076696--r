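# Design generation: multinomial temperature sampling, sequence perplexity,
# perplexity ranking, and the prospective design-filtering cascade.

#' Temperature softmax over logits
#'
#' `q_i = exp(z_i / T) / sum_j exp(z_j / T)`. Probabilities are strictly
#' positive and sum to one.
#'
#' @param z Numeric vector of logits.
#' @param temperature Positive temperature T.
#' @return Probability vector.
#' @export
softmax_temperature <- function(z, temperature = 1.0) {
  stopifnot(temperature > 0, length(z) >= 1)
  z <- z / temperature
  z <- z - max(z)
  e <- exp(z)
  e / sum(e)
}

#' Sample designs from a model
#'
#' Generates strings token by token by multinomial draws from the
#' temperature softmax until the end sentinel or the length cap. Strings that
#' hit the cap without terminating are treated as invalid (truncated
#' molecules are not trustworthy). Valid strings are standardized to
#' canonical SMILES and aggregated into per-design sampling frequencies;
#' invalid emissions are counted. Identity is canonical-SMILES equality.
#'
#' @param model A trained `clm_model`.
#' @param n Number of strings to sample.
#' @param temperature Sampling temperature (default 1.0).
#' @param max_len Token cap per string (default 140).
#' @param seed Optional integer seed.
#' @return A `design_set`: list with `samples` (data.frame: smiles, frequency),
#'   `n_requested`, `n_valid`, `n_invalid`, `temperature`, `raw` (all emitted
#'   strings), `provenance`.
#' @export
sample_designs <- function(model, n, temperature = 1.0, max_len = 140, seed = NULL) {
  stopifnot(inherits(model, "clm_model"), n >= 1)
  if (!is.null(seed)) set.seed(seed)
  vocab <- model$config$vocab
  ids <- cpp_sample(model$theta, model$bn_run, unclass(model$config),
                    as.integer(n), as.integer(max_len), temperature)
  raw <- character(n)
  terminated <- logical(n)
  for (i in seq_len(n)) {
    row <- ids[i, ]
    endpos <- which(row == vocab$end_id)
    if (length(endpos)) {
      terminated[i] <- TRUE
      row <- row[seq_len(endpos[1] - 1)]
    } else {
      row <- row[row != 0L]
    }
    raw[i] <- paste(vocab$tokens[row + 1L], collapse = "")
  }
  val <- rep(FALSE, n)
  canonical <- rep(NA_character_, n)
  if (any(terminated & nzchar(raw))) {
    idx <- which(terminated & nzchar(raw))
    v <- smiles_validity(raw[idx])
    val[idx] <- as.logical(v)
    canonical[idx] <- attr(v, "canonical")
  }
  tab <- table(canonical[val])
  # exemplar: first emitted spelling of each canonical molecule (used to
  # score designs whose canonical form uses tokens outside the vocabulary)
  first_idx <- which(val)[!duplicated(canonical[val])]
  exemplar <- stats::setNames(raw[first_idx], canonical[first_idx])
  samples <- data.frame(
    smiles = names(tab),
    frequency = as.integer(tab),
    exemplar = unname(exemplar[names(tab)]),
    stringsAsFactors = FALSE
  )
  samples <- samples[order(-samples$frequency, samples$smiles), , drop = FALSE]
  rownames(samples) <- NULL
  structure(
    list(samples = samples, n_requested = n, n_valid = sum(val),
         n_invalid = n - sum(val), temperature = temperature,
         raw = raw, raw_valid = val, raw_canonical = canonical,
         provenance = list(epoch = model$epoch, seed = seed)),
    class = "design_set"
  )
}

#' @export
print.design_set <- function(x, ...) {
  cat("<design_set>", x$n_requested, "sampled |", x$n_valid, "valid |",
      nrow(x$samples), "unique molecules\n")
  if (!is.null(x$samples$ppl)) cat("  ranked by perplexity\n")
  invisible(x)
}

#' Perplexity from realized token probabilities
#'
#' `PPL = exp(-(1/N) sum log q_i)` with N the number of scored tokens.
#' Equals 1 exactly when every realized token has probability 1, and equals
#' V for any sequence under a uniform model over V tokens.
#'
#' @param probs Numeric vector of realized token probabilities in (0, 1].
#' @return Perplexity value (>= 1).
#' @export
perplexity_from_probs <- function(probs) {
  stopifnot(length(probs) >= 1, all(probs > 0), all(probs <= 1))
  exp(-mean(log(probs)))
}

#' Perplexity of a SMILES under a model
#'
#' `PPL = exp(-(1/N) sum log q_i)` over the realized token probabilities at
#' temperature 1, where the scored tokens are the chemical tokens plus the
#' end sentinel (the start sentinel conditions the first prediction and is
#' not scored), and N is the number of scored tokens. With `n_augment > 1`
#' the arithmetic mean of the perplexities of randomized spellings is
#' returned (used for the augmented/randomized training variants).
#'
#' @param model A `clm_model`.
#' @param smiles Character vector of SMILES (must tokenize under the model's
#'   vocabulary; an unknown token is an error).
#' @param n_augment Number of randomized spellings to average over (1 =
#'   canonical form only).
#' @return Numeric vector of perplexities (>= 1 up to numerical tolerance).
#' @export
sequence_perplexity <- function(model, smiles, n_augment = 1) {
  stopifnot(inherits(model, "clm_model"))
  vocab <- model$config$vocab
  clist <- unclass(model$config)
  ppl_of <- function(batch) {
    enc <- encode_batch(batch, vocab)
    lp <- cpp_token_logprobs(model$theta, model$bn_run, clist, enc$ids, enc$lengths)
    exp(-rowMeans(lp, na.rm = TRUE))
  }
  if (n_augment <= 1) {
    return(ppl_of(smiles))
  }
  gs <- parse_mol_graphs(smiles)
  vapply(seq_along(smiles), function(i) {
    forms <- vapply(seq_len(n_augment), function(k) {
      .random_dfs_smiles(gs[[i]])
    }, character(1))
    # a rare spelling may need a ring-closure digit outside the vocabulary;
    # average over the spellings the model can read
    ok <- vapply(forms, function(f) {
      !inherits(tryCatch(tokenize_smiles(f, vocab), error = identity), "error")
    }, logical(1))
    if (!any(ok)) return(ppl_of(smiles[i]))
    mean(ppl_of(forms[ok]))
  }, numeric(1), USE.NAMES = FALSE)
}

#' Rank sampled designs by perplexity
#'
#' Removes invalid strings (already absent from the design table), designs
#' present in the fine-tuning set, and ranks the rest by ascending perplexity
#' (lower = more probable design). Ties break by higher sampling frequency,
#' then lexicographic SMILES. The augmented/randomized variants score each
#' design as the mean perplexity over `n_augment` randomized spellings.
#'
#' @param designs A `design_set` from [sample_designs()].
#' @param model The model to score under (usually the one that sampled).
#' @param variant Training variant of the model; `augmented`/`randomized`
#'   trigger augmentation-averaged perplexity.
#' @param finetune_set Character vector of fine-tuning SMILES to exclude.
#' @param n_augment Spellings averaged for augmented/randomized (default 10).
#' @return The `design_set` with `samples` gaining `ppl` and `rank` columns.
#' @export
rank_designs <- function(designs, model, variant = "canonical",
                         finetune_set = character(0), n_augment = 10) {
  stopifnot(inherits(designs, "design_set"))
  if (is.data.frame(finetune_set)) finetune_set <- finetune_set$smiles
  s <- designs$samples
  s <- s[!s$smiles %in% finetune_set, , drop = FALSE]
  if (!nrow(s)) {
    warning("no designs left after filtering")
    designs$samples <- cbind(s, ppl = numeric(0), rank = integer(0))
    return(designs)
  }
  aug <- if (variant %in% c("augmented", "randomized")) n_augment else 1
  vocab <- model$config$vocab
  tokenizable <- vapply(s$smiles, function(x) {
    !inherits(tryCatch(tokenize_smiles(x, vocab), error = identity), "error")
  }, logical(1), USE.NAMES = FALSE)
  s$ppl <- NA_real_
  if (any(tokenizable)) {
    s$ppl[tokenizable] <- sequence_perplexity(model, s$smiles[tokenizable],
                                              n_augment = aug)
  }
  if (any(!tokenizable) && !is.null(s$exemplar)) {
    # canonical spelling uses tokens the model has never seen; score the
    # emitted spelling instead
    s$ppl[!tokenizable] <- sequence_perplexity(model, s$exemplar[!tokenizable])
  }
  s <- s[!is.na(s$ppl), , drop = FALSE]
  ord <- order(s$ppl, -s$frequency, s$smiles)
  s <- s[ord, , drop = FALSE]
  s$rank <- seq_len(nrow(s))
  rownames(s) <- NULL
  designs$samples <- s
  designs
}

#' Filter configuration for the prospective design cascade
#'
#' @param min_naive_perplexity Designs whose perplexity under the naive
#'   (pretrained) model falls below this floor are discarded as pretraining
#'   artifacts. Default 1.012 (corpus-specific; expose per application).
#' @param known_sets List of character vectors of known molecules to exclude.
#' @param baseline_top SMILES found among the top-ranking designs of a
#'   classically fine-tuned (all-data) baseline model, to exclude.
#' @param remove_substructures_isomers Drop designs that are substructures or
#'   constitutional isomers (same molecular formula) of training molecules.
#' @param max_similarity Tanimoto cap against the training series (0.8 or 0.6
#'   depending on the application); NA disables.
#' @param similarity_radius Fingerprint radius for the cap (default 3).
#' @param substructure_blacklist SMARTS patterns that disqualify a design
#'   (e.g. "C1=CCC=CC1" for 1,3-cyclohexadiene).
#' @param max_ring_size Designs with any ring larger than this are removed;
#'   NA disables. Default NA (set 7 to reproduce the ring rule).
#' @param priority_pattern Optional SMARTS; matching designs are stably
#'   moved ahead of non-matching ones (e.g. sulfonamides "S(=O)(=O)N").
#' @return A `filter_config` list.
#' @export
filter_config <- function(min_naive_perplexity = 1.012, known_sets = list(),
                          baseline_top = character(0),
                          remove_substructures_isomers = FALSE,
                          max_similarity = NA, similarity_radius = 3,
                          substructure_blacklist = character(0),
                          max_ring_size = NA, priority_pattern = NULL) {
  stopifnot(is.na(max_similarity) || (max_similarity >= 0 && max_similarity <= 1))
  structure(list(
    min_naive_perplexity = min_naive_perplexity, known_sets = known_sets,
    baseline_top = baseline_top,
    remove_substructures_isomers = remove_substructures_isomers,
    max_similarity = max_similarity, similarity_radius = similarity_radius,
    substructure_blacklist = substructure_blacklist,
    max_ring_size = max_ring_size, priority_pattern = priority_pattern
  ), class = "filter_config")
}

#' Apply the prospective design-filtering cascade
#'
#' Rules apply in a fixed order, and every removal is attributed to exactly
#' one rule in the returned log: (1) naive-model perplexity below the floor;
#' (2) membership in known-molecule sets; (3) membership in the baseline
#' model's top designs; (4) substructure or isomer of a training molecule;
#' (5) Tanimoto similarity to training above the cap; (6) blacklisted
#' substructure or oversized ring; (7) optional stable prioritization of a
#' substructure pattern.
#'
#' @param ranked A ranked `design_set`.
#' @param naive The pretrained (naive) `clm_model` for the perplexity floor.
#' @param cfg A [filter_config()].
#' @param training Character vector (or molecule table) of fine-tuning
#'   molecules for rules 4-5.
#' @return The `design_set` with filtered `samples` (ranks reassigned) and a
#'   `removals` data.frame (smiles, rule).
#' @export
filter_designs <- function(ranked, naive, cfg = filter_config(),
                           training = character(0)) {
  stopifnot(inherits(ranked, "design_set"), inherits(cfg, "filter_config"))
  if (is.data.frame(training)) training <- training$smiles
  s <- ranked$samples
  removals <- data.frame(smiles = character(0), rule = character(0),
                         stringsAsFactors = FALSE)
  drop_rule <- function(mask, rule) {
    if (any(mask)) {
      removals <<- rbind(removals, data.frame(smiles = s$smiles[mask], rule = rule,
                                              stringsAsFactors = FALSE))
      s <<- s[!mask, , drop = FALSE]
    }
  }

  if (nrow(s) && !is.null(naive) && !is.na(cfg$min_naive_perplexity)) {
    vocab <- naive$config$vocab
    naive_ppl <- vapply(seq_len(nrow(s)), function(i) {
      x <- s$smiles[i]
      if (inherits(tryCatch(tokenize_smiles(x, vocab), error = identity), "error")) {
        if (is.null(s$exemplar)) return(Inf)
        x <- s$exemplar[i]
      }
      sequence_perplexity(naive, x)
    }, numeric(1))
    drop_rule(naive_ppl < cfg$min_naive_perplexity, "naive-perplexity-floor")
  }
  if (nrow(s) && length(cfg$known_sets)) {
    known <- unique(unlist(cfg$known_sets))
    drop_rule(s$smiles %in% known, "known-molecule")
  }
  if (nrow(s) && length(cfg$baseline_top)) {
    drop_rule(s$smiles %in% cfg$baseline_top, "baseline-top")
  }
  if (nrow(s) && cfg$remove_substructures_isomers && length(training)) {
    formulas_train <- ob_props(training)$formula
    formulas_design <- ob_props(s$smiles)$formula
    isomer <- formulas_design %in% formulas_train
    substruct <- vapply(seq_len(nrow(s)), function(i) {
      if (isomer[i]) return(FALSE) # already removed by the isomer arm
      hits <- tryCatch(ob_smarts_count(training, s$smiles[i]),
                       error = function(e) integer(length(training)))
      any(hits > 0)
    }, logical(1))
    drop_rule(isomer | substruct, "training-substructure-or-isomer")
  }
  if (nrow(s) && !is.na(cfg$max_similarity) && length(training)) {
    fp_d <- morgan_fp(s$smiles, radius = cfg$similarity_radius)
    fp_t <- morgan_fp(training, radius = cfg$similarity_radius)
    drop_rule(.max_sim_to_set(fp_d, fp_t) > cfg$max_similarity, "training-similarity")
  }
  if (nrow(s) && length(cfg$substructure_blacklist)) {
    bad <- rep(FALSE, nrow(s))
    for (pat in cfg$substructure_blacklist) {
      bad <- bad | ob_smarts_count(s$smiles, pat) > 0
    }
    drop_rule(bad, "substructure-blacklist")
  }
  if (nrow(s) && !is.na(cfg$max_ring_size)) {
    oversized <- vapply(s$smiles, function(x) {
      any(ring_sizes(x) > cfg$max_ring_size)
    }, logical(1), USE.NAMES = FALSE)
    drop_rule(oversized, "ring-size")
  }
  if (nrow(s) && !is.null(cfg$priority_pattern)) {
    hit <- ob_smarts_count(s$smiles, cfg$priority_pattern) > 0
    s <- rbind(s[hit, , drop = FALSE], s[!hit, , drop = FALSE])
  }
  if (nrow(s)) {
    s$rank <- seq_len(nrow(s))
    rownames(s) <- NULL
  }
  ranked$samples <- s
  ranked$removals <- removals
  ranked
}
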