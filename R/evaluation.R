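# Evaluation: rediscovery scoring against the withheld high-potency holdout,
# sampling statistics, distributional similarity over a descriptor panel, the
# potency-perplexity regression, and the retrospective benchmark harness.

#' Rediscovery score
#'
#' Quantifies how well ranked designs recover a withheld high-potency
#' holdout. With `N_R` rediscovered holdout molecules among the `top_k`
#' ranked designs, `sum F_R` their summed sampling frequencies, `sum F_top`
#' the summed frequencies of all top-k designs and `N_hold` the holdout
#' size, the score is the product of three factors:
#' `(N_R / top_k) * (sum F_R / sum F_top) * (N_R / N_hold)`,
#' lying in \[0, 1\] and equal to zero exactly when nothing is rediscovered.
#' The product form compensates extremes (all holdouts at low frequency vs a
#' single holdout at high frequency).
#'
#' @param ranked A ranked `design_set` (or its `samples` data.frame with
#'   `smiles`, `frequency`, `rank`).
#' @param holdout Character vector (or molecule table) of holdout SMILES.
#' @param top_k Number of top designs considered (default 30). When fewer
#'   designs exist, all are used but the denominator stays `top_k`.
#' @return A `rediscovery_result`: list with `n_rediscovered`,
#'   `freq_rediscovered`, `freq_top`, `n_holdout`, `top_k`, `score`.
#' @export
rediscovery_score <- function(ranked, holdout, top_k = 30) {
  s <- if (inherits(ranked, "design_set")) ranked$samples else ranked
  if (is.data.frame(holdout)) holdout <- holdout$smiles
  holdout <- unique(holdout)
  if (!length(holdout)) stop("empty holdout")
  if (!is.null(s$rank)) s <- s[order(s$rank), , drop = FALSE]
  top <- utils::head(s, top_k)
  hit <- top$smiles %in% holdout
  n_r <- sum(hit)
  f_r <- sum(top$frequency[hit])
  f_top <- sum(top$frequency)
  score <- if (n_r == 0 || f_top == 0) 0 else
    (n_r / top_k) * (f_r / f_top) * (n_r / length(holdout))
  structure(
    list(n_rediscovered = n_r, freq_rediscovered = f_r, freq_top = f_top,
         n_holdout = length(holdout), top_k = top_k, score = score),
    class = "rediscovery_result"
  )
}

#' @export
print.rediscovery_result <- function(x, ...) {
  cat(sprintf("<rediscovery> N_R=%d/%d holdout=%d  freq %d/%d  score %.5f\n",
              x$n_rediscovered, x$top_k, x$n_holdout, x$freq_rediscovered,
              x$freq_top, x$score))
  invisible(x)
}

#' Sampling statistics: validity, uniqueness, novelty
#'
#' Validity is the fraction of emitted strings that parse to molecules;
#' uniqueness the fraction of distinct canonical SMILES among the valid
#' ones; novelty the fraction of the unique molecules absent from the
#' supplied training set.
#'
#' @param designs A `design_set`, or a character vector of raw emitted
#'   strings.
#' @param training Character vector (or molecule table) of training SMILES
#'   (canonical); which corpus counts as "training" is the caller's choice.
#' @return List with `validity`, `uniqueness`, `novelty` (each in \[0, 1\]).
#' @export
sampling_statistics <- function(designs, training = character(0)) {
  if (is.data.frame(training)) training <- training$smiles
  if (inherits(designs, "design_set")) {
    n_total <- designs$n_requested
    valid <- designs$raw_valid
    canonical <- designs$raw_canonical[valid]
  } else {
    if (!length(designs)) stop("no emitted strings")
    n_total <- length(designs)
    v <- smiles_validity(designs)
    valid <- as.logical(v)
    canonical <- attr(v, "canonical")[valid]
  }
  if (n_total == 0) stop("no emitted strings")
  n_valid <- sum(valid)
  if (n_valid == 0) stop("no valid molecules among the emitted strings")
  uniq <- unique(canonical)
  list(
    validity = n_valid / n_total,
    uniqueness = length(uniq) / n_valid,
    novelty = sum(!uniq %in% training) / length(uniq)
  )
}

#' Similarity transform of a Frechet ChemNet distance
#'
#' `S_FCD = exp(-0.2 * FCD)`. The FCD itself comes from a pluggable external
#' backend; only the monotone transform to a (0, 1] similarity is provided
#' here.
#'
#' @param fcd_value Non-negative FCD value.
#' @return Similarity in (0, 1]; 1 exactly when the distance is 0.
#' @export
fcd_similarity <- function(fcd_value) {
  if (any(fcd_value < 0)) stop("FCD must be non-negative")
  exp(-0.2 * fcd_value)
}

# ---------------------------------------------------------------------------
# Descriptor panel and KL-divergence similarity
# ---------------------------------------------------------------------------

# Bertz-style graph complexity: bond-connectivity information (over classes
# of adjacent-bond pairs) plus heteroatom-distribution information.
.graph_complexity <- function(g) {
  n_atoms <- length(g$element)
  if (!nrow(g$bonds)) {
    return(0)
  }
  # connections = pairs of bonds sharing an atom, classed by the sorted
  # element triple and bond orders involved
  nb <- vector("list", n_atoms)
  for (k in seq_len(nrow(g$bonds))) {
    a <- g$bonds[k, 1]; b <- g$bonds[k, 2]; o <- g$bonds[k, 3]
    nb[[a]] <- rbind(nb[[a]], c(b, o))
    nb[[b]] <- rbind(nb[[b]], c(a, o))
  }
  classes <- character(0)
  for (a in seq_len(n_atoms)) {
    m <- nb[[a]]
    if (is.null(m) || nrow(m) < 2) next
    for (i in seq_len(nrow(m) - 1)) {
      for (j in (i + 1):nrow(m)) {
        ends <- sort(c(g$element[m[i, 1]], g$element[m[j, 1]]))
        classes <- c(classes, paste(g$element[a], ends[1], ends[2],
                                    m[i, 2] + m[j, 2]))
      }
    }
  }
  xlogx <- function(x) ifelse(x > 0, x * log2(x), 0)
  n_conn <- length(classes)
  bond_term <- if (n_conn > 0) {
    counts <- table(classes)
    2 * xlogx(n_conn) - sum(xlogx(as.numeric(counts)))
  } else 0
  elem_counts <- table(g$element)
  hetero_term <- xlogx(n_atoms) - sum(xlogx(as.numeric(elem_counts)))
  bond_term + hetero_term
}

.smarts_rotatable <- "[!$(*#*)&!D1]-!@[!$(*#*)&!D1]"

#' Physicochemical descriptor panel
#'
#' Computes, per molecule: graph complexity (Bertz-style), logP, molecular
#' weight, topological polar surface area (continuous); hydrogen-bond
#' acceptors and donors, rotatable bonds, aliphatic and aromatic ring counts
#' (discrete).
#'
#' @param smiles Character vector of valid SMILES.
#' @return Data frame, one row per molecule.
#' @export
mol_descriptors <- function(smiles) {
  p <- ob_props(smiles)
  rc <- ring_counts(smiles)
  data.frame(
    complexity = vapply(parse_mol_graphs(smiles), .graph_complexity, numeric(1)),
    logp = as.numeric(p$logP),
    mw = as.numeric(p$MW),
    tpsa = as.numeric(p$TPSA),
    hba = as.integer(p$HBA2),
    hbd = as.integer(p$HBD),
    rotatable = ob_smarts_count(smiles, .smarts_rotatable),
    aliphatic_rings = rc$aliphatic,
    aromatic_rings = rc$aromatic
  )
}

# KL divergence between two samples of a continuous variable via Gaussian
# kernel density estimation (Scott's rule) on a shared grid, with a density
# floor; falls back to the histogram path for degenerate samples.
.kl_continuous <- function(x, y, eps = 1e-10, n_grid = 512) {
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("zero-variance continuous descriptor; falling back to histogram")
    return(.kl_discrete(x, y, eps = eps))
  }
  bw <- function(v) stats::sd(v) * length(v)^(-1 / 5)
  bx <- bw(x); by <- bw(y)
  lo <- min(x, y) - 3 * max(bx, by)
  hi <- max(x, y) + 3 * max(bx, by)
  grid <- seq(lo, hi, length.out = n_grid)
  kde <- function(v, b) {
    d <- vapply(grid, function(g) mean(stats::dnorm(g, v, b)), numeric(1))
    d <- pmax(d, eps)
    d / sum(d)
  }
  px <- kde(x, bx)
  py <- kde(y, by)
  sum(px * log(px / py))
}

# KL divergence via shared 10-bin histograms (discrete descriptors).
.kl_discrete <- function(x, y, eps = 1e-10, bins = 10) {
  lo <- min(x, y); hi <- max(x, y)
  if (lo == hi) return(0)
  breaks <- seq(lo, hi, length.out = bins + 1)
  px <- pmax(graphics::hist(x, breaks = breaks, plot = FALSE)$counts / length(x), eps)
  py <- pmax(graphics::hist(y, breaks = breaks, plot = FALSE)$counts / length(y), eps)
  px <- px / sum(px); py <- py / sum(py)
  sum(px * log(px / py))
}

# Maximum Tanimoto similarity of each molecule to the other members of its
# own set (radius 2, 2048-bit).
.max_internal_similarity <- function(smiles) {
  if (length(smiles) < 2) return(rep(0, length(smiles)))
  sim <- tanimoto_matrix(smiles, radius = 2)
  diag(sim) <- -Inf
  apply(sim, 1, max)
}

#' Aggregate per-descriptor divergences into a similarity score
#'
#' `S_KL = (1/D) sum_d exp(-KL_d)`; equal to 0.5 when every divergence is
#' ln 2, and 1 when every divergence is 0.
#'
#' @param kl Numeric vector of per-descriptor KL divergences (>= 0).
#' @return Similarity in (0, 1].
#' @export
kl_aggregate <- function(kl) {
  stopifnot(length(kl) >= 1, all(kl >= 0))
  mean(exp(-kl))
}

#' Distributional similarity over the descriptor panel
#'
#' Compares generated and reference molecule sets descriptor by descriptor:
#' Kullback-Leibler divergence KL(generated || reference) from Gaussian KDE
#' for continuous descriptors and 10-bin histograms for discrete ones, over
#' the panel of [mol_descriptors()] plus the maximum internal Tanimoto
#' similarity of each set. Aggregated as `S_KL = (1/D) * sum_d exp(-KL_d)`.
#'
#' @param generated,reference Character vectors of valid SMILES.
#' @return List with `s_kl`, `kl` (named per-descriptor divergences), and
#'   `descriptors` (names).
#' @export
kl_similarity <- function(generated, reference) {
  stopifnot(length(generated) >= 2, length(reference) >= 2)
  dg <- mol_descriptors(generated)
  dr <- mol_descriptors(reference)
  continuous <- c("complexity", "logp", "mw", "tpsa")
  discrete <- c("hba", "hbd", "rotatable", "aliphatic_rings", "aromatic_rings")
  kl <- c(
    vapply(continuous, function(d) .kl_continuous(dg[[d]], dr[[d]]), numeric(1)),
    vapply(discrete, function(d) .kl_discrete(dg[[d]], dr[[d]]), numeric(1)),
    max_internal_sim = .kl_continuous(.max_internal_similarity(generated),
                                      .max_internal_similarity(reference))
  )
  list(s_kl = kl_aggregate(kl), kl = kl, descriptors = names(kl))
}

#' Log-linear potency-perplexity regression
#'
#' Ordinary least squares of potency (-log10 molar activity) on the mean
#' design perplexity, reporting the slope, the two-sided t-test p-value of
#' the slope, and R squared. A negative slope means lower (better) perplexity
#' associates with higher potency.
#'
#' @param potency Numeric potencies.
#' @param perplexity Mean perplexity per molecule (over repeats).
#' @return List with `slope`, `p_value`, `r_squared`, `degenerate` (TRUE when
#'   the perplexities are constant and the slope is undefined).
#' @export
potency_perplexity_correlation <- function(potency, perplexity) {
  stopifnot(length(potency) == length(perplexity), length(potency) >= 3)
  if (stats::sd(perplexity) == 0) {
    warning("constant perplexity: slope undefined")
    return(list(slope = 0, p_value = 1, r_squared = 0, degenerate = TRUE))
  }
  fit <- stats::lm(potency ~ perplexity)
  sm <- summary(fit)
  list(slope = unname(stats::coef(fit)[2]),
       p_value = unname(sm$coefficients[2, 4]),
       r_squared = unname(sm$r.squared),
       degenerate = FALSE)
}

#' Retrospective benchmark over splitting strategies
#'
#' For each strategy: withholds the most potent fraction of the series,
#' splits the remainder, incrementally fine-tunes the naive model, samples,
#' applies the naive-perplexity floor, ranks by perplexity (excluding the
#' fine-tuning molecules), and computes the rediscovery score -- repeated
#' over independently seeded fine-tuning runs.
#'
#' @param naive A pretrained `clm_model`.
#' @param series Molecule table with `smiles` and `potency`.
#' @param strategies Character vector of split strategies.
#' @param k Split steps. @param holdout_fraction Withheld fraction.
#' @param n_samples Strings sampled per scoring run (default 2048).
#' @param repeats Fine-tuning repeats per strategy (default 5).
#' @param sampling_repeats Sampling/scoring runs per fine-tuned model
#'   (default 5).
#' @param epochs Epochs per fine-tuning stage.
#' @param variant Training variant.
#' @param initial_lr Learning rate entering the first stage.
#' @param top_k Designs scored (default 30).
#' @param min_naive_perplexity Naive-perplexity floor (NA disables).
#' @param temperature,max_len Sampling controls.
#' @param trace_holdout Record per-epoch holdout perplexity traces.
#' @param seed Base seed; run r of strategy s uses `seed + 97 * s + r`.
#' @param ... Passed to [train_stage()].
#' @return List with `scores` (data.frame: strategy, run, score, components)
#'   and `traces` (holdout-perplexity traces per run).
#' @export
run_retrospective_benchmark <- function(naive, series,
                                        strategies = c("all", "values"),
                                        k = 4, holdout_fraction = 0.25,
                                        n_samples = 2048, repeats = 5,
                                        sampling_repeats = 5,
                                        epochs = 100, variant = "canonical",
                                        initial_lr = 1e-4, top_k = 30,
                                        min_naive_perplexity = 1.012,
                                        temperature = 1.0, max_len = 140,
                                        trace_holdout = TRUE, seed = 1, ...) {
  hs <- extract_holdout(series, fraction = holdout_fraction)
  training <- if (inherits(hs$training, "sar_series")) hs$training$records else hs$training
  holdout <- hs$holdout$smiles
  scores <- NULL
  traces <- list()
  for (si in seq_along(strategies)) {
    strategy <- strategies[si]
    for (r in seq_len(repeats)) {
      run_seed <- seed + 97L * si + r
      split <- split_series(training, strategy = strategy, k = k, seed = run_seed)
      ft <- incremental_finetune(naive, split, variant = variant, epochs = epochs,
                                 initial_lr = initial_lr,
                                 holdout = if (trace_holdout) holdout else NULL,
                                 seed = run_seed, ...)
      for (sr in seq_len(sampling_repeats)) {
        ds <- sample_designs(ft$model, n = n_samples, temperature = temperature,
                             max_len = max_len,
                             seed = run_seed + 7919L * sr)
        ranked <- rank_designs(ds, ft$model, variant = variant,
                               finetune_set = training$smiles)
        if (!is.na(min_naive_perplexity) && nrow(ranked$samples)) {
          ranked <- filter_designs(ranked, naive,
                                   filter_config(min_naive_perplexity = min_naive_perplexity),
                                   training = character(0))
        }
        rs <- rediscovery_score(ranked, holdout, top_k = top_k)
        scores <- rbind(scores, data.frame(
          strategy = strategy, run = r, sampling_run = sr, score = rs$score,
          n_rediscovered = rs$n_rediscovered,
          freq_rediscovered = rs$freq_rediscovered, freq_top = rs$freq_top,
          n_holdout = rs$n_holdout, stringsAsFactors = FALSE
        ))
      }
      traces[[paste(strategy, r, sep = "_")]] <- ft$holdout_trace
    }
  }
  list(scores = scores, traces = traces, holdout = holdout, training = training)
}
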