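# Reference-corpus filtering, SAR-series curation, potency-ordered splitting
# and holdout extraction. A "series" is a set of structurally related
# molecules (one chemotype) with potencies on the -log10 molar scale; all
# ordering is the stable sort on (potency, canonical SMILES).

.order_by_potency <- function(records) {
  records[order(records$potency, records$smiles), , drop = FALSE]
}

#' Filter a reference corpus to be ignorant of a target
#'
#' Removes (i) every corpus molecule carrying an annotation on the target
#' family and (ii) every molecule whose maximum Tanimoto similarity to any
#' target ligand exceeds `sim_threshold` (strictly). The result is a corpus
#' from which knowledge of the target has been eliminated, suitable for
#' pretraining a target-ignorant model.
#'
#' @param corpus Molecule table (data.frame with `smiles`, optionally
#'   `target`) or character vector of SMILES.
#' @param target_ligands Character vector (or molecule table) of known target
#'   ligands.
#' @param sim_threshold Similarity cutoff, default 0.4; a molecule at exactly
#'   the threshold is retained.
#' @param radius Fingerprint radius, default 2.
#' @param annotated_targets Optional character vector of target names; corpus
#'   rows whose `target` matches any of them are removed by the annotation
#'   rule.
#' @return List with `corpus` (filtered, same type as input) and `report`
#'   (removal counts per rule).
#' @export
filter_reference_corpus <- function(corpus, target_ligands, sim_threshold = 0.4,
                                    radius = 2, annotated_targets = NULL) {
  as_df <- is.data.frame(corpus)
  smiles <- if (as_df) corpus$smiles else corpus
  if (is.data.frame(target_ligands)) target_ligands <- target_ligands$smiles
  if (!length(target_ligands)) {
    warning("no target ligands supplied; corpus returned unchanged")
    return(list(corpus = corpus,
                report = data.frame(rule = c("annotation", "similarity"),
                                    removed = c(0L, 0L))))
  }
  by_annotation <- rep(FALSE, length(smiles))
  if (as_df && !is.null(annotated_targets) && "target" %in% names(corpus)) {
    by_annotation <- !is.na(corpus$target) & corpus$target %in% annotated_targets
  }
  fp_c <- morgan_fp(smiles, radius = radius)
  fp_t <- morgan_fp(unique(target_ligands), radius = radius)
  max_sim <- .max_sim_to_set(fp_c, fp_t)
  by_similarity <- !by_annotation & max_sim > sim_threshold
  keep <- !(by_annotation | by_similarity)
  list(
    corpus = if (as_df) corpus[keep, , drop = FALSE] else smiles[keep],
    report = data.frame(rule = c("annotation", "similarity"),
                        removed = c(sum(by_annotation), sum(by_similarity)))
  )
}

#' Curate a candidate SAR series
#'
#' First iteratively drops members whose mean Tanimoto similarity to the
#' remaining members falls below `outlier_sim` (until stable), then rejects
#' the series when fewer than `min_size` members remain or the mean internal
#' pairwise similarity is below `min_mean_sim`.
#'
#' @param candidate Molecule table with `smiles` and `potency` columns.
#' @param id Series label.
#' @param min_size Minimum curated size (default 25).
#' @param min_mean_sim Minimum mean internal pairwise similarity (default 0.3).
#' @param outlier_sim Single-molecule outlier threshold (default 0.5).
#' @param radius Fingerprint radius (default 3).
#' @return A `sar_series` on success, otherwise a `series_rejection` with a
#'   `reason` (`too-few-candidates`, `too-small`, or `too-diverse`) and the
#'   dropped outliers.
#' @export
curate_series <- function(candidate, id = "series", min_size = 25,
                          min_mean_sim = 0.3, outlier_sim = 0.5, radius = 3) {
  if (!is.data.frame(candidate)) {
    candidate <- data.frame(smiles = candidate, potency = NA_real_,
                            stringsAsFactors = FALSE)
  }
  if (nrow(candidate) < 2) {
    return(structure(list(reason = "too-few-candidates", dropped = character(0)),
                     class = "series_rejection"))
  }
  fp <- morgan_fp(candidate$smiles, radius = radius)
  sim <- .tanimoto_cross(fp, fp)
  active <- rep(TRUE, nrow(candidate))
  dropped <- character(0)
  repeat {
    idx <- which(active)
    if (length(idx) < 2) break
    mean_to_rest <- vapply(idx, function(i) {
      others <- setdiff(idx, i)
      mean(sim[i, others])
    }, numeric(1))
    worst <- which.min(mean_to_rest)
    if (mean_to_rest[worst] < outlier_sim) {
      active[idx[worst]] <- FALSE
      dropped <- c(dropped, candidate$smiles[idx[worst]])
    } else {
      break
    }
  }
  records <- candidate[active, , drop = FALSE]
  if (nrow(records) < min_size) {
    return(structure(list(reason = "too-small", dropped = dropped,
                          size = nrow(records)),
                     class = "series_rejection"))
  }
  idx <- which(active)
  mean_sim <- mean(sim[idx, idx][upper.tri(diag(length(idx)))])
  if (mean_sim < min_mean_sim) {
    return(structure(list(reason = "too-diverse", dropped = dropped,
                          mean_internal_similarity = mean_sim),
                     class = "series_rejection"))
  }
  records <- .order_by_potency(records)
  rownames(records) <- NULL
  structure(
    list(id = id, records = records,
         mean_internal_similarity = mean_sim,
         potency_span = if (all(is.na(records$potency))) NA_real_ else
           diff(range(records$potency, na.rm = TRUE)),
         dropped = dropped),
    class = "sar_series"
  )
}

#' @export
print.sar_series <- function(x, ...) {
  cat("<sar_series>", x$id, "|", nrow(x$records), "molecules | mean sim",
      round(x$mean_internal_similarity, 3), "| potency span",
      round(x$potency_span, 2), "log units\n")
  invisible(x)
}

#' Discover SAR series by similarity-graph clustering
#'
#' Builds a molecular similarity graph (edge when Tanimoto >= `threshold`)
#' and returns its connected components as candidate series.
#'
#' @param records Molecule table with `smiles` (and usually `potency`).
#' @param threshold Edge threshold (default 0.5).
#' @param radius Fingerprint radius (default 3).
#' @param min_size Components smaller than this are discarded (default 2).
#' @return List of molecule tables, largest first.
#' @export
find_sar_series <- function(records, threshold = 0.5, radius = 3, min_size = 2) {
  sim <- tanimoto_matrix(records$smiles, radius = radius)
  adj <- sim >= threshold
  diag(adj) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  comp <- igraph::components(g)
  out <- lapply(seq_len(comp$no), function(k) {
    records[comp$membership == k, , drop = FALSE]
  })
  out <- out[vapply(out, nrow, integer(1)) >= min_size]
  out[order(-vapply(out, nrow, integer(1)))]
}

#' Split a series into potency-staged fine-tuning subsets
#'
#' Strategies: `all` (one subset, no splitting), `values` (k contiguous
#' potency-ordered groups of equal size, remainder spread over the
#' lowest-potency groups), `focused` (potency-ordered groups each half the
#' size of the previous, ending at the most potent; leftovers join the first
#' group), `scaffold` (step 1 the Murcko scaffolds of all records, step 2 the
#' full SMILES), `random` (k seed-shuffled groups), `best` (only the most
#' active values-group).
#'
#' @param series A `sar_series` or molecule table with `smiles`, `potency`.
#' @param strategy Split strategy.
#' @param k Number of steps (ignored for `all`; `best` keeps the most active
#'   of k values-groups).
#' @param seed Seed for the `random` strategy.
#' @return A `potency_split`: list with `subsets` (list of molecule tables,
#'   increasing potency), `holdout` (empty here; see [extract_holdout()]),
#'   `strategy`, `k`.
#' @export
split_series <- function(series, strategy = c("values", "focused", "scaffold",
                                              "random", "best", "all"),
                         k = 4, seed = NULL) {
  strategy <- match.arg(strategy)
  records <- if (inherits(series, "sar_series")) series$records else series
  n <- nrow(records)
  if (strategy %in% c("values", "focused", "random", "best") && k > n) {
    stop("k = ", k, " exceeds series size ", n)
  }
  stopifnot(k >= 1)
  records <- .order_by_potency(records)

  values_groups <- function(k) {
    base <- n %/% k
    extra <- n %% k
    sizes <- rep(base, k)
    if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
    ends <- cumsum(sizes)
    starts <- c(1L, utils::head(ends, -1) + 1L)
    lapply(seq_len(k), function(j) records[starts[j]:ends[j], , drop = FALSE])
  }

  subsets <- switch(
    strategy,
    all = list(records),
    values = values_groups(k),
    best = utils::tail(values_groups(k), 1),
    random = {
      if (!is.null(seed)) set.seed(seed)
      perm <- sample(n)
      base <- n %/% k
      extra <- n %% k
      sizes <- rep(base, k)
      if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
      ends <- cumsum(sizes)
      starts <- c(1L, utils::head(ends, -1) + 1L)
      lapply(seq_len(k), function(j) records[perm[starts[j]:ends[j]], , drop = FALSE])
    },
    focused = {
      z <- n %/% (2^k - 1)
      if (z < 1) stop("series of ", n, " cannot support a ", k, "-step focused split")
      sizes <- z * 2^((k - 1):0)
      sizes[1] <- sizes[1] + (n - sum(sizes)) # leftovers join the first group
      ends <- cumsum(sizes)
      starts <- c(1L, utils::head(ends, -1) + 1L)
      lapply(seq_len(k), function(j) records[starts[j]:ends[j], , drop = FALSE])
    },
    scaffold = {
      scaf <- unique(stats::na.omit(vapply(records$smiles, murcko_scaffold,
                                           character(1), USE.NAMES = FALSE)))
      if (!length(scaf)) stop("no scaffolds could be derived for the scaffold split")
      list(data.frame(smiles = sort(scaf), potency = NA_real_,
                      stringsAsFactors = FALSE),
           records)
    }
  )
  structure(
    list(subsets = subsets, holdout = records[0, , drop = FALSE],
         strategy = strategy, k = length(subsets)),
    class = "potency_split"
  )
}

#' @export
print.potency_split <- function(x, ...) {
  cat("<potency_split>", x$strategy, "|", x$k, "step(s), sizes:",
      paste(vapply(x$subsets, nrow, integer(1)), collapse = "/"),
      "| holdout:", nrow(x$holdout), "\n")
  invisible(x)
}

#' Withhold the most potent fraction of a series
#'
#' The holdout is the `ceiling(fraction * n)` most potent records; ties at
#' the boundary resolve by canonical-SMILES lexicographic order so the split
#' is deterministic.
#'
#' @param series A `sar_series` or molecule table.
#' @param fraction Holdout fraction in (0, 1), default 0.25.
#' @return List with `training` (same type as input, potency-ordered) and
#'   `holdout` (molecule table).
#' @export
extract_holdout <- function(series, fraction = 0.25) {
  stopifnot(fraction > 0, fraction < 1)
  is_series <- inherits(series, "sar_series")
  records <- if (is_series) series$records else series
  n <- nrow(records)
  n_hold <- ceiling(fraction * n)
  if (n - n_hold < 2) stop("training set would have fewer than 2 molecules")
  records <- .order_by_potency(records)
  holdout <- records[(n - n_hold + 1):n, , drop = FALSE]
  training <- records[seq_len(n - n_hold), , drop = FALSE]
  rownames(holdout) <- rownames(training) <- NULL
  if (is_series) {
    out <- series
    out$records <- training
    out$potency_span <- if (all(is.na(training$potency))) NA_real_ else
      diff(range(training$potency, na.rm = TRUE))
    list(training = out, holdout = holdout)
  } else {
    list(training = training, holdout = holdout)
  }
}

#' Write a split manifest as JSON
#'
#' @param split A `potency_split`.
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
write_split_manifest <- function(split, path) {
  manifest <- list(
    strategy = split$strategy, k = split$k,
    subsets = lapply(split$subsets, function(s) s$smiles),
    holdout = split$holdout$smiles
  )
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
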