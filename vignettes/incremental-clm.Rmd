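---
title: "Incremental fine-tuning of chemical language models: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Incremental fine-tuning of chemical language models: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Structural optimization — making a known bioactive chemotype more potent on
its target — is the costliest loop in early drug discovery. `increclm`
implements a purely ligand-based, oracle-free approach: a recurrent chemical
language model (CLM) over SMILES strings is first pretrained on a large,
target-ignorant corpus of bioactive molecules, then fine-tuned *incrementally*
on a structure–activity relationship (SAR) series, one potency stratum at a
time, from the least to the most potent subset. The staged curriculum mimics
the learning trajectory of a medicinal-chemistry program: each design–make–test
cycle adds more potent analogues, and the model is always trained last on the
best compounds known so far. Designs are sampled from the fine-tuned model by
multinomial temperature sampling and ranked by the model's own perplexity —
no external activity predictor, docking function or QSAR oracle is involved.

Success is measured retrospectively with a *rediscovery score*: the top-25%
most potent members of a series are withheld, the model is fine-tuned on the
rest, and the score quantifies how many of the withheld high-potency
molecules reappear among the 30 top-ranked designs, how often they were
sampled, and what fraction of the holdout was recovered.

## The model

The CLM is an autoregressive next-token model over SMILES tokens:

* token embedding (default 64 dimensions),
* batch normalization,
* a stack of LSTM layers (reference configuration 1024/256 units; a variant
  with three 1024-unit layers suits broader chemotype spaces),
* batch normalization,
* a dense projection to vocabulary logits with a softmax.

Sequences are wrapped in start/end sentinels, padded per mini-batch, and
trained by teacher forcing with the cross-entropy loss masked on padding.
The engine (Armadillo/C++ under R) stores all parameters in one flat vector,
which makes Adam, bit-exact checkpoint snapshots and finite-difference
gradient checking straightforward; the test suite verifies the analytic
gradients of every layer — including both batch-normalization blocks —
against central differences.

Tokenization is atom-level: bracket atoms, the two-letter halogens `Cl`/`Br`
and `%nn` ring closures are single tokens, all other characters are their
own token. The same segmentation is used for training and for perplexity, so
the sequence length `N` in the perplexity

\[ \mathrm{PPL} = \exp\Big(-\tfrac1N \sum_{i=1}^{N} \log q_i\Big) \]

is the number of scored tokens: the chemical tokens plus the end sentinel
(the start sentinel conditions the first prediction and is not scored).
Under this convention a uniform model over a `V`-token vocabulary scores
`PPL = V` for every sequence, which the tests assert exactly. Sampling draws
each token from the temperature softmax `q_i = exp(z_i/T) / sum_j exp(z_j/T)`
(default `T = 1`) until the end sentinel or a 140-token cap; strings that hit
the cap without terminating are counted as invalid rather than silently
truncated.

## Training schedule

Three data variants are supported, with the same semantics during
pretraining and fine-tuning:

* **canonical** — one canonical SMILES per molecule (40 pretraining epochs);
* **augmented** — ten randomized spellings per molecule, drawn once up front
  (20 epochs);
* **randomized** — one fresh randomized spelling per molecule, re-drawn every
  epoch (100 epochs). Validation sequences are re-randomized too, which is
  why checkpoint selection for this variant smooths the validation loss.

Optimization is Adam (initial rate 1e-3 for pretraining, 1e-4 entering
fine-tuning) with categorical cross-entropy. Canonical and augmented training
reduce the learning rate on plateau (factor 0.5, patience 3, floor 1e-4);
dropout 0.2 applies to the LSTM outputs for those variants and 0 for
randomized. Each fine-tuning stage runs 100 epochs with 10% of the stage's
molecules reserved for validation and is then *restored* — weights, Adam
moments, batch-normalization statistics and the learning rate in effect — to
the epoch with the minimum validation loss; the randomized variant minimizes
a trailing 10-epoch moving average (partial windows at the start, ties to the
earliest epoch, so a constant trace restores epoch 1). The restored state,
including the optimizer, is the starting point of the next stage, so the
learning trajectory is continuous across the potency curriculum.

Between-stage state travel is the one place where several defensible designs
exist; we snapshot the running best epoch online (memory-bounded: only the
incumbent best state is kept) rather than retaining every epoch.

## Data curation and splitting

Standardization removes stereochemistry and isotopes at string level, keeps
the largest carbon-containing fragment (ties by size, then lexicographic),
neutralizes ionizable groups (permanently charged centers such as quaternary
nitrogen are kept), canonicalizes through OpenBabel, and rejects molecules
above 1000 Da or 140 tokens with machine-readable reasons. A strict
syntactic scanner plus a valence audit runs *before* the backend because
OpenBabel silently repairs some malformed strings ("C(((" parses as "C") and
accepts valence-damaged atoms; generated-string validity additionally
rejects canonical forms containing chargeless bracket atoms (other than
`[nH]`), the backend's signature for radicals created from strings like
"c1cc1".

The reference corpus is made target-ignorant by removing every molecule
annotated on the target family and every molecule with Tanimoto similarity
strictly above 0.4 to any known target ligand (Morgan-type/ECFP fingerprints,
radius 2, 2048 bits). SAR series are curated by iteratively dropping members
whose mean similarity to the rest falls below 0.5 (radius 3), then rejecting
series with fewer than 25 members or mean internal pairwise similarity below
0.3. The outlier rule is read as *mean* similarity to the remaining members,
which is stabler than the maximum on small series. Fingerprints are
OpenBabel ECFP4/ECFP6 folded from their native 4096 bits to the requested
width; absolute similarity values therefore differ slightly from other
toolkits' Morgan implementations, and the thresholds act on these values.

Splitting strategies: `all` (no split), `values` (k equal contiguous
potency-ordered groups; remainder molecules join the *lowest*-potency groups
so the most-active step is never diluted), `focused` (halving sizes toward
the most potent group, computed from the final group backwards, leftovers
joining the first group), `scaffold` (Murcko scaffolds first, full SMILES
second), `random`, and `best` (only the most active values-group). Potency
ties everywhere resolve by the stable order (potency, canonical SMILES).
The retrospective holdout is the `ceiling(0.25 n)` most potent records; ties
at the boundary resolve lexicographically so the split is deterministic.

## Ranking and the filter cascade

Sampled designs are aggregated by canonical SMILES with sampling
frequencies; invalid strings are counted but never ranked. Ranking removes
fine-tuning molecules and sorts by ascending perplexity with ties broken by
higher frequency, then lexicographic SMILES. For augmented/randomized models
the ranking perplexity is the mean over 10 randomized spellings. When the
canonical spelling of a novel design uses a token the model has never seen
(OpenBabel's canonical form occasionally introduces `-` between aromatic
systems), the design is scored on its emitted spelling instead — documented
behavior, not a silent drop.

The prospective cascade applies, in order: a naive-model perplexity floor
(default 1.012; the value is corpus-specific and exposed as configuration),
known-molecule exclusion, exclusion of designs also produced by a
classically fine-tuned baseline, removal of substructures/isomers of
training molecules, a Tanimoto cap against training (0.8 or 0.6 by
application), substructure blacklists (e.g. 1,3-cyclohexadiene) and a
ring-size rule (smallest-set rings larger than 7 atoms), and an optional
stable prioritization of a pharmacophore pattern (e.g. sulfonamides). Every
removal is attributed to exactly one rule in a log.

## Metrics

* **Rediscovery score** = `(N_R/30) x (sum F_R / sum F_30) x (N_R/N_hold)` —
  the product of the three factors; it lies in [0, 1] and is zero exactly
  when nothing is rediscovered. The multiplicative composition is our
  reading of the three-factor design (the source panel shows the factors
  without an explicit operator); it compensates the extremes of many
  low-frequency hits versus one high-frequency hit.
* **Sampling statistics**: validity (parsable / emitted), uniqueness (unique
  canonical / valid), novelty (unique not in training / unique). Which corpus
  counts as "training" is a caller decision (pretraining vs fine-tuning set).
* **Distributional similarity**: `S_FCD = exp(-0.2 FCD)` transforms a
  Frechet ChemNet distance from a pluggable external backend;
  `S_KL = (1/D) sum_d exp(-KL_d)` aggregates per-descriptor KL divergences
  KL(generated || reference) over a panel of nine descriptors — a Bertz-style
  graph-complexity index (bond-connectivity and heteroatom information terms
  computed on the molecular graph; our own implementation, as no installed
  backend provides the original index), logP, molecular weight, TPSA
  (continuous; Gaussian KDE with Scott's-rule bandwidth on a shared 512-point
  grid, densities floored at 1e-10), and H-bond acceptors/donors, rotatable
  bonds, aliphatic and aromatic ring counts (discrete; shared 10-bin
  histograms) — plus the maximum internal Tanimoto similarity of each set.
* **Potency–perplexity regression**: ordinary least squares of potency
  (−log10 molar) on mean perplexity with the two-sided t-test on the slope
  and R²; a constant-perplexity input returns slope 0, R² 0, p 1 with a
  degeneracy flag.

## The synthetic universe

Real corpora (ChEMBL/BindingDB extracts) are neither required nor shipped.
`toy_universe()` enumerates a benzimidazole-like two-ring scaffold with three
substitution positions (6 fragments each, 216 enumerants) and attaches a
deterministic pseudo-potency: baseline 6 (1 µM), additive per-position
contributions spanning about three log units, one pairwise interaction
(+0.8 when the acidic head group co-occurs with the distal isopropyloxy
substituent — a long-range dependency the model must capture), and Gaussian
noise with SD 0.15 log units, drawn once per enumerant from the seed. The
noise is small enough to mostly preserve the potency ordering used for
splitting, mirroring curated assay data.

`build_toy_benchmark()` draws a potency-stratified series (default 60
molecules spanning at least 2 log units), assembles a scaffold-disjoint
background corpus (default 2000 molecules) from a remote template pool —
substituted benzenes, pyridines, five-membered heteroaromatics, benzofused
systems, cyclohexanes, esters and amides — and verifies the ignorance
invariant (no corpus molecule above 0.4 Tanimoto to the series) through the
same filter used for real corpora. The truth set is exactly the top-25% of
the series.

What the toy world does *not* emulate: assay heterogeneity across
laboratories, activity cliffs unrelated to substituent identity,
stereochemistry (stripped by design), tautomerism, and the scale and
diversity of a real pretraining corpus. Passing the desk-scale benchmark
therefore demonstrates that the training-and-ranking machinery extracts a
potency-structured signal; it does not certify performance on any real
target.

## Desk-scale benchmark choices

The end-to-end benchmark in the test suite and the acceptance script uses
problem sizes chosen for a laptop-class single CPU: a 16-dimensional
embedding with one 64-unit LSTM layer, batch normalization on, a 2000-molecule
corpus, a 60-molecule series split 4 ways by values, a 15-molecule holdout,
2048 samples per scoring run and 5 independently seeded fine-tuning runs,
all with the canonical training variant (40 pretraining epochs, 100 epochs
per fine-tuning stage). Two schedule choices are deliberate scale
adaptations. First, fine-tuning runs at a constant 1e-3: the reference
1e-4 schedule performs only ~100 Adam steps per stage at this scale and
barely moves the model, while the reference fine-tuning schedule is itself
effectively constant-rate (it starts at its own plateau floor). Second, the
plateau scheduler is disabled during fine-tuning because the 10 %
validation split of an 11-molecule stage holds 2 molecules, whose noisy
loss triggers the patience almost every epoch and silently decays the rate.
The potency landscape of the default universe is built so that contribution
tiers overlap across positions (gaps comparable to the noise scale): every
stratum of the space, including the withheld top quartile, then shares its
fragments with the strata below, and the holdout is reachable by
recombination of seen fragments rather than by extrapolation to unseen
ones — the task the retrospective benchmark is meant to probe. A landscape
dominated by a single high-contribution fragment instead concentrates that
fragment in the holdout and makes rediscovery impossible by construction.

## Numerical and degenerate-input choices

* Softmax is computed with max-subtraction; probabilities are strictly
  positive by construction.
* Batch-normalization statistics are computed over valid (non-padded)
  positions only, with running statistics (momentum 0.1) used at inference
  and during sampling.
* Dropout uses per-sequence feature masks held constant across time steps.
* `train_stage(epochs = 0)` returns its input unchanged; empty corpora,
  empty holdouts, constant perplexities and all-invalid sample sets raise
  informative errors or flagged degenerate results rather than NaNs.
* Ring perception uses the smallest-ring set of the heavy-atom graph;
  Murcko scaffolds are computed by iterative pruning of degree-one atoms.
* The randomized-SMILES writer emits kekulé spellings from a random DFS over
  the heavy-atom graph; every public-API output is round-trip-verified
  against the canonical form of its source (a mismatch is an error, never a
  silent substitution).

## Known limitations

* Fingerprints are OpenBabel ECFP, not RDKit Morgan; similarity thresholds
  transfer in spirit but not bit-for-bit.
* The valence audit covers the neutral organic subset and common charged
  bracket atoms; exotic organometallics pass through to the backend's more
  permissive judgment.
* The FCD backend is pluggable and not bundled; only the similarity
  transform and the descriptor-panel KL similarity are computed natively.
* Parameter counts of the reference architecture depend on the vocabulary
  size; the package enforces architecture shape, not a specific total.
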