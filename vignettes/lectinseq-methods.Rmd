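---
title: "Sequencing glycans from lectin binding fingerprints: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sequencing glycans from lectin binding fingerprints: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lectinseq)
```

## The problem

Glycans are branched oligosaccharides; determining their structure normally
requires mass spectrometry or NMR plus expert annotation. Lectins and
anti-glycan antibodies bind short glycan *motifs* stereospecifically, so a
panel of such reagents assayed against a glycan produces a binding
fingerprint that carries partial structural information. `lectinseq`
implements a probabilistic pipeline that turns a panel fingerprint into a
ranked list of candidate structures - de novo sequencing in the sense that
candidates are generated, not restricted to a reference list.

The pipeline has five stages, each its own module:

1. **Glycan trees** (`parse_iupac`, `canonicalize`): a glycan is a rooted
   labeled tree; the reducing end is the root, each node carries a residue
   name, anomeric configuration, and the attachment position on its parent.
   Strings use the CFG-style condensed dialect with the reducing end
   rightmost and branches parenthesized. Canonical form orders siblings by
   (attachment position, then substring), so isomorphic trees print
   identically.
2. **Motifs** (`enumerate_motifs`, `build_catalog`, `match_motif`): a motif
   is a connected fragment *with exact substitution context*: each node
   records how many unspecified substituents it carries (written `X-`), and
   the fragment root records whether the glycan continues toward the
   reducing end (written `-X`). Terminal `Galb1-4GlcNAcb1-X` and internal
   `X-Galb1-4GlcNAcb1-X` are different motifs. The catalog keeps motifs of
   at most 5 residues present in more than 5 corpus glycans.
3. **Binding features** (`binarize`): raw RFU signals vary strongly with
   context even for a fixed motif, so each reagent-concentration condition
   is binarized against a ladder of log-spaced thresholds from 1000 to
   20000 RFU (8 by default); the bit is 1 iff the signal strictly exceeds
   the threshold.
4. **The Boltzmann model** (`boltzmann_train`, `glycan_loglik`,
   `rank_candidates`): the conditional probability of a motif vector
   `m` given feature vector `l` is
   `log P(m | l) = sum_i A_i m_i + sum_ij C_ij m_i l_j - F(l)`.
   Because there are no motif-motif couplings, the model factorizes into
   independent logistic units and the normalizer has the closed form
   `F(l) = sum_i log(1 + exp(A_i + C_i l))`. The log-likelihood is concave,
   so training has a unique optimum.
5. **Candidate space** (`fit_markov`, `sample_glycans`,
   `build_candidate_pool`): an order-2 Markov growth model is fitted to the
   reference corpus and sampled to produce plausible unseen glycans; the
   candidate pool is the deduplicated union of samples and the reference
   corpus. Each profile is scored by `log P(m(candidate) | l)` and the pool
   is sorted, ties broken by canonical string.

## Modeling decisions

**Factorized conditional.** The model deliberately omits motif-motif and
higher-order couplings. This is the unique reading under which the training
loss is convex and the model is a two-layer network; it also gives the
closed-form normalizer above, which we verify against brute-force
enumeration over all `2^K` motif vectors in the tests. The cross-entropy
comparison in `order_comparison` quantifies what the restriction costs: on
data generated from a first-order model, the saturated second-order
predictor extracts no additional information (median `dH2 - dH1` below 0.01
bits), while a contrived XOR lectin pair is captured only by the
interaction term.

**Optimization.** The reference optimizer is full-batch gradient ascent at
step 0.1 with step-halving backtracking; because the objective is concave,
any method reaches the same optimum, and two faster engines are provided
(`nesterov`, and per-motif guarded Newton exploiting the factorization into
independent logistic regressions). Motif columns with identical presence
patterns are identical units and are trained once and expanded - an exact
shortcut. Convergence is declared on the maximum absolute mean gradient
(`gtol`, default 1e-7). On noiseless (separable) data the weights diverge;
the iteration cap then applies, and candidate ordering is invariant to the
cap because every posterior is on the correct side of 1/2 well before it.

**Glycan likelihood.** A candidate's score is the probability of its *full*
motif vector, absent motifs included: this is exactly `P(m | l)` evaluated
at the candidate's indicator vector. Motifs not covered by any informative
feature contribute their marginal prevalence through `A_i`, which acts as a
prior favoring structurally common candidates.

**Markov growth model.** Growth tokens are (residue, anomer, anomeric
position, attachment position); each node's child list is generated
sequentially with an explicit STOP symbol. Each draw is conditioned on the
node's own token, its parent's token, and the previously drawn sibling
(BEGIN where history is missing). On unbranched chains this is exactly
"predict the next residue from the previous two"; the sibling component is
needed so that a corpus of identical glycans fits a point-mass model (with
a two-residue history alone, a one-child node would always be fitted as a
50/50 child-versus-stop split). No smoothing is applied; sampling can only
visit histories reachable from fitted transitions. Trees exceeding
`max_nodes` (default 30) are rejected and redrawn. Model entropy is
estimated by Monte Carlo as the mean of `-log2 P(glycan)` along the
canonical generation order; a deterministic model scores exactly 0 bits.

**Information measures.** All entropies are plug-in and base 2. A
reagent's MI with a motif is the maximum over its threshold features, since
each threshold is one binarization of the same measurement. The
primary-motif information fraction uses greedy forward selection of motifs
maximizing joint MI, stopping at a gain below 0.01 bits or four motifs;
exhaustive subset search is intractable and the greedy increments mirror
the incremental question being asked ("how much does a second motif add?").
In the two-lectin cross-entropy comparison the second-order model is
saturated over the four `(l1, l2)` cells, so its optimum is computed in
closed form as the per-cell empirical motif frequency; the first-order
model is a logistic (log-odds-linear) fit. The predictors are stated in
the log domain in some treatments; we use the logistic parameterization
throughout because the loss being minimized is the logistic loss and the
zeroth-order optimum then equals the motif entropy exactly.

**Evaluation protocol.** `run_replicates` rebuilds the motif catalog and
the Markov model from the training glycans of each partition, so held-out
structure never informs feature construction; training rows never contain
test glycans (asserted). The candidate pool, however, is the union of
Markov samples and the *full* reference corpus - a candidate list may
contain any known structure without leaking training signal, and this
guarantees the true glycan is rankable. A test glycan absent from the pool
counts as a failure at every `n`. Partition accuracy is averaged with
standard error `sd/sqrt(n_partitions)`; named holdouts use the Bernoulli
standard error. Rank groups follow the published boundaries (high = rank 1,
medium = ranks 3-4, low = ranks above 6 and misses; ranks 2, 5, 6
unassigned), and group enrichment uses a one-sided upper-tail binomial
test, with Bonferroni-adjusted p-values reported alongside the raw ones.

## The synthetic benchmark

Real lectin-array compendia cannot ship with the package, so every claim is
exercised against simulated ground truth with planted specificities.

**Corpus generator.** Random rooted trees are grown over the seven-residue
alphabet (Fuc, Gal, GalNAc, Glc, GlcNAc, Man, Neu) using a fixed vocabulary
of common mammalian linkages (type-2 LacNAc, alpha-2,3/6 sialylation,
fucosylation, the trimannosyl core, O-glycan cores, lactose roots). Sizes
span 2-15 residues with a geometric decay (most array glycans are small);
each step extends the most recent tip or, with probability 0.25, branches
from an earlier residue with a free allowed position. Restricting growth to
a reusable linkage vocabulary is what makes motif statistics meaningful -
real glycomes reuse a small set of linkages, and a uniformly random corpus
would leave almost every motif below any sensible count threshold.

**Planted lectins.** The default benchmark plants 30 single-motif lectins
with sensitivity 0.95 and false-positive rate 0.02. Primaries are
restricted to motifs with non-degenerate, mutually distinct presence
patterns - motifs with identical patterns are information-theoretically
indistinguishable, so "the planted motif attains the maximal MI" would
otherwise be ill-posed - and are then chosen greedily so that each added
lectin maximally refines the joint presence code over the corpus, which
naturally favors motifs of balanced prevalence. This mimics how real panels are assembled from complementary,
individually informative reagents. Each lectin is measured at two
concentrations and each glycan printed on two spacers; every
(observation, reagent, concentration) fires independently, emulating the
replicate structure of real arrays. RFU is a two-state log-normal (bound
median 10000, unbound median 200, dispersion 0.5), spanning the
1000-20000 RFU binarization window.

**What the simulation does and does not capture.** It reproduces binary
motif-driven binding with context-varying intensity, replicate structure,
and false firing, so it tests motif recovery, training, ranking and the
information-theoretic analyses end to end. It does not model spacer
artifacts (beyond labels), spatial array effects, concentration-dependent
affinity curves, glycan density effects, or reagents with genuinely
graded (non-two-state) affinity spectra; passing benchmarks therefore
demonstrates correctness of the machinery under the stated noise model,
not performance on any particular real compendium.

**Problem sizes.** The standard noisy benchmark uses 1000 glycans, 30
lectins, 2 evaluation partitions and 1000 Markov samples in the pool. The
noiseless identifiability experiment uses 300 glycans with an unfiltered
motif catalog and one perfect lectin per distinguishable presence pattern:
in that limit the count filter (a statistical-reliability device) would
only erase discriminating motifs, and duplicate-pattern lectins add no
information. Under this construction the true glycan's motif vector is the
unique likelihood maximizer, so every profile must rank its own glycan
first.

## Numerical choices and degenerate inputs

- Likelihoods are computed in nats internally; entropies and mutual
  informations in bits. `0 log 0 = 0` throughout.
- The softplus in `F(l)` switches to its linear asymptote above 30 to avoid
  overflow.
- Ties in candidate ranking are broken by canonical string ascending -
  deterministic and content-independent. Candidates whose motif vectors
  coincide (for example repeat chains longer than the motif size window,
  the polyLacNAc problem) are genuinely indistinguishable to the model;
  the ranking makes this visible as adjacent ranks rather than hiding it.
- Binarization treats missing RFU as 0 with a warning; negative or
  non-finite RFU is an error naming the cell.
- An empty motif catalog (filters too strict) is allowed with a warning;
  evaluation partitions with empty catalogs are skipped with a warning.
- `"?"` (unknown anomer/position) matches only `"?"` in motif matching:
  conservative, since bond isomers are exactly what lectins distinguish.
- Unknown residue names parse in lenient mode and are dropped by
  `filter_corpus`; strict mode refuses them.

## Known limitations

- Exact-count motif context plus a finite size window means repeat
  structures beyond the window are indistinguishable; this mirrors the
  known difficulty of reading internal polyLacNAc with lectins.
- The Markov generator is corpus-driven and has no biosynthetic
  constraints; it can propose glycans no glycosyltransferase would make.
  It is a candidate generator, not a glycome model.
- The two-state RFU model ignores affinity gradation across
  concentrations; conditions are treated as independent features.
- Mutual information estimates are plug-in and upward-biased at small
  sample sizes; no bias correction is applied.
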