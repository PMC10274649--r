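# lectinseq

De novo glycan sequencing from lectin binding fingerprints.

Glycans — branched oligosaccharides built from a small residue alphabet —
are usually sequenced by mass spectrometry plus expert annotation. Lectins
and anti-glycan antibodies offer a cheaper readout: each reagent binds a
short structural *motif*, so a panel of reagents assayed against a glycan
yields a binding fingerprint that constrains its structure. `lectinseq` is
for glycobiologists and method developers who want to (i) predict glycan
structures from lectin-array profiles, (ii) quantify which lectins
recognize which motifs and how sharply, and (iii) benchmark both on
simulated ground truth.

## The model

A glycan is a rooted labeled tree (reducing end = root) written in
CFG-style IUPAC-condensed notation, e.g.
`Neua2-6Galb1-4GlcNAcb1-2Mana1-3(Mana1-6)Manb1-4GlcNAc`. A motif is a
connected subtree with exact substitution context: `Galb1-4GlcNAcb1-X` is a
terminal LacNAc, `X-Galb1-4GlcNAcb1-X` an internal one, and the two are
distinct. Let `m` be the binary vector of catalog motifs present in a
glycan and `l` the binarized lectin features of its profile (each
reagent–concentration condition thresholded over a log-spaced 1000–20000
RFU ladder). The fully visible Boltzmann model is

    log P(m | l) = Σ_i A_i m_i + Σ_ij C_ij m_i l_j − F(l)

with no motif–motif couplings, so it factorizes into independent logistic
units and the normalizer has the closed form
`F(l) = Σ_i log(1 + exp(A_i + C_i·l))`. Training (gradient ascent at step
0.1, or accelerated/Newton engines reaching the same unique optimum of the
concave likelihood) fits `A`, `C` from profile–structure pairs. To
sequence, an order-2 Markov growth model fitted to the reference corpus is
sampled into a candidate pool (union of samples and all reference
structures), every candidate is scored by `log P(m(candidate) | l)`, and
the pool is ranked. Lectin–motif specificity is quantified by plug-in
mutual information `I(A:B) = H(A) + H(B) − H(AB)` in bits, with a
first- versus second-order cross-entropy probe for interaction effects.

## Worked example

Simulate a small ground-truth benchmark, evaluate held-out sequencing, and
ask which motif each lectin reads:

```r
library(lectinseq)
cfg     <- simulation_config(n_glycans = 200, n_lectins = 12, seed = 42)
corpus  <- generate_corpus(cfg)
catalog <- build_catalog(corpus)        # motifs of <= 5 residues seen > 5 times
lectins <- plant_lectins(catalog, cfg, corpus)
binding <- simulate_binding(corpus, lectins, catalog, cfg)

report <- run_replicates(corpus, binding,
                         experiment_config(n_partitions = 2, pool_n = 300,
                                           seed = 1))
report$accuracy
#> # A tibble: 2 × 4
#>   class top_n accuracy    se
#>   <chr> <int>    <dbl> <dbl>
#> 1 all       1    0.2    0
#> 2 all       3    0.475  0.05
```

Top-3 accuracy of 0.475 means that for 47.5% of held-out glycans the true
structure was among the three highest-likelihood candidates in a pool of
several hundred — with only 12 lectins. Accuracy grows quickly with panel
size (the standard 30-lectin benchmark reaches top-3 ≈ 0.8; see below).
The specificity report recovers the planted motifs:

```r
feats <- binarize(binding)
M     <- motif_matrix(corpus, catalog)
mt    <- mi_table(feats, M[match(feats$glycan_id, rownames(M)), ])
head(mt$report[, c("reagent", "motif_id", "threshold", "mi_bits")], 3)
#>   reagent motif_id threshold mi_bits
#> 1 LEC02   M00008       1000    0.861
#> 2 LEC01   M00001       1000    0.794
#> 3 LEC02   M00008       1534.   0.789
```

and the fitted Markov glycome model reports its entropy, which sets the
candidate-pool size needed to cover the plausible glycan space:

```r
e <- model_entropy(fit_markov(corpus), 5000, seed = 1)
#> Markov model entropy: 11.34 bits (se 0.078)
```

Motif enumeration shows the exact-context annotation:

```r
enumerate_motifs(parse_iupac("Neua2-6Galb1-4GlcNAc"), max_size = 5)
#> # A tibble: 6 × 3
#>   motif                 size count
#> 1 Neua2-X                  1     1
#> 2 X-Galb1-X                1     1
#> 3 X-GlcNAc                 1     1
#> 4 Neua2-6Galb1-X           2     1
#> 5 X-Galb1-4GlcNAc          2     1
#> 6 Neua2-6Galb1-4GlcNAc     3     1
```

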