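---
title: "Methods: pair-fed confounder screening and ceRNA network inference"
author: "heatCeRNA"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pair-fed confounder screening and ceRNA network inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(heatCeRNA)
```

# The design and what the package estimates

Chronic heat stress acts on a bird through two channels: the temperature
itself and the reduced feed intake it causes. The three-group design —
normal control (NC), heat stress (HS), and a pair-fed (PF) group held at
control temperature but restricted to the HS group's intake — lets the two
channels be separated at the level of differential expression. `heatCeRNA`
takes gene-level count matrices for three feature classes (lncRNA, miRNA,
mRNA) over this design and produces (i) the set of *heat-specific* lncRNAs,
(ii) a competing-endogenous-RNA (ceRNA) network around them, (iii) term
enrichment of the network's mRNAs, and (iv) the univariate validation
statistics used for phenotypes and qPCR.

# Differential expression model

Counts for feature $i$ in sample $j$ are modelled as negative binomial with
mean $s_j q_{ig(j)}$ and dispersion $\alpha_i$, where $s_j$ is a sample size
factor and $q_{ig}$ a group-level expected normalized count.

* **Size factors** are median-of-ratios: $s_j = \mathrm{median}_i\,
  (k_{ij}/\bar{k}_i^{geo})$ over features whose geometric mean
  $\bar{k}_i^{geo}$ is nonzero. All-zero features are short-circuited
  (reported with $P = 1$, direction `ns`).
* **Dispersion** is estimated per feature by the method of moments on
  normalized counts, pooled across the two contrast groups, and shrunk
  toward a class-wide trend $\alpha(\mu) = a_0 + a_1/\mu$ fitted by least
  squares over features with positive raw estimates (equal-weight average of
  the per-feature estimate and the trend value, floored at $10^{-8}$).
  Shrinkage stabilises the 6-vs-6 estimates without the full empirical-Bayes
  machinery of larger packages; exact agreement with those packages is not a
  goal, and a cross-check test asserts only concordant fold changes.
* **Testing** is a Wald test on $\log(q_1/q_2)$ with
  $\mathrm{Var}[\log \hat q_g] \approx \frac{1}{q_g}\frac{\sum_j 1/s_j}{n_g^2}
  + \frac{\alpha_i}{n_g}$, the delta-method variance of a mean of normalized
  NB counts. A pseudocount of 0.5 normalized counts guards the log against
  empty groups; at the default baseline of ~50 counts its bias is ~1%.
* **Calling**: DE $\iff P < \alpha$ *and* $|\mathrm{FC}| \ge$ the linear
  threshold (default 1.5, i.e. $|\log_2 \mathrm{FC}| \ge \log_2 1.5$). Raw
  P-values at $\alpha = 0.05$ are the default, matching the conventional
  screen for this design; `adjust = TRUE` switches the call to BH-adjusted
  P. Because the call conjoins the P and FC criteria, the realized null
  flagging rate sits at or slightly below $\alpha$; the type-I test asserts
  it within 3 binomial SDs of $\alpha$ over 2,000 null features.

The Wald construction makes contrast reversal exactly antisymmetric in
log-fold-change with unchanged P, which is tested to $10^{-8}$.

# The pair-fed Venn screen

A lncRNA is *heat-specific* when it is DE with the same direction in
HS-vs-NC and HS-vs-PF, and not DE in NC-vs-PF. The first two conditions
demand a reproducible heat response against either reference; the third
removes features that respond to feed restriction alone (which moves NC vs
PF). Both choices were genuinely open:

* Direction consistency across the two HS contrasts is required by default —
  a feature "up under heat" against one reference but "down" against the
  other is not a coherent heat response.
* The NC-vs-PF exclusion is on by default and can be dropped with
  `exclude_nc_pf = FALSE`, giving the pure two-set intersection. The screen
  is monotone: shrinking the NC-vs-PF DE set can only grow the output
  (property-tested).

# ceRNA network inference

Candidate triplets come from predicted miRNA-target pairs (an input; the
package does not do sequence-based prediction). For a lncRNA $l$ in the
heat-specific set and an mRNA $m$ sharing at least one predicted miRNA:

1. **Shared-sponge test.** With $N$ the number of miRNAs in the pair list,
   $K$ and $n$ the two target-set sizes and $k$ their overlap, the P-value is
   the inclusive upper tail $P[X \ge k]$, $X \sim \mathrm{Hyper}(N, K, n)$;
   the pair is kept when $P < 0.05$.
2. **Co-expression filters**, computed on $\log_2(\mathrm{FPKM}+1)$ across
   *all* samples of the design: Pearson $r(l, m) > 0.9$ (strict), and for
   each shared miRNA, Spearman correlations with both partners strictly below
   $-0.7$. Only miRNAs passing both legs are retained in the triplet.
   Zero-variance vectors give undefined correlations and are excluded with a
   count.

Two background/ordering choices deserve note. The miRNA universe for the
sponge test is the set of miRNAs appearing in the pair list — the natural
"predictable" background. And by default the sponge test is applied to the
*correlation-supported* target sets (predicted targets whose SCC against
that partner passes the threshold) rather than the raw predicted sets:
with sparse in-silico pair lists, raw-set testing makes the P-value depend
on how many unsupported predictions happen to be attached to each partner
— one spurious target on each side of a genuine pair can push
$P[X \ge 1]$ past 0.05 even when the expression evidence is unambiguous —
whereas conditioning on expression support ties the test to the same
evidence the network itself uses. The raw-set variant remains available via
`build_triplets(sponge_on = "predicted")`.

Whether miRNAs and mRNAs must themselves be DE before entering the network
was left open in the source design; the default is no — the heat-specific
gate applies to the lncRNA side only.

Triplets are emitted in lexicographic (lncRNA, mRNA) order and are invariant
to the row order of the pair list. The network deduplicates relationship
pairs into typed edges (lncRNA–miRNA, miRNA–mRNA); hubs are ranked by
degree, ties broken lexicographically. Exports (edge-list TSV, SIF, GraphML
via igraph) are round-trip tested against the edge multiset.

# Enrichment

Over-representation uses the same inclusive upper-tail hypergeometric, with
the universe defaulting to all genes in the gene-set collection (overridable)
— the expression matrix is deliberately not the default background because
annotation coverage, not detectability, defines the draw. BH adjustment runs
across all tested terms (including zero-hit terms, which carry $P = 1$);
results report only terms with at least one hit, ranked by raw P with
adjusted values alongside, matching the usual "top 20 pathways" display
whose adjustment status is ambiguous in most published figures.

# Validation statistics

* `anova_from_summaries()` reconstructs the one-way ANOVA from printed
  mean/SD/n ($SS_B = \sum n_i(\bar x_i - \bar x)^2$,
  $SS_W = \sum (n_i - 1)s_i^2$), which is exact — a published summary table
  is sufficient input. `anova_from_raw()` computes the same decomposition
  from observations; the two agree to $10^{-10}$ and match `lm()`'s ANOVA
  table.
* `duncan_letters()` implements Duncan's multiple range test: means sorted,
  the range spanning $p$ ordered means tested against
  $q'(p, \nu, \alpha)\sqrt{MS_W/n_h}$ where $q'$ is the studentized-range
  quantile at protection level $(1-\alpha)^{p-1}$ (via `qtukey`; no
  hand-rolled quadrature is needed since base R supplies the distribution),
  $n_h$ the harmonic mean of group sizes, with the standard containment rule
  and line-connection lettering. Under a three-group null its familywise
  separation rate is $1 - 0.95^2 \approx 9.8\%$ — by construction more
  permissive than Tukey; this is the test's documented behaviour, and the
  null-rate check asserts it rather than a smaller value.
* `simulate_trait_data(exact = TRUE)` draws normal data rescaled so each
  group's sample mean and SD equal the targets exactly. Both statistics
  above depend on the data only through those moments, so letter patterns
  derived from a printed table reproduce deterministically while the
  underlying values vary; `exact = FALSE` draws are used for null-rate
  checks.
* `ddct()` computes $\Delta Ct = Ct_{target} - Ct_{ref}$,
  $\Delta\Delta Ct$ against the calibrator-group mean, and $2^{-\Delta\Delta
  Ct}$; the calibrator's geometric mean is 1 by construction, and the result
  is invariant to per-sample shifts applied to both Ct values.

# The synthetic-data generator

`simulate_chs_dataset()` emulates the statistical structure the analysis
assumes — it is the test bed, not a read simulator. Defaults are fixed once,
on design grounds:

| parameter | default | rationale |
|---|---|---|
| `n_replicates` | 6 per group | the study design (3 × 6 samples) |
| `baseline_mean` | 50 counts | lncRNAs are lowly expressed; feature means are log-normal (sdlog 0.5) around it |
| `dispersion` | 0.1 | typical bulk RNA-seq biological CV ~0.3 at 6 replicates |
| `heat_fc` | 2.5 | a clearly detectable but not overwhelming effect at n = 6 (Wald power ≈ 0.99 per contrast) |
| `feed_fc` | 1.8 | the feed-intake confound, applied to HS *and* PF |
| `n_planted_de_lnc` / `n_planted_feed_lnc` | 20 / 20 | ~7% planted prevalence each; 70% of heat plants are up-regulated, echoing the predominance of induction under stress |
| `n_planted_triplets` | 10 | small enough that triplet recovery is binomially informative over 25 seeds |
| `latent_sd` | 0.5 log₂ units | per-sample shared activity; combined with the heat shift this puts the planted lncRNA–mRNA correlation near 0.96 |
| `triplet_mean` / `triplet_dispersion` | 400 / 0.005 | triplet members are modelled as highly expressed, tightly co-regulated genes — a PCC > 0.9 threshold is *only* attainable when shared regulation dominates residual noise (residual log₂ SD must be below ~⅓ of the shared-signal SD), so planting detectable triplets at baseline noise levels would be internally inconsistent |
| `triplet_noise_sd` | 0.1 log₂ units | member-specific wobble controlling detectability |
| `depth_jitter` | ±20% | library sizes vary so normalization is non-trivial |

Each planted triplet carries its own latent activity $a_s$ (heat shift plus
Gaussian noise) added to the lncRNA and mRNA log-means and subtracted from
the miRNA log-mean, producing the sign pattern the thresholds test
(PCC > 0 between lncRNA and mRNA, SCC < 0 for each miRNA leg). Triplet
lncRNAs are drawn from the planted heat-specific set so the full
DE → Venn → ceRNA chain can recover them. All randomness flows from one
seed through a scoped generator that restores the caller's RNG state;
identical seeds give byte-identical output.

What the generator does **not** emulate: within-replicate pen structure
(samples are treated as independent, since the sequencing design does not
resolve pens), isoform structure, GC/length biases, batch effects,
correlated background co-expression, or read-level artefacts. Passing
recovery tests therefore demonstrate that the chain is statistically
coherent under its own assumptions — not that real tissue data meet those
assumptions.

`generate_target_pairs()` emits the planted miRNA–partner pairs plus
uniformly drawn unique decoy pairs (default 200 over ~700 partners), so
target lists contain realistic prediction noise.

# Numerical choices and degenerate inputs

* Strict inequalities at all correlation thresholds, so a PCC of exactly 0.9
  is excluded (boundary-tested).
* The hypergeometric tail is inclusive ($P[X \ge k]$), hence $k = 0$ gives
  exactly 1 and the test can never report 0 for an empty overlap.
* PCA reports a degenerate-input warning with all-zero variance fractions
  when samples are identical; fractions otherwise sum to 1 within $10^{-9}$
  and match a direct covariance eigendecomposition to $10^{-8}$.
* Duncan's test refuses zero within-group variance (no scale for ranges);
  summary ANOVA reports an infinite-F flag with $P = 0$ when means differ
  with zero SDs.
* Correlations require $n \ge 3$ finite pairs; zero-variance inputs yield an
  explicit undefined signal rather than NA propagation.

# Problem sizes

The shipped tests and the acceptance script use 300 lncRNA / 80 miRNA / 400
mRNA features at 18 samples, 25–50 simulation seeds for recovery and power
estimates, 2,000 features for the null calibration, and 200/500 repeats for
the Duncan rates — sizes at which Monte-Carlo error is small relative to the
asserted margins while a full run stays in the minutes range on a laptop.

# Known limitations

* The DE stage is deliberately simpler than DESeq2 (no Cox–Reid adjustment,
  no outlier refitting, normal rather than t reference); it is slightly
  anti-conservative in raw P at n = 6, which the conjunction with the
  fold-change criterion offsets in practice.
* The sponge test treats target predictions as exchangeable draws; in real
  prediction output, miRNA families share seeds and violate that symmetry.
* Duncan's test is used because it is the field's convention for carcass
  traits; its per-pair error control is weaker than Tukey's HSD, and the
  package reports the underlying pairwise decisions so users can apply a
  stricter display if desired.
* With a single shared miRNA per planted triplet, network hub degrees in
  simulation are small; hub ranking is exercised structurally (ties,
  recounts) rather than against a planted hub hierarchy.
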