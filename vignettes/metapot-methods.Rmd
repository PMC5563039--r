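---
title: "Community metabolite potential modeling: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Community metabolite potential modeling: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metapot)
```

## The question the model answers

Amplicon surveys of a microbial community tell us *who* is there;
untargeted metabolomics of the same samples tells us *what* the chemical
environment looks like. metapot connects the two: given the gene families
(KEGG Orthology, "KO", identifiers) a community is predicted to encode, how
much of the variation in each measured metabolite can be explained by the
community's capacity to produce or consume it? Metabolites whose measured
abundance profile tracks that predicted capacity are called
**well-predicted**, and for those the package asks a second question: *which
taxa* drive the prediction?

## The model

### Stoichiometric matrix

The reaction network is a table of irreversible enzymatic reactions linking
gene families to compounds with signed stoichiometric coefficients
(positive = produced, negative = consumed). Summing coefficients per
(compound, gene family) pair gives a raw matrix which is then row-normalized:
within each compound row, positive entries are rescaled to sum to 1 and
negative entries to sum to −1. Entry \(M_{ck}\) is then the *relative*
contribution of gene family \(k\) to the production or depletion of compound
\(c\). Normalization makes compounds with many annotated reactions
comparable to sparsely annotated ones.

Two readings of the normalization axis are possible (per compound row or
per gene-family column). We normalize per compound row: the quantity of
interest is each gene's share of a given compound's turnover, and the
row-wise reading is the one under which the scores of different compounds
are on a common scale. The column-wise alternative would instead normalize
each gene's allocation across compounds, which answers a different question.

Reversible reactions are excluded by default, because a reversible record
carries no net direction. `parse_reaction_table(keep_reversible = TRUE)`
retains such records with their stated coefficients rather than expanding
them into both directions: under net-sum aggregation a both-directions
expansion always cancels to exactly zero, so expansion is indistinguishable
from dropping the record and was rejected as vacuous.

### CMP scores

Given a gene-family abundance table \(G\) (families × samples; corrected
relative abundances from a predicted-metagenome pipeline, consumed as-is),
the community metabolite potential score matrix is the product
\[ \mathrm{CMP} = M \, G , \]
so \(\mathrm{CMP}_{cs}\) is the abundance-weighted net capacity of sample
\(s\)'s community to produce (positive) or deplete (negative) compound
\(c\). Gene families absent from either \(M\) or \(G\) are dropped
symmetrically with a logged count rather than raising an error, because KO
coverage differs between database releases; compounds left without any
shared family are flagged unmapped.

When taxon-resolved inputs are available (per-taxon genome content \(C\)
and per-sample relative abundances \(A\)), the community table is assembled
as \(G = \sum_t C_t^\top A_t\), i.e. the sum of single-taxon tables
\(G_t[k,s] = C_{tk} A_{ts}\). Community and single-taxon scores are
computed by the same code path, so the additive decomposition
\(\mathrm{CMP} = \sum_t \mathrm{CMP}_t\) holds to floating-point accuracy by
construction (linearity of the matrix product).

Single-taxon content is scaled by the taxon's per-sample abundance rather
than used raw: an unscaled genome is constant across samples, which would
make every single-taxon score row constant and every contribution
correlation undefined.

### Well-predicted metabolites

For each compound present in both the score matrix and the measured
metabolite table (samples aligned by exact identifier match, unmatched
samples dropped with a warning), a Mantel test compares the two per-sample
vectors: Euclidean distance matrices are built from each vector, and the
Mantel statistic is the Pearson correlation of their upper-triangle
entries. Significance is one-tailed — high concordance of distance
structure — by permuting the sample labels of one layer:
\[ p = \frac{1 + \#\{ r_\text{perm} \ge r_\text{obs} \}}{1 + n_\text{perm}}. \]
When \(n! \le n_\text{perm}\) the test switches to exhaustive enumeration
of all \(n!\) relabelings and reports the exact tail probability (the
identity relabeling included, so \(p > 0\)). The default is 999
permutations; with fewer than 199 the strict \(p < 0.01\) rule below can
never fire, which the package leaves to the user to notice by design —
permutation counts are a resolution parameter, not a tuning knob.

Euclidean distances on one-dimensional vectors are invariant to sign flip
plus shift, so the Mantel statistic cannot distinguish positive from
negative coupling. The reported `direction` (sign of the raw Pearson
correlation between the two vectors) carries that information separately.

Multiple testing is handled by an empirical false-discovery-rate estimate
from permutation-null resampling: in each of `n_boot` rounds (default 50)
the sample labels of the whole metabolite table are permuted at once —
breaking every genuine score/abundance coupling while preserving both
layers' marginal structure and the between-compound correlation of the
metabolite table — and the full vector of Mantel p-values is recomputed.
At a threshold \(t\),
\[ \widehat{\mathrm{FDR}}(t) =
   \frac{\overline{\#\{p_\text{null} \le t\}}}{\max(1, \#\{p_\text{obs} \le t\})}, \]
and each compound's q-value is the smallest estimate at any threshold at or
above its own p (step-up monotonicity), capped at 1. "Bootstrap FDR" is
used here in the resampling-null sense: label permutation is the only
resampling scheme that yields a valid null for a permutation p-value set.

A compound is **well-predicted** when \(p < 0.01\) *and* \(q < 0.01\),
both strict.

### Taxon contributions and the association network

For each well-predicted compound, every taxon's single-taxon score row is
correlated (Pearson by default; Spearman available — the linear form is the
default because contributions are inspected on linear scatterplots) with
the community row across samples. Taxa with correlation above 0.5 are
flagged significant contributors; the **key contributor** is the taxon with
the maximum correlation. Constant score rows (taxa with no activity on the
compound) yield missing correlations and are excluded from the ranking.
The taxa–metabolite graph connects well-predicted compounds to their
significant contributors, with the correlation as edge weight and mean
relative abundances as node attributes.

Because two-taxon compositions that sum to one are perfectly collinear,
contribution correlations only discriminate taxa when at least three taxa
(or unclosed abundances) are present; the fitted object simply reports the
ties in the degenerate case.

## Supporting steps

**OTU preprocessing.** Low-abundance OTUs are removed when their share of
all reads in the dataset is strictly below 0.0005 % (5 × 10⁻⁶); the filter
default is applied after under-sequenced samples are dropped, and both the
threshold and the order are configurable. Rarefaction subsamples each
sample without replacement to a fixed depth (default 60 000 reads);
samples below the depth are removed with a warning. Subsampling delegates
to `vegan::rrarefy` under an explicit seed.

**Set enrichment.** Over- and under-representation of a class label in a
compound subset against a background uses exact hypergeometric tail sums;
the fold ratio is the subset frequency over the background frequency. Raw
p-values are reported by default (the customary convention for these
screens); a `p.adjust` method can be requested.

**Accurate-mass annotation.** Only the two singly protonated adducts are
implemented — [M+H]⁺ and [M−H]⁻, the ones relevant to standard
positive/negative-mode profiling — with the proton mass constant
1.007276 Da; electron-mass refinement is omitted as it is below the 1 ppm
floor at metabolite masses. Candidates within the ppm tolerance (default
7.5, warning outside 1–7.5) are ranked by ascending ppm error with
lexicographic tie-break, so annotation is deterministic and
order-invariant. Intensity normalization divides by a mode-matched internal
standard and sample pellet weight; when two standards are present the
mode-matched one is used (debrisoquine for positive mode, 4-nitrobenzoic
acid for negative), a documented convention.

## The synthetic-study generator

Real paired microbiome–metabolome cohorts with taxon-resolved gene content
are rarely public, so validation uses generated studies whose ground truth
is known. The generator emulates a radiation-exposure mouse cohort: a
factorial design of four doses (0, 0.1, 0.25, 1 Gy) by two time points
(10, 30 days) with 10 animals per group — 80 samples, enough for
well-powered permutation tests at desk scale. Its parts:

- **Network**: each (compound, family) link present with probability
  `density` (default 0.05 over 150 compounds × 200 families, giving ~10
  families per compound), signed integer coefficients with a 60/40
  produce/consume split, and a guaranteed producer per compound.
- **Community**: log-normal taxon baselines (meanlog sd 1.5 across taxa,
  per-sample noise sd 0.5, typical of amplicon relative-abundance spreads),
  optional multiplicative group effects per responder taxon (an arbitrary
  dose × time map, so threshold-like non-monotonic dose responses can be
  emulated), renormalized compositions, multinomial OTU counts at a
  configurable depth, and Bernoulli(0.3) × copy-number(1–3) genomes.
- **Metabolome**: a planted subset of compounds (default 30 of 150) follows
  `intercept + slope × CMP + noise`, with the noise scale chosen so the
  expected score/abundance correlation equals the planted `rho`; all other
  compounds are independent Gaussian noise. The realized correlations are
  recorded in the truth object.
- **Key contributors**: optionally, a planted compound's entire reaction
  set is confined to one taxon, making that taxon the unambiguous true key
  contributor for recovery scoring.

What the generator does *not* emulate — and therefore what passing
recovery tests cannot certify about real data: compositional coupling
between metabolites, heteroscedastic and non-Gaussian LC-MS noise,
annotation ambiguity (features mapped to the wrong compound id),
gene-content prediction error, and unmeasured host contributions to the
metabolome. Results on generated data validate the statistical machinery,
not the biology.

## Numerical and design choices

- **Problem sizes.** Validation experiments run at 80 samples × 150
  compounds with 999 permutations and 50 FDR rounds — large enough that
  the strict 0.01 rules are attainable (the q-value floor is
  \(\approx 150/1000 / 30 = 0.005\)), small enough for a desk machine.
  The null-calibration check uses 2000 independent pairs at n = 20.
- **Permutation kernel.** The inner Mantel loop is compiled (Rcpp): the
  permuted layer's distances are recomputed from the permuted 1-D vector in
  a single fused pass, driven by R's RNG so `set.seed()` reproduces runs
  exactly. A pure-R loop was ~25 ms per test, which makes the
  150-compound × 51-round FDR stage impractical; the kernel brings it to
  ~8 ms per 999-permutation test at n = 80.
- **Ties.** Permuted statistics within 10⁻¹² of the observed one count as
  "at least as large", the conservative convention.
- **Exact cancellations.** Reaction records whose net coefficient is
  exactly 0 after aggregation are removed before normalization; compound
  rows that cancel away entirely are dropped with a warning.
- **Degenerate vectors.** Constant score or abundance vectors make the
  Mantel test undefined and raise an error at the single-test level; in
  the screening loop such compounds get NA statistics and are never
  declared well-predicted. Constant single-taxon rows yield NA
  contributions, excluded from ranking.
- **Strictness.** All classification thresholds are strict inequalities
  (p < 0.01, q < 0.01, contribution r > 0.5, OTU filter < 0.0005 %), and
  boundary cases are pinned by tests.

## Known limitations

- CMP scores are linear in gene abundance and ignore pathway saturation,
  regulation, and transport; they are a capacity surrogate, not a flux
  estimate.
- The empirical FDR needs a reasonable number of compounds to stabilize;
  with very few tested compounds (or few permutations) the attainable
  q-value floor can exceed 0.01, making the well-predicted set empty by
  construction.
- Contribution correlations inherit compositional artifacts of relative
  abundances; with two dominant taxa the scores are nearly collinear and
  the key-contributor ranking is not informative.
- Only proton adducts are implemented in the annotation step; isotopes,
  multimers, and in-source fragments are out of scope.
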