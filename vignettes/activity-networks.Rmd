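---
title: "Inferring TF activity and core regulatory networks from regulons"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring TF activity and core regulatory networks from regulons}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(regulonet)
```

## The problem

A transcription factor (TF) acts through its protein, not its mRNA:
post-translational regulation, signaling, and translation make a TF's own
expression an unreliable readout of its regulatory output. What the
transcriptome *does* record faithfully is the response of the TF's target
genes. `regulonet` therefore estimates a latent per-sample **TF activity**
from the expression of the TF's regulon (its literature-curated target
set), and uses those activities — rather than TF expression — to assemble a
small, signed, core TF–TF network whose dynamics can then be stress-tested
by ensemble simulation.

The workflow has four stages, wrapped by the fitting function
`regulonet()`:

1. differential expression between conditions (`diff_expression()`),
2. enriched-TF selection by gene-set enrichment with a gene-label
   permutation null (`regulon_enrichment()`, `select_tfs()`),
3. activity inference per selected TF (`infer_activity()`),
4. mutual-information network construction over a cutoff sweep
   (`network_sweep()`), with ensemble simulation via
   `simulate()` on the fitted object.

## Selecting TFs: enrichment with a gene-label null

Genes are ranked by the absolute value of their two-group test statistic
(Welch t on log-scale values; externally computed tables, e.g. moderated-t
or negative-binomial Wald statistics, can be imported with
`read_de_table()` and are preferred when available). Each regulon is scored
with the weighted Kolmogorov–Smirnov running-sum statistic: walking down
the ranked list, a hit adds its ranking score to the `weight_exponent`
power (normalized so hit increments sum to one, exponent 1 by default) and
a miss subtracts `1/(N - n_hits)`; the enrichment score is the signed
extreme of the running sum.

Significance uses **gene-label permutation**: the score vector stays in
place and the gene names are shuffled, which is appropriate when the
per-gene statistics come from a designed two-group comparison and the
question is purely about set membership. Two consequences are exploited:

- the null distribution depends only on the score vector and the number of
  hits, so all same-size regulons share one cached null — this is what
  makes the 10,000-permutation default cheap;
- running-sum extrema can only occur immediately before or after a hit, so
  each permutation costs `O(n_hits)`, not `O(N)`.

Permutation p-values use the add-one rule (never zero) and are converted to
q-values by Benjamini–Hochberg across TFs. TFs with `q < 0.05` (default)
are kept; for multi-condition designs each pairwise contrast is tested and
the union of selections is taken. Cutoffs of 0.15, 0.05 or 0.01 are all
reasonable depending on how exploratory the analysis is.

## Inferring activity

For a TF with targets `g_1..g_n` present in the data, activity per sample
is the Hill-weighted signed average of standardized target expression:

$$A = \frac{\sum_i w_i\, g_i\, I_i}{\sum_i w_i},
\qquad w_i = \frac{1}{1 + (s_i / s_0)^n},$$

where `g_i` is the gene's z-score across **all** samples (activities must
be comparable across conditions, so standardization is never
per-condition), `I_i` is +1 for the putatively activated module and −1 for
the inhibited one, and `s_i` is the gene's adjusted p-value. Defaults
`s0 = 0.05`, `n = 1/5`: the weight is exactly 1/2 at `s = 0.05`, and the
shallow exponent keeps even non-significant targets contributing (a gene
with `s = 1` still carries weight ≈ 0.35). In single-condition designs with
no contrast, weights are uniform (`de = NULL`).

**Two-module split.** The signature of a real regulon in co-expression is
two internally coherent, mutually anti-correlated blocks of targets —
activated and inhibited. `split_two_groups()` finds this structure as the
leading-eigenvector bipartition of the *signed modularity matrix* of the
Spearman correlation graph (positive and negative weights get separate
null-model terms). When the leading eigenvalue is non-positive the matrix
is indivisible — all targets coherent — and the second module is left
empty. If finer community structure exists, only the top-level bipartition
is used: the activity model needs exactly two signed groups.

**Coherence filter.** Within each module, each gene's feature vector is its
row of correlations with all targets; the k = 1 centroid is the member
mean, distances are squared Euclidean, and genes whose distance strictly
exceeds the module mean are dropped. Strict inequality means a module of
identical rows passes untouched, and since the minimum distance can never
exceed the mean, a module is never emptied. The filter is deliberately
single-pass: iterating it would re-define the centroid on survivors and
cascade removals that the noise model does not justify.

**Sign assignment.** The split does not say which module is activated. For
a TF that is itself differentially expressed, the convention comes from its
own expression: if Spearman correlation between activity and TF expression
is negative, both the activity and the module labels flip (zero correlation
leaves the sign alone). A second grouping scheme — split targets by the
sign of their correlation with TF expression, filter `|rho|` strictly below
the mean absolute correlation — is computed as well, and the scheme whose
activity better correlates with its *retained* targets (mean absolute
Spearman) wins; ties go to the co-expression scheme, which is the default
and does not depend on the TF's own, possibly noisy, expression. For a
non-differential TF the expression trend is meaningless, so the sign is
either supplied explicitly (`sign_overrides`) or left as computed with a
warning that lists the TF's most significant regulon-overlap partners
(one-sided Fisher test, `rank_overlap_partners()`) among the DE TFs as a
starting point for manual curation.

## Network construction

Candidate directed edges are TF pairs supported by the database
(`a -> b` iff `b` is in `a`'s regulon). Edge strength is the mutual
information of the two activity rows — plug-in MI on equal-frequency
(rank) bins, `max(2, floor(sqrt(n/5)))` bins by default, natural-log
units; rank binning makes the estimate invariant under monotone transforms
and robust at the few dozen samples typical here. Edge sign is the sign of
the Spearman correlation of the activities (an exactly-zero correlation is
unsignable and drops the edge). Because the MI matrix is computed once,
thresholding at an ascending cutoff grid yields strictly nested candidate
networks (`network_sweep()`); the final model size is chosen by inspecting
ensemble simulations of each candidate, not by an automatic rule.

## Ensemble simulation

A fitted network is validated as a dynamical system by simulating many
models with random kinetics over the fixed topology and asking whether the
ensemble's stable states reproduce the observed expression clusters.
Expression dynamics per gene:

$$\frac{dx_i}{dt} = G_i \prod_{j \to i\ \mathrm{transcriptional}} H(a_j;\ X^0_{ji}, h_{ji}, \lambda_{ji}) - k_i x_i,$$

with the shifted Hill function
`H(X) = lam + (1 - lam)/(1 + (X/X0)^h)` (1 at zero regulator, `lam` at
saturation). Regulation reads the regulator's **activity**

$$a_j = c_j\, x_j \prod_{l \to j\ \mathrm{signaling}} H(a_l),$$

so signaling edges change a TF's activity without touching its expression,
while transcriptional edges change both. Non-regulator genes have
`a = x` identically. The factor `c_j` is an optional per-model random
translation/stability scale for regulator nodes
(`protein_noise`, log10 half-spread, default 0): biologically, a TF's
regulatory output is set by its protein state, which transcriptomics does
not measure, and the synthetic benchmark (below) switches this on so that
TF expression is an informative but imperfect surrogate of TF activity —
as in real data.

Signaling activities are defined implicitly when signaling edges form
cycles; they are resolved by fixed-point iteration from `a = c x` (exact
in depth-many steps for acyclic graphs, tolerance `1e-10` otherwise, hard
error only on non-convergence). An earlier design that simply rejected
cyclic signaling proved unusable: random TF–TF wiring produces cycles in
most realizations.

**Parameter ranges.** `G ~ U[1,100]`, `k ~ U[0.1,1]`, `h ~ U{1..6}`,
excitatory `lam ~ U[1,100]`, inhibitory `lam = 1/U[1,100]` (same (0.01, 1]
range, but mass at strong repression — mirroring the excitatory
distribution on the fold-change scale; a uniform draw on (0.01, 1] makes
median repression a biologically negligible 2× and, e.g., destroys
toggle-switch bistability). Thresholds follow the **half-functional
rule**: `X0 ~ U[0.02 M, 1.98 M]` with `M` the *contextual* median level of
the source node, estimated once per topology by Monte Carlo with one
random shifted-Hill factor per incoming edge (`estimate_node_medians()`,
private RNG stream, deterministic). Centering every threshold on the
global isolated median `G/k = 1010/11` instead leaves strongly regulated
TFs saturated against their targets and kills the very coupling the
simulation is supposed to produce.

**Integration.** Initial conditions are log-uniform over
`[0.01 G/k, 100 G/k]` per node. The system's timescales are bounded by the
degradation rates (1–10 time units), so a non-stiff Adams multistep
integrator is used to `t_max = 200`, followed by damped per-node
relaxation steps (`x <- x + 0.3 (dx/dt)/k`) until the residual
`max|dx/dt|` falls below `tol = 1e-6`; one retry at 4× the horizon, then
the trajectory is discarded (limit cycles and slow transients are not
recorded as states). Converged endpoints are deduplicated at 10⁻² in
log10 space. Every recorded state stores both `x` and `a`, and the test
suite re-verifies residuals with an independent, naively coded evaluator.

Knockdowns multiply the target gene's `G` by `kd_factor` (default 0.1)
*after* sampling, so a knockdown ensemble at the same seed is paired
model-for-model with the unperturbed one. `bifurcation_sweep()` clamps a
control gene across a grid (its equation removed) and projects pooled
standardized activities on their first principal component;
`classify_states()` maps simulated states to labeled reference profiles by
Pearson correlation (ties to the first reference label).

## The synthetic benchmark

`synthetic_grn()` generates the ground-truth study conditions: 30 TFs,
each with 20 distinct targets drawn from a shared 1000-gene pool (sharing
across TFs allowed, pool disjoint from the TF set) and 2 distinct TF–TF
edges; TF–TF edges are excitatory/inhibitory/signaling with probability
0.25/0.25/0.50 (signaling edges signed 50/50), TF–target edges
excitatory/inhibitory 50/50. Every realization has exactly
`30·20 + 30·2 = 660` directed links, and the distinct-target count
concentrates near the occupancy expectation
`1000(1 − 0.98³⁰) ≈ 454`.

`simulate_grn_data()` simulates the benchmark profiles (one initial
condition per model; non-converged models dropped) with
`protein_noise = 1`, `perturb_regulons()` corrupts the database by
replacing 0/5/10/15 of each TF's 20 targets (0–75%) with non-interacting
pool genes, and `run_activity_benchmark()` scores recovery as the median
over perturbed databases of the TF-averaged absolute Spearman correlation
between inferred and simulated activity. Absolute values are the right
scale because a single-condition design leaves one global sign per TF
unidentified. Network recovery is scored by precision–recall over the
MI-ranked undirected TF pairs (`network_pr()`; undirected because MI is
symmetric), and regulon recovery by the Jaccard index of MI-ranked top-20
target sets (`regulon_recovery_mi()`).

The test suite runs this benchmark at desk scale — one 50-model ensemble,
20 perturbation repeats per level, occupancy over 200 generator seeds —
sizes chosen so the whole suite characterizes the distributions it asserts
about while staying quick to run; the generator defaults themselves are
never scaled down.

**What passing does and does not show.** The generator emulates a
hierarchical regulon-structured GRN with decoupled activity and
expression; it does not emulate measurement noise models (microarray vs
RNA-seq), batch structure, correlated regulons from TF families, or
missing-data patterns of real curated databases. Recovery on this
benchmark demonstrates internal consistency of the estimator under its own
generative assumptions, not performance on any particular real dataset.

## Numerical and design choices

- Symbol matching is case-sensitive everywhere; `read_gmt(casefold =)` is
  the explicit opt-in normalizer (human symbols are upper-case, mouse
  title-case).
- Regulons need at least `min_targets = 5` usable genes (below that the
  two-module split and the weighted average are not meaningful); the
  benchmark runner lowers this to 2 because its regulons are small by
  construction.
- All filter boundaries are strict inequalities, so degenerate
  equal-distance or equal-correlation sets pass through unchanged.
- Scheme selection scores correlations over *retained* targets only:
  filtered genes were judged unrelated to the TF, so they should not vote.
- `rank_genes()` breaks score ties lexicographically; results are
  invariant to input row order.
- BH is used wherever "adjusted p-value" appears.
- Every stochastic entry point takes an explicit `seed`; ensembles are
  byte-identical at a fixed seed, and knockdown/clamp runs pair with their
  baselines.

## Limitations

- Activity is linear in target z-scores; strongly nonlinear or switch-like
  target responses are only captured through the ranks entering Spearman
  correlations.
- Non-differential TFs get no automatic activity sign; the Fisher-overlap
  partner ranking is an aid to manual curation, not a replacement
  (protein–protein interaction evidence stays outside this package's
  scope).
- The MI estimator is the plug-in on rank bins; at very small sample
  counts (< ~15) its bias is material, and the default bin count floors at
  2 for that reason.
- The ensemble simulator explores random kinetics on a fixed topology; it
  is a robustness probe, not a fit of kinetic parameters to data.
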