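---
title: "Methods: module-connectivity hub prioritization and its validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: module-connectivity hub prioritization and its validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(modhub)
```

## The model

A functional network over genes $1..N$ carries, for each unordered pair, a
posterior probability in $[0,1]$ that the two genes participate in a common
cellular process in the cell type of interest. Given a module $M$ of $n$
genes, the module-connectivity z-score of gene $g$ is

$$ z_g = \frac{\bar x_g - \mu_g}{\sigma_g / \sqrt{n}} $$

with $\bar x_g$ the mean edge weight between $g$ and the members of $M$
($g$ excluded if it is a member, so $n$ is the *effective* module size),
and $\mu_g$, $\sigma_g$ the mean and sample standard deviation (divisor
$N-2$, over the $N-1$ values) of $g$'s weights to all other genes.
Self-edges are stored as 1 by convention and excluded from every statistic:
self-connectivity is not a defined quantity in this kind of network.

The interpretation is a one-sample standardization: if a module of $n$
genes were drawn at random from $g$'s partners, the mean weight to it would
have expectation $\mu_g$ and, for modules drawn independently of $g$'s
weights, standard deviation close to $\sigma_g/\sqrt{n}$ (exactly so for
draws with replacement; the without-replacement correction is
$\sqrt{(N-1-n)/(N-2)}$, negligible at $n \ll N$). $z_g$ therefore measures
how many such null standard errors $g$'s observed module connectivity sits
above its genome-wide habit. The acceptance suite verifies this calibration
directly: over 1,000 random modules on an i.i.d.-edge network the mean of
$z$ is statistically indistinguishable from 0 and the empirical SD of
$\bar x_g$ matches $\sigma_g/\sqrt{n}$ within 10%.

**The denominator.** The score is also meaningful with denominator
$\sigma_g/n$, and published descriptions of statistics of this family are
not always typographically unambiguous between the two. We default to
$\sigma_g/\sqrt{n}$ because only that choice is scale-free across module
sizes and matches the null-calibration property above; `z_denominator =
"sd_over_n"` selects the other reading, and every ranking, report and
rendered summary records which one was used. The two differ only by the
factor $\sqrt{n}$, so rankings against a single module are identical under
either.

**Assumptions.** The score assumes the genome-wide weight distribution of
$g$ is a meaningful null for its module connectivity; it is a marginal,
per-gene standardization, not a joint model of the network, and it is
invariant under affine rescaling $w \mapsto aw + b$ ($a>0$) of all weights
(tested to $10^{-9}$).

## Ranking and queries

`rank_module_hubs()` scores every network gene (module members included by
default, each against the module minus itself — whether a published
analysis of this kind scored members is usually unstated, so both
behaviours are exposed via `include_module_members`). Output order is $z$
descending with ties broken by gene identifier; ranks are competition ranks
("1, 2, 2, 4"), so output is deterministic across platforms. Genes with
$\sigma_g = 0$ (a constant-weight row) have no defined $z$; they are
flagged `degenerate_sigma` and kept, unranked, at the bottom of the table
rather than silently scored 0 — a constant row is a pathology worth
surfacing. Module members absent from the network are dropped with a
warning; an effective module smaller than `min_module_size` (default 3,
configurable) is an error for the single-gene call and a per-gene flag in
the ranking, which never aborts wholesale.

`pair_connectivity_rank()` answers the converse query: the weight between
a query and a target gene, and the competition rank of that weight among
all $N-1$ genes' weights to the target.

## Validation statistics

Given a DESeq2-shaped table for a perturbation of a candidate hub:

- **DEG connectivity test** (`deg_connectivity_test`): one-sided Wilcoxon
  rank-sum comparing hub edge weights of significant vs non-significant
  genes, alternative "DEGs are more connected". The exact null distribution
  is used when both groups have at most 20 members (`stats::pwilcox` when
  the pooled weights are tie-free; full enumeration of group assignments
  when ties are present and the assignment count is below $2\times10^5$);
  otherwise the normal approximation with tie and continuity correction.
  The method actually used is recorded in the result. On tie-free instances
  with a dozen observations the approximation tracks the exact tail within
  0.01; heavily tied tiny instances can deviate by ~0.02–0.03, which is why
  the switch favours enumeration there.
- **Set overlap** (`fisher_overlap`): one-sided hypergeometric upper tail
  $P(X \ge \text{overlap})$ — only the enrichment alternative is exposed,
  since that is the only claim these analyses make. The odds ratio is the
  sample odds ratio; the 0.5 Haldane correction is applied (and flagged)
  only when a margin cell is zero. `signed_overlap` stratifies two DEG
  tables by sign of log2 fold change (up∩up, down∩down), runs the
  combined test on the full DEG sets, and reports genes significant with
  opposite signs as discordant. Whether a reported "overlap" p-value in a
  figure legend refers to the combined or the per-direction test is often
  ambiguous; this package reports all three.
- **Rank-enrichment curve** (`rank_enrichment_curve`): the tested universe
  ranked by hub connectivity; at cutoff $k$ the fold is
  $(\text{hits}_k/k)/(m/N)$ — the precision among the top $k$ over the DEG
  prevalence. This precision/prevalence fold is a declared convention (the
  exact normalization behind published curves of this type is rarely
  stated); it is 1 in expectation at every $k$ under random DEG placement
  (verified by a 1,000-rep Monte-Carlo in the acceptance suite) and exactly
  1 at $k = N$ by construction. Every rank is evaluated for universes up to
  5,000; 200 log-spaced cutoffs otherwise (plot fidelity at small $k$ is
  what matters, and small-$k$ cutoffs are dense in log space).

**Thresholding.** Significance defaults to `padj < 0.05` (Benjamini–
Hochberg, via `stats::p.adjust` behind `bh_adjust()`); the nominal-p
fallback (`threshold = "pvalue"`) exists for weak-signal arms but must be
requested explicitly. Genes with a missing adjusted p are excluded from the
universe, not treated as non-significant: an untested gene in the null
group would bias the rank-sum test toward rejection.

## The simulator

`generator_params()` / `simulate_study()` produce the three objects the
pipeline consumes, with known ground truth:

- **Network**: all unordered pairs draw Beta-distributed weights
  (respecting the $[0,1]$ posterior semantics): background Beta(1, 9)
  (mean 0.1), module-internal pairs Beta(4, 6) (mean 0.4), hub–module
  pairs Beta(6, 4) (mean 0.6). Defaults: 2,000 genes, 100-gene module.
  These sizes and separations give a clearly planted but not trivially
  separable module: module members themselves score high z, and the hub
  must beat them through its stronger module connection. The hub sits
  *outside* the module by default — a regulator of, not a member of, the
  module — configurable via `hub_in_module`.
- **DEG table**: gene $g$ is differentially expressed with probability
  $\mathrm{logit}^{-1}(\beta_0 + \beta_1 w_{hub,g})$, defaults
  $\beta_0 = -3$, $\beta_1 = 6$ (background genes ≈ 0.08, strong partners
  ≈ 0.65). DE genes draw $p = 10^{-U(2,8)}$ and $|\log_2 FC| \sim N(2,
  0.5)$ with random sign; null genes draw uniform $p$ and
  $N(0, 0.25)$ fold changes; `padj` is the BH adjustment. $\beta_1 = 0$ is
  the calibration null in which DE labels are independent of connectivity.
  P-values are drawn directly rather than simulated from counts: the
  pipeline consumes differential-expression *output*, and a count
  simulation would re-implement the upstream testing this package
  deliberately does not do.
- **Paired tables**: two noise realizations of the same DE labels and
  signs, the second attenuated (default: half of the DE genes reverted to
  null), emulating a weaker in-vivo arm against an in-vitro arm.

One integer seed governs everything through fixed sub-streams
(`stream_seed`: network / labels / noise / attenuation), so redrawing the
noise never perturbs the network.

**What the simulator does not emulate**: count overdispersion and
library-size effects (absorbed into the drawn p-values), correlated DE
among co-regulated genes beyond the hub-connectivity link, multiple
overlapping modules, weight distributions with atoms at 0, and gene-symbol
messiness. Passing tests therefore demonstrate correctness of the
statistics and recoverability under the planted model — not that any
particular real network satisfies that model.

## Numerical choices

- $\sigma$ uses the sample divisor; at genome scale the difference from the
  population divisor is negligible and the convention is recorded here.
- Degeneracy is declared at $\sigma < 10^{-14}$ (absolute, on weights in
  $[0,1]$).
- Brute-force oracle equivalence of the vectorized scorer is asserted to
  $10^{-12}$; discrete tails (Fisher, exact Wilcoxon) to $10^{-12}$ against
  full enumeration.
- Edge-list serialization uses 6 decimals (posterior-probability
  precision); the dense dialect uses 17 significant digits and round-trips
  doubles exactly. Edge lists omit zero-weight pairs, which read back as 0.
- Tie-breaks are everywhere by gene identifier, ascending, making every
  output byte-reproducible (verified end-to-end modulo the report
  timestamp).

## Pipeline and reporting

`run_pipeline()` takes one YAML/JSON (or list) config naming either
generator parameters or input paths, validates it before any computation,
and runs simulate/load → score → validate → report, writing `ranking.tsv`,
`curve.tsv`, `report.json`, `report.md`, `truth.json` (simulated runs) and
a log with one checksummed line per stage. The resolved config — every
default materialized, seed included — is embedded in the report, so the
report alone suffices to re-run identically. If no hub is configured, the
top-ranked gene is carried into validation. The several validation
p-values in one report are deliberately *not* corrected across each other;
each is reported raw with its settings, and the rendered report says so.

## Test scales

The suite exercises: exhaustive Fisher enumeration for universes up to 30;
Wilcoxon assignment enumeration up to 12 observations; brute-force z
recomputation on networks up to 50 genes; planted-hub recovery over 100
replicate 2,000-gene studies (≥ 95 required); z-calibration over 1,000
random modules on a 400-gene i.i.d. network; type-I calibration of the DEG
test over 2,000 null replicates on one fixed default network (rejection
rate required in 4–6% at nominal 5%, Kolmogorov–Smirnov distance from
uniform < 0.05) — the labels, not the network, carry the null, so a fixed
network is the efficient design; and 1,000-rep Monte-Carlo nulls for the
enrichment curve.

## Limitations

The z-score is marginal per gene: it does not model dependence between
genes' scores, and ranking significance should be judged against the
planted-truth benchmarks, not against a per-gene normal tail. Only
enrichment ("greater") alternatives are provided for the overlap tests. No
gene-identifier mapping is performed — inputs must share a namespace. The
network is taken as given; building one, and calling differential
expression from reads, are out of scope.
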