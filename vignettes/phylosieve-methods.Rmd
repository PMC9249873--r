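---
title: "Curation and robustness methods in phylosieve"
author: "phylosieve maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Curation and robustness methods in phylosieve}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phylosieve)
```

# Scope

phylosieve implements the curation and robustness layer of a phylogenomic
supermatrix study of deep divergences: per-gene quality screening,
partitioned concatenation with occupancy filters, per-site rate
categorisation with fast-site stripping, quartet-frequency internode
certainty, and the approximately unbiased (AU) topology test. Maximum
likelihood tree *search*, profile mixture models (C60/PMSF internals) and
Bayesian inference are deliberately out of scope: the package consumes
gene alignments, trees and per-site log-likelihood tables, and produces
curated matrices and robustness statistics around them.

Everything is validated end-to-end against a seeded synthetic-data
generator with ground-truth labels, so the pipeline is testable without
any downloads.

# The substitution model

All likelihood machinery runs on a time-reversible amino-acid model: a
symmetric exchangeability matrix $S$, stationary frequencies $\pi$, rate
matrix $Q_{ij} = s_{ij}\pi_j$ with rows summing to zero, scaled so that
$\sum_i \pi_i(-q_{ii}) = 1$ (branch lengths in expected substitutions per
site). Rate heterogeneity across sites uses the discrete-gamma
approximation: $K$ equal-probability categories, category $k$ carrying
the conditional mean of its quantile bin of a Gamma$(\alpha,\alpha)$
density, renormalised so the mean rate is exactly 1. The closed form uses
the incomplete-gamma identity
$\int_a^b x\,f_{\alpha,\alpha}(x)\,dx = F_{\alpha+1,\alpha}(b)-F_{\alpha+1,\alpha}(a)$.
For $\alpha = 1, K = 4$ this gives $(0.1370, 0.4768, 1.0000, 2.3863)$,
verified in the tests against numerical integration.

Two exchangeability sets are built in: Poisson (all equal, uniform
frequencies -- analytically convenient, the default for simulation and
self-tests) and the Le--Gascuel (LG) empirical rates with either LG or
empirical (`+F`, counted from the data) frequencies, the practical
default for real matrices. The profile-mixture aspect of the model used
in large empirical studies is intentionally replaced by this
single-profile model: the reproducible object here is the
*categorisation* of sites, not model fidelity.

Site likelihoods come from Felsenstein pruning over a pattern-compressed
matrix, with per-node scaling against underflow and a symmetric-form
eigendecomposition of $Q$ for transition matrices. Gaps and unknowns are
fully ambiguous (partial likelihood 1 in every state). Impossible sites
are guarded with a $-10^{300}$ sentinel that is never exponentiated
without a shift. The engine is tested to $10^{-10}$ against brute-force
enumeration over all internal-state assignments on trees of up to 5
leaves, and for invariance under re-rooting.

# The synthetic study generator

`simulateStudy()` emulates the input of a deep-phylogenomics study: many
gene alignments sampled along one species tree, heterogeneous taxon
occupancy, gamma rate heterogeneity, and the classic failure modes that
gene screening is meant to catch. Choices, fixed once:

* **Species tree.** A pure-birth (Yule) ingroup clade rescaled to height
  0.5 substitutions/site, plus an outgroup clade of half that height
  attached on a long stem (root at $1.5\times$ the ingroup height). The
  long outgroup stem mirrors the situation where the outgroup is a
  distant sister supergroup. Default 16 taxa, 4 of them outgroup -- large
  enough for clade structure, small enough that a hundred gene trees cost
  seconds.
* **Genes.** Default 50 genes of 500 sites (tests and the acceptance
  experiments state their own sizes where a property needs more data).
  Each gene runs on the substream `seed + gene index`, so extending a
  study never perturbs existing genes.
* **Rates.** $\alpha = 1$, $K = 4$ by default; each site carries a known
  true category, the label downstream recovery is measured against.
* **Artifacts**, applied per gene with the configured probabilities and
  recorded in a `GroundTruth` table:
  * *masked*: taxon deleted (drives occupancy heterogeneity; default
    rate 0.1 per taxon per gene);
  * *long branch*: the taxon is resimulated from its parent node with
    its terminal branch multiplied by 10. Only lineages whose elongated
    branch would be an unambiguous outlier of the true ingroup cohort
    (1.5$\times$ the Tukey fence, margin for gene-tree estimation noise)
    are eligible: elongating a near-zero twig produces a branch inside
    the cohort's normal range, and a `long_branch` label that does not
    describe a long branch would be unsound ground truth. Real
    long-branch lineages are lineage-level fast evolvers, which is what
    the eligibility rule emulates.
  * *contaminant*: the taxon's sequence is replaced by a wrong-source
    sequence -- evolved onward from a random outgroup tip until it sits
    $2\times$ the tree height from the root. Contamination in real
    transcriptome studies comes from other organisms on the outgroup
    side of the tree, so the copy nests inside the outgroup clade, which
    is exactly the signature the anomaly screen looks for.
  * *paralog*: an extra copy of the taxon (label suffix `__2`) seeded
    from a donor in a different subtree and evolved a further 0.5
    substitutions/site, emulating an out-paralog that violates
    orthology.

The generator does **not** simulate indels (gaps arise only from
masking), codon structure, heterotachy, alignment error or compositional
bias. Passing tests therefore demonstrate that the pipeline's rules do
what they claim under the model they assume -- not that real data are
free of the failure modes the generator omits.

# Gene screening

Gene trees are neighbor joining on pairwise maximum-likelihood distances
under the rate model (each pair a 1-D likelihood optimisation; the
default engine maximises on a fine log-spaced grid with parabolic
refinement, agreeing with golden-section search to $\sim 10^{-3}$).
Bootstrap supports come from site resampling. Screening then applies
three detectors and a decision rule:

* **Long branches.** An ingroup taxon is flagged when its terminal
  branch exceeds $Q_3 + 1.5\,\mathrm{IQR}$ of the ingroup terminal
  branch lengths (type-7 quantiles). The pooled fence is the default; a
  leave-one-out variant exists but over-flags in small per-gene cohorts.
  Duplicate sequence copies are not taxa and never join the cohort.
* **Anomalous grouping.** With the tree read relative to the outgroup,
  a taxon is anomalous when the smallest clade containing it and at
  least one outgroup member has bootstrap support above 90 and contains
  no other ingroup member; or when it nests *inside* a single foreign
  expected clade (part of that clade outside the containing clade) at
  the same support level. The nesting requirement matters: a taxon
  sister to an intact foreign clade may simply be in its true position,
  and flagging it would reject clean genes wholesale when a clade has a
  single sampled representative.
* **Paralogy.** Any taxon with $\ge 2$ sequence copies is flagged;
  copies forming a single clade (cherry) are treated as putative
  alleles/isoforms and do not drop the gene by default (strict mode
  available); dispersed copies are the paralogy sign.

A gene is dropped iff it has $\ge 3$ distinct non-whitelisted
long-branch taxa, or any anomaly, or a paralogy sign. The whitelist
exempts known long-branch lineages that a study keeps deliberately. On
artifact-free synthetic gene sets $\ge 95\%$ of genes are kept; injected
artifacts are recovered with sensitivity $\ge 0.9$ (long branches,
paralogs) and $\ge 0.8$ (contaminants, which need bootstrap support
above 90 to fire and so sit closer to the rule's edge).

# Supermatrix assembly and filters

Concatenation takes the union of taxa, gap-fills absent blocks and
records 1-based inclusive partitions. Filters run in the stated order:
taxa with *over* 80% missing characters first (strict inequality -- a
row at exactly the threshold stays), then constant sites (all
non-missing residues identical; switchable to a strict no-missing
definition) and sites with more than 50% missing data, evaluated on the
post-taxon-filter matrix. Both `-` and `X` count as missing by default
(`countX = FALSE` restores a gap-only reading); removals are logged
against original coordinates so any reduced matrix can be audited or
replayed. The tests pin the boundary semantics, the precedence of
"missing" over "constant" in the log, order sensitivity, idempotence
and exact width conservation on an 824-gene concatenation.

# Site rates and fast-site stripping

Given a fixed guide tree, each site's likelihood is computed under every
category rate; the posterior over categories uses the uniform prior
(equal-probability bins), the assigned category is the posterior argmax
(ties to the slower category) and the posterior mean rate is recorded
per site. Stripping removes all sites assigned to the `n` fastest
categories and remaps partitions. With $K = 16$ and 6 categories
stripped, close to $6/16 \approx 38\%$ of sites are removed on gamma
data -- the equal-probability-bin arithmetic behind that fraction. On
simulated data (16 taxa, 5000 sites, $K = 4$, $\alpha = 1$) the argmax
recovers the true category more than twice as often as chance and the
posterior mean rate correlates with the true rate at Spearman
$\rho > 0.8$; stripping monotonically lowers the mean retained rate.

Caveats for empirical use: published studies rarely state whether their
rate categories came from a gamma discretisation or a free-rate model --
gamma is adopted here with `K` configurable; and the guide tree is taken
as fixed (no branch or $\alpha$ re-optimisation during categorisation).

# Quartet internode certainty

For every internal edge of a binary reference tree, a quartet takes one
leaf from each of the four incident subtrees; each evaluation tree
containing all four leaves votes for the resolution it induces
(node-count four-point criterion; polytomies abstain). Trees missing a
leaf simply do not vote -- the missing-taxon correction that makes the
score usable with patchy bootstrap or gene trees. Edges with at most
10,000 quartets are enumerated exhaustively; larger ones are sampled
(default $m = 1000$, seed-reproducible). The score is the entropy-based
internode certainty over the three resolutions,
$\mathrm{IC} = 1 + \sum_i p_i \log_3 p_i$, sign-flipped when the
reference resolution is not the strict majority: 1 means unanimity, 0
maximal conflict, negative values a dominant conflicting resolution. Of
the published variants of quartet-based IC only this equally-weighted
pooled-count flavour is implemented. Tests check exhaustive counts
against a brute-force four-leaf-pruning oracle, sampled against
exhaustive proportions within binomial error, and the score against
hand-computed values.

# The AU test

Input is a per-site log-likelihood table (read from `.sitelh`-style
text or computed internally). The multiscale RELL bootstrap resamples
site indices at ten scale factors $r \in \{0.5, \dots, 1.4\}$ (no
refitting; replicate log-likelihoods are sums of resampled per-site
values), with exact ties splitting the replicate's credit equally. The
bootstrap proportions are mapped to normal quantiles and fitted by
one-step weighted least squares to $z(r) = d\sqrt{r} + c/\sqrt{r}$, with
weights $B\,\phi(z)^2 / (\mathrm{BP}(1-\mathrm{BP}))$; the AU p-value is
$1 - \Phi(d - c)$, and the plain $r = 1$ proportion is reported as
p-RELL for transparency. Proportions are clamped to
$[1/2B,\,1 - 1/2B]$; a topology clamped at the same bound on every scale
is degenerate and gets the corresponding boundary p-value with a flag.
One-step WLS (rather than iterative reweighting) is a documented
simplification -- stable at $B = 10^4$. A topology is not rejected iff
$\mathrm{p\text{-}AU} \ge 0.05$.

**Calibration.** The fit recovers known $(d, c)$ from noisy generated
curves within 0.05, and the RELL proportions match an independently
coded naive resampler. For the type-I error of the whole pipeline the
calibration experiment uses a *weak-signal null*: quartet data generated
under a tree whose internal edge (0.001 substitutions/site at 2000
sites) sits at the edge of resolvability, with the true tree among three
fixed candidate topologies. In this noise-dominated regime -- the regime
short deep internodes actually occupy -- the measured rejection rate of
the true tree at $\alpha = 0.05$ is $\approx 0.03$ and stable as the
edge shrinks further. Two alternative designs were examined and set
aside: candidates branch-optimised on star-tree data place the truth at
a three-cone apex, where the AU test is intrinsically conservative
(empirical rate $\le 0.01$ here, with the machinery itself exactly
calibrated on a flat-boundary Gaussian toy); and a strongly resolved
edge makes rejection of the truth vanishingly rare, which measures
nothing. Power is checked separately: with a clearly resolved edge
(0.03 at 5000 sites) the true resolution survives testing in $\ge 95\%$
of runs while the alternatives are rejected.

# Numerical and degenerate-input policy

* Zero-length branches, identical sequences and constant columns are
  legal everywhere; impossible likelihoods hit the sentinel, never
  `-Inf` arithmetic.
* Saturated pairwise distances cap at 10 substitutions/site with a
  warning; NJ's negative branch estimates clamp to 0.
* Argmax ties anywhere (categories, RELL winners) resolve
  deterministically (lower index / equal credit).
* Every stochastic routine takes a seed and restores the caller's RNG
  state; fixed seed means byte-identical output.
* Quantiles are type-7 (linear interpolation) throughout.

# Problem sizes used in validation

The shipped tests and the acceptance script run: enumeration oracles on
4--5-leaf trees; site-rate recovery on 16 taxa $\times$ 5000 sites;
screening sensitivity on 100 genes of 1000 sites (16 taxa); IC fixtures
on 6--8 leaves with $m = 10^4$ sampled quartets; AU calibration on 200
simulated datasets of 2000 sites at $B = 1000$, plus 40 power runs of
5000 sites. These sizes give stable estimates for the properties being
checked while keeping a full validation run in the minutes range on one
core.

# Known limitations

* NJ on model distances stands in for full ML gene-tree search; it is
  accurate on clean simulated genes (RF 0 to the truth in $\ge 90\%$ of
  5000-site genes) but weaker than ML on short or highly heterogeneous
  genes.
* The anomaly screen formalises only the stated rules; a study's manual
  inspection of alignments cannot be reproduced. A sequence-length
  filter is available (`min-ungapped` style screening) but off by
  default, since no quantitative criterion is published.
* The single-profile model understates site-specific compositional
  heterogeneity; rate categorisation inherits that approximation.
* IC is reported in one variant only; scores from other variants are
  not comparable number-for-number.
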