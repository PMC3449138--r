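---
title: "Site-model selection profiles and ligand-receptor coevolution with coevsel"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Site-model selection profiles and ligand-receptor coevolution with coevsel}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coevsel)
```

## The question and the approach

Ligands and their receptors are expected to evolve in a correlated way: a
codon substitution that changes a binding interface on one side creates
selection pressure on the other. `coevsel` operationalises this idea for
gene families such as the relaxin-family peptides (RLN/INSL) and their
G-protein-coupled receptors (RXFP), where teleost genomes carry more
receptor than ligand genes and the pairings are largely unknown. The
package (i) quantifies, per gene, the proportions of codon sites under
purifying, neutral and positive selection, (ii) compares those
three-component *selection profiles* between hypothesised ligand-receptor
pairs, (iii) tests for lineage-specific (branch-site) selection and maps
selected codons onto receptor domains, and (iv) integrates relative
expression from qPCR as independent coexpression evidence. All inputs can
be simulated by the package's seeded generators, so the entire chain is
testable without sequence downloads.

## Codon model

The engine is a Goldman-Yang-style codon substitution model over the 61
sense codons (standard code, T<C<A<G order). The instantaneous rate from
codon $i$ to $j$ is zero unless they differ at one position, and otherwise
proportional to $\pi_j$, multiplied by $\kappa$ for transitions and by
$\omega = d_N/d_S$ for nonsynonymous changes. Equilibrium frequencies
$\pi$ come from the F3x4 position-specific nucleotide model by default
(`f3x4_frequencies()`; empirical F61 is available). The likelihood of an
alignment on a tree is computed by Felsenstein pruning with per-node
rescaling; missing or ambiguous codons contribute a partial likelihood of
one over all states, so site indexing is preserved for posteriors and
domain mapping.

Selection heterogeneity across sites is a mixture over $\omega$ classes:

* **M0** — one $\omega$ for all sites (used to estimate branch lengths and
  $\kappa$).
* **M7** — $\omega \sim \mathrm{Beta}(p, q)$ on $(0,1)$: purifying/neutral
  variation only.
* **M8** — with probability $p_0$ the M7 beta, else an extra class at
  $\omega_s \ge 1$: admits positive selection.
* **M8a** — M8 with $\omega_s = 1$ frozen: relaxation of constraint, no
  true positive selection.
* **Branch-site model A** — four classes whose $\omega$ differs between
  *foreground* branches (tagged `#1` in the Newick input) and the
  background; the null fixes the foreground $\omega_2$ at 1.

A gene is called under positive selection only when M8 beats **both** M7
(df 2) and M8a (df 1) in likelihood-ratio tests at the chosen $\alpha$; if
only the M7 comparison is significant the verdict is *relaxation*. Sites
driving an M8 or branch-site signal are located with Bayes Empirical Bayes
(BEB) posteriors, reported at the conventional 0.9 (positive) and 0.8
(suggestive) thresholds.

## Numerical and statistical choices

**Rate scale.** Every class rate matrix is divided by the mean rate at
$\omega = 1$ (same $\kappa$ and $\pi$), so branch lengths are expected
substitutions per codon under neutrality. One shared scale per model keeps
the relative speeds of the site classes correct, and it makes each class's
per-site likelihood a function of $(\kappa, \omega)$ only — the fitting
layer caches these columns across optimizer iterations, which is why
perturbing a mixture proportion costs no pruning at all. The standalone
`build_rate_matrix()` keeps the textbook unit-mean-rate normalisation.

**Discretisation.** Beta mixtures use $K = 10$ equal-probability
categories at the quantile midpoints $(2k-1)/2K$; the likelihood is stable
in $K$ (the test suite checks $|\ell_{K=10} - \ell_{K=50}| < 0.5$ on a
100-codon fixture). Category $\omega$ values are floored at $10^{-6}$ so
every class can explain nonsynonymous variation and mixture likelihoods
stay finite over the whole parameter space.

**Optimisation.** Bounded L-BFGS-B on transformed parameters (log for
$\kappa$, $\omega$, beta shapes and $\omega_s - 1$; logit for
proportions), with three restarts by default (warm start plus seeded
random draws). Branch-length blocks of the gradient are analytic (upward
and downward pruning recursions in the C++ kernel); the few mixture
parameters use forward differences. $\kappa$ and branch lengths are
estimated jointly under M0 and then fixed for the site-model fits — in
our experiments $\kappa$ is nearly orthogonal to the $\omega$-distribution
parameters, and refitting it per model multiplies runtime without changing
the tests (a joint refit is available via `fix_kappa = FALSE` /
`fix_branch_lengths = FALSE`). M8a is warm-started from M7 and M8 from
both, so the nested-likelihood ordering
$\ell_{M8} \ge \ell_{M8a}, \ell_{M7}$ holds by construction; any residual
negative LRT statistic (round-off) is clamped to zero.

**Branch-site nuisance handling.** The branch-site LRT is acutely
sensitive to how branch lengths are treated, because a single foreground
stem's length can absorb — or fake — the $\omega_2$ signal. Development
experiments showed that lengths fixed from M0 destroy power, while lengths
from a foreground-aware branch model inflate the type-I error severalfold
(partly through a degenerate $p_0 + p_1 \to 0$ alternative in which
$\omega_2$ acts as a branch-wide rate multiplier). The shipped protocol
estimates branch lengths jointly under the branch-site *null* model and
fixes them for both fits. One identifiability detail is essential: at a
bifurcating root only the *sum* of the two root-adjacent branch lengths is
identifiable under a reversible model (the pulley principle — the reason
codeml insists on unrooted trees), so joint fits tie those two edges to a
single total-length parameter split evenly. Without the tie the optimizer
splits the sum arbitrarily; a collapsed root-adjacent foreground stem both
opens the degenerate $\omega_2$ escape on null data and erases power on
selected data. With it, the test is cleanly conservative (0/20 null
rejections at the fixture scale) and powerful (19/20 rejections at
$\omega_2 = 3$ on 25% of sites). The alternative fit is warm-started both
at the $\omega_2 = 1$ boundary and away from it, because the boundary is a
near-stationary trap for the optimizer.

**LRT reference.** $2\Delta\ell$ is compared to $\chi^2_{df}$ with df the
difference in free-parameter counts (M7 vs M8: 2; M8a vs M8 and
branch-site: 1), the plain reference of the standard protocol. Because the
nulls sit on the boundary of the alternatives, this is conservative; the
50:50 $\chi^2_0{:}\chi^2_1$ mixture is available via
`lrt(..., boundary_mixture = TRUE)` but off by default.

**BEB.** Posteriors are averaged over a uniform prior grid on the
parameters governing the positively selected class — for M8, $p_0 \in
(0,1)$ and $\omega_s \in (1,11)$; for branch-site A, $p_0+p_1$ and
$p_0/(p_0+p_1)$ on $(0,1)$ and $\omega_2 \in (1,11)$ — with 10 midpoints
per axis and all other parameters at their MLEs, each grid point weighted
by its marginal data likelihood. A one-point grid reproduces the
naive-empirical-Bayes (NEB) posterior exactly, which the tests assert
bit-for-bit.

**Profiles.** The paper-style three-way classification of sites is not
uniquely defined by the models, so it is explicit and configurable: a site
is *positive* when its posterior probability of the $\omega > 1$ class
exceeds 0.5, else *neutral* when its posterior mean $\omega$ lies in
$[0.9, 1.1]$, else *purifying*. Profile concordance between a ligand and a
receptor is the mean over the three classes of the perpendicular distance
$|x - y|/\sqrt{2}$ to the diagonal of the XY-plot; the package also scores
cross-lineage concordance (Euclidean distance between a pair's XY points
in two lineages) and combines concordance with qPCR coexpression
($w_1(1 - d) + w_2 \rho$, Spearman on log fold changes, sexes averaged)
to rank candidate receptors.

**Expression.** The $\Delta\Delta C_T$ chain follows the usual assumptions
(perfect doubling per cycle): per replicate, $\Delta C_T$ against the
reference gene; the calibrator is the mean $\Delta C_T$ over all genes in
the same (tissue, sex, replicate) block; fold change $2^{-\Delta\Delta
C_T}$ with replicate means and standard errors. Cross-tissue comparison
multiplies folds by the block's total-RNA yield relative to the mean
yield. Undetected wells (Ct above the 40-cycle ceiling) are flagged and
excluded; a zero-variance expression vector yields a flagged coexpression
of 0 rather than an error so ranking can proceed.

## What the simulators emulate — and what they do not

`simulate_alignment()` draws a class per site, a root codon from $\pi$,
and evolves along the tree with the class rate matrix (foreground
$\omega$ on flagged branches), returning true class labels.
`simulate_coevolving_pair()` builds two genes from a shared three-class
profile (default $\omega$ = 0.1, 1, 3) perturbed independently by
$\pm\varepsilon$, and `simulate_ct_table()` inverts the
$\Delta\Delta C_T$ chain exactly at zero noise. The generators capture the
features the inference uses — $\omega$ mixtures, branch-site
heterogeneity, correlated class proportions, log-linear Ct — but not
indels and alignment error, codon-usage or GC evolution, recombination,
saturation at deep divergences, or qPCR efficiency differences between
primer pairs. Green tests therefore demonstrate correctness of the
inference machinery under the model class, not robustness to the ways real
relaxin-family alignments violate it.

## Fixture scales

Problem sizes were chosen once so the full suite runs on a single CPU in
minutes: site-model calibration at 8 taxa x 300 codons (25 null
replicates) and power at 400 codons (15 replicates); M0 recovery at
$\omega \in \{0.2, 1, 2\}$, 20 replicates each; branch-site calibration
and power at 8 taxa x 800 codons (an RXFP1/2-scale CDS), 20 + 20
replicates, on a balanced tree whose foreground is one clade stem of 0.5
neutral substitutions per codon; the coevolution monotonicity check at 6
taxa x 500 codons with common random numbers across jitter levels (the
estimation-noise floor of the concordance distance scales as
$1/\sqrt{n}$, and at short gene lengths it hides the jitter signal); and the
end-to-end toy study (three ligand-receptor pairs, one truly coevolving)
at 6 taxa x 150 codons over 10 seeds.

## Known limitations

* The branch-site test concentrates its information on the foreground
  branch(es); with a short foreground stem or few sites its power drops
  quickly, so "not significant" on real single-gene data is weak evidence
  of absence.
* The three-way profile depends on configurable thresholds; comparisons
  between genes are meaningful because the same rule is applied
  everywhere, but absolute proportions shift with the neutral band.
* The concordance statistic is descriptive — no null distribution is
  attached to it, so rankings order hypotheses rather than test them.
* F3x4 frequencies are estimated per gene from the alignment itself;
  very short ligands (~50 codons) make both frequencies and profiles
  noisy, which is visible in the toy study's ligand-side estimates.

## A minimal worked run

```{r example, eval = FALSE}
toy <- simulate_toy_study(seed = 1)
sel <- run_selection(toy$genes, tree = toy$tree,
                     options = list(n_restarts = 2, seed = 1))
rel <- delta_delta_ct(toy$expression)
report <- run_coevolution(sel, toy$hypotheses, expression = rel)
report$pairs
```

The README shows the printed output of this exact run; the repository's
`analysis/` scripts run the same steps over files on disk, writing every
table under `results/`.
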