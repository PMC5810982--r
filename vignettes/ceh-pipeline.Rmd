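---
title: "Conserved extended haplotypes of the MHC: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Conserved extended haplotypes of the MHC: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cehtools)
```

## The problem

The major histocompatibility complex (MHC) on chromosome 6p21.3 carries the
strongest common-variant associations with several immune-mediated diseases,
multiple sclerosis prominently among them. Those associations are usually
reported for single HLA alleles (e.g. DRB1\*15:01), but MHC alleles rarely
travel alone: despite recombination hotspots, specific allele combinations
spanning more than 2.7 Mb — *conserved extended haplotypes* (CEHs) — persist
at high frequency. `cehtools` implements a complete analysis chain for
asking whether disease risk attaches to an allele, to a Class II motif, or
to the full extended haplotype it rides on.

A CEH here is the ordered tuple of alleles at HLA-A, -C, -B, -DRB1, -DQB1
plus an 11-SNP haplotype of the Class II region treated as one
multi-allelic locus, written
`A*03:01~C*07:02~B*07:02~DRB1*15:01~DQB1*06:02~10110100010`. The named
SNP haplotypes of that window (`a1`, `a2`, ...) and the Class II motifs
they travel with are tabulated in `snp_haplotype_table()`; `0` denotes the
major and `1` the minor allele at each site.

## Phasing model

Unphased genotypes are resolved by standard multinomial
expectation-maximization (`em_haplotype_frequencies()`). For a genotype
heterozygous at $k$ loci there are $\max(1, 2^{k-1})$ compatible unordered
haplotype pairs (`enumerate_compatible_pairs()`, validated in the tests
against exhaustive enumeration of all $2^L$ orderings). The E-step weights
a compatible pair $(a, b)$ of individual $i$ by

$$w_{ab} \propto 2^{[a \ne b]} f_a f_b,$$

normalised within the individual; the M-step re-estimates each $f_h$ as its
expected dose over $2N$. The log-likelihood is non-decreasing at every
iteration (asserted on the stored trace) and the frequency vector remains
on the simplex to $10^{-9}$.

Numerical choices, made here because the underlying algorithm is standard
but its details matter for reproducibility:

* initialisation is uniform over the haplotypes compatible with at least
  one observed genotype;
* convergence is declared when the largest per-iteration frequency change
  falls below `tol` ($10^{-6}$ by default); hitting `max_iter` (200) flags
  the result as non-converged rather than erroring;
* haplotypes with estimated frequency below `prune_threshold` (default
  $1/(4N)$, i.e. half a copy) are pruned once, after iteration 5, unless
  that would leave a genotype with no compatible pair. Pruning is off
  (`prune_threshold = 0`) wherever strict likelihood monotonicity is being
  asserted, since removing mass is not an EM step;
* individuals with any missing call at the loci being phased are excluded
  from that phasing run and reported in `n_excluded`.

Each individual is then assigned the maximum-posterior pair
(`assign_best_pair()`); exact ties are broken lexicographically on the
canonical `~`-joined pair encoding so that runs are reproducible. The
fraction of assignments with posterior above 0.5 / 0.6 / 0.7 is the
standard quality summary (`posterior_coverage_summary()`, strict
inequality).

Extended haplotypes are phased in two stages
(`phase_extended_haplotypes()`): the 11-SNP window first, collapsing each
individual's assigned SNP-haplotype pair into a single multi-allelic
locus, then a joint EM over the six loci. Phasing all 16 symbols jointly
would square the pair enumeration for no practical benefit; the staged
design mirrors treating the SNP window as one more gene.

The analysis window itself can be chosen from the data:
`scan_snp_windows()` phases every window of 2–15 consecutive SNPs,
scores each by the smallest carrier chi-square p-value among haplotypes
with at least `min_copies` assigned copies, and selects the most
significant window (ties: smaller width, then leftmost; coordinates are
0-based half-open). Only haplotypes with a minimum copy count are tested
because carrier chi-squares on a handful of copies are noise; the default
(10) is deliberately low since window selection is exploratory.

## Synthetic cohorts

Real datasets of this kind are access-controlled, so the package ships a
generator rather than data. A `build_pool()` recipe draws a two-block
frequency spectrum: `n_common` CEHs share `common_mass` of the total
frequency with Zipf-like weights $\mathrm{rank}^{-\mathrm{skew}}$, and an
`n_rare` tail shares the rest as a truncated power law
($\mathrm{rank}^{-\mathrm{rare\_exponent}}$), water-filled so the tail
stays strictly rarer than the common block. The defaults (`n_common = 10`,
`common_mass = 0.22`, `skew = 1`) reproduce the published concentration of
large MHC cohorts, where the 10 most common CEHs carry 22% of all copies;
the tail exponent is the package's own choice (no published estimate
exists), defaulting to 1 and set to 0.5 in the analysis scripts to give a
singleton-heavy tail at cohort size. Class II alleles are a deterministic
function of the SNP haplotype, emulating the near-perfect Class II / SNP
linkage seen in practice; Class I alleles are drawn freely, which
*understates* real Class I–Class II association.

Diplotypes are two independent multinomial draws per individual (random
mating), or, under a `subpop_scheme()`, both draws come from one
subpopulation's frequencies — the Wahlund construction, whose pooled
homozygote excess is the classic confounder of the selection signal.
Disease status is Bernoulli with odds
$\mathrm{baseline\_odds} \times \prod_h rr_h(\mathrm{copies})$: a
recessive CEH is encoded $rr_1 = 1, rr_2 > 1$ and a dose-dependent one
$rr_1 = r, rr_2 = r^2$. `unphase()` destroys phase (and optionally masks
calls) to produce the observable dataset, while `generate_dataset()` keeps
the truth table alongside for parameter-recovery checks.

What the generator does **not** emulate: recombination or mutation within
a lineage, genotyping or imputation error, a genetic map, realistic
Class I allele frequencies, or linkage beyond the deterministic Class II
map. Passing tests therefore demonstrate correctness of the estimators
under the stated sampling model, not robustness to imputation artifacts.

## Association testing

Carrier tables contrast individuals with exactly 1 (or exactly 2) copies
of a target against individuals with none; the other copy count is
excluded so the two contrasts stay separate. `carrier_or()` applies the
Haldane–Anscombe 0.5 correction to all four cells when any cell is zero
(rare CEHs routinely produce empty cells; the correction choice is ours,
as published reports show finite ORs without stating one), a 95% Wald
interval on the log scale, and a two-sided normal p-value. All tests in
the package are two-sided.

Because one Class II motif (DRB1\*15:01~DQB1\*06:02 on `a1`) dominates MS
association, every other association is assessed after *excluding* its
carriers (`conditional_carrier_or()`). When the target itself bears the
exclusion motif, only the other motif carriers are removed, so a
motif-bearing CEH is still compared against motif-free non-carriers.
Two ORs are compared by
$z = (\ln OR_1 - \ln OR_2)/\sqrt{SE_1^2 + SE_2^2}$ with each SE recovered
from its interval — deliberately so, because published tables carry
intervals, not SEs.

Class I × Class II contingency uses the Fisher exact test when any
expected cell is 5 or less (inclusive, per the usual rule) and otherwise a
Pearson chi-square, taken *without* continuity correction since the
rule already routes small tables to the exact path. The Fisher path is
`stats::fisher.test`; the acceptance suite verifies it against direct
hypergeometric enumeration on every 2×2 table with total at most 40.
Multiplicity is handled by Benjamini–Hochberg (`stats::p.adjust`) for the
Class I × Class II grid and by a Bonferroni threshold $\alpha/m$ for the
haplotype association family; `association_table()` analyses only CEHs
with at least 50 copies, the conventional floor below which carrier ORs
are not meaningful, and reports the threshold for exactly that family.

Dose regression (`dose_regression()`) is a logistic model of phenotype on
0/1/2 copy counts with optional covariates (principal components ingested
precomputed, region dummies, sex) and optional pairwise interactions.
Rank-deficient designs error with the collinear columns named; complete
separation flags the coefficient non-estimable instead of crashing.

## Homozygosity and selection–conversion dynamics

Under random mating the per-individual homozygosity probability is
$q = \sum_i f_i^2$. `homozygote_excess_test()` compares the observed
homozygote count with $E = Nq$ using a Binomial variance,
$z = (O - E)/\sqrt{Nq(1-q)}$. Per-individual homozygosity is a Bernoulli
trial, so this is the natural variance model; with the published
observed/expected counts as inputs it reproduces the published z-scores
to within ±0.05, which is also the tolerance asserted in the tests.

The two-class model (`two_class_model()`) collapses the spectrum into
"frequent" (observed more than once) and "rare" (observed once) classes
and tracks the frequent-class frequency $p_f$ through: random union of
gametes → viability selection on the three diplotype classes (relative
survivals $w_{ff} = 1$, $w_{fr}$, $w_{rr}$) → gamete output → class
conversion at per-haplotype probabilities $c_{fr}$, $c_{rf}$. The order
(selection before conversion) is a documented choice. Heterozygote
fitness defaults to 1, placing selection on the homozygote classes. With
$w_{fr} = 1$ the interior gamete fixed point has the closed form
$(1 - w_{rr})(1 - p^*)^2 = c_{fr}$, which the bisection solver
(`equilibrium_solve()`) and a 10,000-generation iteration oracle both
reproduce to $10^{-10}$.

`estimate_conversion_selection()` inverts the model: given an observed
census of frequent-frequent / frequent-rare / rare-rare individuals it
finds $(c, w_{rr})$ whose equilibrium census reproduces the observed
adult frequent-class frequency and the observed signed deviation of
homozygosity from its HWE expectation, via a coarse grid refined by
bounded quasi-Newton optimisation. Round-trip recovery from
model-generated censuses at $N = 30{,}000$ is within ±0.01 on $c$ and
±0.05 on $w_{rr}$ (acceptance suite). Two caveats are intrinsic:

* near the neutral point the mapping degenerates — $(c, w_{rr}) \to (0, 1)$
  along a ray reproduces any Hardy–Weinberg census — so null censuses
  return small $c$ and $w_{rr}$ near 1 rather than a unique point;
* classifying haplotypes from the *same finite sample* being tested is
  itself a selection-like distortion: a CEH observed once can never appear
  in a homozygote, so the rare-rare class is mechanically depleted and the
  inversion reports apparent selection even for random-mating data (the
  stage-5 analysis script shows this). Applying the inversion to real
  censuses requires classes defined on external or split data, or the
  published class-wise counts themselves.

## Hamming profiles

`hamming()` counts differing positions between equal-length SNP strings;
`carriage_by_distance()` groups CEH copies by distance from an anchor SNP
haplotype and reports how often each distance class carries a given HLA
motif. Both weightings are emitted — overall copy-weighted proportions and
per-unique-SNP-haplotype proportions (whose copy-weighted mean equals the
overall curve exactly) — because either convention is defensible and the
qualitative argument (carriage is a property of the specific SNP
haplotype, not of distance) holds under both. Unique haplotypes are split
at 10% carriage into the two conventional subgroup curves.

## Problem sizes and determinism

All randomness flows through explicit integer seeds; a configuration plus
seed reproduces byte-identical outputs. The shipped analyses use a
3,000-individual cohort over an 810-CEH pool, chosen so the full six-stage
chain runs in about a minute; the statistical checks use the sizes their
precision requires — phasing recovery on a 20-CEH pool at $n = 5{,}000$
(L1 below 0.05), OR coverage over 100 simulated cohorts of $n = 2{,}000$,
type-I error over 1,000 null cohorts of $n = 2{,}000$ (within 0.03–0.07 at
nominal 0.05), and the conversion–selection round trip at
$N = 30{,}000$. The cohort-scale frequency-spectrum summaries are computed
from `synthetic_cohort_counts()`, a deterministic synthetic spectrum whose
aggregate anchors (59,884 copies, 10,078 unique, top-10 = 13,302 copies,
6,016 singletons, 1,397 doubletons) match published cohort totals while
the interpolated counts between anchors are synthetic.

## Limitations

HLA imputation, reference-panel phasing, genome-wide SNP QC and PCA
computation are out of scope: HLA typings and principal components enter
as given. The EM phasing here is the plain multinomial algorithm; it is
validated against grid-search and enumeration oracles and against the
generator's truth tables, not against HMM phasers. The two-class dynamics
deliberately stop at two classes — no multi-class spectrum dynamics, no
explicit recombination model of the MHC's frozen blocks.
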