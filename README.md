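# cehtools

Analysis of **conserved extended haplotypes (CEHs)** of the major
histocompatibility complex: multi-megabase combinations of alleles at
HLA-A, -C, -B, -DRB1 and -DQB1 plus an 11-SNP haplotype of the Class II
region, inherited as units and strongly skewed in frequency. The package
is for statistical geneticists who want to ask whether disease risk (the
motivating case is multiple sclerosis) attaches to a single HLA allele, to
a Class II motif such as DRB1\*15:01~DQB1\*06:02, or to the full extended
haplotype carrying it — and to do so on fully synthetic cohorts, since the
real datasets of this kind are access-controlled.

The pipeline, organised as numbered drivers under `analysis/` over the
package functions in `R/`:

1. **Simulate** (`generate_dataset`): diploid case-control cohorts drawn
   from a configurable CEH pool with a Zipf-like common block plus a rare
   tail, tight Class II / SNP linkage, dominant/dose-dependent vs recessive
   per-CEH risks (odds multiplied by `rr(copies)`), and optional
   subpopulation structure (Wahlund homozygote excess).
2. **Phase** (`em_haplotype_frequencies`, `phase_extended_haplotypes`):
   multinomial EM over the `2^(k-1)` haplotype pairs compatible with each
   genotype — E-step weight `2^[het] f_a f_b`, M-step dose/2N — then
   maximum-posterior pair assignment. The 11-SNP window is phased first and
   collapsed into one multi-allelic locus; `scan_snp_windows` picks the
   most disease-associated window of 2–15 SNPs.
3. **Spectrum** (`build_spectrum`, `spectrum_summary`, `coverage_curve`,
   `rank_by_group`): copy-count spectra, top-k coverage, singleton tails,
   per-region rank orders.
4. **Associate** (`carrier_or`, `conditional_carrier_or`,
   `dose_regression`): carrier odds ratios `ad/bc` with Wald intervals
   `exp(ln OR ± 1.96·SE)`, computed after excluding carriers of a dominant
   motif; ln-OR z-tests between haplotypes; Fisher-or-chi-square rule for
   Class I × Class II tables; Benjamini–Hochberg and Bonferroni control;
   covariate-adjusted logistic dose regression.
5. **Selection** (`homozygote_excess_test`, `equilibrium_solve`,
   `estimate_conversion_selection`): Hardy–Weinberg homozygote-excess
   z-tests with Binomial variance `z = (O − Nq)/√(Nq(1−q))`, `q = Σf²`,
   and a two-class (rare/frequent) conversion–selection equilibrium model
   inverted to estimate the net conversion rate `c` and the rare-homozygote
   relative survival `w_rr`.
6. **Hamming** (`hamming`, `carriage_by_distance`): motif carriage as a
   function of Hamming distance from an anchor SNP haplotype.

## Worked example

```r
library(cehtools)

pool <- build_pool(recipe = list(n_common = 10, n_rare = 300,
                                 common_mass = 0.22, skew = 1,
                                 rare_exponent = 0.5, seed = 5))
pool$rr1 <- ifelse(motif_matches(pool$haplotype,
                                 "DRB1*15:01~DQB1*06:02~a1"), 3, 1)
pool$rr2 <- pool$rr1^2

ds <- generate_dataset(list(pool = pool, n = 2000, baseline_odds = 0.35),
                       seed = 5)
ph <- phase_extended_haplotypes(ds$genotypes)
sm <- spectrum_summary(build_spectrum(ph$assignments))
conditional_carrier_or(ph$assignments,
                       "*~*~*~DRB1*15:01~DQB1*06:02~a1", copies = 1)
homozygote_excess_test(observed = 383, n = 29942, expected = 269)
```

On this 2,000-individual cohort every phasing assignment has posterior
above 0.5; the spectrum holds 321 unique CEHs over 4,000 copies with the
top 10 carrying 23%; the single-copy carrier OR for the
DRB1\*15:01~DQB1\*06:02~a1 motif comes back as

```
    or ci_lower ci_upper        p
  2.71     2.15     3.42 3.26e-17
```

i.e. the programmed per-copy risk of 3 is recovered within its confidence
interval. The homozygote-excess test on published observed/expected counts
(383 observed vs 269 expected among 29,942 individuals) gives `z = 6.98`,
`p = 2.9e-12`: a homozygote excess far beyond random-mating expectations.

The full chain runs with

```sh
Rscript analysis/01_simulate.R   # synthetic cohort -> results/data/
Rscript analysis/02_phase.R      # EM phasing + window scan
Rscript analysis/03_spectrum.R   # frequency spectra and rank orders
Rscript analysis/04_association.R
Rscript analysis/05_selection.R
Rscript analysis/06_hamming.R
```

each narrating what it found and writing its tables under `results/`.

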