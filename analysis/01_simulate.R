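#!/usr/bin/env Rscript

## Stage 1: simulate a case-control cohort from a skewed CEH pool.
##
## The pool emulates the shape of real MHC cohorts: 10 common CEHs holding
## 22% of all haplotype copies over a long rare tail, tight Class II / SNP
## linkage, and three programmed disease effects -- a dose-dependent risk
## on the DRB1*15:01~DQB1*06:02~a1 motif (per-copy OR 3), a weaker dose
## effect on the a2 arm of DRB1*03:01~DQB1*02:01 (per-copy OR 2), and a
## recessive effect on its a6 arm (homozygote OR 4).

suppressPackageStartupMessages(library(cehtools))

out <- "results/data"
dir.create(out, showWarnings = FALSE, recursive = TRUE)
seed <- 20260927 %% 1000003L

pool <- build_pool(recipe = list(n_common = 10, n_rare = 800,
                                 common_mass = 0.22, skew = 1,
                                 rare_exponent = 0.5, seed = seed))
on_motif <- function(m) motif_matches(pool$haplotype, m)
pool$rr1[on_motif("DRB1*15:01~DQB1*06:02~a1")] <- 3
pool$rr1[on_motif("DRB1*03:01~DQB1*02:01~a2")] <- 2
pool$rr2 <- pool$rr1^2
rec <- on_motif("DRB1*03:01~DQB1*02:01~a6")
pool$rr1[rec] <- 1
pool$rr2[rec] <- 4

config <- list(pool = pool, n = 3000, baseline_odds = 0.35,
               n_regions = 14, n_pcs = 10, seed = seed)
ds <- generate_dataset(config, seed = seed)

write_snp_vcf(ds$genotypes, file.path(out, "snp_genotypes.vcf"))
write_hla_tsv(ds$genotypes, file.path(out, "hla_typings.tsv"))
write_phenotype_tsv(ds$genotypes, file.path(out, "phenotypes.tsv"))
write_truth_tsv(ds$truth, file.path(out, "truth.tsv"))

message("simulated ", nrow(ds$genotypes), " individuals (",
        sum(ds$genotypes$phenotype == "case"), " cases) from a pool of ",
        nrow(pool), " CEHs; top-10 mass ",
        round(sum(sort(pool$frequency, decreasing = TRUE)[1:10]), 3))
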