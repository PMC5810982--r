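#' Sample diplotypes from a haplotype pool
#'
#' With no subpopulation scheme each individual is two independent draws
#' from the pool frequencies (Hardy-Weinberg / random mating). With a
#' scheme, the subpopulation is drawn first from its mixing weights and
#' both haplotypes are then drawn from that subpopulation's frequencies
#' (the Wahlund construction, which inflates pooled homozygosity).
#'
#' @param pool a `ceh_pool` from [build_pool()].
#' @param n number of individuals (`n = 0` returns an empty table).
#' @param scheme optional [subpop_scheme()]; its frequency columns must
#'   align with the pool's haplotype order.
#' @param seed optional integer seed.
#' @return tibble with columns `sample_id`, `hap1`, `hap2` (canonical
#'   lexicographic order), `homozygous`, `subpop`.
#' @export
sample_diplotypes <- function(pool, n, scheme = NULL, seed = NULL) {
  stopifnot(inherits(pool, "ceh_pool"), n >= 0)
  if (!is.null(seed)) {
    wr <- withr_seed(seed)
    on.exit(wr())
  }
  haps <- pool$haplotype
  if (n == 0) {
    return(tibble::tibble(sample_id = character(), hap1 = character(),
                          hap2 = character(), homozygous = logical(),
                          subpop = integer()))
  }
  if (is.null(scheme)) {
    subpop <- rep(NA_integer_, n)
    i1 <- sample.int(length(haps), n, replace = TRUE, prob = pool$frequency)
    i2 <- sample.int(length(haps), n, replace = TRUE, prob = pool$frequency)
  } else {
    if (ncol(scheme$frequencies) != length(haps)) {
      stop("scheme frequencies must have one column per pool haplotype")
    }
    subpop <- sample.int(length(scheme$mixing_weights), n, replace = TRUE,
                         prob = scheme$mixing_weights)
    i1 <- i2 <- integer(n)
    for (s in unique(subpop)) {
      k <- which(subpop == s)
      fs <- scheme$frequencies[s, ]
      i1[k] <- sample.int(length(haps), length(k), replace = TRUE, prob = fs)
      i2[k] <- sample.int(length(haps), length(k), replace = TRUE, prob = fs)
    }
  }
  pr <- canonical_pair(haps[i1], haps[i2])
  tibble::tibble(
    sample_id = sprintf("S%05d", seq_len(n)),
    hap1 = pr$hap1, hap2 = pr$hap2,
    homozygous = pr$hap1 == pr$hap2,
    subpop = subpop
  )
}

#' Assign case/control phenotypes from per-CEH genotype relative risks
#'
#' Per-individual disease odds are `baseline_odds` multiplied, over the
#' CEHs carried, by the genotype relative risk for the carried copy count:
#' a homozygote for haplotype h contributes `rr2[h]`, a heterozygote
#' carrying h and h' contributes `rr1[h] * rr1[h']`. A recessive CEH is
#' encoded `rr1 = 1, rr2 > 1`; a dose-dependent CEH `rr1 = r, rr2 = r^2`.
#' Phenotype is a Bernoulli draw from `odds / (1 + odds)`.
#'
#' @param diplotypes tibble from [sample_diplotypes()].
#' @param pool the `ceh_pool` the diplotypes were drawn from.
#' @param baseline_odds positive baseline disease odds.
#' @param seed optional integer seed.
#' @return `diplotypes` with a `phenotype` column (`"case"`/`"control"`).
#' @export
assign_phenotypes <- function(diplotypes, pool, baseline_odds, seed = NULL) {
  stopifnot(baseline_odds > 0)
  if (any(pool$rr1 <= 0) || any(pool$rr2 <= 0)) {
    stop("relative risks must be positive")
  }
  if (!is.null(seed)) {
    wr <- withr_seed(seed)
    on.exit(wr())
  }
  rr1 <- stats::setNames(pool$rr1, pool$haplotype)
  rr2 <- stats::setNames(pool$rr2, pool$haplotype)
  hom <- diplotypes$hap1 == diplotypes$hap2
  mult <- ifelse(hom, rr2[diplotypes$hap1],
                 rr1[diplotypes$hap1] * rr1[diplotypes$hap2])
  odds <- baseline_odds * unname(mult)
  p <- odds / (1 + odds)
  diplotypes$phenotype <- ifelse(stats::runif(nrow(diplotypes)) < p,
                                 "case", "control")
  diplotypes
}

#' Destroy phase: diplotypes to unordered genotype records
#'
#' The inverse of phasing: each individual's two CEHs are reduced to
#' unordered per-locus allele pairs (HLA loci as `"x/y"` calls with the
#' alleles sorted, SNP sites as `"0/1"`-style calls). Optional per-locus
#' missingness replaces calls with `NA`.
#'
#' @param diplotypes tibble with `hap1`, `hap2` (full CEH strings) and any
#'   passenger columns (`sample_id`, `phenotype`, ...), which are kept.
#' @param missing_rate single rate or named vector over
#'   `c(HLA loci, "SNP")`; the SNP rate applies per site.
#' @param seed optional integer seed (used only when masking).
#' @return tibble of genotype records: passenger columns, `A` ... `DQB1`
#'   calls, and `s01` ... `s11` SNP calls.
#' @export
unphase <- function(diplotypes, missing_rate = 0, seed = NULL) {
  if (!is.null(seed)) {
    wr <- withr_seed(seed)
    on.exit(wr())
  }
  f1 <- ceh_split(diplotypes$hap1)
  f2 <- ceh_split(diplotypes$hap2)
  n <- nrow(diplotypes)
  rate <- missing_rate
  if (length(rate) == 1 && is.null(names(rate))) {
    rate <- stats::setNames(rep(rate, 6), CEH_FIELDS)
  }
  out <- diplotypes[, setdiff(names(diplotypes),
                              c("hap1", "hap2", "homozygous")), drop = FALSE]
  for (loc in HLA_LOCI) {
    call <- genotype_call(f1[[loc]], f2[[loc]])
    r <- unname(rate[loc])
    if (!is.na(r) && r > 0) call[stats::runif(n) < r] <- NA
    out[[loc]] <- call
  }
  s1 <- do.call(rbind, strsplit(f1$SNP, "", fixed = TRUE))
  s2 <- do.call(rbind, strsplit(f2$SNP, "", fixed = TRUE))
  r <- unname(rate["SNP"])
  for (j in seq_len(SNP_WIDTH)) {
    call <- genotype_call(s1[, j], s2[, j])
    if (!is.na(r) && r > 0) call[stats::runif(n) < r] <- NA
    out[[sprintf("s%02d", j)]] <- call
  }
  tibble::as_tibble(out)
}

#' Generate a complete synthetic case-control dataset
#'
#' One call producing both the observable unphased dataset and the truth
#' table needed for parameter-recovery tests. Deterministic under
#' `seed`: the same `config` and `seed` give identical outputs.
#'
#' @param config list with elements:
#'   \describe{
#'     \item{pool}{a `ceh_pool`, or a list passed to [build_pool()].}
#'     \item{n}{number of individuals.}
#'     \item{scheme}{optional [subpop_scheme()].}
#'     \item{baseline_odds}{baseline disease odds (default 0.25).}
#'     \item{n_regions}{number of geographic region labels (default 14).}
#'     \item{n_pcs}{number of principal-component covariates (default 10).}
#'     \item{missing_rate}{passed to [unphase()] (default 0).}
#'   }
#' @param seed integer seed for all stochastic draws.
#' @return list with `genotypes` (records with phenotype, region, sex and
#'   PC covariates) and `truth` (true diplotypes and subpopulations).
#' @export
generate_dataset <- function(config, seed) {
  pool <- config$pool
  if (!inherits(pool, "ceh_pool")) pool <- do.call(build_pool, pool)
  n <- config$n
  baseline_odds <- config$baseline_odds %||% 0.25
  n_regions <- config$n_regions %||% 14L
  n_pcs <- config$n_pcs %||% 10L

  wr <- withr_seed(seed)
  on.exit(wr())

  truth <- sample_diplotypes(pool, n, scheme = config$scheme)
  truth <- assign_phenotypes(truth, pool, baseline_odds)
  truth$region <- if (!is.null(config$scheme)) {
    sprintf("R%02d", truth$subpop)
  } else {
    sprintf("R%02d", sample.int(n_regions, n, replace = TRUE))
  }
  truth$sex <- sample(c("female", "male"), n, replace = TRUE)

  observable <- truth[, setdiff(names(truth), "subpop"), drop = FALSE]
  geno <- unphase(observable, missing_rate = config$missing_rate %||% 0)
  if (n_pcs > 0) {
    for (j in seq_len(n_pcs)) {
      geno[[paste0("PC", j)]] <- round(stats::rnorm(n), 6)
    }
  }
  list(genotypes = geno, truth = truth)
}
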