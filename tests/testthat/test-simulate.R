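test_that("random-mating homozygosity matches the Binomial expectation", {
  pool <- two_ceh_pool()
  n <- 10000
  for (seed in 1:3) {
    d <- sample_diplotypes(pool, n, seed = seed)
    q <- sum(pool$frequency^2)
    expect_lt(abs(sum(d$homozygous) - n * q), 4 * sqrt(n * q * (1 - q)))
  }
  expect_equal(nrow(sample_diplotypes(pool, 0)), 0)
})

test_that("the extreme Wahlund construction doubles homozygosity", {
  pool <- two_ceh_pool()
  scheme <- subpop_scheme(c(0.5, 0.5), rbind(c(1, 0), c(0, 1)))
  d <- sample_diplotypes(pool, 2000, scheme = scheme, seed = 1)
  expect_true(all(d$homozygous))
  ## pooled-HWE expectation q = 0.5 -> observed/expected = 2
  expect_equal(nrow(d) / (nrow(d) * 0.5), 2)
})

test_that("any non-degenerate scheme satisfies the Wahlund inequality", {
  ## expected pooled homozygosity >= homozygosity of the pooled frequencies
  set.seed(99)
  for (rep in 1:20) {
    k <- sample(2:4, 1)
    h <- sample(3:6, 1)
    mw <- as.vector(stats::rgamma(k, 1)); mw <- mw / sum(mw)
    fm <- matrix(stats::rgamma(k * h, 1), k)
    fm <- fm / rowSums(fm)
    q_scheme <- sum(mw * rowSums(fm^2))
    pooled <- colSums(mw * fm)
    expect_gte(q_scheme, sum(pooled^2) - 1e-12)
  }
})

test_that("null risk models reproduce the baseline prevalence", {
  pool <- toy_pool()
  d <- sample_diplotypes(pool, 20000, seed = 5)
  d <- assign_phenotypes(d, pool, baseline_odds = 0.25, seed = 6)
  prev <- mean(d$phenotype == "case")
  p0 <- 0.25 / 1.25
  expect_lt(abs(prev - p0), 4 * sqrt(p0 * (1 - p0) / 20000))
})

test_that("recessive and dose-dependent risk encodings yield the programmed ORs", {
  emp_or <- function(d, cp, k) {
    keep <- cp %in% c(0, k)
    case <- d$phenotype[keep] == "case"
    expo <- cp[keep] == k
    (sum(case & expo) * sum(!case & !expo)) /
      (sum(case & !expo) * sum(!case & expo))
  }
  sim <- function(rr1, rr2, seed) {
    pool <- toy_pool(rr1 = c(rr1, 1, 1, 1, 1), rr2 = c(rr2, 1, 1, 1, 1))
    d <- sample_diplotypes(pool, 50000, seed = seed)
    d <- assign_phenotypes(d, pool, baseline_odds = 0.1, seed = seed + 1)
    list(d = d, copies = (d$hap1 == pool$haplotype[1]) +
           (d$hap2 == pool$haplotype[1]))
  }
  rec <- sim(1, 4, seed = 10) # recessive: no heterozygote effect
  expect_equal(emp_or(rec$d, rec$copies, 1), 1, tolerance = 0.15)
  expect_equal(emp_or(rec$d, rec$copies, 2), 4, tolerance = 0.35)
  dose <- sim(3, 9, seed = 12) # dose-dependent: rr2 = rr1^2
  expect_equal(emp_or(dose$d, dose$copies, 1), 3, tolerance = 0.15)
  expect_equal(emp_or(dose$d, dose$copies, 2), 9, tolerance = 0.35)
  expect_error(assign_phenotypes(dose$d, toy_pool(), baseline_odds = 0))
})

test_that("unphasing removes phase but preserves the allele multiset", {
  pool <- toy_pool()
  d <- sample_diplotypes(pool, 200, seed = 2)
  g <- unphase(d)
  ## truth-table linkage: records reconstructible from the truth alleles
  f1 <- ceh_split(d$hap1); f2 <- ceh_split(d$hap2)
  for (loc in c("A", "B", "DRB1")) {
    expect_equal(g[[loc]],
                 ifelse(f1[[loc]] <= f2[[loc]],
                        paste(f1[[loc]], f2[[loc]], sep = "/"),
                        paste(f2[[loc]], f1[[loc]], sep = "/")))
  }
  hom <- which(d$homozygous)[1]
  if (!is.na(hom)) {
    calls <- strsplit(unlist(g[hom, c("A", "C", "B", "DRB1", "DQB1")]), "/")
    expect_true(all(vapply(calls, function(p) p[1] == p[2], logical(1))))
  }
})

test_that("SNP heterozygosity sits exactly where the haplotype strings differ", {
  ## a1 = 10110100010 vs a2 = 00000000100 differ at positions 1,3,4,6,9,10
  d <- tibble::tibble(
    sample_id = "S1",
    hap1 = "A*03:01~C*07:02~B*07:02~DRB1*15:01~DQB1*06:02~10110100010",
    hap2 = "A*01:01~C*07:01~B*08:01~DRB1*03:01~DQB1*02:01~00000000100")
  g <- unphase(d)
  s <- unlist(g[1, sprintf("s%02d", 1:11)])
  het <- vapply(strsplit(s, "/"), function(p) p[1] != p[2], logical(1))
  diff <- strsplit("10110100010", "")[[1]] != strsplit("00000000100", "")[[1]]
  expect_equal(unname(het), diff)
})

test_that("masking rate 1 at one locus blanks every call there", {
  pool <- toy_pool()
  d <- sample_diplotypes(pool, 50, seed = 3)
  g <- unphase(d, missing_rate = c(A = 1), seed = 4)
  expect_true(all(is.na(g$A)))
  expect_false(anyNA(g$B))
})

test_that("generate_dataset is deterministic and carries its truth table", {
  cfg <- list(pool = toy_pool(), n = 300, n_regions = 14, n_pcs = 3)
  d1 <- generate_dataset(cfg, seed = 21)
  d2 <- generate_dataset(cfg, seed = 21)
  expect_identical(d1, d2)
  expect_equal(length(unique(d1$genotypes$region)), 14)
  expect_false("subpop" %in% names(d1$genotypes))
  expect_true(all(c("hap1", "hap2") %in% names(d1$truth)))
})

test_that("truth diplotype frequencies approach the pool at large n", {
  pool <- toy_pool()
  d <- generate_dataset(list(pool = pool, n = 20000, n_pcs = 0), seed = 8)
  emp <- table(factor(c(d$truth$hap1, d$truth$hap2), levels = pool$haplotype))
  l1 <- sum(abs(as.numeric(emp) / 40000 - pool$frequency))
  expect_lt(l1, 0.03) # multinomial L1 tolerance at 40k draws
})
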