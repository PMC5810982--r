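## Brute-force oracle: all 2^L ordered allele assignments, collapsed to
## unordered pairs. Independent of the package's enumeration shortcut.
brute_force_pairs <- function(alleles, collapse = "~") {
  L <- length(alleles)
  grid <- expand.grid(rep(list(1:2), L))
  pairs <- unique(t(apply(grid, 1, function(ch) {
    h1 <- mapply(function(a, k) a[k], alleles, ch)
    h2 <- mapply(function(a, k) a[3 - k], alleles, ch)
    sort(c(paste(h1, collapse = collapse), paste(h2, collapse = collapse)))
  })))
  pairs <- pairs[order(pairs[, 1], pairs[, 2]), , drop = FALSE]
  tibble::tibble(hap1 = pairs[, 1], hap2 = pairs[, 2])
}

test_that("compatible-pair enumeration matches the exhaustive oracle", {
  expect_equal(nrow(enumerate_compatible_pairs(c("a/a", "b/b", "c/c"))), 1)
  g3 <- c("a/x", "b/b", "c/y", "d/d", "e/e", "f/z") # het at 3 of 6 loci
  expect_equal(nrow(enumerate_compatible_pairs(g3)), 4)

  set.seed(7)
  for (rep in 1:25) {
    alleles <- lapply(1:6, function(j) {
      a <- sample(letters, 1)
      if (stats::runif(1) < 0.5) c(a, a) else sort(c(a, sample(LETTERS, 1)))
    })
    got <- enumerate_compatible_pairs(alleles)
    want <- brute_force_pairs(alleles)
    expect_equal(got[, c("hap1", "hap2")], want)
    k <- sum(vapply(alleles, function(a) a[1] != a[2], logical(1)))
    expect_equal(nrow(got), max(1, 2^(k - 1)))
  }
  expect_error(enumerate_compatible_pairs(list(c("a", "b", "c"))),
               "exactly two alleles")
})

test_that("EM reduces to counting when every genotype is homozygous", {
  g <- rbind(c("a/a", "b/b"), c("a/a", "b/b"), c("a/a", "b/b"),
             c("x/x", "y/y"))
  fit <- em_haplotype_frequencies(g, collapse = "~")
  f <- stats::setNames(fit$frequencies$frequency, fit$frequencies$haplotype)
  expect_equal(unname(f["a~b"]), 0.75)
  expect_equal(unname(f["x~y"]), 0.25)
  expect_true(fit$converged)
})

test_that("a lone single-locus heterozygote splits 50/50", {
  fit <- em_haplotype_frequencies(rbind(c("a/x", "b/b")), collapse = "~")
  expect_equal(sort(fit$frequencies$frequency), c(0.5, 0.5))
  expect_setequal(fit$frequencies$haplotype, c("a~b", "x~b"))
})

test_that("EM attains the grid-search maximum of the multinomial likelihood", {
  ## 10 AB/AB, 10 ab/ab, 10 double heterozygotes over 2 biallelic loci
  g <- rbind(matrix(rep(c("A/A", "B/B"), 10), ncol = 2, byrow = TRUE),
             matrix(rep(c("a/a", "b/b"), 10), ncol = 2, byrow = TRUE),
             matrix(rep(c("A/a", "B/b"), 10), ncol = 2, byrow = TRUE))
  fit <- em_haplotype_frequencies(g, tol = 1e-10, prune_threshold = 0)
  f <- stats::setNames(fit$frequencies$frequency, fit$frequencies$haplotype)
  f <- c(f, "A~B" = 0, "a~b" = 0, "A~b" = 0, "a~B" = 0)[
    c("A~B", "a~b", "A~b", "a~B")]

  loglik <- function(fab, fAb, faB) {
    fAB <- 1 - fab - fAb - faB
    if (fAB < 0) return(-Inf)
    20 * log(fAB) + 20 * log(fab) + 10 * log(2 * fAB * fab + 2 * fAb * faB)
  }
  ## coarse simplex grid, then local refinement at 1e-4 resolution
  best <- c(-Inf, 0, 0, 0)
  step <- 0.01
  for (fab in seq(0, 1, step)) for (fAb in seq(0, 1 - fab, step)) {
    for (faB in seq(0, 1 - fab - fAb, step)) {
      ll <- loglik(fab, fAb, faB)
      if (is.finite(ll) && ll > best[1]) best <- c(ll, fab, fAb, faB)
    }
  }
  fine <- expand.grid(
    fab = pmax(0, best[2] + seq(-0.01, 0.01, 1e-4)),
    fAb = pmax(0, best[3] + seq(-0.01, 0.01, 1e-3)),
    faB = pmax(0, best[4] + seq(-0.01, 0.01, 1e-3)))
  fine <- fine[fine$fab + fine$fAb + fine$faB <= 1, ]
  ll <- mapply(loglik, fine$fab, fine$fAb, fine$faB)
  opt <- fine[which.max(ll), ]
  expect_equal(unname(f["a~b"]), opt$fab, tolerance = 1e-4)
  expect_equal(unname(f["A~b"]), opt$fAb, tolerance = 1e-3)
  expect_equal(unname(f["A~B"]), 1 - opt$fab - opt$fAb - opt$faB,
               tolerance = 1e-3)
})

test_that("EM log-likelihood is monotone and frequencies stay a simplex", {
  pool <- toy_pool()
  for (seed in 1:3) {
    d <- generate_dataset(list(pool = pool, n = 150, n_pcs = 0), seed = seed)
    gm <- as.matrix(d$genotypes[, c("A", "C", "B", "DRB1", "DQB1")])
    fit <- em_haplotype_frequencies(gm, prune_threshold = 0)
    expect_true(all(diff(fit$loglik) >= -1e-8))
    expect_equal(sum(fit$frequencies$frequency), 1, tolerance = 1e-9)
    expect_true(all(fit$frequencies$frequency >= 0))
  }
})

test_that("non-convergence is flagged, not thrown", {
  g <- rbind(c("A/A", "B/B"), c("A/a", "B/b"))
  fit <- em_haplotype_frequencies(g, tol = 1e-12, max_iter = 1)
  expect_false(fit$converged)
})

test_that("best-pair assignment normalises pair weights and breaks ties", {
  f1 <- tibble::tibble(haplotype = "a~b", frequency = 1)
  one <- assign_best_pair(c("a/a", "b/b"), f1)
  expect_equal(one$posterior, 1)

  f <- tibble::tibble(haplotype = c("A~B", "a~b", "A~b", "a~B"),
                      frequency = c(0.4, 0.4, 0.1, 0.1))
  dbl <- assign_best_pair(c("A/a", "B/b"), f)
  expect_equal(dbl$posterior, 0.32 / 0.34, tolerance = 1e-12)
  expect_equal(c(dbl$hap1, dbl$hap2), c("A~B", "a~b"))

  funi <- dplyr::mutate(f, frequency = 0.25)
  tie <- assign_best_pair(c("A/a", "B/b"), funi)
  expect_equal(tie$posterior, 0.5)
  ## lexicographically first canonical pair among the tied ones
  expect_equal(c(tie$hap1, tie$hap2), c("A~B", "a~b"))

  zero <- assign_best_pair(c("q/q", "r/r"), f1)
  expect_true(zero$unassignable)
})

test_that("posterior coverage counts strictly-greater fractions", {
  expect_equal(unname(posterior_coverage_summary(rep(1, 4))), c(1, 1, 1))
  expect_equal(unname(posterior_coverage_summary(c(0.55, 0.65, 0.75, 0.45))),
               c(0.75, 0.50, 0.25))
  ## weakly decreasing in the threshold by construction
  pool <- recovery_pool(10)
  d <- generate_dataset(list(pool = pool, n = 400, n_pcs = 0), seed = 31)
  ph <- phase_extended_haplotypes(d$genotypes)
  cov <- posterior_coverage_summary(ph$assignments$posterior)
  expect_true(all(diff(cov) <= 0))
})

test_that("staged six-locus phasing recovers truth on a skewed pool", {
  pool <- recovery_pool(20, seed = 42)
  d <- generate_dataset(list(pool = pool, n = 5000, n_pcs = 0), seed = 77)
  ph <- phase_extended_haplotypes(d$genotypes)
  est <- stats::setNames(ph$frequencies$frequency, ph$frequencies$haplotype)
  lev <- union(pool$haplotype, names(est))
  est_full <- est[lev]
  est_full[is.na(est_full)] <- 0
  truth_full <- table(factor(c(d$truth$hap1, d$truth$hap2), levels = lev))
  truth_full <- as.numeric(truth_full) / sum(truth_full)
  expect_lt(sum(abs(est_full - truth_full)), 0.05)
  acc <- mean(ph$assignments$hap1 == d$truth$hap1 &
                ph$assignments$hap2 == d$truth$hap2)
  expect_gt(acc, 0.95)
})

test_that("individuals with missing calls are excluded from phasing", {
  pool <- toy_pool()
  d <- generate_dataset(list(pool = pool, n = 200, n_pcs = 0,
                             missing_rate = c(A = 0.2)), seed = 13)
  ph <- phase_extended_haplotypes(d$genotypes)
  expect_equal(ph$n_excluded, sum(is.na(d$genotypes$A)))
  expect_equal(nrow(ph$assignments), 200 - ph$n_excluded)
})

test_that("window scan honours widths, ties and degenerate input", {
  pool <- recovery_pool(8, seed = 5)
  d <- generate_dataset(list(pool = pool, n = 300, n_pcs = 0), seed = 6)
  snp <- as.matrix(d$genotypes[, sprintf("s%02d", 1:11)])
  pheno <- d$genotypes$phenotype
  one <- scan_snp_windows(snp, pheno, widths = 11, min_copies = 5)
  expect_equal(nrow(one$windows), 1)
  expect_equal(one$windows$start, 0)
  expect_error(scan_snp_windows(snp[, 1, drop = FALSE], pheno, widths = 2:15),
               "fewer SNPs")
})

## pool whose causal SNP haplotype is distinguishable only at sites 4-6
## (1-based), so informative windows must overlap 0-based positions 3..5
localised_pool <- function(rr = 3) {
  snp <- c("00011100000", # causal: the 111 block is its only signature
           "00000000000", "10000000001", "01000000010",
           "00000001100", "11000000011")
  build_pool(haplotypes = tibble::tibble(
    A = sprintf("A*%02d:01", 1:6), C = sprintf("C*%02d:01", 1:6),
    B = sprintf("B*%02d:01", 1:6),
    DRB1 = sprintf("DRB1*%02d:01", c(15, 3, 4, 11, 7, 1)),
    DQB1 = sprintf("DQB1*%02d:01", c(6, 2, 3, 3, 2, 5)),
    SNP = snp,
    frequency = c(0.25, 0.30, 0.15, 0.12, 0.10, 0.08),
    rr1 = c(rr, rep(1, 5)), rr2 = c(rr^2, rep(1, 5))))
}

test_that("window scan localises a programmed causal haplotype", {
  hits <- 0
  for (seed in 1:10) {
    d <- generate_dataset(list(pool = localised_pool(), n = 2000, n_pcs = 0,
                               baseline_odds = 0.3), seed = 100 + seed)
    snp <- as.matrix(d$genotypes[, sprintf("s%02d", 1:11)])
    scan <- scan_snp_windows(snp, d$genotypes$phenotype, widths = 2:4,
                             min_copies = 10)
    sel <- scan$selected
    overlap <- sel$start < 6 && (sel$start + sel$width) > 3
    if (overlap) hits <- hits + 1
  }
  expect_gte(hits, 9)
})

test_that("under the null the selected window shows no positional bias", {
  starts <- numeric(0)
  minp <- numeric(0)
  for (seed in 1:40) {
    pool <- build_pool(recipe = list(n_common = 8, n_rare = 0,
                                     common_mass = 1, skew = 0.5,
                                     seed = seed)) # all risks null
    d <- generate_dataset(list(pool = pool, n = 250, n_pcs = 0,
                               baseline_odds = 0.5), seed = 500 + seed)
    snp <- as.matrix(d$genotypes[, sprintf("s%02d", 1:6)])
    scan <- scan_snp_windows(snp, d$genotypes$phenotype, widths = 2,
                             min_copies = 10)
    starts <- c(starts, scan$selected$start)
    minp <- c(minp, scan$selected$p)
  }
  ## five width-2 windows, starts 0..4: selection spreads over positions
  ## (ties resolve leftward by the stated rule, so the centre sits slightly
  ## left of 2, but no runaway pile-up at the first window)
  expect_gte(length(unique(starts)), 3)
  expect_gt(mean(starts), 0.5)
  expect_lt(mean(starts), 3.5)
  ## minimum over ~5 correlated tests: clearly sub-uniform but not tiny
  expect_gt(stats::median(minp), 0.01)
  expect_lt(stats::median(minp), 0.6)
})
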