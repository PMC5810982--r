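test_that("carrier ORs follow the Wald formulas", {
  null <- carrier_or(50, 50, 50, 50)
  expect_equal(null$or, 1)
  expect_equal(null$p, 1)

  r <- carrier_or(30, 70, 10, 90)
  expect_equal(r$or, 27 / 7, tolerance = 1e-12)
  expect_equal(r$ci_lower, 1.7666, tolerance = 1e-4)
  expect_equal(r$ci_upper, 8.4210, tolerance = 1e-4)
  expect_lt(r$p, 0.001)

  zc <- carrier_or(10, 10, 0, 10)
  expect_true(zc$corrected)
  expect_true(is.finite(zc$or))
  expect_equal(zc$or, (10.5 * 10.5) / (10.5 * 0.5))

  expect_error(carrier_or(0, 0, 5, 5), "row or column")
  expect_error(carrier_or(-1, 1, 1, 1), "non-negative")
})

test_that("swapping case/control labels inverts the OR", {
  set.seed(8)
  for (rep in 1:10) {
    cells <- sample(1:80, 4)
    r <- carrier_or(cells[1], cells[2], cells[3], cells[4])
    swapped <- carrier_or(cells[3], cells[4], cells[1], cells[2])
    expect_equal(swapped$or, 1 / r$or, tolerance = 1e-12)
    expect_equal(swapped$p, r$p, tolerance = 1e-12)
  }
})

test_that("OR difference z-scores recover SEs from the intervals", {
  r <- carrier_or(30, 70, 10, 90)
  same <- compare_or_z(r, r)
  expect_equal(same$z, 0)
  expect_equal(same$p, 1)

  r1 <- list(or = 3.2, ci_lower = 3.0, ci_upper = 3.5)
  r2 <- list(or = 0.7, ci_lower = 0.3, ci_upper = 1.3)
  z <- compare_or_z(r1, r2)
  expect_equal(z$z, 4.041, tolerance = 1e-3)
  rev <- compare_or_z(r2, r1)
  expect_equal(rev$z, -z$z)
  expect_equal(rev$p, z$p)

  expect_error(compare_or_z(list(or = 2, ci_lower = 2, ci_upper = 2), r1),
               "degenerate")
})

test_that("conditional ORs apply the motif-exclusion rules", {
  pool <- toy_pool(rr1 = c(3, 1, 1, 1, 1), rr2 = c(9, 1, 1, 1, 1))
  d <- sample_diplotypes(pool, 8000, seed = 20)
  d <- assign_phenotypes(d, pool, baseline_odds = 0.3, seed = 21)
  target <- pool$haplotype[1]

  ## target contains the exclusion motif: only *other* motif carriers drop
  motif <- "*~*~*~DRB1*15:01~DQB1*06:02~a1"
  uncond <- conditional_carrier_or(d, target, copies = 1)
  cond <- conditional_carrier_or(d, target, copies = 1, exclusion = motif)
  expect_equal(cond$or, uncond$or) # only CEH 1 carries the motif here
  expect_equal(attr(cond, "n_excluded"), 0L)

  ## exclusion of a disjoint motif removes its carriers from both arms
  other <- "*~*~*~DRB1*03:01~DQB1*02:01~*"
  cond2 <- conditional_carrier_or(d, target, copies = 1, exclusion = other)
  carriers_other <- (motif_matches(d$hap1, other) | motif_matches(d$hap2, other))
  expect_equal(attr(cond2, "n_excluded"), sum(carriers_other))
  expect_equal(cond2$a + cond2$b + cond2$c + cond2$d,
               sum(!carriers_other &
                     ((d$hap1 == target) + (d$hap2 == target)) %in% c(0, 1)))

  ## programmed dose effect: the 1-copy CI covers 3, 2-copy covers 9
  expect_gt(3, cond$ci_lower); expect_lt(3, cond$ci_upper)
  two <- conditional_carrier_or(d, target, copies = 2)
  expect_gt(9, two$ci_lower); expect_lt(9, two$ci_upper)
})

test_that("a programmed recessive CEH shows no heterozygote association", {
  pool <- toy_pool(rr1 = rep(1, 5), rr2 = c(4, 1, 1, 1, 1))
  d <- sample_diplotypes(pool, 30000, seed = 30)
  d <- assign_phenotypes(d, pool, baseline_odds = 0.3, seed = 31)
  target <- pool$haplotype[1]
  one <- conditional_carrier_or(d, target, copies = 1)
  expect_gt(1, one$ci_lower); expect_lt(1, one$ci_upper)
  two <- conditional_carrier_or(d, target, copies = 2)
  expect_gt(4, two$ci_lower); expect_lt(4, two$ci_upper)
})

test_that("the Fisher/chi-square rule follows expected cell frequencies", {
  f <- class1_class2_association(matrix(c(3, 1, 1, 3), 2))
  expect_equal(f$method, "fisher")
  expect_equal(f$p, 34 / 70, tolerance = 1e-12)

  big <- class1_class2_association(matrix(c(100, 100, 100, 100), 2))
  expect_equal(big$method, "chisq")
  expect_equal(big$p, 1)

  ## an expected cell of exactly 5 takes the Fisher path ("5 or less")
  edge <- matrix(c(5, 5, 5, 5), 2)
  expect_equal(class1_class2_association(edge)$method, "fisher")
  expect_error(class1_class2_association(matrix(0, 2, 2)), "empty")
})

test_that("Fisher path equals hypergeometric enumeration on small tables", {
  ## spot-check here; the exhaustive sweep lives in the acceptance suite
  set.seed(5)
  for (rep in 1:25) {
    tab <- matrix(sample(0:8, 4, replace = TRUE), 2)
    if (sum(tab) == 0 || any(rowSums(tab) == 0) || any(colSums(tab) == 0)) next
    got <- stats::fisher.test(tab)$p.value
    m <- sum(tab[1, ]); n <- sum(tab[2, ]); k <- sum(tab[, 1])
    x <- 0:min(m, k)
    probs <- stats::dhyper(x, m, n, k)
    want <- sum(probs[probs <= probs[x == tab[1, 1]] * (1 + 1e-7)])
    expect_equal(got, min(1, want), tolerance = 1e-10)
  }
})

test_that("multiplicity corrections match their definitions", {
  bon <- adjust_pvalues(c(0.0001, 0.01), "bonferroni", m = 146)
  expect_equal(bon$threshold, 0.05 / 146)
  expect_equal(round(bon$threshold, 4), 3e-04)
  expect_equal(bon$significant, c(TRUE, FALSE))

  bh <- adjust_pvalues(c(0.01, 0.02, 0.03, 0.04), "benjamini-hochberg")
  expect_equal(bh$adjusted, rep(0.04, 4))
  expect_equal(adjust_pvalues(0.123, "benjamini-hochberg")$adjusted, 0.123)
  expect_error(adjust_pvalues(numeric(0)), "no p-values")
  expect_error(adjust_pvalues(c(0.5, 0)), "in \\(0, 1\\]")

  set.seed(9)
  p <- stats::runif(30)
  adj <- adjust_pvalues(p, "benjamini-hochberg")$adjusted
  expect_true(all(adj >= p))
  expect_true(all(diff(adj[order(p)]) >= -1e-12)) # monotone in raw rank
})

test_that("dose regression recovers programmed effects and flags pathologies", {
  pool <- toy_pool(rr1 = c(3, 1, 1, 1, 1), rr2 = c(9, 1, 1, 1, 1))
  d <- sample_diplotypes(pool, 10000, seed = 40)
  d <- assign_phenotypes(d, pool, baseline_odds = 0.2, seed = 41)
  dose <- (d$hap1 == pool$haplotype[1]) + (d$hap2 == pool$haplotype[1])
  fit <- dose_regression(d$phenotype, data.frame(dose = dose))
  co <- fit[fit$term == "dose", ]
  expect_gt(3, exp(co$estimate - 1.96 * co$se))
  expect_lt(3, exp(co$estimate + 1.96 * co$se))

  ## constant covariates change nothing
  fit2 <- dose_regression(d$phenotype, data.frame(dose = dose),
                          covariates = data.frame(const = rep(1, length(dose))))
  expect_equal(fit2[fit2$term == "dose", ]$estimate, co$estimate)

  ## collinear design names the offending column
  expect_error(
    dose_regression(d$phenotype, data.frame(dose = dose, dose2 = 2 * dose)),
    "collinear.*dose2")

  ## complete separation is flagged, not thrown
  y <- rep(c("case", "control"), each = 20)
  x <- rep(c(1, 0), each = 20)
  sep <- dose_regression(y, data.frame(x = x))
  expect_true(sep$non_estimable[sep$term == "x"])
})

test_that("association tables apply the copy threshold and exclusion motif", {
  pool <- toy_pool(rr1 = c(3, 1, 1, 1, 1), rr2 = c(9, 1, 1, 1, 1))
  d <- sample_diplotypes(pool, 4000, seed = 50)
  d <- assign_phenotypes(d, pool, baseline_odds = 0.3, seed = 51)
  tab <- association_table(d, min_copies = 50,
                           exclusion = "*~*~*~DRB1*15:01~DQB1*06:02~a1")
  expect_true(all(tab$count >= 50))
  expect_equal(attr(tab, "bonferroni_threshold"), 0.05 / nrow(tab))
  risk_row <- tab[tab$haplotype == pool$haplotype[1], ]
  expect_gt(risk_row$or, 2)
  expect_true(risk_row$significant)
})
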