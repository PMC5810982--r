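#' Carrier odds ratio with Wald confidence interval
#'
#' Odds ratio `ad/bc` for the 2x2 table of carrier status against disease,
#' with the Haldane-Anscombe correction (0.5 added to all four cells) when
#' any cell is zero, a 95% Wald interval on the log scale
#' (`exp(ln OR +- 1.96 SE)`, `SE = sqrt(1/a + 1/b + 1/c + 1/d)`), and a
#' two-sided normal p-value from `|ln OR| / SE`.
#'
#' @param a exposed (carrier) cases.
#' @param b unexposed cases.
#' @param c exposed controls.
#' @param d unexposed controls.
#' @return one-row tibble of class `ceh_assoc`: `or`, `ci_lower`,
#'   `ci_upper`, `p`, `se_log`, the four cell counts, `corrected`.
#' @export
carrier_or <- function(a, b, c, d) {
  cells <- c(a = a, b = b, c = c, d = d)
  if (any(cells < 0)) stop("cell counts must be non-negative")
  if ((a + b == 0) || (c + d == 0) || (a + c == 0) || (b + d == 0)) {
    stop("undefined OR: a whole row or column of the 2x2 table is zero")
  }
  corrected <- any(cells == 0)
  if (corrected) cells <- cells + 0.5
  or <- (cells["a"] * cells["d"]) / (cells["b"] * cells["c"])
  se <- sqrt(sum(1 / cells))
  lo <- exp(log(or) - 1.96 * se)
  hi <- exp(log(or) + 1.96 * se)
  p <- 2 * stats::pnorm(-abs(log(or)) / se)
  out <- tibble::tibble(or = unname(or), ci_lower = unname(lo),
                        ci_upper = unname(hi), p = unname(p),
                        se_log = unname(se), a = a, b = b, c = c, d = d,
                        corrected = corrected)
  class(out) <- c("ceh_assoc", class(out))
  out
}

## Copies of haplotypes matching `pattern` carried by each individual.
motif_copies <- function(assignments, pattern, snp_labels = NULL) {
  u <- unique(c(assignments$hap1, assignments$hap2))
  hit <- stats::setNames(motif_matches(u, pattern, snp_labels), u)
  as.integer(hit[assignments$hap1]) + as.integer(hit[assignments$hap2])
}

#' Conditional carrier odds ratio with motif exclusion
#'
#' The carrier odds ratio for a target CEH (or motif), computed after
#' removing individuals who carry an exclusion motif. When the target
#' itself contains the exclusion motif, only the *other* carriers of the
#' motif are excluded (individuals whose motif copies all sit on the
#' target haplotype are kept), so that a motif-bearing CEH can still be
#' tested against motif-free non-carriers. The table compares individuals
#' carrying exactly `copies` copies of the target against individuals
#' carrying none; individuals with the other copy count are excluded.
#'
#' @param assignments tibble with `hap1`, `hap2`, `phenotype`
#'   (`"case"`/`"control"`).
#' @param target CEH string or motif pattern to test.
#' @param copies 1 or 2: copy count contrasted against 0 copies.
#' @param exclusion optional exclusion motif pattern (e.g.
#'   `"*~*~*~DRB1*15:01~DQB1*06:02~a1"`).
#' @param snp_labels optional SNP label map (see [resolve_snp_label()]).
#' @return a `ceh_assoc` row (see [carrier_or()]) with attributes
#'   `target`, `copies`, `exclusion`, `n_excluded`.
#' @export
conditional_carrier_or <- function(assignments, target, copies = 1,
                                   exclusion = NULL, snp_labels = NULL) {
  stopifnot(copies %in% c(1, 2))
  tgt <- motif_copies(assignments, target, snp_labels)
  n_excluded <- 0L
  if (!is.null(exclusion)) {
    exc <- motif_copies(assignments, exclusion, snp_labels)
    u <- unique(c(assignments$hap1, assignments$hap2))
    target_is_sub <- all(motif_matches(u, exclusion, snp_labels)[
      motif_matches(u, target, snp_labels)])
    drop <- if (target_is_sub) exc > tgt else exc > 0
    n_excluded <- sum(drop)
    assignments <- assignments[!drop, ]
    tgt <- tgt[!drop]
  }
  keep <- tgt %in% c(0L, copies)
  assignments <- assignments[keep, ]
  tgt <- tgt[keep]
  if (nrow(assignments) == 0) stop("empty stratum after exclusion")
  is_case <- assignments$phenotype == "case"
  res <- carrier_or(sum(is_case & tgt == copies), sum(is_case & tgt == 0),
                    sum(!is_case & tgt == copies), sum(!is_case & tgt == 0))
  attr(res, "target") <- target
  attr(res, "copies") <- copies
  attr(res, "exclusion") <- exclusion
  attr(res, "n_excluded") <- n_excluded
  res
}

#' z-test for the difference of two odds ratios
#'
#' `z = (ln OR1 - ln OR2) / sqrt(SE1^2 + SE2^2)`, with each standard error
#' recovered from the 95% interval as `(ln upper - ln lower) / (2 * 1.96)`,
#' and a two-sided normal p-value.
#'
#' @param result1,result2 `ceh_assoc` rows, or any objects with `or`,
#'   `ci_lower`, `ci_upper` fields.
#' @return list with `z` and `p`.
#' @export
compare_or_z <- function(result1, result2) {
  se_of <- function(r) {
    if (r$ci_upper <= r$ci_lower) stop("degenerate confidence interval")
    (log(r$ci_upper) - log(r$ci_lower)) / (2 * 1.96)
  }
  if (result1$or <= 0 || result2$or <= 0) stop("ORs must be positive")
  z <- (log(result1$or) - log(result2$or)) /
    sqrt(se_of(result1)^2 + se_of(result2)^2)
  list(z = z, p = 2 * stats::pnorm(-abs(z)))
}

#' Class I x Class II association p-value (Fisher / chi-square rule)
#'
#' Association of one Class I allele combination with one Class II
#' combination from the collapsed 2x2 cross-tabulation (target combination
#' against all others on each axis). Uses the Fisher exact test (two-sided
#' by summing tables as or less probable than the observed one) if any
#' expected cell frequency is 5 or less, and otherwise a Pearson
#' chi-square test without continuity correction.
#'
#' @param table 2x2 matrix (or `a`,`b`,`c`,`d` counts via `...`).
#' @return list with `p`, `method` (`"fisher"`/`"chisq"`), `expected`.
#' @export
class1_class2_association <- function(table) {
  tab <- matrix(as.numeric(table), 2, 2)
  if (sum(tab) == 0) stop("empty contingency table")
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (any(expected <= 5)) {
    list(p = stats::fisher.test(tab)$p.value, method = "fisher",
         expected = expected)
  } else {
    list(p = stats::chisq.test(tab, correct = FALSE)$p.value,
         method = "chisq", expected = expected)
  }
}

#' Multiple-testing adjustment: Benjamini-Hochberg or Bonferroni
#'
#' @param pvals raw p-values in `(0, 1]`.
#' @param method `"benjamini-hochberg"` (step-up adjusted values) or
#'   `"bonferroni"` (reports the `alpha/m` threshold and per-test
#'   pass/fail).
#' @param m number of tests (defaults to `length(pvals)`; the Bonferroni
#'   family can be larger than the p-values supplied).
#' @param alpha family-wise significance level.
#' @return list with `method`, `m`, `alpha`, `adjusted` (BH only),
#'   `threshold` and `significant` (Bonferroni only).
#' @export
adjust_pvalues <- function(pvals, method = c("benjamini-hochberg", "bonferroni"),
                           m = length(pvals), alpha = 0.05) {
  method <- match.arg(method)
  if (length(pvals) == 0) stop("no p-values supplied")
  if (any(pvals <= 0 | pvals > 1)) stop("p-values must be in (0, 1]")
  stopifnot(m >= 1, alpha > 0, alpha < 1)
  if (method == "benjamini-hochberg") {
    list(method = method, m = m, alpha = alpha,
         adjusted = stats::p.adjust(pvals, method = "BH", n = m))
  } else {
    thr <- alpha / m
    list(method = method, m = m, alpha = alpha, threshold = thr,
         significant = pvals < thr)
  }
}

#' Covariate-adjusted dose regression for haplotype effects
#'
#' Logistic regression of case/control status on the dose (0, 1 or 2
#' copies) of one or more haplotypes, with optional covariates
#' (principal components, region dummies, sex) and optional pairwise
#' dose-by-dose interactions. Exponentiated dose coefficients estimate
#' per-copy odds ratios.
#'
#' @param phenotype vector (`"case"`/`"control"`, or 0/1).
#' @param doses data frame / matrix of per-haplotype dose vectors.
#' @param covariates optional data frame of covariates; factors (for
#'   example region) are expanded to dummies with the first level dropped.
#' @param interactions logical: add pairwise interactions between the dose
#'   columns.
#' @return tibble: `term`, `estimate` (log-odds), `se`, `z`, `p`, `or`,
#'   `non_estimable` (flagged under separation instead of erroring).
#' @export
dose_regression <- function(phenotype, doses, covariates = NULL,
                            interactions = FALSE) {
  y <- as.integer(phenotype %in% c("case", 1, TRUE))
  doses <- as.data.frame(doses)
  dat <- cbind(data.frame(.y = y), doses)
  rhs <- colnames(doses)
  if (interactions && length(rhs) > 1) {
    rhs <- c(rhs, utils::combn(colnames(doses), 2,
                               FUN = function(p) paste(p, collapse = ":")))
  }
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    keep <- vapply(covariates, function(x) length(unique(x)) > 1, logical(1))
    covariates <- covariates[, keep, drop = FALSE]
    if (ncol(covariates) > 0) {
      dat <- cbind(dat, covariates)
      rhs <- c(rhs, colnames(covariates))
    }
  }
  form <- stats::as.formula(paste(".y ~", paste(rhs, collapse = " + ")))
  mm <- stats::model.matrix(form, dat)
  qr_mm <- qr(mm)
  if (qr_mm$rank < ncol(mm)) {
    aliased <- colnames(mm)[qr_mm$pivot[(qr_mm$rank + 1):ncol(mm)]]
    stop("rank-deficient design; collinear column(s): ",
         paste(aliased, collapse = ", "))
  }
  fit <- suppressWarnings(stats::glm(form, data = dat, family = stats::binomial()))
  sm <- summary(fit)$coefficients
  sep <- !fit$converged | abs(sm[, "Estimate"]) > 15 | sm[, "Std. Error"] > 100
  tibble::tibble(
    term = rownames(sm),
    estimate = sm[, "Estimate"], se = sm[, "Std. Error"],
    z = sm[, "z value"], p = sm[, "Pr(>|z|)"],
    or = exp(sm[, "Estimate"]),
    non_estimable = unname(sep)
  )
}

#' Haplotype-wise association table (Table 2/3 style)
#'
#' Runs [conditional_carrier_or()] for every CEH in a spectrum with at
#' least `min_copies` copies, applying the motif-exclusion rule, and
#' returns a results table mirroring the usual published layout.
#'
#' @param assignments phased assignments with `phenotype`.
#' @param spectrum `ceh_spectrum` of the same assignments (built if
#'   `NULL`).
#' @param exclusion exclusion motif pattern or `NULL`.
#' @param min_copies analyse only CEHs with at least this many copies
#'   (50 in the usual convention).
#' @param copies copy count tested (1 or 2).
#' @param snp_labels optional SNP label map.
#' @return tibble: `haplotype`, `count`, `or`, `ci_lower`, `ci_upper`,
#'   `p`, plus a Bonferroni `significant` flag at `0.05 / n tests`.
#' @export
association_table <- function(assignments, spectrum = NULL, exclusion = NULL,
                              min_copies = 50, copies = 1, snp_labels = NULL) {
  if (is.null(spectrum)) spectrum <- build_spectrum(assignments)
  targets <- spectrum[spectrum$count >= min_copies, ]
  rows <- lapply(seq_len(nrow(targets)), function(i) {
    res <- tryCatch(
      conditional_carrier_or(assignments, targets$haplotype[i],
                             copies = copies, exclusion = exclusion,
                             snp_labels = snp_labels),
      error = function(e) NULL)
    if (is.null(res)) return(NULL)
    tibble::tibble(haplotype = targets$haplotype[i], count = targets$count[i],
                   or = res$or, ci_lower = res$ci_lower,
                   ci_upper = res$ci_upper, p = res$p)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) stop("no haplotype reached ", min_copies, " copies")
  adj <- adjust_pvalues(out$p, "bonferroni", m = nrow(out))
  out$significant <- adj$significant
  attr(out, "bonferroni_threshold") <- adj$threshold
  out
}
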