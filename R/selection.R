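#' Test for homozygote excess against Hardy-Weinberg expectations
#'
#' Under random mating the probability that an individual is homozygous is
#' `q = sum(f_i^2)` over the haplotype frequencies (optionally restricted
#' to a haplotype class, treating class members as interchangeable). The
#' expected homozygote count is `E = N q`; the observed count `O` is
#' compared with a Binomial-variance z-score
#' `z = (O - E) / sqrt(N q (1 - q))` and a two-sided normal p-value.
#'
#' @param frequencies haplotype frequency vector (or a `ceh_spectrum`,
#'   whose `frequency` column is used). Ignored when `expected` is given.
#' @param observed observed number of homozygous individuals.
#' @param n number of individuals.
#' @param expected optional externally supplied expected count; then
#'   `q = expected / n`.
#' @return list of class `ceh_hwe_test`: `n`, `q`, `expected`, `observed`,
#'   `z`, `p`.
#' @export
homozygote_excess_test <- function(frequencies = NULL, observed, n,
                                   expected = NULL) {
  if (observed > n) stop("observed homozygote count exceeds N")
  if (is.null(expected)) {
    f <- if (is.data.frame(frequencies)) frequencies$frequency else frequencies
    if (abs(sum(f) - 1) > 1e-6) stop("frequencies must sum to 1")
    q <- sum(f^2)
    expected <- n * q
  } else {
    q <- expected / n
  }
  if (q <= 0) stop("expected homozygosity rate is zero")
  if (q >= 1) stop("degenerate pool: every individual is expected homozygous")
  z <- (observed - expected) / sqrt(n * q * (1 - q))
  structure(list(n = n, q = q, expected = expected, observed = observed,
                 z = z, p = 2 * stats::pnorm(-abs(z))),
            class = "ceh_hwe_test")
}

#' Construct a two-class (rare/frequent) conversion-selection model
#'
#' Haplotypes are classified as "frequent" or "rare"; the model tracks the
#' frequency `p_f` of the frequent class through generations of random
#' union of gametes, viability selection on the three diplotype classes
#' (relative survivals `w_ff = 1` referent, `w_fr`, `w_rr`), and
#' per-haplotype conversion between the classes with probabilities `c_fr`
#' (frequent to rare) and `c_rf`.
#'
#' @param p_f frequency of the frequent class (in `[0, 1]`).
#' @param c_fr,c_rf conversion probabilities per haplotype per generation.
#' @param w_ff,w_fr,w_rr relative survival of the three diplotype classes
#'   (positive; `w_ff` is the referent and defaults to 1, as does `w_fr` -
#'   selection is modelled on the homozygote classes).
#' @return list of class `ceh_two_class_model`.
#' @export
two_class_model <- function(p_f, c_fr = 0, c_rf = 0,
                            w_ff = 1, w_fr = 1, w_rr = 1) {
  probs <- c(p_f = p_f, c_fr = c_fr, c_rf = c_rf)
  if (any(probs < 0 | probs > 1)) stop("p_f, c_fr, c_rf must be in [0, 1]")
  if (any(c(w_ff, w_fr, w_rr) <= 0)) stop("survival weights must be positive")
  structure(list(p_f = p_f, p_r = 1 - p_f, c_fr = c_fr, c_rf = c_rf,
                 w_ff = w_ff, w_fr = w_fr, w_rr = w_rr),
            class = "ceh_two_class_model")
}

#' Adult diplotype census of a two-class model (after selection)
#'
#' Genotype-class frequencies at conception are the Hardy-Weinberg
#' proportions of `p_f`; viability weighting and renormalisation give the
#' adult census, from which the adult haplotype frequency and the signed
#' deviation of adult homozygosity from the HWE expectation computed at
#' the adult haplotype frequencies are derived.
#'
#' @param model a [two_class_model()].
#' @return list: `P_ff`, `P_fr`, `P_rr` (adult genotype-class
#'   frequencies), `p_adult` (adult frequent-class haplotype frequency),
#'   `hom_obs`, `hom_hwe`, `hwe_deviation` (`hom_obs - hom_hwe`).
#' @export
adult_census <- function(model) {
  p <- model$p_f; q <- 1 - p
  w <- c(model$w_ff * p^2, 2 * model$w_fr * p * q, model$w_rr * q^2)
  w <- w / sum(w)
  p_adult <- w[1] + w[2] / 2
  hom_obs <- w[1] + w[3]
  hom_hwe <- p_adult^2 + (1 - p_adult)^2
  list(P_ff = w[1], P_fr = w[2], P_rr = w[3], p_adult = p_adult,
       hom_obs = hom_obs, hom_hwe = hom_hwe,
       hwe_deviation = hom_obs - hom_hwe)
}

#' Advance the two-class model one generation
#'
#' One generation is: random union of gametes (HWE diplotype classes),
#' viability selection with renormalisation, gamete output, then
#' per-haplotype conversion applied to the gametes (`c_fr` frequent to
#' rare, `c_rf` rare to frequent). `p_f + p_r = 1` is conserved exactly.
#'
#' @param model a [two_class_model()].
#' @return the model with `p_f`, `p_r` updated.
#' @export
forward_generation <- function(model) {
  census <- adult_census(model)
  p_sel <- census$p_adult
  p_next <- p_sel * (1 - model$c_fr) + (1 - p_sel) * model$c_rf
  model$p_f <- p_next
  model$p_r <- 1 - p_next
  model
}

#' Solve for the equilibrium frequent-class frequency
#'
#' Finds the fixed point of [forward_generation()] in `p_f` by bisection
#' on `(0, 1)`. If the one-generation map has no interior sign change the
#' boundary toward which the dynamics drift is returned with
#' `boundary = TRUE`.
#'
#' @param c_fr,c_rf,w_ff,w_fr,w_rr model parameters (see
#'   [two_class_model()]).
#' @param tol bisection tolerance on `p_f`.
#' @return list: `p_f` (equilibrium), `boundary`, `iterations`.
#' @export
equilibrium_solve <- function(c_fr = 0, c_rf = 0, w_ff = 1, w_fr = 1,
                              w_rr = 1, tol = 1e-12) {
  g <- function(p) {
    m <- two_class_model(p, c_fr, c_rf, w_ff, w_fr, w_rr)
    forward_generation(m)$p_f - p
  }
  eps <- 1e-9
  lo <- eps; hi <- 1 - eps
  glo <- g(lo); ghi <- g(hi)
  if (glo == 0) return(list(p_f = lo, boundary = FALSE, iterations = 0L))
  if (ghi == 0) return(list(p_f = hi, boundary = FALSE, iterations = 0L))
  if (sign(glo) == sign(ghi)) {
    ## no interior fixed point: dynamics drift to a boundary
    return(list(p_f = if (glo > 0) 1 else 0, boundary = TRUE,
                iterations = 0L))
  }
  it <- 0L
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    gm <- g(mid)
    if (gm == 0) { lo <- hi <- mid; break }
    if (sign(gm) == sign(glo)) { lo <- mid; glo <- gm } else hi <- mid
    it <- it + 1L
    if (it > 200L) break
  }
  list(p_f = (lo + hi) / 2, boundary = FALSE, iterations = it)
}

#' Estimate conversion rate and rare-homozygote survival from census data
#'
#' Inverts the two-class forward model: finds the net frequent-to-rare
#' conversion probability `c` (with `c_rf = 0`) and the rare-homozygote
#' relative survival `w_rr` whose equilibrium adult census reproduces the
#' observed adult frequent-class haplotype frequency and the observed
#' signed deviation of homozygosity from its HWE expectation. Solved on a
#' coarse parameter grid refined by bounded optimisation.
#'
#' @param n_ff,n_fr,n_rr observed counts of frequent-frequent,
#'   frequent-rare and rare-rare individuals (class homozygosity is
#'   assessed regardless of the actual CEHs in the pair).
#' @param w_fr heterozygote relative survival held fixed (default 1).
#' @param c_max,w_min search bounds: `c` in `[0, c_max]`, `w_rr` in
#'   `[w_min, 1.5]`.
#' @return list: `c_hat`, `w_rr_hat`, `residual` (root-mean-square misfit
#'   of the two matched observables), `feasible` (residual below
#'   `4 / sqrt(N)`), plus the observed `p_adult` and `hwe_deviation`.
#' @export
estimate_conversion_selection <- function(n_ff, n_fr, n_rr, w_fr = 1,
                                          c_max = 0.25, w_min = 0.05) {
  N <- n_ff + n_fr + n_rr
  if (N <= 0) stop("no individuals")
  p_obs <- (2 * n_ff + n_fr) / (2 * N)
  hom_obs <- (n_ff + n_rr) / N
  dev_obs <- hom_obs - (p_obs^2 + (1 - p_obs)^2)

  predict <- function(c, w_rr) {
    eq <- equilibrium_solve(c_fr = c, c_rf = 0, w_fr = w_fr, w_rr = w_rr)
    if (eq$boundary) return(c(NA_real_, NA_real_))
    cen <- adult_census(two_class_model(eq$p_f, c_fr = c, c_rf = 0,
                                        w_fr = w_fr, w_rr = w_rr))
    c(cen$p_adult, cen$hwe_deviation)
  }
  objective <- function(par) {
    pr <- predict(par[1], par[2])
    if (anyNA(pr)) return(1e6)
    (pr[1] - p_obs)^2 + (pr[2] - dev_obs)^2
  }
  grid <- expand.grid(c = seq(0.001, c_max, length.out = 25),
                      w = seq(w_min, 1.5, length.out = 30))
  vals <- apply(grid, 1, objective)
  start <- as.numeric(grid[which.min(vals), ])
  opt <- stats::optim(start, objective, method = "L-BFGS-B",
                      lower = c(1e-6, w_min), upper = c(c_max, 1.5),
                      control = list(factr = 1e4))
  resid <- sqrt(opt$value / 2)
  list(c_hat = opt$par[1], w_rr_hat = opt$par[2], residual = resid,
       feasible = resid <= 4 / sqrt(N),
       p_adult_obs = p_obs, hwe_deviation_obs = dev_obs)
}

#' Classify a spectrum into rare and frequent haplotype classes
#'
#' "Rare" CEHs are those observed exactly once; "frequent" CEHs more than
#' once. Returns per-individual class diplotypes from phased assignments.
#'
#' @param assignments tibble with `hap1`, `hap2`.
#' @param spectrum optional prebuilt `ceh_spectrum` of the assignments.
#' @return list: `class_counts` (named counts of `ff`, `fr`, `rr`
#'   individuals), `p_f` (frequent-class haplotype frequency),
#'   `classes` (per-individual class pair labels).
#' @export
rare_frequent_classes <- function(assignments, spectrum = NULL) {
  if (is.null(spectrum)) spectrum <- build_spectrum(assignments)
  freq_set <- spectrum$haplotype[spectrum$count > 1]
  f1 <- assignments$hap1 %in% freq_set
  f2 <- assignments$hap2 %in% freq_set
  cls <- ifelse(f1 & f2, "ff", ifelse(!f1 & !f2, "rr", "fr"))
  counts <- c(ff = sum(cls == "ff"), fr = sum(cls == "fr"),
              rr = sum(cls == "rr"))
  list(class_counts = counts,
       p_f = (2 * counts["ff"] + counts["fr"]) / (2 * length(cls)),
       classes = cls)
}
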