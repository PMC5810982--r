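#' Build a haplotype pool
#'
#' A pool is the ground truth of the synthetic generator: a set of conserved
#' extended haplotypes (CEHs), their population frequencies (a simplex) and a
#' per-CEH genotype relative-risk triple `(rr0, rr1, rr2)` for carrying 0, 1
#' or 2 copies (`rr0` is always 1, the referent). Supply either an explicit
#' haplotype table or a generator `recipe`.
#'
#' An explicit `haplotypes` table needs a `haplotype` column of full CEH
#' strings (or the six allele columns `A`,`C`,`B`,`DRB1`,`DQB1`,`SNP`) and a
#' `frequency` column; `rr1`/`rr2` default to 1 (no disease effect).
#'
#' A `recipe` draws a two-block frequency spectrum emulating the extreme
#' skew seen in real MHC cohorts: `n_common` common CEHs sharing
#' `common_mass` of the total frequency mass with Zipf-like weights
#' `rank^-skew`, and an `n_rare` long tail sharing the rest with truncated
#' power-law weights `rank^-rare_exponent`. Class II alleles are a
#' deterministic function of the SNP haplotype (tight Class II / SNP
#' linkage); Class I alleles are drawn freely.
#'
#' @param haplotypes explicit pool table (see Details), or `NULL`.
#' @param recipe list with elements `n_common`, `n_rare`, `common_mass`,
#'   `skew`, `rare_exponent`, `seed` (all optional except `seed` when
#'   `n_rare > 0`); or `NULL`.
#' @param tol tolerance on the frequency-sum-to-1 check.
#' @return a `ceh_pool` tibble with columns `haplotype`, the six allele
#'   fields, `frequency`, `rr1`, `rr2`.
#' @export
build_pool <- function(haplotypes = NULL, recipe = NULL, tol = 1e-8) {
  if (is.null(haplotypes) == is.null(recipe)) {
    stop("supply exactly one of `haplotypes` or `recipe`")
  }
  if (!is.null(recipe)) {
    haplotypes <- pool_from_recipe(recipe)
  }
  haplotypes <- tibble::as_tibble(haplotypes)
  if (nrow(haplotypes) == 0) stop("pool must contain at least one haplotype")
  if (!"haplotype" %in% names(haplotypes)) {
    miss <- setdiff(CEH_FIELDS, names(haplotypes))
    if (length(miss) > 0) {
      stop("pool table needs a `haplotype` column or all of: ",
           paste(CEH_FIELDS, collapse = ", "))
    }
    haplotypes$haplotype <- with(haplotypes, ceh_string(A, C, B, DRB1, DQB1, SNP))
  }
  fields <- ceh_split(haplotypes$haplotype)
  for (f in CEH_FIELDS) haplotypes[[f]] <- fields[[f]]
  if (!"frequency" %in% names(haplotypes)) stop("pool table needs a `frequency` column")
  if (!"rr1" %in% names(haplotypes)) haplotypes$rr1 <- 1
  if (!"rr2" %in% names(haplotypes)) haplotypes$rr2 <- 1

  if (anyDuplicated(haplotypes$haplotype)) {
    stop("duplicate haplotypes in pool: ",
         haplotypes$haplotype[duplicated(haplotypes$haplotype)][1])
  }
  bad_snp <- nchar(haplotypes$SNP) != SNP_WIDTH |
    grepl("[^01]", haplotypes$SNP)
  if (any(bad_snp)) {
    stop("SNP haplotype strings must be length ", SNP_WIDTH,
         " over {0,1}; offender: ", haplotypes$SNP[bad_snp][1])
  }
  f <- haplotypes$frequency
  if (any(f < 0)) stop("haplotype frequencies must be non-negative")
  if (abs(sum(f) - 1) > tol) {
    stop("haplotype frequencies must sum to 1 (got ", format(sum(f)), ")")
  }
  if (any(haplotypes$rr1 <= 0) || any(haplotypes$rr2 <= 0)) {
    stop("relative risks must be positive")
  }
  out <- haplotypes[, c("haplotype", CEH_FIELDS, "frequency", "rr1", "rr2")]
  class(out) <- c("ceh_pool", class(out))
  out
}

## Generator recipe -> explicit haplotype table (frequencies and alleles).
pool_from_recipe <- function(recipe) {
  n_common <- recipe$n_common %||% 10L
  n_rare <- recipe$n_rare %||% 2000L
  common_mass <- recipe$common_mass %||% 0.22
  skew <- recipe$skew %||% 1
  rare_exponent <- recipe$rare_exponent %||% 1
  if (is.null(recipe$seed)) stop("recipe needs a `seed`")
  if (n_common < 1 && n_rare < 1) stop("recipe yields an empty pool")
  if (common_mass <= 0 || common_mass > 1) stop("common_mass must be in (0, 1]")
  if (n_rare == 0) common_mass <- 1

  wr <- withr_seed(recipe$seed)
  on.exit(wr())

  wc <- seq_len(n_common)^(-skew)
  freq <- wc / sum(wc) * common_mass
  if (n_rare > 0) {
    wrr <- seq_len(n_rare)^(-rare_exponent)
    rare <- wrr / sum(wrr) * (1 - common_mass)
    ## the tail must stay rarer than the common block so that the top
    ## n_common CEHs carry exactly common_mass: water-fill any excess
    cap <- min(freq) * 0.999
    if ((1 - common_mass) / n_rare > cap) {
      stop("recipe infeasible: rare tail cannot stay below the common block")
    }
    for (i in 1:50) {
      over <- rare > cap
      if (!any(over)) break
      excess <- sum(rare[over] - cap)
      rare[over] <- cap
      rare[!over] <- rare[!over] + excess * rare[!over] / sum(rare[!over])
    }
    rare[rare > cap] <- cap
    rare <- rare / sum(rare) * (1 - common_mass)
    freq <- c(freq, rare)
  }
  n <- n_common + n_rare

  ## SNP alphabet: the named Class II SNP haplotypes first, then random
  ## novel strings for the rare tail. Class II alleles follow the SNP
  ## haplotype deterministically; Class I alleles are drawn freely.
  base <- snp_haplotype_table()
  n_snp <- max(8L, min(n, n_common + ceiling(n_rare / 10)))
  snp_strings <- base$snp
  class2 <- base[, c("DRB1", "DQB1")]
  while (length(snp_strings) < n_snp) {
    cand <- paste(sample(c("0", "1"), SNP_WIDTH, replace = TRUE), collapse = "")
    if (!cand %in% snp_strings) {
      snp_strings <- c(snp_strings, cand)
      class2 <- rbind(class2, tibble::tibble(
        DRB1 = sprintf("DRB1*%02d:01", sample(1:16, 1)),
        DQB1 = sprintf("DQB1*%02d:0%d", sample(2:6, 1), sample(1:3, 1))
      ))
    }
  }
  ## Common CEHs cycle through the common SNP strings; rare CEHs mostly
  ## reuse them (real rare CEHs usually carry a common SNP haplotype) with
  ## occasional novel tails.
  idx_common <- rep_len(seq_len(min(n_common, length(snp_strings))),
                        length.out = n_common)
  idx_rare <- sample(length(snp_strings), n_rare, replace = TRUE,
                     prob = 0.9 * c(rep(1, min(n_common, length(snp_strings))),
                                    rep(0, length(snp_strings) -
                                          min(n_common, length(snp_strings)))) + 0.1)
  idx <- c(idx_common, idx_rare)

  a_alleles <- sprintf("A*%02d:01", c(1:3, 11, 23:26, 29:33, 66, 68))
  c_alleles <- sprintf("C*%02d:0%d", c(1, 3:8, 12, 15:17), rep(1:2, length.out = 11))
  b_alleles <- sprintf("B*%02d:01", c(7, 8, 13, 14, 15, 18, 27, 35, 37,
                                      39, 40, 41, 44, 49, 51, 55, 57))
  tab <- tibble::tibble(
    A = sample(a_alleles, n, replace = TRUE),
    C = sample(c_alleles, n, replace = TRUE),
    B = sample(b_alleles, n, replace = TRUE),
    DRB1 = class2$DRB1[idx],
    DQB1 = class2$DQB1[idx],
    SNP = snp_strings[idx],
    frequency = freq
  )
  tab$haplotype <- with(tab, ceh_string(A, C, B, DRB1, DQB1, SNP))
  ## resolve collisions: resample Class I until all tuples are distinct
  for (attempt in 1:100) {
    dup <- duplicated(tab$haplotype)
    if (!any(dup)) break
    k <- which(dup)
    tab$A[k] <- sample(a_alleles, length(k), replace = TRUE)
    tab$C[k] <- sample(c_alleles, length(k), replace = TRUE)
    tab$B[k] <- sample(b_alleles, length(k), replace = TRUE)
    tab$haplotype <- with(tab, ceh_string(A, C, B, DRB1, DQB1, SNP))
  }
  if (anyDuplicated(tab$haplotype)) {
    tab <- tab[!duplicated(tab$haplotype), ]
    tab$frequency <- tab$frequency / sum(tab$frequency)
  }
  tab
}

#' Define a subpopulation scheme (Wahlund construction)
#'
#' @param mixing_weights numeric simplex: probability that an individual
#'   belongs to each subpopulation.
#' @param frequencies matrix (subpopulation x haplotype) of per-subpopulation
#'   haplotype frequencies; each row a simplex over the pool's haplotypes.
#' @return a `ceh_subpop_scheme` list.
#' @export
subpop_scheme <- function(mixing_weights, frequencies) {
  frequencies <- as.matrix(frequencies)
  if (length(mixing_weights) != nrow(frequencies)) {
    stop("one frequency row per subpopulation is required")
  }
  if (abs(sum(mixing_weights) - 1) > 1e-8 || any(mixing_weights < 0)) {
    stop("mixing weights must form a simplex")
  }
  if (any(abs(rowSums(frequencies) - 1) > 1e-8) || any(frequencies < 0)) {
    stop("each subpopulation's frequencies must form a simplex")
  }
  structure(list(mixing_weights = mixing_weights, frequencies = frequencies),
            class = "ceh_subpop_scheme")
}

## set.seed scoped to the calling computation; returns a restore function.
withr_seed <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  set.seed(seed)
  function() {
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }
}

`%||%` <- function(x, y) if (is.null(x)) y else x
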