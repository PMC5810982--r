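#' Enumerate all haplotype pairs compatible with an unphased genotype
#'
#' For a genotype heterozygous at k loci there are `max(1, 2^(k-1))`
#' distinct unordered haplotype pairs whose locus-wise union reproduces the
#' genotype. Pairs are returned in canonical (lexicographic) order.
#'
#' @param genotype one individual's genotype: a character vector of
#'   `"x/y"` calls (one per locus, in locus order), or a list of length-2
#'   allele vectors.
#' @param collapse separator used to join per-locus alleles into haplotype
#'   strings (`"~"` for HLA/extended haplotypes, `""` for SNP windows).
#' @return tibble with columns `hap1`, `hap2`, `het` (is the pair
#'   heterozygous, i.e. hap1 != hap2).
#' @export
enumerate_compatible_pairs <- function(genotype, collapse = "~") {
  if (is.character(genotype)) {
    alleles <- strsplit(genotype, "/", fixed = TRUE)
  } else {
    alleles <- genotype
  }
  nal <- lengths(alleles)
  if (any(nal != 2)) {
    stop("each locus needs exactly two alleles (locus ", which(nal != 2)[1],
         " has ", nal[nal != 2][1], ")")
  }
  if (anyNA(unlist(alleles))) stop("missing calls are not allowed here")
  L <- length(alleles)
  a1 <- vapply(alleles, `[`, character(1), 1)
  a2 <- vapply(alleles, `[`, character(1), 2)
  het <- which(a1 != a2)
  k <- length(het)
  if (k == 0) {
    h <- paste(a1, collapse = collapse)
    return(tibble::tibble(hap1 = h, hap2 = h, het = FALSE))
  }
  ## fix the orientation of the first heterozygous locus to halve the
  ## enumeration (unordered pairs)
  free <- het[-1]
  combos <- if (length(free) == 0) {
    matrix(integer(0), nrow = 1, ncol = 0)
  } else {
    as.matrix(expand.grid(rep(list(1:2), length(free)),
                          KEEP.OUT.ATTRS = FALSE))
  }
  n_pairs <- nrow(combos)
  m1 <- matrix(a1, nrow = n_pairs, ncol = L, byrow = TRUE)
  m2 <- m1
  m2[, het] <- rep(a2[het], each = n_pairs)
  m1[, het[1]] <- a1[het[1]]
  m2[, het[1]] <- a2[het[1]]
  if (length(free) > 0) {
    for (j in seq_along(free)) {
      flip <- combos[, j] == 2
      m1[flip, free[j]] <- a2[free[j]]
      m2[flip, free[j]] <- a1[free[j]]
    }
  }
  h1 <- apply(m1, 1, paste, collapse = collapse)
  h2 <- apply(m2, 1, paste, collapse = collapse)
  pr <- canonical_pair(h1, h2)
  out <- tibble::tibble(hap1 = pr$hap1, hap2 = pr$hap2, het = TRUE)
  out[order(out$hap1, out$hap2), ]
}

## Collapse a genotype matrix to unique row patterns with multiplicities
## and the long table of compatible pairs, indexed against a haplotype
## dictionary. Rows with any NA are excluded (callers report the count).
compile_patterns <- function(gm, collapse) {
  key <- apply(gm, 1, paste, collapse = "|")
  upat <- !duplicated(key)
  ukey <- key[upat]
  cnt <- as.vector(table(factor(key, levels = ukey)))
  pair_list <- lapply(which(upat), function(i) {
    enumerate_compatible_pairs(gm[i, ], collapse = collapse)
  })
  np <- vapply(pair_list, nrow, integer(1))
  pairs <- do.call(rbind, pair_list)
  pid <- rep(seq_along(pair_list), np)
  haps <- sort(unique(c(pairs$hap1, pairs$hap2)))
  list(
    n_patterns = length(ukey), counts = cnt, haplotypes = haps,
    pid = pid,
    i1 = match(pairs$hap1, haps), i2 = match(pairs$hap2, haps),
    mult = ifelse(pairs$het, 2, 1),
    row_pattern = match(key, ukey)
  )
}

#' Estimate haplotype frequencies from unphased genotypes by EM
#'
#' Standard multinomial expectation-maximization over the compatible
#' haplotype pairs of each genotype. The E-step weights each compatible
#' pair (a, b) of an individual by `2^[a != b] * f_a * f_b`, normalised per
#' individual; the M-step sets each haplotype frequency to its expected
#' dose divided by 2N. Frequencies are initialised uniformly over the
#' haplotypes compatible with at least one observed genotype. Individuals
#' with any missing call at the phased loci are excluded from the run.
#'
#' After iteration 5, haplotypes whose estimated frequency has fallen
#' below `prune_threshold` (default `1/(4N)`) are dropped (unless that
#' would leave some genotype without a compatible pair) and the remaining
#' frequencies renormalised.
#'
#' @param genotypes data frame or character matrix of `"x/y"` calls, one
#'   row per individual, one column per locus in locus order.
#' @param tol convergence tolerance on the maximum absolute frequency
#'   change per iteration.
#' @param max_iter maximum EM iterations; exceeding it flags the result
#'   as non-converged rather than erroring.
#' @param prune_threshold frequency below which haplotypes are pruned
#'   after iteration 5; `NULL` for the `1/(4N)` default, `0` disables.
#' @param collapse separator for haplotype strings (see
#'   [enumerate_compatible_pairs()]).
#' @return object of class `ceh_phasing`: list with `frequencies`
#'   (tibble `haplotype`, `frequency`), `loglik` (per-iteration trace),
#'   `converged`, `n_iter`, `n_used`, `n_excluded`.
#' @export
em_haplotype_frequencies <- function(genotypes, tol = 1e-6, max_iter = 200,
                                     prune_threshold = NULL, collapse = "~") {
  stopifnot(tol > 0)
  gm <- as.matrix(genotypes)
  if (nrow(gm) == 0) stop("at least one genotype is required")
  ok <- stats::complete.cases(gm)
  n_excluded <- sum(!ok)
  gm <- gm[ok, , drop = FALSE]
  if (nrow(gm) == 0) stop("no complete genotypes to phase")
  N <- nrow(gm)
  if (is.null(prune_threshold)) prune_threshold <- 1 / (4 * N)

  cp <- compile_patterns(gm, collapse)
  H <- length(cp$haplotypes)
  f <- rep(1 / H, H)
  pid <- cp$pid; i1 <- cp$i1; i2 <- cp$i2; mult <- cp$mult
  cnt <- cp$counts
  ll_trace <- numeric(0)
  converged <- FALSE
  keep <- rep(TRUE, H)

  for (iter in seq_len(max_iter)) {
    w <- f[i1] * f[i2] * mult
    tot <- as.vector(rowsum(w, pid))
    ll_trace <- c(ll_trace, sum(cnt * log(tot)))
    wn <- w / tot[pid] * cnt[pid]
    dose <- as.vector(rowsum(c(wn, wn), c(i1, i2), reorder = FALSE))
    grp <- unique(c(i1, i2))
    f_new <- numeric(H)
    f_new[grp] <- dose
    f_new <- f_new / (2 * N)
    delta <- max(abs(f_new - f))
    f <- f_new

    if (iter == 5 && prune_threshold > 0) {
      drop <- f < prune_threshold & keep
      if (any(drop)) {
        pair_ok <- !(drop[i1] | drop[i2])
        ## never orphan a genotype: restore the currently best pair of any
        ## pattern that would lose all its compatible pairs
        per_pat <- rowsum(as.numeric(pair_ok), pid)
        orphan <- as.integer(rownames(per_pat))[per_pat[, 1] == 0]
        for (p in orphan) {
          rows <- which(pid == p)
          best <- rows[which.max(w[rows])]
          drop[c(i1[best], i2[best])] <- FALSE
        }
        pair_ok <- !(drop[i1] | drop[i2])
        pid <- pid[pair_ok]; i1 <- i1[pair_ok]; i2 <- i2[pair_ok]
        mult <- mult[pair_ok]
        f[drop] <- 0
        f <- f / sum(f)
        keep <- !drop
      }
    }
    if (delta < tol) {
      converged <- TRUE
      break
    }
  }
  ord <- order(-f, cp$haplotypes)
  ord <- ord[f[ord] > 0]
  structure(list(
    frequencies = tibble::tibble(haplotype = cp$haplotypes[ord],
                                 frequency = f[ord]),
    loglik = ll_trace, converged = converged, n_iter = length(ll_trace),
    n_used = N, n_excluded = n_excluded
  ), class = "ceh_phasing")
}

#' Assign the most likely haplotype pair to one genotype
#'
#' Each compatible pair is weighted `2^[het] * f_a * f_b`; the posterior of
#' a pair is its weight over the sum across compatible pairs. The maximum-
#' posterior pair is returned; exact ties are broken lexicographically on
#' the canonical pair encoding. Haplotypes missing from the frequency table
#' are treated as frequency zero; if every compatible pair has zero weight
#' the genotype is flagged unassignable.
#'
#' @param genotype as in [enumerate_compatible_pairs()].
#' @param frequencies tibble with `haplotype`, `frequency` (for example
#'   from [em_haplotype_frequencies()]).
#' @param collapse haplotype string separator.
#' @return one-row tibble: `hap1`, `hap2`, `posterior`, `unassignable`.
#' @export
assign_best_pair <- function(genotype, frequencies, collapse = "~") {
  pairs <- enumerate_compatible_pairs(genotype, collapse = collapse)
  f <- stats::setNames(frequencies$frequency, frequencies$haplotype)
  g1 <- f[pairs$hap1]; g1[is.na(g1)] <- 0
  g2 <- f[pairs$hap2]; g2[is.na(g2)] <- 0
  w <- unname(g1 * g2 * ifelse(pairs$het, 2, 1))
  tot <- sum(w)
  if (tot == 0) {
    return(tibble::tibble(hap1 = NA_character_, hap2 = NA_character_,
                          posterior = NA_real_, unassignable = TRUE))
  }
  best <- which(w == max(w))[1] # pairs are already in canonical lexicographic order
  tibble::tibble(hap1 = pairs$hap1[best], hap2 = pairs$hap2[best],
                 posterior = w[best] / tot, unassignable = FALSE)
}

#' Assign most likely pairs to a whole genotype table
#'
#' Vectorised [assign_best_pair()] over the rows of a genotype matrix;
#' identical genotype patterns are phased once. Rows with missing calls
#' get an `NA` assignment.
#'
#' @inheritParams em_haplotype_frequencies
#' @param frequencies tibble with `haplotype`, `frequency`.
#' @return tibble with one row per input row: `hap1`, `hap2`, `posterior`,
#'   `unassignable`.
#' @export
assign_best_pairs <- function(genotypes, frequencies, collapse = "~") {
  gm <- as.matrix(genotypes)
  ok <- stats::complete.cases(gm)
  out <- tibble::tibble(hap1 = rep(NA_character_, nrow(gm)),
                        hap2 = NA_character_, posterior = NA_real_,
                        unassignable = NA)
  if (!any(ok)) return(out)
  key <- apply(gm[ok, , drop = FALSE], 1, paste, collapse = "|")
  upat <- which(!duplicated(key))
  assigned <- do.call(rbind, lapply(upat, function(i) {
    assign_best_pair(gm[ok, , drop = FALSE][i, ], frequencies,
                     collapse = collapse)
  }))
  idx <- match(key, key[upat])
  out[ok, ] <- assigned[idx, ]
  out
}

#' Fraction of phasing assignments above posterior thresholds
#'
#' @param posteriors numeric vector of per-individual posterior
#'   probabilities of the assigned pair.
#' @param thresholds thresholds; the reported fraction is of posteriors
#'   strictly greater than each.
#' @return named numeric vector of fractions.
#' @export
posterior_coverage_summary <- function(posteriors, thresholds = c(0.5, 0.6, 0.7)) {
  posteriors <- posteriors[!is.na(posteriors)]
  if (length(posteriors) == 0) stop("no assignments to summarise")
  vapply(thresholds, function(t) mean(posteriors > t), numeric(1)) |>
    stats::setNames(paste0(">", thresholds))
}

#' Scan sliding SNP windows for the strongest disease-associated haplotype
#'
#' Every window of `widths` consecutive SNPs is phased by EM; within a
#' window, each haplotype with at least `min_copies` assigned copies is
#' tested for association by a carrier chi-square (carriers of >= 1 copy
#' against phenotype, 2x2 Pearson chi-square without continuity
#' correction), and the window's score is the minimum p-value. The window
#' with the smallest score is selected; ties go to the smaller width, then
#' the leftmost start. Window coordinates are 0-based, half-open over the
#' ordered SNP list.
#'
#' @param snp_genotypes matrix/data frame of `"0/1"`-style calls, columns
#'   in SNP order.
#' @param phenotype vector coercible to two levels (`"case"`/`"control"`).
#' @param widths window widths to scan (clipped to the number of SNPs).
#' @param min_copies minimum assigned copy count for a haplotype to be
#'   tested.
#' @param ... passed to [em_haplotype_frequencies()].
#' @return object of class `ceh_window_scan`: list with `windows` (tibble
#'   `start`, `width`, `best_haplotype`, `p`) and `selected` (one row).
#' @export
scan_snp_windows <- function(snp_genotypes, phenotype, widths = 2:15,
                             min_copies = 10, ...) {
  gm <- as.matrix(snp_genotypes)
  S <- ncol(gm)
  widths <- sort(unique(widths[widths >= 2]))
  if (length(widths) == 0 || min(widths) > S) {
    stop("fewer SNPs (", S, ") than the smallest window width")
  }
  widths <- widths[widths <= S]
  is_case <- phenotype %in% c("case", 1, TRUE)
  rows <- list()
  for (w in widths) {
    for (start in 0:(S - w)) {
      sub <- gm[, (start + 1):(start + w), drop = FALSE]
      ok <- stats::complete.cases(sub)
      fit <- em_haplotype_frequencies(sub[ok, , drop = FALSE],
                                      collapse = "", ...)
      asg <- assign_best_pairs(sub[ok, , drop = FALSE], fit$frequencies,
                               collapse = "")
      copies_tab <- table(c(asg$hap1, asg$hap2))
      eligible <- names(copies_tab)[copies_tab >= min_copies]
      best_p <- NA_real_; best_h <- NA_character_
      for (h in eligible) {
        carrier <- asg$hap1 == h | asg$hap2 == h
        tab <- table(factor(carrier, levels = c(TRUE, FALSE)),
                     factor(is_case[ok], levels = c(TRUE, FALSE)))
        if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) next
        p <- suppressWarnings(stats::chisq.test(tab, correct = FALSE)$p.value)
        if (!is.na(p) && (is.na(best_p) || p < best_p)) {
          best_p <- p; best_h <- h
        }
      }
      rows[[length(rows) + 1]] <-
        tibble::tibble(start = start, width = w, best_haplotype = best_h,
                       p = best_p)
    }
  }
  windows <- do.call(rbind, rows)
  cand <- windows[!is.na(windows$p), ]
  if (nrow(cand) == 0) stop("no testable haplotype in any window")
  sel <- cand[order(cand$p, cand$width, cand$start), ][1, ]
  structure(list(windows = windows, selected = sel),
            class = "ceh_window_scan")
}

#' Phase extended haplotypes: 11-SNP window plus five HLA loci
#'
#' Staged phasing of the full conserved extended haplotype. The SNP window
#' is phased first by EM and each individual is assigned its most likely
#' SNP haplotype pair; the window is then collapsed to a single
#' multi-allelic "SNP-haplotype" locus and EM is run jointly over
#' HLA-A, -C, -B, -DRB1, -DQB1 and that locus. Individuals with a missing
#' call at any involved locus are excluded.
#'
#' @param records genotype records (from [unphase()] or [read_inputs()]):
#'   columns `A`,`C`,`B`,`DRB1`,`DQB1` plus SNP call columns.
#' @param snp_cols names of the SNP call columns, in SNP order.
#' @param ... passed to [em_haplotype_frequencies()] for both stages.
#' @return list of class `ceh_extended_phasing`: `frequencies` (six-locus
#'   CEH frequency table), `assignments` (per-sample `hap1`, `hap2`,
#'   `posterior`, joined canonical CEH strings), `snp_fit` and `em` (the
#'   two stage fits), `n_excluded`.
#' @export
phase_extended_haplotypes <- function(records,
                                      snp_cols = sprintf("s%02d", 1:SNP_WIDTH),
                                      ...) {
  cols <- c(HLA_LOCI, snp_cols)
  miss <- setdiff(cols, names(records))
  if (length(miss) > 0) stop("missing genotype columns: ", paste(miss, collapse = ", "))
  gm <- as.matrix(records[, cols])
  ok <- stats::complete.cases(gm)
  n_excluded <- sum(!ok)
  used <- records[ok, , drop = FALSE]

  snp_gm <- as.matrix(used[, snp_cols])
  snp_fit <- em_haplotype_frequencies(snp_gm, collapse = "", ...)
  snp_asg <- assign_best_pairs(snp_gm, snp_fit$frequencies, collapse = "")

  six <- cbind(as.matrix(used[, HLA_LOCI]),
               SNP = genotype_call(snp_asg$hap1, snp_asg$hap2))
  em <- em_haplotype_frequencies(six, collapse = "~", ...)
  asg <- assign_best_pairs(six, em$frequencies, collapse = "~")
  assignments <- tibble::tibble(
    sample_id = if ("sample_id" %in% names(used)) used$sample_id
                else sprintf("S%05d", seq_len(nrow(used))),
    hap1 = asg$hap1, hap2 = asg$hap2, posterior = asg$posterior
  )
  if ("phenotype" %in% names(used)) assignments$phenotype <- used$phenotype
  if ("region" %in% names(used)) assignments$region <- used$region
  structure(list(frequencies = em$frequencies, assignments = assignments,
                 snp_fit = snp_fit, em = em, n_excluded = n_excluded),
            class = "ceh_extended_phasing")
}
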