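#' Build the CEH copy-count spectrum from assigned haplotype pairs
#'
#' Each phased individual contributes both haplotypes of its assigned
#' pair, so the spectrum totals 2 copies per individual. With `group`
#' labels, one spectrum is built per group; the group spectra partition
#' the global one.
#'
#' @param assignments tibble with `hap1`, `hap2` (one row per individual),
#'   or a list/two-column object of pairs.
#' @param group optional vector of group labels (region, cohort, ...).
#' @return a `ceh_spectrum` tibble: `haplotype`, `count`, `rank`
#'   (descending count, ties broken on the haplotype string), `frequency`,
#'   `percent`, `cum_percent`, and `group` when grouped.
#' @export
build_spectrum <- function(assignments, group = NULL) {
  haps <- c(assignments$hap1, assignments$hap2)
  if (anyNA(haps)) {
    keep <- !(is.na(assignments$hap1) | is.na(assignments$hap2))
    assignments <- assignments[keep, ]
    if (!is.null(group)) group <- group[keep]
    haps <- c(assignments$hap1, assignments$hap2)
  }
  one <- function(h, g = NA_character_) {
    tab <- table(h)
    out <- tibble::tibble(haplotype = names(tab), count = as.integer(tab))
    out <- out[order(-out$count, out$haplotype), ]
    out$rank <- seq_len(nrow(out))
    out$frequency <- out$count / sum(out$count)
    out$percent <- 100 * out$frequency
    out$cum_percent <- cumsum(out$percent)
    if (!is.na(g)) out$group <- g
    class(out) <- c("ceh_spectrum", class(out))
    out
  }
  if (is.null(group)) return(one(haps))
  gg <- rep(as.character(group), 2)
  out <- do.call(rbind, lapply(sort(unique(gg)), function(g) one(haps[gg == g], g)))
  class(out) <- c("ceh_spectrum", class(out))
  out
}

#' Build a spectrum from a copy-count vector
#'
#' @param counts integer copy counts, one per unique CEH.
#' @param haplotype optional names (defaults to `c1`, `c2`, ... in rank
#'   order of the supplied counts).
#' @return a `ceh_spectrum` tibble.
#' @export
spectrum_from_counts <- function(counts, haplotype = NULL) {
  if (is.null(haplotype)) haplotype <- sprintf("c%0*d", nchar(length(counts)),
                                               seq_along(counts))
  out <- tibble::tibble(haplotype = haplotype, count = as.integer(counts))
  out <- out[order(-out$count, out$haplotype), ]
  out$rank <- seq_len(nrow(out))
  out$frequency <- out$count / sum(out$count)
  out$percent <- 100 * out$frequency
  out$cum_percent <- cumsum(out$percent)
  class(out) <- c("ceh_spectrum", class(out))
  out
}

#' Summarise a frequency spectrum: top-k coverage and rare-tail shares
#'
#' @param spectrum a `ceh_spectrum` (ungrouped).
#' @param top_k vector of k values: report copies and percent of all
#'   copies carried by the k most common CEHs.
#' @param multiplicity_cutoffs vector of m values: report how many unique
#'   CEHs have `count <= m`, their share of unique CEHs and of copies.
#' @return list with `total_copies`, `n_unique`, `top` (tibble `k`,
#'   `copies`, `percent`, `percent_rounded`), `tail` (tibble `max_count`,
#'   `n_unique`, `percent_unique`, `percent_unique_rounded`, `copies`,
#'   `percent_copies`). Rounded percentages are to the nearest integer,
#'   matching the usual reporting style; raw values are retained.
#' @export
spectrum_summary <- function(spectrum, top_k = c(10, 25),
                             multiplicity_cutoffs = c(1, 2)) {
  stopifnot(nrow(spectrum) > 0)
  counts <- sort(spectrum$count, decreasing = TRUE)
  total <- sum(counts)
  top <- do.call(rbind, lapply(top_k, function(k) {
    cp <- sum(counts[seq_len(min(k, length(counts)))])
    tibble::tibble(k = k, copies = cp, percent = 100 * cp / total,
                   percent_rounded = round(100 * cp / total))
  }))
  tail <- do.call(rbind, lapply(multiplicity_cutoffs, function(m) {
    sel <- counts <= m
    tibble::tibble(max_count = m, n_unique = sum(sel),
                   percent_unique = 100 * mean(sel),
                   percent_unique_rounded = round(100 * mean(sel)),
                   copies = sum(counts[sel]),
                   percent_copies = 100 * sum(counts[sel]) / total)
  }))
  list(total_copies = total, n_unique = length(counts), top = top, tail = tail)
}

#' Cumulative coverage curve of a frequency spectrum
#'
#' Unique CEHs sorted by descending copy count against the cumulative
#' percent of all copies they account for (the classic "few common CEHs
#' carry most of the population" curve).
#'
#' @param spectrum a `ceh_spectrum` (ungrouped).
#' @return tibble with `n_unique` (1..number of unique CEHs) and
#'   `cum_percent`, non-decreasing and reaching 100 at the last CEH.
#' @export
coverage_curve <- function(spectrum) {
  stopifnot(nrow(spectrum) > 0)
  counts <- sort(spectrum$count, decreasing = TRUE)
  tibble::tibble(n_unique = seq_along(counts),
                 cum_percent = 100 * cumsum(counts) / sum(counts))
}

#' Rank reference CEHs within each group's spectrum
#'
#' For a set of reference CEHs (by default the global top 10), report each
#' one's rank inside every group spectrum; a reference CEH absent from a
#' group gets `NA`. Groups can be ordered by the descending within-group
#' frequency of a chosen CEH.
#'
#' @param spectra a grouped `ceh_spectrum` (from `build_spectrum(...,
#'   group = )`), or a list of ungrouped spectra named by group.
#' @param reference character vector of reference CEHs; `NULL` takes the
#'   top 10 of the pooled spectrum.
#' @param order_by optional single CEH whose descending frequency orders
#'   the group columns.
#' @return tibble `haplotype` x one rank column per group (ordered).
#' @export
rank_by_group <- function(spectra, reference = NULL, order_by = NULL) {
  if (!is.data.frame(spectra)) {
    spectra <- do.call(rbind, lapply(names(spectra), function(g) {
      s <- spectra[[g]]; s$group <- g; s
    }))
  }
  if (!"group" %in% names(spectra)) stop("at least one group is required")
  groups <- unique(spectra$group)
  if (is.null(reference)) {
    pooled <- stats::aggregate(count ~ haplotype, data = spectra, FUN = sum)
    pooled <- pooled[order(-pooled$count, pooled$haplotype), ]
    reference <- utils::head(pooled$haplotype, 10)
  }
  if (!is.null(order_by)) {
    fr <- vapply(groups, function(g) {
      s <- spectra[spectra$group == g, ]
      i <- match(order_by, s$haplotype)
      if (is.na(i)) 0 else s$frequency[i]
    }, numeric(1))
    groups <- groups[order(-fr)]
  }
  out <- tibble::tibble(haplotype = reference)
  for (g in groups) {
    s <- spectra[spectra$group == g, ]
    out[[g]] <- s$rank[match(reference, s$haplotype)]
  }
  out
}

#' Synthetic copy-count spectrum matching large-cohort aggregate totals
#'
#' A deterministic synthetic spectrum whose aggregate structure matches
#' the shape reported for MHC extended-haplotype studies of large
#' case-control cohorts: 59,884 haplotype copies (2 per individual over
#' 29,942 individuals), 10,078 unique CEHs, 13,302 copies in the 10 most
#' common CEHs, 6,016 singletons and 1,397 doubletons. The individual
#' counts between those anchors are a smooth synthetic interpolation, not
#' observed data; only the aggregate summaries are meaningful.
#'
#' @return integer vector of copy counts in descending order.
#' @export
synthetic_cohort_counts <- function() {
  top10 <- c(3782, 2961, 1465, 910, 906, 728, 700, 660, 610, 580)
  n_single <- 6016L
  n_double <- 1397L
  n_unique <- 10078L
  total <- 59884L
  n_mid <- n_unique - 10L - n_single - n_double
  mid_total <- total - sum(top10) - n_single - 2L * n_double

  ## descending mid-range counts in [3, 580]: power-of-rank profile with
  ## the exponent solved so the continuous sum hits the target
  shape <- function(g) 3 + (580 - 3) * ((n_mid - seq_len(n_mid)) / (n_mid - 1))^g
  g <- stats::uniroot(function(g) sum(shape(g)) - mid_total,
                      c(1, 500), tol = 1e-10)$root
  mid <- round(shape(g))
  mid <- pmin(pmax(mid, 3L), 580L)
  gap <- mid_total - sum(mid)
  step <- sign(gap)
  i <- 1L
  while (gap != 0L) {
    cand <- mid[i] + step
    upper <- if (i == 1L) 580L else mid[i - 1L]
    lower <- if (i == n_mid) 3L else mid[i + 1L]
    if (cand >= max(3L, lower) && cand <= min(580L, upper)) {
      mid[i] <- cand
      gap <- gap - step
    }
    i <- if (i == n_mid) 1L else i + 1L
  }
  counts <- c(top10, mid, rep(2L, n_double), rep(1L, n_single))
  stopifnot(sum(counts) == total, length(counts) == n_unique,
            !is.unsorted(rev(counts)))
  as.integer(counts)
}
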