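#' HLA-motif carriage as a function of Hamming distance from an anchor
#'
#' Groups haplotype copies by the Hamming distance of their SNP part from
#' an anchor SNP haplotype and reports, per distance, how often the copies
#' carry a given HLA motif - the profile used to argue that motif carriage
#' is a property of the specific SNP haplotype rather than of its distance
#' from the anchor. The distance-0 class contains only the anchor itself.
#'
#' Both weightings are emitted: the overall (copy-weighted) proportion per
#' distance, and the per-unique-SNP-haplotype breakdown, whose
#' copy-weighted mean reproduces the overall proportion exactly. Unique
#' SNP haplotypes are split into the two conventional subgroups carrying
#' the motif on fewer than 10% versus at least 10% of their copies.
#'
#' @param haplotypes tibble of unique CEHs with copy counts: either a
#'   `ceh_spectrum` (`haplotype`, `count`) or any table with those two
#'   columns.
#' @param anchor the anchor SNP haplotype (binary string or label, e.g.
#'   `"a1"`).
#' @param motif HLA motif pattern over the five HLA loci (and optionally
#'   the SNP field), e.g. `"*~*~*~DRB1*15:01~DQB1*06:02~*"`.
#' @param snp_labels optional SNP label map (see [resolve_snp_label()]).
#' @param subgroup_cut carriage proportion splitting the two subgroups
#'   (default 0.10).
#' @return list of class `ceh_distance_profile`:
#'   `overall` (tibble `distance`, `copies`, `carriers`, `proportion`),
#'   `by_haplotype` (tibble `snp`, `distance`, `copies`, `carriers`,
#'   `proportion`, `subgroup`), and `subgroups` (per-subgroup
#'   copy-weighted curves).
#' @export
carriage_by_distance <- function(haplotypes, anchor, motif,
                                 snp_labels = NULL, subgroup_cut = 0.10) {
  anchor <- resolve_snp_label(anchor, snp_labels)
  if (nchar(anchor) != SNP_WIDTH || grepl("[^01]", anchor)) {
    stop("anchor must be a length-", SNP_WIDTH, " binary SNP haplotype")
  }
  tab <- tibble::as_tibble(haplotypes)[, c("haplotype", "count")]
  fields <- ceh_split(tab$haplotype)
  tab$snp <- fields$SNP
  tab$distance <- hamming(tab$snp, anchor)
  tab$carries <- motif_matches(tab$haplotype, motif, snp_labels)

  by_snp <- dplyr::summarise(
    dplyr::group_by(tab, .data$snp, .data$distance),
    copies = sum(.data$count),
    carriers = sum(.data$count[.data$carries]),
    .groups = "drop")
  by_snp$proportion <- by_snp$carriers / by_snp$copies
  by_snp$subgroup <- ifelse(by_snp$proportion < subgroup_cut,
                            sprintf("<%d%%", round(100 * subgroup_cut)),
                            sprintf(">=%d%%", round(100 * subgroup_cut)))
  by_snp <- by_snp[order(by_snp$distance, by_snp$snp), ]

  overall <- dplyr::summarise(
    dplyr::group_by(by_snp, .data$distance),
    copies = sum(.data$copies), carriers = sum(.data$carriers),
    .groups = "drop")
  overall$proportion <- overall$carriers / overall$copies

  subgroups <- dplyr::summarise(
    dplyr::group_by(by_snp, .data$subgroup, .data$distance),
    copies = sum(.data$copies), carriers = sum(.data$carriers),
    .groups = "drop")
  subgroups$proportion <- subgroups$carriers / subgroups$copies

  structure(list(overall = overall, by_haplotype = by_snp,
                 subgroups = subgroups, anchor = anchor, motif = motif),
            class = "ceh_distance_profile")
}
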