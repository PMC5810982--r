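#' @keywords internal
#' @importFrom rlang .data
"_PACKAGE"

## Locus order used everywhere: Class I (A, C, B), Class II (DRB1, DQB1),
## then the 11-SNP haplotype locus treated as one multi-allelic gene.
HLA_LOCI <- c("A", "C", "B", "DRB1", "DQB1")
CEH_FIELDS <- c(HLA_LOCI, "SNP")
SNP_WIDTH <- 11L

#' Join per-locus alleles into a canonical extended-haplotype string
#'
#' A conserved extended haplotype (CEH) is written as the `~`-joined tuple of
#' alleles at HLA-A, -C, -B, -DRB1, -DQB1 plus the 11-character binary SNP
#' haplotype, e.g. `"A*03:01~C*07:02~B*07:02~DRB1*15:01~DQB1*06:02~10110100010"`.
#'
#' @param A,C,B,DRB1,DQB1 character vectors of HLA allele names.
#' @param SNP character vector of 11-character binary SNP haplotypes.
#' @return character vector of CEH strings.
#' @export
ceh_string <- function(A, C, B, DRB1, DQB1, SNP) {
  paste(A, C, B, DRB1, DQB1, SNP, sep = "~")
}

#' Split CEH strings into a tibble of per-locus alleles
#'
#' @param haplotype character vector of `~`-joined CEH strings (6 fields).
#' @return tibble with columns `A`, `C`, `B`, `DRB1`, `DQB1`, `SNP`.
#' @export
ceh_split <- function(haplotype) {
  parts <- strsplit(haplotype, "~", fixed = TRUE)
  bad <- lengths(parts) != length(CEH_FIELDS)
  if (any(bad)) {
    stop("malformed CEH string (expected ", length(CEH_FIELDS),
         " '~'-separated fields): ", haplotype[bad][1])
  }
  m <- do.call(rbind, parts)
  colnames(m) <- CEH_FIELDS
  tibble::as_tibble(m)
}

#' SNP haplotypes of the Class II region with their HLA associations
#'
#' The named 11-SNP haplotypes of the Class II region around HLA-DRB1
#' (labels `a1`, `a2`, ...), each with its binary allele string (0 = major
#' allele, 1 = minor allele), the Class II HLA motif it travels with, and
#' its population frequency in two cohorts. Used as the default SNP-locus
#' alphabet by the synthetic generator and to resolve `a`-labels inside
#' motif patterns.
#'
#' @return tibble with columns `label`, `snp`, `DRB1`, `DQB1` and the
#'   haplotype frequency in two large European-ancestry cohorts
#'   (`freq_cohort_a`, `freq_cohort_b`). Haplotypes associated with several
#'   Class II motifs carry the most common one.
#' @export
snp_haplotype_table <- function() {
  tibble::tribble(
    ~label, ~snp,          ~DRB1,         ~DQB1,         ~freq_cohort_a, ~freq_cohort_b,
    "a1",  "10110100010", "DRB1*15:01", "DQB1*06:02", 0.12, 0.11,
    "a2",  "00000000100", "DRB1*03:01", "DQB1*02:01", 0.02, 0.02,
    "a3",  "00000010001", "DRB1*04:01", "DQB1*03:01", 0.19, 0.21,
    "a4",  "00000000001", "DRB1*11:01", "DQB1*03:01", 0.11, 0.13,
    "a5",  "10100010001", "DRB1*07:01", "DQB1*02:02", 0.09, 0.08,
    "a6",  "01011100100", "DRB1*03:01", "DQB1*02:01", 0.10, 0.09,
    "a8",  "10110100011", "DRB1*15:01", "DQB1*05:02", 0.00, 0.00,
    "a9",  "01000001010", "DRB1*01:01", "DQB1*05:01", 0.11, 0.11,
    "a11", "00000010010", "DRB1*13:01", "DQB1*06:03", 0.02, 0.03,
    "a14", "10111111001", "DRB1*13:03", "DQB1*03:01", 0.01, 0.01,
    "a27", "10100100011", "DRB1*15:01", "DQB1*06:02", 0.00, 0.00,
    "a34", "10111100010", "DRB1*15:01", "DQB1*06:02", 0.00, 0.00,
    "a36", "10100100010", "DRB1*15:01", "DQB1*06:02", 0.00, 0.00,
    "a43", "00000100010", "DRB1*15:01", "DQB1*06:02", 0.00, 0.00
  )
}

#' Resolve SNP-haplotype labels to binary strings
#'
#' @param x character vector mixing binary strings and labels such as `"a1"`.
#' @param snp_labels named character vector mapping label to binary string;
#'   defaults to [snp_haplotype_table()].
#' @return character vector of binary strings (entries already binary are
#'   passed through; `"*"` is preserved as a wildcard).
#' @export
resolve_snp_label <- function(x, snp_labels = NULL) {
  if (is.null(snp_labels)) {
    tab <- snp_haplotype_table()
    snp_labels <- stats::setNames(tab$snp, tab$label)
  }
  hit <- x %in% names(snp_labels)
  x[hit] <- unname(snp_labels[x[hit]])
  x
}

#' Match CEH strings against a partial haplotype pattern (motif)
#'
#' A motif is a `~`-joined 6-field pattern over A, C, B, DRB1, DQB1 and the
#' SNP locus, with `"*"` as a field wildcard, e.g.
#' `"*~*~*~DRB1*15:01~DQB1*06:02~a1"`. Fewer than 6 fields are right-aligned
#' (a 3-field motif constrains DRB1, DQB1 and SNP). SNP fields may be given
#' either as a binary string or as a label resolvable via `snp_labels`.
#'
#' @param haplotype character vector of full CEH strings.
#' @param motif a single pattern string.
#' @param snp_labels optional label-to-string map (see [resolve_snp_label()]).
#' @return logical vector.
#' @export
motif_matches <- function(haplotype, motif, snp_labels = NULL) {
  fields <- strsplit(motif, "~", fixed = TRUE)[[1]]
  if (length(fields) > length(CEH_FIELDS)) {
    stop("motif has more than ", length(CEH_FIELDS), " fields: ", motif)
  }
  fields <- c(rep("*", length(CEH_FIELDS) - length(fields)), fields)
  fields[length(fields)] <- resolve_snp_label(fields[length(fields)], snp_labels)
  hm <- as.matrix(ceh_split(haplotype))
  ok <- rep(TRUE, length(haplotype))
  for (j in seq_along(fields)) {
    if (fields[j] != "*") ok <- ok & hm[, j] == fields[j]
  }
  ok
}

#' Hamming distance between equal-length haplotype strings
#'
#' Number of positions at which two strings differ. Vectorised over `h1`
#' and `h2` (recycled to a common length).
#'
#' @param h1,h2 character vectors of equal-length strings (e.g. 11-character
#'   binary SNP haplotypes).
#' @return integer vector of distances.
#' @export
hamming <- function(h1, h2) {
  n <- max(length(h1), length(h2))
  h1 <- rep_len(h1, n)
  h2 <- rep_len(h2, n)
  if (any(nchar(h1) != nchar(h2))) {
    stop("hamming distance requires equal-length strings")
  }
  m1 <- strsplit(h1, "", fixed = TRUE)
  m2 <- strsplit(h2, "", fixed = TRUE)
  vapply(seq_len(n), function(i) sum(m1[[i]] != m2[[i]]), integer(1))
}

#' Normalise HLA allele names to two-field resolution
#'
#' Allele strings with more than two `:`-separated fields are truncated to
#' two fields (`"DRB1*15:01:01"` becomes `"DRB1*15:01"`) with a warning.
#'
#' @param allele character vector of allele names.
#' @return character vector.
#' @export
normalize_hla_allele <- function(allele) {
  parts <- strsplit(allele, ":", fixed = TRUE)
  deep <- lengths(parts) > 2
  if (any(deep, na.rm = TRUE)) {
    warning(sum(deep, na.rm = TRUE),
            " allele name(s) truncated to two-field resolution")
    allele[which(deep)] <- vapply(parts[which(deep)],
                                  function(p) paste(p[1:2], collapse = ":"),
                                  character(1))
  }
  allele
}

## Sort the two alleles of an unordered genotype call and join with "/";
## a missing allele on either side gives a missing call.
genotype_call <- function(x, y) {
  swap <- which(!is.na(x) & !is.na(y) & x > y)
  tmp <- x[swap]
  x[swap] <- y[swap]
  y[swap] <- tmp
  out <- paste(x, y, sep = "/")
  out[is.na(x) | is.na(y)] <- NA_character_
  out
}

## Canonical unordered haplotype pair: lexicographically ordered.
canonical_pair <- function(h1, h2) {
  swap <- h1 > h2
  tmp <- h1[swap]
  h1[swap] <- h2[swap]
  h2[swap] <- tmp
  list(hap1 = h1, hap2 = h2)
}
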