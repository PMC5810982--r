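## Site metadata for the 11 Class II SNPs (positions are placeholders on
## a 6p21.3-like scale; only order matters to the pipeline).
snp_sites <- function() {
  tibble::tibble(
    chrom = "6",
    pos = seq(32374000L, 32680000L, length.out = SNP_WIDTH),
    id = c("rs2395173", "rs2395174", "rs3129871", "rs7192", "rs3129890",
           "rs9268832", "rs532098", "rs17533090", "rs2187668", "rs1063355",
           "rs9275141"),
    ref = "A", alt = "G"
  )
}

#' Write SNP genotypes as a minimal VCF
#'
#' Eleven biallelic sites, GT-only FORMAT, unphased `/` separators; allele
#' `0` is written as the REF allele and `1` as ALT. Missing calls become
#' `./.`.
#'
#' @param records genotype records with `sample_id` and SNP call columns.
#' @param path output path.
#' @param snp_cols SNP call column names, in site order.
#' @return `path`, invisibly.
#' @export
write_snp_vcf <- function(records, path,
                          snp_cols = sprintf("s%02d", 1:SNP_WIDTH)) {
  sites <- snp_sites()
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=cehtools",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", records$sample_id), collapse = "\t")
  )
  body <- vapply(seq_len(SNP_WIDTH), function(j) {
    gt <- records[[snp_cols[j]]]
    gt <- ifelse(is.na(gt), "./.", gt)
    paste(c(sites$chrom[j], sites$pos[j], sites$id[j], sites$ref[j],
            sites$alt[j], ".", "PASS", ".", "GT", gt), collapse = "\t")
  }, character(1))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read SNP genotypes from a VCF
#'
#' Reads a VCF of the 11 Class II sites back into genotype-record columns.
#' Phased `|` separators are accepted but treated as unphased input.
#'
#' @param path VCF path.
#' @return tibble with `sample_id` and `s01` ... `s11` columns of sorted
#'   `"0/1"`-style calls (`NA` for missing).
#' @export
read_snp_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  if (nrow(gt) != SNP_WIDTH) {
    stop("expected ", SNP_WIDTH, " SNP sites, found ", nrow(gt))
  }
  out <- tibble::tibble(sample_id = colnames(gt))
  for (j in seq_len(SNP_WIDTH)) {
    calls <- gsub("|", "/", gt[j, ], fixed = TRUE)
    parts <- strsplit(calls, "/", fixed = TRUE)
    call <- vapply(parts, function(p) {
      if (length(p) != 2 || any(p == ".") || anyNA(p)) return(NA_character_)
      genotype_call(p[1], p[2])
    }, character(1))
    out[[sprintf("s%02d", j)]] <- unname(call)
  }
  out
}

#' Write HLA typings as a long TSV
#'
#' One row per sample and locus: `sample`, `locus`, `allele1`, `allele2`.
#'
#' @param records genotype records with `sample_id` and the five HLA call
#'   columns.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_hla_tsv <- function(records, path) {
  rows <- lapply(HLA_LOCI, function(loc) {
    parts <- strsplit(records[[loc]], "/", fixed = TRUE)
    tibble::tibble(
      sample = records$sample_id, locus = loc,
      allele1 = vapply(parts, function(p) p[1] %||% NA_character_, character(1)),
      allele2 = vapply(parts, function(p) if (length(p) > 1) p[2] else NA_character_,
                       character(1)))
  })
  readr::write_tsv(do.call(rbind, rows), path)
  invisible(path)
}

#' Read HLA typings from the long TSV format
#'
#' Allele names are normalised to two-field resolution (higher-resolution
#' input is truncated with a warning).
#'
#' @param path TSV with columns `sample`, `locus`, `allele1`, `allele2`.
#' @return tibble with `sample_id` and one sorted `"x/y"` call column per
#'   HLA locus.
#' @export
read_hla_tsv <- function(path) {
  long <- readr::read_tsv(path, show_col_types = FALSE,
                          col_types = readr::cols(.default = "c"))
  need <- c("sample", "locus", "allele1", "allele2")
  miss <- setdiff(need, names(long))
  if (length(miss) > 0) stop("HLA TSV lacks column(s): ", paste(miss, collapse = ", "))
  bad <- setdiff(unique(long$locus), HLA_LOCI)
  if (length(bad) > 0) stop("unknown HLA locus label(s): ", paste(bad, collapse = ", "))
  long$allele1 <- normalize_hla_allele(long$allele1)
  long$allele2 <- normalize_hla_allele(long$allele2)
  out <- tibble::tibble(sample_id = unique(long$sample))
  for (loc in HLA_LOCI) {
    sub <- long[long$locus == loc, ]
    i <- match(out$sample_id, sub$sample)
    a1 <- sub$allele1[i]; a2 <- sub$allele2[i]
    call <- ifelse(is.na(a1) | is.na(a2), NA_character_, genotype_call(a1, a2))
    out[[loc]] <- call
  }
  out
}

#' Write / read the phenotype and covariate table
#'
#' @param records table with `sample_id`, `phenotype`, `region`, `sex` and
#'   any covariate columns (for example `PC1` ...).
#' @param path TSV path.
#' @return `path` invisibly (write); a tibble (read).
#' @export
write_phenotype_tsv <- function(records, path) {
  keep <- intersect(c("sample_id", "phenotype", "region", "sex",
                      grep("^PC", names(records), value = TRUE)),
                    names(records))
  readr::write_tsv(records[, keep], path)
  invisible(path)
}

#' @rdname write_phenotype_tsv
#' @export
read_phenotype_tsv <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE)
}

#' Write / read the simulation truth table
#'
#' @param truth truth tibble from [generate_dataset()].
#' @param path TSV path.
#' @return `path` invisibly (write); a tibble (read).
#' @export
write_truth_tsv <- function(truth, path) {
  readr::write_tsv(truth, path)
  invisible(path)
}

#' @rdname write_truth_tsv
#' @export
read_truth_tsv <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE,
                  col_types = readr::cols(subpop = "i", .default = "c"))
}

#' Join SNP, HLA and phenotype inputs into one genotype-record table
#'
#' Reads the VCF and the two TSVs, checks that the three files describe
#' the same samples, joins on sample id, and reports per-locus
#' missingness as an attribute.
#'
#' @param vcf_path SNP genotype VCF (11 sites).
#' @param hla_path HLA typing TSV.
#' @param phenotype_path phenotype/covariate TSV.
#' @return genotype-record tibble; attribute `missingness` holds the
#'   per-locus missing-call fraction.
#' @export
read_inputs <- function(vcf_path, hla_path, phenotype_path) {
  snp <- read_snp_vcf(vcf_path)
  hla <- read_hla_tsv(hla_path)
  phe <- read_phenotype_tsv(phenotype_path)
  for (tab in list(snp = snp, hla = hla, phe = phe)) {
    if (anyDuplicated(tab$sample_id)) {
      stop("duplicate sample id(s): ",
           paste(unique(tab$sample_id[duplicated(tab$sample_id)]), collapse = ", "))
    }
  }
  ids <- snp$sample_id
  for (other in list(hla$sample_id, phe$sample_id)) {
    extra <- c(setdiff(ids, other), setdiff(other, ids))
    if (length(extra) > 0) {
      stop("sample ids do not match across input files: ",
           paste(utils::head(extra, 5), collapse = ", "))
    }
  }
  out <- dplyr::inner_join(phe, dplyr::inner_join(hla, snp, by = "sample_id"),
                           by = "sample_id")
  loci <- c(HLA_LOCI, sprintf("s%02d", 1:SNP_WIDTH))
  attr(out, "missingness") <- vapply(loci, function(l) mean(is.na(out[[l]])),
                                     numeric(1))
  out
}
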