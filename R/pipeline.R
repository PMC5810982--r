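#' Run the CEH analysis pipeline end to end
#'
#' Executes the selected stages in order - `simulate` (synthetic dataset),
#' `phase` (EM phasing of the SNP window plus the five HLA loci),
#' `spectrum` (frequency-spectrum summaries), `associate` (conditional
#' carrier odds ratios), `hwe` (homozygote-excess test), `select`
#' (rare/frequent conversion-selection estimates) and `hamming`
#' (motif-carriage distance profile) - writing every output table as TSV
#' (reports as JSON) under `out_dir`, together with a provenance JSON
#' recording the configuration, seed and thresholds. A stage failure
#' aborts with an error naming the stage.
#'
#' @param config list: `pool` (a `ceh_pool` or [build_pool()] arguments),
#'   `n`, `seed`, and optionally `scheme`, `baseline_odds`, `n_regions`,
#'   `missing_rate`, `exclusion` (motif pattern), `min_copies` (default
#'   50), `anchor` (default `"a1"`), `motif` (default the DRB1*15:01 ~
#'   DQB1*06:02 Class II motif), `em_tol`, `alpha`.
#' @param out_dir output directory (created if needed).
#' @param stages character vector of stages to run (default: all, in
#'   order). Later stages reuse earlier in-memory results; `simulate` and
#'   `phase` are always run when a downstream stage needs them.
#' @return named list of stage results, invisibly; artifacts on disk.
#' @export
run_pipeline <- function(config, out_dir,
                         stages = c("simulate", "phase", "spectrum",
                                    "associate", "hwe", "select", "hamming")) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (is.null(config$seed)) stop("config needs a `seed`")
  min_copies <- config$min_copies %||% 50
  exclusion <- config$exclusion %||% "*~*~*~DRB1*15:01~DQB1*06:02~a1"
  anchor <- config$anchor %||% "a1"
  motif <- config$motif %||% "*~*~*~DRB1*15:01~DQB1*06:02~*"
  em_tol <- config$em_tol %||% 1e-6

  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  results <- list()

  results$simulate <- run_stage("simulate", {
    ds <- generate_dataset(config, seed = config$seed)
    write_snp_vcf(ds$genotypes, file.path(out_dir, "snp_genotypes.vcf"))
    write_hla_tsv(ds$genotypes, file.path(out_dir, "hla_typings.tsv"))
    write_phenotype_tsv(ds$genotypes, file.path(out_dir, "phenotypes.tsv"))
    write_truth_tsv(ds$truth, file.path(out_dir, "truth.tsv"))
    message("simulate: ", nrow(ds$genotypes), " individuals")
    ds
  })
  if ("associate" %in% stages &&
      !"phenotype" %in% names(results$simulate$genotypes)) {
    stop("pipeline stage 'associate' failed: ",
         "dataset lacks the `phenotype` column", call. = FALSE)
  }

  results$phase <- run_stage("phase", {
    ph <- phase_extended_haplotypes(results$simulate$genotypes, tol = em_tol)
    readr::write_tsv(ph$frequencies, file.path(out_dir, "ceh_frequencies.tsv"))
    readr::write_tsv(ph$assignments, file.path(out_dir, "ceh_assignments.tsv"))
    message("phase: ", nrow(ph$assignments), " individuals phased, ",
            ph$n_excluded, " excluded; SNP-stage EM ",
            ph$snp_fit$n_iter, " iterations")
    ph
  })
  assignments <- results$phase$assignments
  spectrum <- run_stage("spectrum", build_spectrum(assignments))

  if ("spectrum" %in% stages) {
    results$spectrum <- run_stage("spectrum", {
      readr::write_tsv(spectrum, file.path(out_dir, "spectrum.tsv"))
      readr::write_tsv(coverage_curve(spectrum),
                       file.path(out_dir, "coverage_curve.tsv"))
      summ <- spectrum_summary(spectrum)
      jsonlite::write_json(summ, file.path(out_dir, "spectrum_summary.json"),
                           auto_unbox = TRUE, digits = NA)
      message("spectrum: ", summ$n_unique, " unique CEHs / ",
              summ$total_copies, " copies")
      summ
    })
  }

  if ("associate" %in% stages) {
    results$associate <- run_stage("associate", {
      tab <- association_table(assignments, spectrum, exclusion = exclusion,
                               min_copies = min_copies)
      readr::write_tsv(tab, file.path(out_dir, "associations.tsv"))
      message("associate: ", nrow(tab), " CEHs tested (>= ", min_copies,
              " copies)")
      tab
    })
  }

  if ("hwe" %in% stages) {
    results$hwe <- run_stage("hwe", {
      hw <- homozygote_excess_test(
        spectrum, observed = sum(assignments$hap1 == assignments$hap2),
        n = nrow(assignments))
      jsonlite::write_json(unclass(hw), file.path(out_dir, "hwe_test.json"),
                           auto_unbox = TRUE, digits = NA)
      message("hwe: observed ", hw$observed, " vs expected ",
              round(hw$expected, 1), " homozygotes (z = ", round(hw$z, 2), ")")
      hw
    })
  }

  if ("select" %in% stages) {
    results$select <- run_stage("select", {
      cls <- rare_frequent_classes(assignments, spectrum)
      est <- estimate_conversion_selection(cls$class_counts["ff"],
                                           cls$class_counts["fr"],
                                           cls$class_counts["rr"])
      out <- c(list(class_counts = as.list(cls$class_counts),
                    p_f = unname(cls$p_f)), est)
      jsonlite::write_json(out, file.path(out_dir, "selection_model.json"),
                           auto_unbox = TRUE, digits = NA)
      message("select: c = ", signif(est$c_hat, 3), ", w_rr = ",
              signif(est$w_rr_hat, 3))
      out
    })
  }

  if ("hamming" %in% stages) {
    results$hamming <- run_stage("hamming", {
      prof <- carriage_by_distance(spectrum, anchor = anchor, motif = motif)
      readr::write_tsv(prof$overall, file.path(out_dir, "hamming_overall.tsv"))
      readr::write_tsv(prof$by_haplotype,
                       file.path(out_dir, "hamming_by_haplotype.tsv"))
      message("hamming: ", nrow(prof$by_haplotype),
              " unique SNP haplotypes profiled")
      prof
    })
  }

  provenance <- list(
    seed = config$seed, n = config$n,
    min_copies = min_copies, exclusion = exclusion, anchor = anchor,
    motif = motif, em_tol = em_tol, stages = stages,
    package_version = as.character(utils::packageVersion("cehtools")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  jsonlite::write_json(provenance, file.path(out_dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(results)
}
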