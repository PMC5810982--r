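## Small explicit pools built from realistic Class II / SNP-haplotype
## combinations; used across the module tests.

toy_pool <- function(freq = c(0.30, 0.25, 0.20, 0.15, 0.10),
                     rr1 = rep(1, 5), rr2 = rep(1, 5)) {
  build_pool(haplotypes = tibble::tibble(
    A = c("A*03:01", "A*01:01", "A*02:01", "A*30:02", "A*02:01"),
    C = c("C*07:02", "C*07:01", "C*05:01", "C*05:01", "C*06:02"),
    B = c("B*07:02", "B*08:01", "B*44:02", "B*18:01", "B*57:01"),
    DRB1 = c("DRB1*15:01", "DRB1*03:01", "DRB1*04:01", "DRB1*03:01",
             "DRB1*07:01"),
    DQB1 = c("DQB1*06:02", "DQB1*02:01", "DQB1*03:01", "DQB1*02:01",
             "DQB1*02:02"),
    SNP = c("10110100010", "01011100100", "00000010001", "00000000100",
            "10100010001"),
    frequency = freq, rr1 = rr1, rr2 = rr2))
}

two_ceh_pool <- function(f1 = 0.5) {
  build_pool(haplotypes = tibble::tibble(
    A = c("A*03:01", "A*01:01"), C = c("C*07:02", "C*07:01"),
    B = c("B*07:02", "B*08:01"),
    DRB1 = c("DRB1*15:01", "DRB1*03:01"),
    DQB1 = c("DQB1*06:02", "DQB1*02:01"),
    SNP = c("10110100010", "00000000100"),
    frequency = c(f1, 1 - f1)))
}

## skewed multi-CEH pool for phasing recovery tests
recovery_pool <- function(n_hap = 20, seed = 42) {
  build_pool(recipe = list(n_common = n_hap, n_rare = 0, common_mass = 1,
                           skew = 1, seed = seed))
}
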