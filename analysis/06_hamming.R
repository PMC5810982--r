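#!/usr/bin/env Rscript

## Stage 6: Hamming-distance profile of Class II motif carriage. Groups
## the phased CEH copies by the Hamming distance of their SNP haplotype
## from the a1 anchor and asks how often each distance class carries the
## DRB1*15:01~DQB1*06:02 motif. Carriage should track the identity of the
## specific SNP haplotype, not its distance from the anchor.

suppressPackageStartupMessages(library(cehtools))
suppressPackageStartupMessages(library(readr))

out <- "results/analysis"
spec <- read_tsv(file.path(out, "spectrum.tsv"), show_col_types = FALSE)

prof <- carriage_by_distance(spec, anchor = "a1",
                             motif = "*~*~*~DRB1*15:01~DQB1*06:02~*")
write_tsv(prof$overall, file.path(out, "hamming_overall.tsv"))
write_tsv(prof$by_haplotype, file.path(out, "hamming_by_haplotype.tsv"))
write_tsv(prof$subgroups, file.path(out, "hamming_subgroups.tsv"))

d0 <- prof$overall[prof$overall$distance == 0, ]
message("at distance 0 (the a1 anchor itself): ",
        round(100 * d0$proportion, 1), "% of ", d0$copies,
        " copies carry the motif")
far <- prof$overall[prof$overall$distance >= 3, ]
message("at distance >= 3: ",
        round(100 * sum(far$carriers) / sum(far$copies), 1), "% of ",
        sum(far$copies), " copies carry the motif, spread over ",
        nrow(prof$by_haplotype[prof$by_haplotype$distance >= 3, ]),
        " distinct SNP haplotypes")
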