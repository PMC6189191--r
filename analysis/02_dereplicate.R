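#!/usr/bin/env Rscript
# Dereplicate the simulated sequence database: within each phylum, cluster
# sequences at >= 85% global-alignment identity and keep the longest member
# of each cluster, mirroring how redundancy is removed before homolog
# sampling.

suppressPackageStartupMessages(library(lgtscreen))

out <- "results/simulated"
records <- read_fasta_records(file.path(out, "families.faa"))
# restore the generator's round-robin family -> phylum assignment (5 per phylum)
fam_no <- as.integer(sub("^fam([0-9]+)_.*$", "\\1", records$id))
records$phylum <- sprintf("P%03d", ceiling(fam_no / 5))

cl <- dereplicate(records, threshold = 0.85)
write_cluster_report(cl, file.path(out, "derep_report.tsv"))

cat("input sequences: ", nrow(records), "\n", sep = "")
cat("representatives: ", length(cl$representatives), "\n", sep = "")
cat("removed:         ", nrow(cl$assignment),
    " (identity >= ", cl$threshold, " to their representative)\n", sep = "")
cat("report: ", file.path(out, "derep_report.tsv"), "\n", sep = "")
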