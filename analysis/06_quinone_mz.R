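#!/usr/bin/env Rscript
# Naphthoquinone identification: theoretical [M+H]+ / [M+Na]+ m/z for the
# bundled vitamin-K-family candidates, and matching of the demo UPLC-MS peak
# list (selected monitoring window 466.5-467.5 for the OH-PhQ channel).

suppressPackageStartupMessages(library(lgtscreen))

out <- "results/quinone"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

theo <- theoretical_mz_table()
cat("theoretical adduct m/z:\n")
print(transform(theo, mz = round(mz, 4)), row.names = FALSE)

peaks <- read_peaks(system.file("extdata", "demo_peaks.csv",
                                package = "lgtscreen"))
res <- run_quinone(peaks, tol_ppm = 20,
                   out_path = file.path(out, "matches.tsv"))
cat("\nmatches within 20 ppm:\n")
print(transform(res$matches, theoretical_mz = round(theoretical_mz, 4),
                error_ppm = round(error_ppm, 2)), row.names = FALSE)

win <- match_peaks(peaks, tol_ppm = 20, window = c(466.5, 467.5))
cat("\nin the 466.5-467.5 monitoring window:", nrow(win), "match(es);",
    "retention", paste(unique(win$rt_min), collapse = ", "), "min\n")
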