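#!/usr/bin/env Rscript
# The headline analysis: a 200-tree screen with 17 planted chlamydial and 6
# planted proteobacterial transfer events (three chlamydial events witnessed
# by paralogous query pairs). Every stage runs end to end -- hit simulation,
# capped two-pass sampling, the bacterial gate, tree simulation, monophyly
# classification, Jaccard case grouping, non-redundant counting -- and the
# reported counts are compared against the generator's truth record.

suppressPackageStartupMessages(library(lgtscreen))

out <- "results/screen"
cfg <- simulation_config(seed = 101)
res <- run_screen(cfg, out_dir = out)

cat("screen of", cfg$n_trees, "gene trees\n")
cat("calls:", res$summary$n_calls, "| non-redundant events:",
    res$summary$n_groups, "\n")
for (ph in names(res$counts)) cat(sprintf("  %-16s %d\n", ph, res$counts[[ph]]))

planted <- res$truth[res$truth$planted, ]
called_q <- vapply(res$calls, `[[`, "", "query_id")
cat("sensitivity:", mean(planted$query_id %in% called_q), "\n")
cat("false calls on negative controls:",
    sum(!called_q %in% planted$query_id), "\n")
truth_counts <- table(planted$donor_phylum[!duplicated(planted$event_id)])
cat("truth (events per donor):",
    paste(names(truth_counts), truth_counts, sep = "=", collapse = ", "), "\n")
cat("reports written under ", out, "/\n", sep = "")
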