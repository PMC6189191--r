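#!/usr/bin/env Rscript
# Build the taxonomically balanced homolog sample for the example query:
# E-value screen at 1e-05, top 1,200 hits by bit score, first-come-first-serve
# sampling capped at 6 per phylum, then a second pass on the identity
# ordering; finally the >= 3 bacterial sequences gate.

suppressPackageStartupMessages(library(lgtscreen))

out <- "results/simulated"
cfg <- read_config(file.path(out, "config.json"))
tax <- read_taxonomy(file.path(out, "taxonomy.tsv"))
tax <- add_query_taxa(tax, "ATq0001")

hits <- read_hits(file.path(out, "ATq0001.blast.tsv"),
                  evalue_cutoff = cfg$evalue_cutoff)
cat("significant hits:", nrow(hits), "\n")

smp <- build_sample("ATq0001", hits, tax, cap = cfg$phylum_cap,
                    top_n = cfg$top_n)
write_sample_json(smp, file.path(out, "ATq0001.sample.json"))

cat("sample size:", length(smp$member_ids), "members\n")
cat("per phylum:\n")
for (ph in names(smp$per_phylum_counts))
  cat(sprintf("  %-16s %d\n", ph, smp$per_phylum_counts[[ph]]))
cat("admissions: ", sum(smp$passes$pass == "bitscore"), " by bit score, ",
    sum(smp$passes$pass == "identity"), " by identity (union kept)\n", sep = "")
cat("tree-worthy (>= ", cfg$min_bacteria, " bacteria): ",
    tree_worthy(smp, tax, cfg$min_bacteria), "\n", sep = "")
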