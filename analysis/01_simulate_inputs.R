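#!/usr/bin/env Rscript
# Generate the synthetic inputs every later stage consumes: the taxonomy of
# the sequence database, redundant sequence families, one query's BLAST-style
# hit table, and a pair of example gene trees (one with a planted chlamydial
# transfer, one negative control). All files land under results/simulated/.

suppressPackageStartupMessages(library(lgtscreen))

out <- "results/simulated"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

cfg <- simulation_config(seed = 101)
write_config(cfg, file.path(out, "config.json"))

tax <- simulate_taxonomy(cfg)
write_taxonomy(tax, file.path(out, "taxonomy.tsv"))
cat("taxonomy:", nrow(tax$entries), "entries over",
    length(unique(tax$entries$phylum)), "phyla\n")

fam <- simulate_seq_families(cfg, n_families = 12, family_size = 5)
write_fasta_records(fam$records, file.path(out, "families.faa"))
cat("sequences:", nrow(fam$records), "members of", max(fam$truth$family),
    "families (within-family identity near the 85% threshold)\n")

hits <- simulate_hits(cfg, "ATq0001")
write_hits(hits, file.path(out, "ATq0001.blast.tsv"))
cat("hit table: ", nrow(hits), " rows, ",
    sum(hits$evalue > cfg$evalue_cutoff), " above the 1e-05 cutoff\n", sep = "")

planted <- simulate_gene_tree(cfg, plant = TRUE, seed_offset = 1)
control <- simulate_gene_tree(cfg, plant = FALSE, seed_offset = 2)
write_newick(planted$tree, file.path(out, "tree_planted.nwk"))
write_newick(control$tree, file.path(out, "tree_control.nwk"))
write_taxonomy(planted$tax, file.path(out, "taxonomy_with_queries.tsv"))
cat("trees: planted clade of", length(planted$truth$clade),
    "leaves (donor", planted$truth$donor_phylum, ") plus a negative control\n")
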