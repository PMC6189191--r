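# Shared toy fixtures built in code.

# Six-leaf taxonomy around a query Q: two chlamydial donors, three other
# bacteria, plus optional Archaeplastida / secondary-plastid leaves.
toy_tax <- function(extra_arch = 0, extra_sec = 0, extra_donor = 0,
                    extra_foreign = 0) {
  ids <- c("Q", "D1", "D2", "X1", "X2", "X3")
  phylum <- c("Archaeplastida", "Chlamydiae", "Chlamydiae",
              "Proteobacteria", "Proteobacteria", "Proteobacteria")
  flags <- c("archaeplastida;query", "chlamydiae;bacteria", "chlamydiae;bacteria",
             "bacteria", "bacteria", "bacteria")
  if (extra_donor > 0) {
    ids <- c(ids, paste0("D", 2 + seq_len(extra_donor)))
    phylum <- c(phylum, rep("Chlamydiae", extra_donor))
    flags <- c(flags, rep("chlamydiae;bacteria", extra_donor))
  }
  if (extra_foreign > 0) {
    ids <- c(ids, paste0("X", 3 + seq_len(extra_foreign)))
    phylum <- c(phylum, rep("Proteobacteria", extra_foreign))
    flags <- c(flags, rep("bacteria", extra_foreign))
  }
  if (extra_arch > 0) {
    ids <- c(ids, paste0("A", seq_len(extra_arch)))
    phylum <- c(phylum, rep("Viridiplantae", extra_arch))
    flags <- c(flags, rep("archaeplastida", extra_arch))
  }
  if (extra_sec > 0) {
    ids <- c(ids, paste0("S", seq_len(extra_sec)))
    phylum <- c(phylum, rep("Haptophyta", extra_sec))
    flags <- c(flags, rep("secondary_plastid", extra_sec))
  }
  taxonomy_map(ids, phylum, flags)
}

# taxonomy_map -> plain data frame for the oracle classifier.
tax_as_df <- function(tax) {
  e <- tax$entries
  data.frame(id = e$id, phylum = e$phylum,
             exempt = tax_is_exempt(tax, e$id),
             stringsAsFactors = FALSE)
}

# Random support-annotated tree over a random taxonomy, for fuzzing the
# classifier. Returns list(tree, tax, phy, query).
random_lgt_tree <- function(n_leaves, n_phyla = 4, p_exempt = 0.2,
                            supports = c(NA, 50, 80, 90, 95, 100)) {
  phy <- ape::rtree(n_leaves, br = NULL)
  phy$tip.label <- sprintf("L%02d", seq_len(n_leaves))
  phy$node.label <- as.character(sample(supports, phy$Nnode, replace = TRUE))
  phy$node.label[is.na(phy$node.label)] <- ""
  query <- sample(phy$tip.label, 1)
  others <- setdiff(phy$tip.label, query)
  role <- sample(c("bact", "exempt"), length(others), replace = TRUE,
                 prob = c(1 - p_exempt, p_exempt))
  phylum <- ifelse(role == "bact",
                   paste0("Bact", sample.int(n_phyla, length(others), replace = TRUE)),
                   "Archaeplastida")
  flags <- ifelse(role == "bact", "bacteria", "archaeplastida")
  tax <- taxonomy_map(c(query, others),
                      phylum = c("Archaeplastida", phylum),
                      flags = c("archaeplastida;query", flags))
  list(tree = gene_tree(phy), tax = tax, phy = phy, query = query)
}

# Random hit table (in memory) for fuzzing the sampler.
random_hits <- function(n, n_phyla = 4, query = "Q1") {
  subj <- sprintf("s%03d", sample.int(500, n, replace = TRUE))
  data.frame(query_id = query, subject_id = subj,
             identity_pct = round(stats::runif(n, 20, 100), 1),
             evalue = 10^stats::runif(n, -60, -6),
             bitscore = round(stats::runif(n, 50, 1500), 1),
             stringsAsFactors = FALSE)
}

# Taxonomy covering the s000..s500 subject pool used by random_hits.
subject_pool_tax <- function(n_phyla = 4) {
  ids <- sprintf("s%03d", 0:500)
  taxonomy_map(ids, phylum = paste0("Ph", (0:500) %% n_phyla + 1),
               flags = rep("bacteria", 501))
}
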