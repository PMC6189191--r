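# Deterministic fan-out of the global seed into per-stage child seeds, kept
# inside the 32-bit integer range.
child_seed <- function(seed, stage, i = 0L) {
  (as.numeric(seed) * 7919 + stage * 104729 + i * 131) %% 2147483647
}

# Bacterial phylum names used by the generator, donor first.
.BACT_PHYLA <- c("Chlamydiae", "Proteobacteria", "Cyanobacteria", "Firmicutes",
                 "Actinobacteria", "Bacteroidetes", "Spirochaetes",
                 "Planctomycetes", "Chloroflexi", "Fusobacteria")

#' Configuration of the synthetic screen
#'
#' Bundles the data-generation parameters and the screening thresholds into
#' one reproducible configuration. The defaults describe the study
#' conditions the pipeline is exercised under: 200 gene trees over a
#' database of 8 phyla (6 bacterial, one primary-plastid Archaeplastida
#' group, one secondary-plastid group) with 30 taxa each; 17 planted
#' chlamydial and 6 planted proteobacterial transfer events, of which 3
#' chlamydial events are witnessed by two paralogous query trees; clean
#' (support = 100) edges; 2,000-row hit tables per query with bit scores
#' strictly decreasing in rank and rank-correlated but jittered identities.
#'
#' @param seed integer master seed; every stage derives its own child seed
#'   from it.
#' @param n_phyla number of phyla (>= 3): \code{n_phyla - 2} bacterial plus
#'   the Archaeplastida and secondary-plastid groups.
#' @param taxa_per_phylum sequences per phylum in the database.
#' @param n_trees total gene trees in the screen.
#' @param events named integer vector of planted non-redundant events per
#'   donor phylum.
#' @param paralog_events how many events (taken from the first donor phylum)
#'   are witnessed by two paralogous query trees.
#' @param plant_fraction fraction of trees carrying a planted event;
#'   \code{NA} (default) derives it from \code{events} and
#'   \code{paralog_events}.
#' @param donor_phylum default donor for single-tree simulation.
#' @param planted_donor_size donor sequences in a planted clade (>= 2).
#' @param support_model list \code{(kind = "clean"|"noisy", noise_sd)};
#'   clean assigns support 100 to every edge, noisy draws truncated-normal
#'   supports around 95.
#' @param n_foreign_in_clade other-bacteria leaves inserted inside a planted
#'   clade.
#' @param n_exempt_in_clade exempt (Archaeplastida/secondary-plastid) leaves
#'   inserted inside a planted clade.
#' @param leaves_per_tree leaves sampled for a standalone simulated tree.
#' @param hit_table_size rows per simulated hit table.
#' @param identity_decay list \code{(rate, jitter)}: per-rank identity decay
#'   and Gaussian jitter creating rank inversions between the bit-score and
#'   identity orderings.
#' @param evalue_cutoff,top_n,phylum_cap,min_bacteria,support_min,min_donor,max_foreign,derep_identity,jaccard_min
#'   screening thresholds (see the stage functions for their meaning).
#' @return a list of class \code{sim_config}.
#' @export
simulation_config <- function(seed = 1L,
                              n_phyla = 8L,
                              taxa_per_phylum = 30L,
                              n_trees = 200L,
                              events = c(Chlamydiae = 17L, Proteobacteria = 6L),
                              paralog_events = 3L,
                              plant_fraction = NA_real_,
                              donor_phylum = "Chlamydiae",
                              planted_donor_size = 3L,
                              support_model = list(kind = "clean", noise_sd = 0),
                              n_foreign_in_clade = 0L,
                              n_exempt_in_clade = 1L,
                              leaves_per_tree = 20L,
                              hit_table_size = 2000L,
                              identity_decay = list(rate = 0.03, jitter = 2),
                              evalue_cutoff = 1e-05,
                              top_n = 1200L,
                              phylum_cap = 6L,
                              min_bacteria = 3L,
                              support_min = 90,
                              min_donor = 2L,
                              max_foreign = 2L,
                              derep_identity = 0.85,
                              jaccard_min = 0.5) {
  if (n_phyla < 3L) stop("need at least 3 phyla", call. = FALSE)
  if (taxa_per_phylum < 1L || n_trees < 1L) stop("counts must be positive", call. = FALSE)
  if (planted_donor_size < 2L) stop("planted_donor_size must be >= 2", call. = FALSE)
  if (!is.na(plant_fraction) && (plant_fraction < 0 || plant_fraction > 1))
    stop("plant_fraction must be in [0, 1]", call. = FALSE)
  if (!support_model$kind %in% c("clean", "noisy"))
    stop("support_model$kind must be 'clean' or 'noisy'", call. = FALSE)
  structure(as.list(environment()), class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("sim_config: seed", x$seed, "|", x$n_phyla, "phyla x", x$taxa_per_phylum,
      "taxa |", x$n_trees, "trees | events:",
      paste(names(x$events), x$events, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Serialise / read a configuration as JSON
#' @param cfg a \code{sim_config}.
#' @param path JSON file.
#' @export
write_config <- function(cfg, path) {
  x <- unclass(cfg)
  x$events <- as.list(x$events)   # keep donor names in the JSON object
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$events <- unlist(x$events)
  # an unset plant_fraction serialises as null; restore the NA sentinel
  if (is.null(x$plant_fraction) || length(x$plant_fraction) == 0L ||
      !is.numeric(x$plant_fraction))
    x$plant_fraction <- NA_real_
  x <- x[!vapply(x, is.null, NA)]
  do.call(simulation_config, x)
}

# Phylum name -> lineage flags for the generated database.
.sim_phyla <- function(cfg) {
  n_bact <- cfg$n_phyla - 2L
  bact <- .BACT_PHYLA[seq_len(n_bact)]
  if (n_bact > length(.BACT_PHYLA))
    bact <- c(.BACT_PHYLA, paste0("Phylum", seq_len(n_bact - length(.BACT_PHYLA))))[
      seq_len(n_bact)]
  data.frame(
    phylum = c(bact, "Archaeplastida", "Haptophyta"),
    flags = c(ifelse(bact == "Chlamydiae", "chlamydiae;bacteria", "bacteria"),
              "archaeplastida", "secondary_plastid"),
    stringsAsFactors = FALSE)
}

#' Simulate the taxonomy of the sequence database
#'
#' Generates \code{n_phyla * taxa_per_phylum} entries: one chlamydial phylum,
#' further generic bacterial phyla, one Archaeplastida group and one
#' secondary-plastid group, with consistent lineage flags.
#'
#' @param cfg a \code{\link{simulation_config}}.
#' @return a \code{\link{taxonomy_map}} (queries are added separately by the
#'   screen simulator).
#' @export
simulate_taxonomy <- function(cfg) {
  ph <- .sim_phyla(cfg)
  ids <- unlist(lapply(seq_len(nrow(ph)), function(i)
    sprintf("%s_t%03d", ph$phylum[i], seq_len(cfg$taxa_per_phylum))))
  taxonomy_map(ids,
               phylum = rep(ph$phylum, each = cfg$taxa_per_phylum),
               flags = rep(ph$flags, each = cfg$taxa_per_phylum),
               species = sub("_t", " sp. ", ids))
}

#' Add query entries to a taxonomy map
#'
#' Queries are Archaeplastida sequences flagged \code{query}; the screen adds
#' one per gene tree.
#'
#' @param tax a \code{\link{taxonomy_map}}.
#' @param query_ids ids to add.
#' @return the extended \code{taxonomy_map}.
#' @export
add_query_taxa <- function(tax, query_ids) {
  e <- tax$entries
  taxonomy_map(c(e$id, query_ids),
               phylum = c(e$phylum, rep("Archaeplastida", length(query_ids))),
               flags = c(e$flags, rep("archaeplastida;query", length(query_ids))),
               species = c(e$species, rep("Arabidopsis thaliana", length(query_ids))),
               exempt_lineages = tax$exempt_lineages)
}

## ---- topology construction -------------------------------------------------

.draw_support <- function(model) {
  if (model$kind == "clean") return(100)
  round(min(100, max(0, stats::rnorm(1, mean = 95, sd = model$noise_sd))))
}

# Random sequential coalescent joins over a set of subtree strings; returns a
# single Newick fragment (no trailing ";"). Supports drawn per join.
.coalesce <- function(units, model) {
  while (length(units) > 1L) {
    pick <- sample.int(length(units), 2L)
    joined <- sprintf("(%s,%s)%s", units[pick[1]], units[pick[2]],
                      format(.draw_support(model)))
    units <- c(units[-pick], joined)
  }
  units
}

# Build a gene tree with an optional planted clade: the query grafted sister
# to a coalesced group of donor + foreign + exempt leaves. Background leaves
# coalesce freely around it.
.build_tree <- function(query_id, background, model,
                        donor = character(0), foreign = character(0),
                        exempt = character(0)) {
  if (length(donor) > 0L) {
    inner <- .coalesce(c(donor, foreign, exempt), model)
    planted <- sprintf("(%s,%s)%s", query_id, inner, format(.draw_support(model)))
    units <- c(planted, background)
    clade <- sort(c(query_id, donor, foreign, exempt))
  } else {
    units <- c(query_id, background)
    clade <- character(0)
  }
  if (length(units) < 2L) stop("tree needs background leaves", call. = FALSE)
  txt <- paste0(.coalesce(units, model), ";")
  list(tree = parse_newick(txt), planted_clade = clade)
}

# Sample leaves for one tree from the taxonomy (excluding reserved ids).
.sample_leaves <- function(tax, n, exclude = character(0)) {
  pool <- setdiff(tax$entries$id, exclude)
  sample(pool, min(n, length(pool)))
}

#' Simulate one gene tree, optionally with a planted transfer
#'
#' Draws a random coalescent-style topology over leaves sampled from the
#' taxonomy. When \code{plant = TRUE} the query is grafted sister to a clade
#' of \code{planted_donor_size} donor-phylum leaves, with
#' \code{n_foreign_in_clade} other-bacteria and \code{n_exempt_in_clade}
#' exempt leaves inserted inside the clade. Under the clean support model
#' each simulated tree is verified against the classifier's predicates at
#' generation time: a planted tree must yield exactly the planted call and an
#' unplanted tree no call at all; offending topologies are redrawn.
#'
#' @param cfg a \code{\link{simulation_config}}.
#' @param plant logical: plant a transfer clade?
#' @param tax taxonomy map (default: \code{simulate_taxonomy(cfg)}).
#' @param query_id id of the query leaf (added to the taxonomy on the fly if
#'   absent).
#' @param donor_phylum donor for the planted clade (default from cfg).
#' @param seed_offset integer offset mixed into the child seed, so batches of
#'   trees differ.
#' @return list with elements \code{tree} (a \code{gene_tree}), \code{tax}
#'   (possibly extended), and \code{truth} (list: \code{planted},
#'   \code{donor_phylum}, \code{clade}, \code{query_id}).
#' @export
simulate_gene_tree <- function(cfg, plant, tax = NULL, query_id = "ATq0001",
                               donor_phylum = cfg$donor_phylum,
                               seed_offset = 0L) {
  if (is.null(tax)) tax <- simulate_taxonomy(cfg)
  if (!query_id %in% tax$entries$id) tax <- add_query_taxa(tax, query_id)
  donors_avail <- tax$entries$id[tax$entries$phylum == donor_phylum]
  if (plant && length(donors_avail) < cfg$planted_donor_size)
    stop("planted_donor_size exceeds available donor taxa", call. = FALSE)
  set.seed(child_seed(cfg$seed, 2L, seed_offset))
  for (attempt in 1:200) {
    res <- .simulate_tree_once(cfg, plant, tax, query_id, donor_phylum)
    if (cfg$support_model$kind != "clean" || .tree_verifies(cfg, res, tax, query_id))
      return(list(tree = res$tree, tax = tax,
                  truth = list(planted = plant, donor_phylum = if (plant) donor_phylum
                               else NA_character_,
                               clade = res$planted_clade, query_id = query_id)))
  }
  stop("could not simulate a verifiable topology in 200 attempts", call. = FALSE)
}

.simulate_tree_once <- function(cfg, plant, tax, query_id, donor_phylum) {
  e <- tax$entries
  queries <- e$id[grepl("query", e$flags)]
  if (plant) {
    donors <- sample(e$id[e$phylum == donor_phylum], cfg$planted_donor_size)
    bact <- e$id[tax_has_flag(tax, e$id, "bacteria") & e$phylum != donor_phylum]
    foreign <- if (cfg$n_foreign_in_clade > 0L)
      sample(bact, cfg$n_foreign_in_clade) else character(0)
    ex_pool <- e$id[tax_is_exempt(tax, e$id) & !(e$id %in% queries)]
    exempt <- if (cfg$n_exempt_in_clade > 0L)
      sample(ex_pool, min(cfg$n_exempt_in_clade, length(ex_pool))) else character(0)
    used <- c(query_id, donors, foreign, exempt, queries)
    n_bg <- max(2L, cfg$leaves_per_tree - length(c(donors, foreign, exempt)) - 1L)
    background <- .sample_leaves(tax, n_bg, exclude = used)
    .build_tree(query_id, background, cfg$support_model,
                donor = donors, foreign = foreign, exempt = exempt)
  } else {
    background <- .sample_leaves(tax, cfg$leaves_per_tree - 1L,
                                 exclude = c(query_id, queries))
    .build_tree(query_id, background, cfg$support_model)
  }
}

# Generation-time truth check under clean supports: a planted tree (with a
# tolerable foreign load) must produce exactly the planted call; any other
# tree must produce none.
.tree_verifies <- function(cfg, res, tax, query_id) {
  calls <- scan_donors(res$tree, tax, query_id,
                       support_min = cfg$support_min, min_donor = cfg$min_donor,
                       max_foreign = cfg$max_foreign)
  expect_call <- length(res$planted_clade) > 0L &&
    cfg$n_foreign_in_clade <= cfg$max_foreign
  if (!expect_call) return(length(calls) == 0L)
  length(calls) == 1L &&
    identical(calls[[1]]$clade_leaves, res$planted_clade)
}

## ---- hit tables ------------------------------------------------------------

#' Simulate a BLAST-style hit table for one query
#'
#' Produces \code{hit_table_size} rows with bit scores strictly decreasing in
#' rank, identities decaying with rank but jittered (so the bit-score and
#' identity orderings differ), and E-values spanning the significance cutoff.
#' Optionally boosts a set of subject ids to the top ranks, which is how
#' planted donors reach the sampled homolog set.
#'
#' @param cfg a \code{\link{simulation_config}}.
#' @param query_id the query id.
#' @param tax taxonomy supplying the subject pool (default
#'   \code{simulate_taxonomy(cfg)}).
#' @param boost subject ids forced to the highest ranks.
#' @param seed_offset child-seed offset (paralogous queries re-use the same
#'   offset and hence the same table).
#' @return data frame of hit rows (\code{query_id}, \code{subject_id},
#'   \code{identity_pct}, \code{evalue}, \code{bitscore}), unfiltered.
#' @export
simulate_hits <- function(cfg, query_id, tax = NULL, boost = character(0),
                          seed_offset = 0L) {
  if (is.null(tax)) tax <- simulate_taxonomy(cfg)
  set.seed(child_seed(cfg$seed, 3L, seed_offset))
  n <- cfg$hit_table_size
  pool <- setdiff(tax$entries$id, c(query_id, boost))
  subjects <- c(boost, sample(pool, n - length(boost), replace = TRUE))
  rank <- seq_len(n)
  bitscore <- round(1500 - (rank - 1) * (1400 / n), 3)
  identity <- pmin(100, pmax(5, 98 - rank * cfg$identity_decay$rate +
                               stats::rnorm(n, 0, cfg$identity_decay$jitter)))
  evalue <- 10^(seq(-60, -2, length.out = n))
  data.frame(query_id = query_id, subject_id = subjects,
             identity_pct = round(identity, 3), evalue = signif(evalue, 3),
             bitscore = bitscore, stringsAsFactors = FALSE)
}

#' Write hit rows as a 12-column outfmt-6 TSV
#'
#' Columns the sampler does not use are filled with deterministic
#' placeholders so the file is a valid outfmt-6 table.
#'
#' @param hits hit rows (as from \code{\link{simulate_hits}}).
#' @param path output file.
#' @export
write_hits <- function(hits, path) {
  n <- nrow(hits)
  writeLines(paste(hits$query_id, hits$subject_id,
                   formatC(hits$identity_pct, format = "f", digits = 3),
                   200L, 10L, 1L, 1L, 200L, 1L, 200L,
                   formatC(hits$evalue, format = "e", digits = 2),
                   formatC(hits$bitscore, format = "f", digits = 1),
                   sep = "\t"), path)
  invisible(path)
}

## ---- sequence families -----------------------------------------------------

.AA <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

.mutate_seq <- function(s, rate) {
  x <- strsplit(s, "")[[1]]
  hit <- stats::runif(length(x)) < rate
  x[hit] <- sample(.AA, sum(hit), replace = TRUE)
  paste(x, collapse = "")
}

#' Simulate families of related protein sequences
#'
#' Each family derives from one random seed sequence mutated independently
#' per member at a fixed per-site rate, with member lengths varied by
#' C-terminal truncation, so that within-family identities sit near the
#' dereplication threshold while cross-family identities are far below it.
#' Families are assigned to phyla round-robin.
#'
#' @param cfg a \code{\link{simulation_config}}.
#' @param n_families number of families.
#' @param family_size members per family.
#' @param seq_length length of the family seed sequence.
#' @param mutation_rate per-site substitution probability per member.
#' @param families_per_phylum families sharing one phylum label.
#' @return list with \code{records} (a sequence-record data frame) and
#'   \code{truth} (data frame \code{id}, \code{family}).
#' @export
simulate_seq_families <- function(cfg, n_families = 10L, family_size = 5L,
                                  seq_length = 120L, mutation_rate = 0.05,
                                  families_per_phylum = 5L) {
  set.seed(child_seed(cfg$seed, 4L))
  ids <- character(0); seqs <- character(0); phyla <- character(0)
  fam <- integer(0)
  for (f in seq_len(n_families)) {
    seed_seq <- paste(sample(.AA, seq_length, replace = TRUE), collapse = "")
    for (m in seq_len(family_size)) {
      s <- .mutate_seq(seed_seq, mutation_rate)
      drop <- sample(0:max(1L, round(seq_length * 0.1)), 1L)
      if (drop > 0L) s <- substr(s, 1L, nchar(s) - drop)
      ids <- c(ids, sprintf("fam%03d_m%02d", f, m))
      seqs <- c(seqs, s)
      phyla <- c(phyla, sprintf("P%03d", ceiling(f / families_per_phylum)))
      fam <- c(fam, f)
    }
  }
  list(records = seq_records(ids, seqs, phyla),
       truth = data.frame(id = ids, family = fam, stringsAsFactors = FALSE))
}
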