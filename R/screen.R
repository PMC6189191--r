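#' Run the end-to-end synthetic transfer screen
#'
#' Executes the full pipeline on generated data with known ground truth:
#' database dereplication (on simulated sequence families), per-query hit
#' simulation, two-pass capped homolog sampling, the bacterial-representation
#' gate, gene-tree simulation with planted transfer clades, donor
#' classification, paralog case grouping and non-redundant event counting.
#'
#' Planted events follow \code{cfg$events}; paralogous query trees of one
#' event share their hit table (hence their homolog sample), which is what
#' the Jaccard grouping stage detects. Under the clean support model every
#' simulated topology is verified against the classifier's predicates at
#' generation time, so the truth record is exact.
#'
#' @param cfg a \code{\link{simulation_config}}.
#' @param out_dir optional directory; when given, writes
#'   \code{calls.tsv}, \code{groups.json} and \code{summary.json}.
#' @param derep_families number of simulated sequence families for the
#'   dereplication stage (0 skips the stage).
#' @return a list of class \code{screen_result}: \code{counts} (named vector
#'   of non-redundant events per donor), \code{calls}, \code{groups},
#'   \code{truth} (per-tree data frame), \code{samples}, \code{derep},
#'   \code{summary}.
#' @export
run_screen <- function(cfg = simulation_config(), out_dir = NULL,
                       derep_families = 8L) {
  tax0 <- simulate_taxonomy(cfg)
  query_ids <- sprintf("ATq%04d", seq_len(cfg$n_trees))
  tax <- add_query_taxa(tax0, query_ids)

  derep <- NULL
  if (derep_families > 0L) {
    fam <- simulate_seq_families(cfg, n_families = derep_families)
    derep <- dereplicate(fam$records, threshold = cfg$derep_identity)
  }

  # Plan planted events: event table with one or two witness trees each.
  ev_donors <- rep(names(cfg$events), cfg$events)
  n_events <- length(ev_donors)
  n_paralog <- min(cfg$paralog_events, sum(ev_donors == ev_donors[1]))
  witness <- rep(1L, n_events)
  if (n_paralog > 0L) witness[which(ev_donors == ev_donors[1])[seq_len(n_paralog)]] <- 2L
  n_planted_trees <- sum(witness)
  if (n_planted_trees > cfg$n_trees)
    stop("more planted trees than trees in the screen", call. = FALSE)

  set.seed(child_seed(cfg$seed, 10L))
  planted_idx <- sort(sample.int(cfg$n_trees, n_planted_trees))
  tree_event <- rep(NA_integer_, cfg$n_trees)
  tree_event[planted_idx] <- rep(seq_len(n_events), witness)

  # Event-level donor leaf draws (shared by paralogous witnesses).
  event_donors <- lapply(seq_len(n_events), function(e) {
    pool <- tax0$entries$id[tax0$entries$phylum == ev_donors[e]]
    sample(pool, cfg$planted_donor_size)
  })

  calls <- list()
  samples <- list()
  truth <- data.frame(query_id = query_ids, planted = !is.na(tree_event),
                      donor_phylum = ifelse(is.na(tree_event), NA_character_,
                                            ev_donors[tree_event]),
                      event_id = tree_event, stringsAsFactors = FALSE)
  gated_out <- 0L

  for (i in seq_len(cfg$n_trees)) {
    q <- query_ids[i]
    e <- tree_event[i]
    planted <- !is.na(e)
    # Paralogous witnesses of one event re-use the event's hit-table seed.
    hit_off <- if (planted) 100000L + e else i
    boost <- if (planted) event_donors[[e]] else character(0)
    hits <- simulate_hits(cfg, q, tax0, boost = boost, seed_offset = hit_off)
    hits <- hits[hits$evalue <= cfg$evalue_cutoff, , drop = FALSE]
    smp <- build_sample(q, hits, tax, cap = cfg$phylum_cap, top_n = cfg$top_n)
    samples[[q]] <- smp$member_ids
    if (!tree_worthy(smp, tax, min_bacteria = cfg$min_bacteria)) {
      gated_out <- gated_out + 1L
      next
    }
    members <- setdiff(smp$member_ids, q)
    gt <- .screen_tree(cfg, q, members, tax,
                       donors = boost,
                       donor_phylum = if (planted) ev_donors[e] else NA,
                       seed_offset = i)
    tree_calls <- scan_donors(gt, tax, q,
                              support_min = cfg$support_min,
                              min_donor = cfg$min_donor,
                              max_foreign = cfg$max_foreign)
    calls <- c(calls, tree_calls)
  }

  groups <- group_cases(calls, samples, jaccard_min = cfg$jaccard_min)
  counts <- count_nonredundant(groups)
  summary <- list(
    n_trees = cfg$n_trees, n_gated_out = gated_out,
    n_calls = length(calls), n_groups = length(groups),
    counts = as.list(counts),
    derep = if (!is.null(derep))
      list(input = length(derep$representatives) + nrow(derep$assignment),
           representatives = length(derep$representatives)))

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_call_report(calls, file.path(out_dir, "calls.tsv"))
    jsonlite::write_json(
      lapply(groups, function(g) list(donor_phylum = g$donor_phylum,
                                      member_queries = g$member_queries)),
      file.path(out_dir, "groups.json"), auto_unbox = TRUE, digits = NA)
    jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA)
  }

  structure(list(config = cfg, counts = counts, calls = calls, groups = groups,
                 truth = truth, samples = samples, derep = derep,
                 summary = summary),
            class = "screen_result")
}

# Simulate (and under clean supports, verify) the gene tree of one screened
# query over its sampled homologs.
.screen_tree <- function(cfg, query_id, members, tax, donors, donor_phylum,
                         seed_offset) {
  planted <- length(donors) > 0L
  set.seed(child_seed(cfg$seed, 5L, seed_offset))
  for (attempt in 1:200) {
    if (planted) {
      rest <- setdiff(members, donors)
      is_bact <- tax_has_flag(tax, rest, "bacteria")
      is_ex <- tax_is_exempt(tax, rest)
      foreign <- if (cfg$n_foreign_in_clade > 0L)
        sample(rest[is_bact & tax_phylum(tax, rest) != donor_phylum],
               cfg$n_foreign_in_clade) else character(0)
      exempt <- if (cfg$n_exempt_in_clade > 0L) {
        pool <- setdiff(rest[is_ex], foreign)
        sample(pool, min(cfg$n_exempt_in_clade, length(pool)))
      } else character(0)
      bg <- setdiff(rest, c(foreign, exempt))
      res <- .build_tree(query_id, bg, cfg$support_model,
                         donor = donors, foreign = foreign, exempt = exempt)
    } else {
      res <- .build_tree(query_id, members, cfg$support_model)
    }
    if (cfg$support_model$kind != "clean" ||
        .tree_verifies(cfg, res, tax, query_id))
      return(res$tree)
  }
  stop("could not simulate a verifiable screened topology", call. = FALSE)
}

#' @export
print.screen_result <- function(x, ...) {
  cat("screen_result:", x$summary$n_trees, "trees,", x$summary$n_calls,
      "calls,", x$summary$n_groups, "non-redundant events\n")
  if (length(x$counts)) {
    for (ph in names(x$counts)) cat("  ", ph, ":", x$counts[[ph]], "\n")
  }
  invisible(x)
}

#' Run the naphthoquinone identification stage
#'
#' Computes the theoretical adduct m/z table for the candidate compounds and
#' matches an observed peak list against it within a ppm tolerance,
#' optionally restricted to a selected-monitoring m/z window.
#'
#' @param peaks data frame (\code{rt_min}, \code{mz}) or path to a peak CSV.
#' @param out_path optional TSV report path.
#' @inheritParams match_peaks
#' @return list with \code{theoretical} (the candidate m/z block) and
#'   \code{matches} (the \code{\link{match_peaks}} result).
#' @export
run_quinone <- function(peaks, candidates = quinone_candidates(),
                        adducts = adduct_specs(), tol_ppm = 20, window = NULL,
                        out_path = NULL) {
  if (is.character(peaks)) peaks <- read_peaks(peaks)
  theo <- theoretical_mz_table(candidates, adducts)
  matches <- match_peaks(peaks, candidates, adducts, tol_ppm = tol_ppm,
                         window = window)
  if (!is.null(out_path)) {
    con <- file(out_path, "w")
    writeLines("# theoretical candidate m/z", con)
    utils::write.table(theo, con, sep = "\t", quote = FALSE, row.names = FALSE)
    writeLines("# matches", con)
    utils::write.table(matches, con, sep = "\t", quote = FALSE, row.names = FALSE)
    close(con)
  }
  list(theoretical = theo, matches = matches)
}
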