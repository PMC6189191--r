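#' Parse a Newick gene tree with support-valued internal labels
#'
#' Internal node labels are interpreted as edge support percentages when
#' numeric; non-numeric or absent labels give missing support. Trees are
#' treated as unrooted: every internal edge induces one leaf bipartition, and
#' duplicate bipartitions arising from a rooted representation are merged
#' (keeping the defined support).
#'
#' @param text a Newick string.
#' @param label_split optional single character; when given, node labels of
#'   the form \code{name<label_split>support} carry the support after the
#'   last separator (e.g. \code{"cladeA/97"} with \code{label_split = "/"}).
#' @return an object of class \code{gene_tree} wrapping an \code{ape::phylo}
#'   tree plus its internal-edge bipartitions and supports.
#' @export
parse_newick <- function(text, label_split = NULL) {
  phy <- tryCatch(ape::read.tree(text = text),
                  error = function(e) NULL, warning = function(w) NULL)
  if (is.null(phy) || !inherits(phy, "phylo"))
    stop("malformed Newick string", call. = FALSE)
  gene_tree(phy, label_split = label_split)
}

#' Read a gene tree from a Newick file
#' @param path file containing one Newick tree.
#' @inheritParams parse_newick
#' @return a \code{gene_tree}.
#' @export
read_gene_tree <- function(path, label_split = NULL) {
  parse_newick(paste(readLines(path, warn = FALSE), collapse = ""),
               label_split = label_split)
}

#' Construct a gene tree from an ape phylo object
#' @param phy an \code{ape::phylo} tree with >= 3 uniquely labelled tips.
#' @inheritParams parse_newick
#' @return a \code{gene_tree}.
#' @export
gene_tree <- function(phy, label_split = NULL) {
  if (!inherits(phy, "phylo")) stop("phy must be an ape phylo tree", call. = FALSE)
  if (length(phy$tip.label) < 3L) stop("tree must have >= 3 leaves", call. = FALSE)
  if (anyDuplicated(phy$tip.label)) {
    dup <- unique(phy$tip.label[duplicated(phy$tip.label)])
    stop("duplicate leaf label(s): ", paste(dup, collapse = ", "), call. = FALSE)
  }
  structure(list(phylo = phy, splits = .tree_splits(phy, label_split)),
            class = "gene_tree")
}

# Node-label -> support value. Numeric labels are supports; with label_split,
# the token after the last separator is used.
.label_support <- function(labels, label_split = NULL) {
  if (is.null(labels)) return(numeric(0))
  if (!is.null(label_split)) {
    labels <- vapply(strsplit(labels, label_split, fixed = TRUE), function(p) {
      if (length(p) == 0L) "" else p[length(p)]
    }, "")
  }
  suppressWarnings(as.numeric(labels))
}

# Enumerate internal-edge bipartitions of a (possibly rooted) phylo. Each
# split separates >= 2 leaves from >= 2 leaves; identical splits from the two
# root edges of a rooted binary tree are merged, keeping the max defined
# support. Sides are stored canonically (the side holding the alphabetically
# first leaf).
.tree_splits <- function(phy, label_split = NULL) {
  ntip <- length(phy$tip.label)
  pp <- ape::prop.part(phy)
  labs <- attr(pp, "labels")
  sup <- .label_support(phy$node.label, label_split)
  if (length(sup) == 0L) sup <- rep(NA_real_, phy$Nnode)
  first_leaf <- sort(labs)[1]
  sides <- list(); supports <- numeric(0); keys <- character(0)
  for (i in seq_along(pp)) {
    clade <- labs[pp[[i]]]
    if (length(clade) < 2L || length(clade) > ntip - 2L) next
    side <- if (first_leaf %in% clade) clade else setdiff(labs, clade)
    side <- sort(side)
    key <- paste(side, collapse = "\r")
    s <- sup[i]
    j <- match(key, keys)
    if (is.na(j)) {
      keys <- c(keys, key)
      sides[[length(sides) + 1L]] <- side
      supports <- c(supports, s)
    } else if (!is.na(s) && (is.na(supports[j]) || s > supports[j])) {
      supports[j] <- s
    }
  }
  list(sides = sides, supports = supports, leaves = sort(labs))
}

#' @export
print.gene_tree <- function(x, ...) {
  cat("gene_tree:", length(x$phylo$tip.label), "leaves,",
      length(x$splits$sides), "internal edge(s)\n")
  invisible(x)
}

#' Leaf labels of a gene tree
#' @param tree a \code{gene_tree}.
#' @return character vector of leaf ids.
#' @export
tree_leaves <- function(tree) tree$phylo$tip.label

#' Write a gene tree to Newick
#' @param tree a \code{gene_tree}.
#' @param path output file; when \code{NULL} the Newick string is returned.
#' @export
write_newick <- function(tree, path = NULL) {
  if (is.null(path)) return(ape::write.tree(tree$phylo))
  ape::write.tree(tree$phylo, file = path)
  invisible(path)
}

#' Enumerate anchored clades of a gene tree
#'
#' For every internal edge of the (unrooted) tree, yields the side of the
#' induced leaf bipartition that contains the anchor leaf, together with that
#' edge's support. This is the clade calculus behind the monophyly test: a
#' group is "monophyletic with" the anchor exactly when it appears as such an
#' anchored side.
#'
#' @param tree a \code{gene_tree}.
#' @param anchor a leaf id present in the tree.
#' @return a list with one element per internal edge, each a list
#'   \code{leaves} (the anchored side) and \code{support} (percent or NA).
#' @export
clades <- function(tree, anchor) {
  leaves <- tree$splits$leaves
  if (!anchor %in% leaves) stop("anchor '", anchor, "' is not a leaf", call. = FALSE)
  lapply(seq_along(tree$splits$sides), function(i) {
    side <- tree$splits$sides[[i]]
    if (!anchor %in% side) side <- setdiff(leaves, side)
    list(leaves = side, support = tree$splits$supports[i])
  })
}

#' Classify a gene tree for lateral transfer from a donor phylum
#'
#' Applies the monophyly rule: the query must sit in a supported clade
#' (support >= \code{support_min}, missing support disqualifies) together
#' with at least \code{min_donor} donor-phylum sequences, and that clade may
#' be interrupted by any number of exempt-lineage sequences (Archaeplastida
#' and secondary-plastid algae by default) but by at most \code{max_foreign}
#' other sequences. Clades whose donor phylum is represented by a single
#' sequence are rejected. Among qualifying clades the smallest is reported
#' (ties: higher support, then lexicographically smallest leaf set).
#'
#' @param tree a \code{gene_tree} whose leaves resolve in \code{tax}.
#' @param tax a \code{\link{taxonomy_map}}.
#' @param query_id the query leaf.
#' @param donor_phylum candidate donor phylum name.
#' @param support_min minimum edge support, inclusive (default 90).
#' @param min_donor minimum donor-phylum sequences in the clade (default 2).
#' @param max_foreign maximum non-donor, non-exempt, non-query leaves
#'   tolerated in the clade (default 2).
#' @return an \code{lgt_call} (list with \code{query_id},
#'   \code{donor_phylum}, \code{clade_leaves}, \code{support},
#'   \code{n_donor}, \code{n_exempt}, \code{n_foreign}), or \code{NULL} when
#'   no clade qualifies.
#' @export
classify_lgt <- function(tree, tax, query_id, donor_phylum,
                         support_min = 90, min_donor = 2L, max_foreign = 2L) {
  leaves <- tree_leaves(tree)
  if (!query_id %in% leaves)
    stop("query '", query_id, "' is not a leaf of the tree", call. = FALSE)
  if (anyNA(tax_phylum(tax, leaves))) {
    miss <- leaves[is.na(tax_phylum(tax, leaves))]
    stop("leaf id(s) missing from taxonomy: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  best <- NULL
  for (cl in clades(tree, query_id)) {
    cand <- .score_clade(cl, tax, query_id, donor_phylum,
                         support_min, min_donor, max_foreign)
    if (is.null(cand)) next
    if (is.null(best) || .clade_before(cand, best)) best <- cand
  }
  best
}

.score_clade <- function(cl, tax, query_id, donor_phylum,
                         support_min, min_donor, max_foreign) {
  if (is.na(cl$support) || cl$support < support_min) return(NULL)
  others <- setdiff(cl$leaves, query_id)
  is_donor <- tax_phylum(tax, others) == donor_phylum
  is_exempt <- !is_donor & tax_is_exempt(tax, others)
  n_donor <- sum(is_donor); n_exempt <- sum(is_exempt)
  n_foreign <- length(others) - n_donor - n_exempt
  if (n_donor < min_donor || n_foreign > max_foreign) return(NULL)
  structure(list(query_id = query_id, donor_phylum = donor_phylum,
                 clade_leaves = sort(cl$leaves), support = cl$support,
                 n_donor = n_donor, n_exempt = n_exempt, n_foreign = n_foreign),
            class = "lgt_call")
}

# Ordering for the reported clade: smallest leaf set, then higher support,
# then lexicographically smallest sorted leaf set.
.clade_before <- function(a, b) {
  if (length(a$clade_leaves) != length(b$clade_leaves))
    return(length(a$clade_leaves) < length(b$clade_leaves))
  if (a$support != b$support) return(a$support > b$support)
  paste(a$clade_leaves, collapse = "\r") < paste(b$clade_leaves, collapse = "\r")
}

#' @export
print.lgt_call <- function(x, ...) {
  cat("lgt_call:", x$query_id, "<-", x$donor_phylum,
      sprintf("(support %.0f, donor %d, exempt %d, foreign %d, clade %d leaves)\n",
              x$support, x$n_donor, x$n_exempt, x$n_foreign,
              length(x$clade_leaves)))
  invisible(x)
}

#' Scan a gene tree for every plausible bacterial donor
#'
#' Runs \code{\link{classify_lgt}} once per bacterial phylum represented in
#' the tree and collects all resulting calls. When two or more donor phyla
#' qualify the result is flagged as conflicting.
#'
#' @inheritParams classify_lgt
#' @param ... further arguments passed to \code{\link{classify_lgt}}.
#' @return a list of \code{lgt_call}s (possibly empty), with attribute
#'   \code{conflict} set to \code{TRUE} when more than one donor qualifies.
#' @export
scan_donors <- function(tree, tax, query_id, ...) {
  leaves <- setdiff(tree_leaves(tree), query_id)
  bact <- leaves[tax_has_flag(tax, leaves, "bacteria")]
  phyla <- sort(unique(tax_phylum(tax, bact)))
  calls <- list()
  for (ph in phyla) {
    call <- classify_lgt(tree, tax, query_id, ph, ...)
    if (!is.null(call)) calls[[length(calls) + 1L]] <- call
  }
  attr(calls, "conflict") <- length(calls) >= 2L
  calls
}

## ---- case grouping and counting -------------------------------------------

jaccard <- function(a, b) {
  u <- union(a, b)
  if (length(u) == 0L) return(1)
  length(intersect(a, b)) / length(u)
}

#' Group paralogous transfer calls into non-redundant events
#'
#' Recent gene duplications in the recipient genome produce several query
#' trees that witness the same ancestral transfer. Calls with the same donor
#' phylum whose sampled homolog sets overlap (Jaccard index >=
#' \code{jaccard_min}) are merged by single linkage into one case group.
#'
#' @param calls a list of \code{lgt_call}s.
#' @param samples named list mapping each call's query id to its sampled
#'   homolog id set (e.g. \code{member_ids} of its \code{sample_set}).
#' @param jaccard_min single-linkage merge threshold (default 0.5).
#' @return a list of \code{lgt_case_group}s, each with
#'   \code{member_queries}, \code{donor_phylum} and \code{evidence} (the
#'   member calls); ordered by donor phylum then first query id.
#' @export
group_cases <- function(calls, samples, jaccard_min = 0.5) {
  if (length(calls) == 0L) return(list())
  qs <- vapply(calls, `[[`, "", "query_id")
  donors <- vapply(calls, `[[`, "", "donor_phylum")
  miss <- setdiff(qs, names(samples))
  if (length(miss)) stop("no sample for query id(s): ", paste(miss, collapse = ", "),
                         call. = FALSE)
  n <- length(calls)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  if (n > 1L) for (i in 1:(n - 1L)) for (j in (i + 1L):n) {
    if (donors[i] != donors[j]) next
    if (jaccard(samples[[qs[i]]], samples[[qs[j]]]) >= jaccard_min) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
    }
  }
  roots <- vapply(seq_len(n), find, 1L)
  groups <- lapply(sort(unique(roots)), function(r) {
    idx <- which(roots == r)
    structure(list(member_queries = sort(qs[idx]),
                   donor_phylum = donors[idx[1]],
                   evidence = calls[idx]),
              class = "lgt_case_group")
  })
  ord <- order(vapply(groups, `[[`, "", "donor_phylum"),
               vapply(groups, function(g) g$member_queries[1], ""))
  groups[ord]
}

#' @export
print.lgt_case_group <- function(x, ...) {
  cat("lgt_case_group:", x$donor_phylum, "<-",
      paste(x$member_queries, collapse = ", "), "\n")
  invisible(x)
}

#' Count non-redundant transfer events per donor phylum
#' @param groups a list of \code{lgt_case_group}s.
#' @return named integer vector, one count per donor phylum (empty for no
#'   groups); the counts sum to \code{length(groups)}.
#' @export
count_nonredundant <- function(groups) {
  if (length(groups) == 0L) return(integer(0))
  tab <- table(vapply(groups, `[[`, "", "donor_phylum"))
  out <- as.integer(tab); names(out) <- names(tab)
  out
}

## ---- congruence and concatenation -----------------------------------------

# Restrict splits to a taxon set; drop splits that become trivial. Splits are
# re-canonicalised and deduplicated (max defined support wins).
.restrict_splits <- function(splits, taxa) {
  taxa <- sort(taxa)
  sides <- list(); supports <- numeric(0); keys <- character(0)
  for (i in seq_along(splits$sides)) {
    side <- intersect(splits$sides[[i]], taxa)
    if (length(side) < 2L || length(side) > length(taxa) - 2L) next
    if (!(taxa[1] %in% side)) side <- setdiff(taxa, side)
    side <- sort(side)
    key <- paste(side, collapse = "\r")
    j <- match(key, keys)
    s <- splits$supports[i]
    if (is.na(j)) {
      keys <- c(keys, key); sides[[length(sides) + 1L]] <- side
      supports <- c(supports, s)
    } else if (!is.na(s) && (is.na(supports[j]) || s > supports[j])) {
      supports[j] <- s
    }
  }
  list(sides = sides, supports = supports, leaves = taxa)
}

# Two splits conflict on taxon set S iff all four intersection cells of their
# bipartitions restricted to S are non-empty.
.conflict_cells <- function(sideA, sideB, taxa) {
  a1 <- intersect(sideA, taxa); a0 <- setdiff(taxa, a1)
  b1 <- intersect(sideB, taxa); b0 <- setdiff(taxa, b1)
  cells <- list(intersect(a1, b1), intersect(a1, b0),
                intersect(a0, b1), intersect(a0, b0))
  if (any(lengths(cells) == 0L)) NULL else cells
}

#' Largest congruent taxon set of two gene trees
#'
#' Restricts both trees to their shared taxa, collapses weakly supported
#' edges (support below \code{collapse_below}; edges with no support value
#' are kept), and then removes taxa until the two restricted trees are
#' compatible, i.e. no bipartition of one conflicts with a bipartition of the
#' other. Removal is greedy: at each step the taxon implicated in the most
#' conflicting bipartition pairs (as a member of the smallest intersection
#' cell of each conflict) is dropped, ties broken alphabetically. The
#' surviving taxon set is the congruence-gated set on which the two
#' alignments may be concatenated.
#'
#' @param treeA,treeB \code{gene_tree}s sharing >= 4 taxa.
#' @param collapse_below collapse edges with support strictly below this
#'   percentage before comparing (default 0: collapse nothing).
#' @return character vector of congruent taxa (sorted).
#' @export
congruent_taxa <- function(treeA, treeB, collapse_below = 0) {
  shared <- intersect(tree_leaves(treeA), tree_leaves(treeB))
  if (length(shared) < 4L) stop("trees share fewer than 4 taxa", call. = FALSE)
  keep_strong <- function(spl) {
    keep <- is.na(spl$supports) | spl$supports >= collapse_below
    list(sides = spl$sides[keep], supports = spl$supports[keep],
         leaves = spl$leaves)
  }
  sA <- keep_strong(treeA$splits); sB <- keep_strong(treeB$splits)
  taxa <- sort(shared)
  repeat {
    rA <- .restrict_splits(sA, taxa); rB <- .restrict_splits(sB, taxa)
    votes <- integer(0)
    n_conf <- 0L
    for (i in seq_along(rA$sides)) for (j in seq_along(rB$sides)) {
      cells <- .conflict_cells(rA$sides[[i]], rB$sides[[j]], taxa)
      if (is.null(cells)) next
      n_conf <- n_conf + 1L
      m <- min(lengths(cells))
      for (cell in cells[lengths(cells) == m]) for (t in cell)
        votes[t] <- (if (t %in% names(votes)) votes[[t]] else 0L) + 1L
    }
    if (n_conf == 0L) return(taxa)
    worst <- names(votes)[votes == max(votes)]
    taxa <- setdiff(taxa, sort(worst)[1])
    if (length(taxa) < 4L)
      stop("fewer than 4 congruent taxa remain", call. = FALSE)
  }
}

## ---- alignments ------------------------------------------------------------

#' Read an aligned FASTA file
#' @param path FASTA file of gap-aligned sequences ("-" gaps).
#' @return named character vector, one aligned row per taxon; errors if rows
#'   differ in width.
#' @export
read_alignment <- function(path) {
  s <- Biostrings::readAAStringSet(path)
  aln <- as.character(s)
  names(aln) <- sub("\\s.*$", "", names(s))
  .check_rectangular(aln)
  aln
}

#' Write an alignment to FASTA
#' @param aln named character vector of equal-width rows.
#' @param path output file.
#' @export
write_alignment <- function(aln, path) {
  .check_rectangular(aln)
  s <- Biostrings::AAStringSet(aln)
  Biostrings::writeXStringSet(s, path)
  invisible(path)
}

.check_rectangular <- function(aln) {
  if (length(aln) == 0L) stop("empty alignment", call. = FALSE)
  if (length(unique(nchar(aln))) != 1L)
    stop("alignment is not rectangular", call. = FALSE)
  invisible(TRUE)
}

#' Concatenate two alignments over a congruent taxon set
#'
#' Row-wise join of two rectangular alignments restricted to the given taxa;
#' the output width is the sum of the input widths and the partition boundary
#' is recorded in the \code{"partition"} attribute (the two block widths).
#'
#' @param alnA,alnB named character vectors (aligned rows).
#' @param taxa taxa to keep; must number >= 4 (the congruence rule) and be
#'   present in both alignments.
#' @return the concatenated alignment (named character vector).
#' @export
concatenate_alignments <- function(alnA, alnB, taxa) {
  .check_rectangular(alnA); .check_rectangular(alnB)
  if (length(taxa) == 0L) stop("empty taxon set", call. = FALSE)
  if (length(taxa) < 4L) stop("fewer than 4 taxa requested", call. = FALSE)
  missA <- setdiff(taxa, names(alnA)); missB <- setdiff(taxa, names(alnB))
  if (length(missA) || length(missB))
    stop("taxa missing from alignment: ",
         paste(unique(c(missA, missB)), collapse = ", "), call. = FALSE)
  out <- paste0(alnA[taxa], alnB[taxa])
  names(out) <- taxa
  attr(out, "partition") <- c(nchar(alnA[[1]]), nchar(alnB[[1]]))
  out
}

#' Remove gap-rich alignment columns
#'
#' Drops every column whose gap fraction exceeds \code{max_gap_fraction};
#' column order is otherwise preserved.
#'
#' @param aln named character vector of aligned rows.
#' @param max_gap_fraction columns with gap fraction strictly greater than
#'   this are removed (default 0.5).
#' @return the trimmed alignment; errors if no column survives.
#' @export
trim_alignment <- function(aln, max_gap_fraction = 0.5) {
  .check_rectangular(aln)
  m <- do.call(rbind, strsplit(aln, "", fixed = TRUE))
  gapfrac <- colMeans(m == "-")
  keep <- gapfrac <= max_gap_fraction
  if (!any(keep)) stop("no alignment columns survive trimming", call. = FALSE)
  out <- apply(m[, keep, drop = FALSE], 1L, paste, collapse = "")
  names(out) <- names(aln)
  out
}

#' Write a transfer-call report
#'
#' One TSV row per call:
#' \code{query, donor_phylum, support, n_donor, n_exempt, n_foreign, clade_leaves}.
#'
#' @param calls list of \code{lgt_call}s.
#' @param path output TSV; when \code{NULL} a data frame is returned.
#' @export
write_call_report <- function(calls, path = NULL) {
  df <- data.frame(
    query = vapply(calls, `[[`, "", "query_id"),
    donor_phylum = vapply(calls, `[[`, "", "donor_phylum"),
    support = vapply(calls, `[[`, 0, "support"),
    n_donor = vapply(calls, function(x) as.integer(x$n_donor), 1L),
    n_exempt = vapply(calls, function(x) as.integer(x$n_exempt), 1L),
    n_foreign = vapply(calls, function(x) as.integer(x$n_foreign), 1L),
    clade_leaves = vapply(calls, function(x) paste(x$clade_leaves, collapse = ","), ""),
    stringsAsFactors = FALSE)
  if (is.null(path)) return(df)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
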