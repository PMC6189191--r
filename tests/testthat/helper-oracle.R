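# Independent oracles, deliberately written against the raw ape edge matrix
# (graph traversal per edge) rather than the package's clade machinery.

# All leaf bipartitions of a phylo induced by its internal edges, found by
# deleting each edge in turn and flood-filling the two components. Returns a
# list of list(side1, side2, support); duplicate splits merged keeping the
# max defined support.
oracle_splits <- function(phy) {
  ntip <- length(phy$tip.label)
  edges <- phy$edge
  labels <- phy$tip.label
  sup_of_node <- function(node) {
    if (node <= ntip) return(NA_real_)
    if (is.null(phy$node.label)) return(NA_real_)
    suppressWarnings(as.numeric(phy$node.label[node - ntip]))
  }
  adj <- split(c(edges[, 2], edges[, 1]), c(edges[, 1], edges[, 2]))
  reach <- function(start, banned_a, banned_b) {
    seen <- c(start); queue <- start
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      for (w in adj[[as.character(v)]]) {
        if ((v == banned_a && w == banned_b) || (v == banned_b && w == banned_a)) next
        if (!w %in% seen) { seen <- c(seen, w); queue <- c(queue, w) }
      }
    }
    seen
  }
  out <- list(); keys <- character(0)
  for (k in seq_len(nrow(edges))) {
    a <- edges[k, 1]; b <- edges[k, 2]
    compA <- reach(a, a, b)
    side1 <- sort(labels[intersect(compA, seq_len(ntip))])
    side2 <- sort(setdiff(labels, side1))
    if (length(side1) < 2 || length(side2) < 2) next
    s <- sup_of_node(b)   # support annotates the child (subtree) node
    key <- paste(min(paste(side1, collapse = ","), paste(side2, collapse = ",")))
    j <- match(key, keys)
    if (is.na(j)) {
      keys <- c(keys, key)
      out[[length(out) + 1]] <- list(side1 = side1, side2 = side2, support = s)
    } else if (!is.na(s) && (is.na(out[[j]]$support) || s > out[[j]]$support)) {
      out[[j]]$support <- s
    }
  }
  out
}

# Literal re-statement of the monophyly rules over the oracle splits.
# taxdf: data.frame(id, phylum, exempt (logical)).
oracle_classify <- function(phy, taxdf, query, donor,
                            support_min = 90, min_donor = 2, max_foreign = 2) {
  best <- NULL
  for (sp in oracle_splits(phy)) {
    side <- if (query %in% sp$side1) sp$side1 else sp$side2
    if (!query %in% side) next
    if (is.na(sp$support) || sp$support < support_min) next
    others <- setdiff(side, query)
    ph <- taxdf$phylum[match(others, taxdf$id)]
    ex <- taxdf$exempt[match(others, taxdf$id)]
    nd <- sum(ph == donor)
    ne <- sum(ph != donor & ex)
    nf <- length(others) - nd - ne
    if (nd < min_donor || nf > max_foreign) next
    cand <- list(leaves = sort(side), support = sp$support,
                 n_donor = nd, n_exempt = ne, n_foreign = nf)
    if (is.null(best)) { best <- cand; next }
    take <- FALSE
    if (length(cand$leaves) != length(best$leaves)) {
      take <- length(cand$leaves) < length(best$leaves)
    } else if (cand$support != best$support) {
      take <- cand$support > best$support
    } else take <- paste(cand$leaves, collapse = ",") < paste(best$leaves, collapse = ",")
    if (take) best <- cand
  }
  best
}

# Reference greedy dereplication: longest-first, id tiebreak, assign each
# sequence to the first earlier representative reaching the threshold.
oracle_dereplicate <- function(records, threshold) {
  reps <- character(0); removed <- character(0); rep_of <- character(0)
  for (ph in unique(records$phylum)) {
    r <- records[records$phylum == ph, ]
    r <- r[order(-r$length, r$id), ]
    ph_reps <- character(0)
    for (i in seq_len(nrow(r))) {
      home <- NA_character_
      for (p in ph_reps) {
        if (pairwise_identity(r$sequence[i], records$sequence[records$id == p]) >= threshold) {
          home <- p; break
        }
      }
      if (is.na(home)) ph_reps <- c(ph_reps, r$id[i])
      else { removed <- c(removed, r$id[i]); rep_of <- c(rep_of, home) }
    }
    reps <- c(reps, ph_reps)
  }
  list(representatives = reps,
       assignment = data.frame(removed_id = removed, representative_id = rep_of,
                               stringsAsFactors = FALSE))
}

# Literal single-pass first-come-first-serve sampler with per-phylum counters.
oracle_select <- function(subject_ids, phyla, cap) {
  counts <- list(); out <- character(0)
  for (i in seq_along(subject_ids)) {
    ph <- phyla[i]
    if (is.na(ph)) next
    k <- if (!is.null(counts[[ph]])) counts[[ph]] else 0
    if (k < cap) { counts[[ph]] <- k + 1; out <- c(out, subject_ids[i]) }
  }
  out
}

# Exhaustive congruence oracle: the largest subset of shared taxa (>= 4) on
# which the two restricted split sets are mutually compatible.
oracle_congruent <- function(treeA, treeB, collapse_below = 0) {
  shared <- sort(intersect(tree_leaves(treeA), tree_leaves(treeB)))
  strong <- function(tr) {
    spl <- tr$splits
    keep <- is.na(spl$supports) | spl$supports >= collapse_below
    spl$sides[keep]
  }
  sA <- strong(treeA); sB <- strong(treeB)
  compatible_on <- function(taxa) {
    restrict <- function(sides) {
      out <- list()
      for (s in sides) {
        s2 <- intersect(s, taxa)
        if (length(s2) >= 2 && length(s2) <= length(taxa) - 2)
          out[[length(out) + 1]] <- s2
      }
      out
    }
    rA <- restrict(sA); rB <- restrict(sB)
    for (x in rA) for (y in rB) {
      x1 <- x; x0 <- setdiff(taxa, x); y1 <- y; y0 <- setdiff(taxa, y)
      if (length(intersect(x1, y1)) && length(intersect(x1, y0)) &&
          length(intersect(x0, y1)) && length(intersect(x0, y0))) return(FALSE)
    }
    TRUE
  }
  for (size in seq(length(shared), 4)) {
    combs <- utils::combn(shared, size, simplify = FALSE)
    ok <- Filter(compatible_on, combs)
    if (length(ok)) return(ok)
  }
  list()
}
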