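# BLAST outfmt-6 column order; only the columns the sampler needs are kept.
OUTFMT6_COLS <- c("qseqid", "sseqid", "pident", "length", "mismatch", "gapopen",
                  "qstart", "qend", "sstart", "send", "evalue", "bitscore")

#' Read a BLAST-style tabular hit file
#'
#' Parses a tab-separated hit table in outfmt-6 column order (overridable) and
#' applies the significance screen: rows with E-value above the cutoff are
#' dropped. Lines starting with \code{#} are ignored.
#'
#' @param path TSV file.
#' @param evalue_cutoff retain rows with \code{evalue <= evalue_cutoff}
#'   (default \code{1e-05}).
#' @param columns column names in file order; must include \code{qseqid},
#'   \code{sseqid}, \code{pident}, \code{evalue}, \code{bitscore}.
#' @return data frame with columns \code{query_id}, \code{subject_id},
#'   \code{identity_pct}, \code{evalue}, \code{bitscore}.
#' @export
read_hits <- function(path, evalue_cutoff = 1e-05, columns = OUTFMT6_COLS) {
  need <- c("qseqid", "sseqid", "pident", "evalue", "bitscore")
  if (!all(need %in% columns))
    stop("columns must include ", paste(need, collapse = ", "), call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  keep <- which(nzchar(trimws(lines)) & !grepl("^\\s*#", lines))
  if (length(keep) == 0L)
    return(data.frame(query_id = character(0), subject_id = character(0),
                      identity_pct = numeric(0), evalue = numeric(0),
                      bitscore = numeric(0), stringsAsFactors = FALSE))
  parts <- strsplit(lines[keep], "\t", fixed = TRUE)
  if (any(lengths(parts) < length(columns))) {
    bad <- keep[which(lengths(parts) < length(columns))[1]]
    stop("line ", bad, ": expected ", length(columns), " columns", call. = FALSE)
  }
  grab <- function(col) vapply(parts, `[`, "", match(col, columns))
  num <- function(col) {
    x <- suppressWarnings(as.numeric(grab(col)))
    if (anyNA(x)) {
      bad <- keep[which(is.na(x))[1]]
      stop("line ", bad, ": non-numeric ", col, call. = FALSE)
    }
    x
  }
  h <- data.frame(query_id = grab("qseqid"), subject_id = grab("sseqid"),
                  identity_pct = num("pident"), evalue = num("evalue"),
                  bitscore = num("bitscore"), stringsAsFactors = FALSE)
  h[h$evalue <= evalue_cutoff, , drop = FALSE]
}

#' Keep the top hits of one query by bit score
#'
#' Stable sort by descending bit score (ties broken by ascending subject id),
#' truncation to the first \code{n} rows, and dense 1-based rank assignment.
#'
#' @param hits hit rows of a single query (see \code{\link{read_hits}}).
#' @param n maximum number of hits to keep (default 1200).
#' @return the retained rows, sorted, with a \code{rank} column.
#' @export
top_hits <- function(hits, n = 1200L) {
  if (length(unique(hits$query_id)) > 1L)
    stop("top_hits expects hits of a single query", call. = FALSE)
  o <- order(-hits$bitscore, hits$subject_id)
  out <- hits[o, , drop = FALSE][seq_len(min(n, nrow(hits))), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Select taxonomically capped representative hits
#'
#' Walks the hit list once, in the order given, and admits a hit if and only
#' if its phylum has been admitted fewer than \code{cap} times so far
#' (first come, first served). Encounter order is preserved.
#'
#' @param hits hit rows already in the desired traversal order.
#' @param tax a \code{\link{taxonomy_map}} resolving subject ids to phyla.
#' @param cap per-phylum admission cap (default 6).
#' @param unmapped what to do with subject ids absent from \code{tax}:
#'   \code{"skip"} (default, with a warning) or \code{"error"}.
#' @return character vector of admitted subject ids, in encounter order.
#' @export
select_representatives <- function(hits, tax, cap = 6L, unmapped = c("skip", "error")) {
  unmapped <- match.arg(unmapped)
  phyla <- tax_phylum(tax, hits$subject_id)
  if (anyNA(phyla)) {
    miss <- unique(hits$subject_id[is.na(phyla)])
    if (unmapped == "error")
      stop("subject id(s) missing from taxonomy: ", paste(miss, collapse = ", "),
           call. = FALSE)
    warning("skipping ", length(miss), " subject id(s) missing from taxonomy",
            call. = FALSE)
  }
  counts <- integer(0)
  admitted <- character(0)
  for (i in seq_along(phyla)) {
    ph <- phyla[i]
    if (is.na(ph)) next
    k <- if (ph %in% names(counts)) counts[[ph]] else 0L
    if (k < cap) {
      counts[ph] <- k + 1L
      admitted <- c(admitted, hits$subject_id[i])
    }
  }
  admitted
}

#' Build the two-pass taxon-balanced homolog sample for a query
#'
#' Pass 1 samples representatives from the hits sorted by bit score; pass 2
#' re-sorts the same hits by the query--hit alignment identity (descending,
#' subject-id tiebreak) and samples again with a fresh per-phylum budget. The
#' sample is the union of both passes plus the query itself.
#'
#' @param query_id the query sequence id.
#' @param hits hit rows of that query.
#' @param tax a \code{\link{taxonomy_map}}.
#' @param cap per-phylum cap applied within each pass (default 6).
#' @param top_n bit-score truncation applied before sampling (default 1200).
#' @param unmapped passed to \code{\link{select_representatives}}.
#' @return an object of class \code{sample_set}: \code{query_id},
#'   \code{member_ids} (query first, then subjects in admission order),
#'   \code{per_phylum_counts}, and \code{passes} (data frame id/pass).
#' @export
build_sample <- function(query_id, hits, tax, cap = 6L, top_n = 1200L,
                         unmapped = "skip") {
  if (nrow(hits) > 0L && any(hits$query_id != query_id))
    stop("hits must all belong to the query", call. = FALSE)
  if (nrow(hits) > 0L) {
    h1 <- top_hits(hits, n = top_n)
    pass1 <- select_representatives(h1, tax, cap = cap, unmapped = unmapped)
    o2 <- order(-h1$identity_pct, h1$subject_id)
    pass2 <- select_representatives(h1[o2, , drop = FALSE], tax, cap = cap,
                                    unmapped = unmapped)
  } else {
    pass1 <- pass2 <- character(0)
  }
  members <- c(query_id, union(pass1, pass2))
  passes <- rbind(
    if (length(pass1)) data.frame(id = pass1, pass = "bitscore",
                                  stringsAsFactors = FALSE),
    if (length(pass2)) data.frame(id = pass2, pass = "identity",
                                  stringsAsFactors = FALSE))
  if (is.null(passes)) passes <- data.frame(id = character(0), pass = character(0),
                                            stringsAsFactors = FALSE)
  ph <- tax_phylum(tax, members)
  counts <- table(ph[!is.na(ph)])
  structure(list(query_id = query_id, member_ids = members,
                 per_phylum_counts = as.list(counts), passes = passes),
            class = "sample_set")
}

#' @export
print.sample_set <- function(x, ...) {
  cat("sample_set for", x$query_id, ":", length(x$member_ids), "members over",
      length(x$per_phylum_counts), "phyla\n")
  invisible(x)
}

#' Gate a sample on bacterial representation
#'
#' A homolog sample is worth a tree only if it contains enough bacterial
#' sequences for a donor clade to be resolvable.
#'
#' @param sample a \code{sample_set}.
#' @param tax a \code{\link{taxonomy_map}}.
#' @param min_bacteria minimum number of members flagged \code{bacteria}
#'   (default 3).
#' @return \code{TRUE} or \code{FALSE}.
#' @export
tree_worthy <- function(sample, tax, min_bacteria = 3L) {
  sum(tax_has_flag(tax, sample$member_ids, "bacteria")) >= min_bacteria
}

#' Serialise a sample set to JSON
#' @param sample a \code{sample_set}.
#' @param path output file; when \code{NULL}, returns the JSON string.
#' @export
write_sample_json <- function(sample, path = NULL) {
  obj <- list(query = sample$query_id, members = sample$member_ids,
              per_phylum_counts = sample$per_phylum_counts,
              passes = sample$passes)
  if (is.null(path)) return(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
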