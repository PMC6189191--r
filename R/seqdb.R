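# Recognised lineage flags. "chlamydiae" implies "bacteria"; the photosynthetic
# flags ("archaeplastida", "secondary_plastid") are incompatible with "bacteria".
KNOWN_FLAGS <- c("chlamydiae", "archaeplastida", "secondary_plastid", "bacteria", "query")

#' Validate a set of lineage flags
#'
#' Checks that every flag is recognised and that the combination is
#' biologically consistent: a chlamydial sequence is bacterial, and the
#' Archaeplastida / secondary-plastid flags mark eukaryotic lineages so they
#' can never co-occur with \code{bacteria}.
#'
#' @param flags character vector of flags (may be empty).
#' @return invisibly \code{TRUE}; errors on violation.
#' @keywords internal
validate_flags <- function(flags) {
  flags <- flags[nzchar(flags)]
  bad <- setdiff(flags, KNOWN_FLAGS)
  if (length(bad) > 0L)
    stop("unknown lineage flag(s): ", paste(bad, collapse = ", "), call. = FALSE)
  if ("chlamydiae" %in% flags && !("bacteria" %in% flags))
    stop("flag 'chlamydiae' requires 'bacteria'", call. = FALSE)
  if ("bacteria" %in% flags && any(c("archaeplastida", "secondary_plastid") %in% flags))
    stop("flags 'archaeplastida'/'secondary_plastid' cannot combine with 'bacteria'",
         call. = FALSE)
  invisible(TRUE)
}

split_flags <- function(x) {
  f <- strsplit(x, ";", fixed = TRUE)[[1]]
  f <- trimws(f)
  f[nzchar(f) & f != "-"]
}

#' Construct a taxonomy map
#'
#' A taxonomy map resolves sequence ids to their phylum, species and lineage
#' flags, and records which lineages are treated as non-interrupting
#' ("exempt") when testing query--donor monophyly. By default the exempt
#' lineages are the primary-plastid Archaeplastida and lineages bearing a
#' plastid of secondary endosymbiotic origin.
#'
#' @param ids character vector of unique sequence ids.
#' @param phylum character vector, one phylum per id.
#' @param flags character vector of semicolon-separated flag strings
#'   (\code{""} or \code{"-"} for none).
#' @param species optional character vector of species names.
#' @param exempt_lineages flags whose carriers never count as foreign
#'   interruptions of a candidate donor clade.
#' @return an object of class \code{taxonomy_map}.
#' @export
taxonomy_map <- function(ids, phylum, flags = character(length(ids)),
                         species = character(length(ids)),
                         exempt_lineages = c("archaeplastida", "secondary_plastid")) {
  ids <- as.character(ids)
  if (anyDuplicated(ids)) {
    dup <- unique(ids[duplicated(ids)])
    stop("duplicate sequence id(s): ", paste(dup, collapse = ", "), call. = FALSE)
  }
  stopifnot(length(phylum) == length(ids), length(flags) == length(ids))
  if (length(species) == 0L) species <- character(length(ids))
  flag_list <- lapply(as.character(flags), split_flags)
  for (i in seq_along(flag_list)) {
    tryCatch(validate_flags(flag_list[[i]]),
             error = function(e) stop("id '", ids[i], "': ", conditionMessage(e),
                                      call. = FALSE))
  }
  bad_ex <- setdiff(exempt_lineages, KNOWN_FLAGS)
  if (length(bad_ex)) stop("unknown exempt lineage(s): ", paste(bad_ex, collapse = ", "),
                           call. = FALSE)
  structure(list(
    entries = data.frame(id = ids, phylum = as.character(phylum),
                         species = as.character(species),
                         flags = vapply(flag_list, paste, "", collapse = ";"),
                         stringsAsFactors = FALSE, row.names = ids),
    exempt_lineages = exempt_lineages
  ), class = "taxonomy_map")
}

#' @export
print.taxonomy_map <- function(x, ...) {
  cat("taxonomy_map:", nrow(x$entries), "ids,",
      length(unique(x$entries$phylum)), "phyla; exempt:",
      paste(x$exempt_lineages, collapse = ", "), "\n")
  invisible(x)
}

#' Read a taxonomy map from a tab-separated file
#'
#' Expected columns: \code{id<TAB>phylum<TAB>flags[<TAB>species]}, where
#' \code{flags} is a semicolon-separated list (\code{-} for none). Lines
#' starting with \code{#} and blank lines are ignored.
#'
#' @param path path to the TSV file.
#' @inheritParams taxonomy_map
#' @return a \code{taxonomy_map}.
#' @export
read_taxonomy <- function(path,
                          exempt_lineages = c("archaeplastida", "secondary_plastid")) {
  lines <- readLines(path, warn = FALSE)
  keep <- which(nzchar(trimws(lines)) & !grepl("^\\s*#", lines))
  parts <- strsplit(lines[keep], "\t", fixed = TRUE)
  nfield <- lengths(parts)
  if (any(nfield < 3L)) {
    bad <- keep[which(nfield < 3L)[1]]
    stop("malformed taxonomy line ", bad, ": expected >= 3 tab-separated fields",
         call. = FALSE)
  }
  taxonomy_map(
    ids = vapply(parts, `[`, "", 1L),
    phylum = vapply(parts, `[`, "", 2L),
    flags = vapply(parts, `[`, "", 3L),
    species = vapply(parts, function(p) if (length(p) >= 4L) p[4L] else "", ""),
    exempt_lineages = exempt_lineages
  )
}

#' Write a taxonomy map to TSV
#' @param tax a \code{taxonomy_map}.
#' @param path output file.
#' @export
write_taxonomy <- function(tax, path) {
  e <- tax$entries
  flags <- ifelse(nzchar(e$flags), e$flags, "-")
  writeLines(c("# id\tphylum\tflags\tspecies",
               paste(e$id, e$phylum, flags, e$species, sep = "\t")), path)
  invisible(path)
}

tax_lookup <- function(tax, ids, what) {
  stopifnot(inherits(tax, "taxonomy_map"))
  tax$entries[match(ids, tax$entries$id), what]
}

#' Resolve phyla for sequence ids
#' @param tax a \code{taxonomy_map}.
#' @param ids sequence ids; unmapped ids give \code{NA}.
#' @return character vector of phyla.
#' @export
tax_phylum <- function(tax, ids) tax_lookup(tax, ids, "phylum")

#' Test whether sequence ids carry a lineage flag
#' @inheritParams tax_phylum
#' @param flag a single flag name.
#' @return logical vector; \code{FALSE} for unmapped ids.
#' @export
tax_has_flag <- function(tax, ids, flag) {
  f <- tax_lookup(tax, ids, "flags")
  out <- vapply(strsplit(ifelse(is.na(f), "", f), ";", fixed = TRUE),
                function(fl) flag %in% fl, NA)
  out & !is.na(f)
}

#' Test whether ids belong to an exempt (non-interrupting) lineage
#' @inheritParams tax_phylum
#' @return logical vector.
#' @export
tax_is_exempt <- function(tax, ids) {
  out <- rep(FALSE, length(ids))
  for (fl in tax$exempt_lineages) out <- out | tax_has_flag(tax, ids, fl)
  out
}

## ---- sequences ------------------------------------------------------------

#' Build a sequence record table
#'
#' Sequence records are kept as a plain data frame with columns \code{id},
#' \code{phylum}, \code{species}, \code{sequence} and \code{length}.
#'
#' @param ids unique sequence ids.
#' @param sequences amino-acid strings (non-empty).
#' @param phylum phylum per sequence.
#' @param species optional species names.
#' @return a data frame of sequence records.
#' @export
seq_records <- function(ids, sequences, phylum, species = character(length(ids))) {
  ids <- as.character(ids); sequences <- as.character(sequences)
  if (anyDuplicated(ids)) stop("duplicate sequence id(s)", call. = FALSE)
  if (any(!nzchar(sequences))) stop("empty sequence(s) not allowed", call. = FALSE)
  if (length(species) == 0L) species <- character(length(ids))
  data.frame(id = ids, phylum = as.character(phylum), species = as.character(species),
             sequence = sequences, length = nchar(sequences),
             stringsAsFactors = FALSE)
}

#' Read protein sequences from FASTA
#'
#' Wrapped lines are tolerated; the id is the header token before the first
#' whitespace. Phylum and flags are resolved from the taxonomy map when given.
#'
#' @param path FASTA file.
#' @param tax optional \code{taxonomy_map} used to fill the phylum column.
#' @return a sequence-record data frame (see \code{\link{seq_records}}).
#' @export
read_fasta_records <- function(path, tax = NULL) {
  s <- Biostrings::readAAStringSet(path)
  ids <- sub("\\s.*$", "", names(s))
  phylum <- if (!is.null(tax)) tax_phylum(tax, ids) else rep(NA_character_, length(ids))
  seq_records(ids, as.character(s), phylum)
}

#' Write sequence records to FASTA
#' @param records a sequence-record data frame.
#' @param path output file.
#' @param width line-wrap width.
#' @export
write_fasta_records <- function(records, path, width = 60L) {
  s <- Biostrings::AAStringSet(records$sequence)
  names(s) <- records$id
  Biostrings::writeXStringSet(s, path, width = width)
  invisible(path)
}

## ---- pairwise identity and dereplication ----------------------------------

#' Global-alignment pairwise identity
#'
#' Identity between two amino-acid sequences, defined as the number of
#' identical aligned positions divided by the alignment length of a global
#' (Needleman--Wunsch) alignment scored with match = 1, mismatch = 0 and an
#' affine gap penalty (open 10, extend 0.5). Symmetric, and 1 for a sequence
#' against itself.
#'
#' @param a,b amino-acid strings (non-empty).
#' @return identity fraction in \[0, 1\].
#' @export
pairwise_identity <- function(a, b) {
  a <- as.character(a); b <- as.character(b)
  if (!nzchar(a) || !nzchar(b)) stop("empty sequence", call. = FALSE)
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b), type = "global",
    substitutionMatrix = .identity_matrix(), gapOpening = 10, gapExtension = 0.5)
  Biostrings::nmatch(aln) / Biostrings::nchar(aln)
}

.identity_matrix <- local({
  m <- NULL
  function() {
    if (is.null(m)) {
      letters27 <- c(LETTERS, "*")
      mm <- diag(1, length(letters27))
      dimnames(mm) <- list(letters27, letters27)
      m <<- mm
    }
    m
  }
})

#' Dereplicate sequences within each phylum by identity clustering
#'
#' Reduces within-phylum redundancy the way a greedy identity clusterer does:
#' records are sorted longest-first (ties broken by id), the first unclustered
#' record founds a cluster and becomes its representative, and every later
#' record whose identity to an existing representative reaches the threshold
#' is assigned to the first such representative. Only the longest sequence of
#' each cluster is retained; assignment never crosses phylum boundaries.
#'
#' @param records a sequence-record data frame (\code{\link{seq_records}}).
#' @param threshold identity fraction in (0, 1\]; inclusive comparison
#'   (default 0.85, i.e. identity >= 85\%).
#' @return an object of class \code{cluster_result} with elements
#'   \code{representatives} (ids), \code{assignment} (data frame
#'   \code{removed_id}, \code{representative_id}, \code{identity}) and
#'   \code{threshold}.
#' @export
dereplicate <- function(records, threshold = 0.85) {
  if (!is.numeric(threshold) || threshold <= 0 || threshold > 1)
    stop("threshold must be in (0, 1]", call. = FALSE)
  if (any(is.na(records$phylum))) stop("records must carry phylum labels", call. = FALSE)
  reps <- character(0)
  rem <- data.frame(removed_id = character(0), representative_id = character(0),
                    identity = numeric(0), stringsAsFactors = FALSE)
  for (ph in unique(records$phylum)) {
    r <- records[records$phylum == ph, , drop = FALSE]
    r <- r[order(-r$length, r$id), , drop = FALSE]
    ph_reps <- character(0)
    for (i in seq_len(nrow(r))) {
      assigned <- FALSE
      for (rep_id in ph_reps) {
        idn <- pairwise_identity(r$sequence[i],
                                 r$sequence[match(rep_id, r$id)])
        if (idn >= threshold) {
          rem <- rbind(rem, data.frame(removed_id = r$id[i],
                                       representative_id = rep_id,
                                       identity = idn, stringsAsFactors = FALSE))
          assigned <- TRUE
          break
        }
      }
      if (!assigned) ph_reps <- c(ph_reps, r$id[i])
    }
    reps <- c(reps, ph_reps)
  }
  structure(list(representatives = reps, assignment = rem, threshold = threshold),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat("cluster_result:", length(x$representatives), "representatives,",
      nrow(x$assignment), "removed (identity >=", x$threshold, ")\n")
  invisible(x)
}

#' Write a dereplication report
#'
#' One row per removed sequence: \code{removed_id<TAB>representative_id<TAB>identity}.
#'
#' @param cl a \code{cluster_result}.
#' @param path output TSV file.
#' @export
write_cluster_report <- function(cl, path) {
  a <- cl$assignment
  writeLines(c("removed_id\trepresentative_id\tidentity",
               if (nrow(a)) paste(a$removed_id, a$representative_id,
                                  formatC(a$identity, digits = 6, format = "f"),
                                  sep = "\t")), path)
  invisible(path)
}
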