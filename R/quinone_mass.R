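# Monoisotopic atomic masses (Da) of the elements a quinone formula can
# contain, from the IUPAC/CODATA atomic mass evaluation (most abundant
# isotope of each element).
MONOISOTOPIC_MASS <- c(
  H = 1.0078250319, C = 12.0, N = 14.0030740052, O = 15.9949146221,
  Na = 22.98976928, Mg = 23.985041697, P = 30.97376151, S = 31.97207069,
  Cl = 34.96885271, K = 38.9637064864, Fe = 55.9349375, Br = 78.9183376
)

# Singly charged positive-mode adduct mass shifts (Da): a proton, and sodium
# minus the electron it displaces.
PROTON_MASS <- 1.007276
SODIUM_MINUS_ELECTRON <- 22.989220

#' Positive-mode adduct specifications
#'
#' The two singly charged positive ions considered: the protonated molecule
#' \code{[M+H]+} and the sodium adduct \code{[M+Na]+}.
#'
#' @return data frame with columns \code{name}, \code{mass_delta} (Da) and
#'   \code{charge}.
#' @export
adduct_specs <- function() {
  data.frame(name = c("[M+H]+", "[M+Na]+"),
             mass_delta = c(PROTON_MASS, SODIUM_MINUS_ELECTRON),
             charge = c(1L, 1L), stringsAsFactors = FALSE)
}

#' Parse a Hill-notation molecular formula
#'
#' Accepts strings like \code{"C31H46O3"}; an omitted count means 1, and a
#' repeated element symbol accumulates.
#'
#' @param text the formula string.
#' @return named integer vector of element counts (class
#'   \code{molecular_formula}).
#' @export
parse_formula <- function(text) {
  text <- trimws(text)
  if (!nzchar(text)) stop("empty formula", call. = FALSE)
  matches <- gregexpr("[A-Z][a-z]?[0-9]*", text)[[1]]
  tokens <- regmatches(text, gregexpr("[A-Z][a-z]?[0-9]*", text))[[1]]
  if (sum(attr(matches, "match.length")) != nchar(text))
    stop("cannot parse formula '", text, "'", call. = FALSE)
  counts <- integer(0)
  for (tok in tokens) {
    el <- sub("[0-9]*$", "", tok)
    n <- sub("^[A-Za-z]+", "", tok)
    n <- if (nzchar(n)) as.integer(n) else 1L
    if (!el %in% names(MONOISOTOPIC_MASS))
      stop("unknown element symbol '", el, "'", call. = FALSE)
    if (n < 1L) stop("element count must be >= 1 in '", tok, "'", call. = FALSE)
    counts[el] <- (if (el %in% names(counts)) counts[[el]] else 0L) + n
  }
  structure(counts, class = "molecular_formula")
}

#' @export
print.molecular_formula <- function(x, ...) {
  cat(paste0(names(x), ifelse(unclass(x) > 1L, unclass(x), ""), collapse = ""), "\n")
  invisible(x)
}

#' Monoisotopic mass of a molecular formula
#'
#' Sum of count-weighted monoisotopic atomic masses; additive over formula
#' union.
#'
#' @param formula a \code{molecular_formula} (or a formula string, parsed on
#'   the fly).
#' @return neutral monoisotopic mass in Da.
#' @export
monoisotopic_mass <- function(formula) {
  if (is.character(formula)) formula <- parse_formula(formula)
  els <- names(formula)
  miss <- setdiff(els, names(MONOISOTOPIC_MASS))
  if (length(miss)) stop("no monoisotopic mass for: ", paste(miss, collapse = ", "),
                         call. = FALSE)
  sum(unclass(formula) * MONOISOTOPIC_MASS[els])
}

#' m/z of a singly charged adduct ion
#'
#' \code{(mass + mass_delta) / charge} for the requested adduct.
#'
#' @param mass neutral monoisotopic mass (Da), positive.
#' @param adduct \code{"[M+H]+"} or \code{"[M+Na]+"} (or a one-row data frame
#'   as returned by \code{\link{adduct_specs}}).
#' @return the ion m/z.
#' @export
adduct_mz <- function(mass, adduct = "[M+H]+") {
  if (!is.numeric(mass) || mass <= 0) stop("mass must be positive", call. = FALSE)
  if (is.character(adduct)) {
    specs <- adduct_specs()
    i <- match(adduct, specs$name)
    if (is.na(i)) stop("unknown adduct '", adduct, "'", call. = FALSE)
    adduct <- specs[i, , drop = FALSE]
  }
  (mass + adduct$mass_delta) / adduct$charge
}

#' Bundled naphthoquinone candidate table
#'
#' The vitamin-K-family candidates relevant to algal photosystem I:
#' phylloquinone (PhQ, vitamin K1), monohydroxyphylloquinone (OH-PhQ, the
#' major naphthoquinone of several algae), the menaquinones MK-4 and MK-7,
#' and the pathway intermediate DHNA (1,4-dihydroxy-2-naphthoate). Formulas
#' follow the standard structures: PhQ C31H46O2 and its monohydroxylated
#' derivative C31H46O3, MK-n C11H8O2 plus n C5H8 prenyl units, DHNA C11H8O4.
#'
#' @return data frame with columns \code{name} and \code{formula}.
#' @export
quinone_candidates <- function() {
  data.frame(
    name = c("phylloquinone", "OH-phylloquinone", "menaquinone-4",
             "menaquinone-7", "DHNA"),
    formula = c("C31H46O2", "C31H46O3", "C31H40O2", "C46H64O2", "C11H8O4"),
    stringsAsFactors = FALSE)
}

#' Match observed peaks to candidate adduct ions
#'
#' Every combination of observed peak, candidate compound and adduct whose
#' mass error is within \code{tol_ppm} is reported. An optional
#' selected-monitoring window restricts the peaks considered before
#' matching.
#'
#' @param peaks data frame with columns \code{rt_min} (retention time,
#'   minutes) and \code{mz} (observed m/z, Da); may be empty.
#' @param candidates data frame with columns \code{name} and \code{formula}
#'   (default: \code{\link{quinone_candidates}}).
#' @param adducts adduct table (default \code{\link{adduct_specs}}).
#' @param tol_ppm match tolerance in parts per million (default 20).
#' @param window optional numeric length-2 m/z window, e.g.
#'   \code{c(466.5, 467.5)} for the selected-monitoring mode; peaks outside
#'   it are ignored.
#' @return data frame with one row per match: \code{rt_min},
#'   \code{observed_mz}, \code{candidate}, \code{adduct},
#'   \code{theoretical_mz}, \code{error_ppm}.
#' @export
match_peaks <- function(peaks, candidates = quinone_candidates(),
                        adducts = adduct_specs(), tol_ppm = 20, window = NULL) {
  if (!is.numeric(tol_ppm) || tol_ppm < 0)
    stop("tolerance must be non-negative", call. = FALSE)
  empty <- data.frame(rt_min = numeric(0), observed_mz = numeric(0),
                      candidate = character(0), adduct = character(0),
                      theoretical_mz = numeric(0), error_ppm = numeric(0),
                      stringsAsFactors = FALSE)
  if (nrow(peaks) == 0L) return(empty)
  if (!is.null(window)) {
    stopifnot(length(window) == 2L)
    peaks <- peaks[peaks$mz >= window[1] & peaks$mz <= window[2], , drop = FALSE]
    if (nrow(peaks) == 0L) return(empty)
  }
  theo <- theoretical_mz_table(candidates, adducts)
  out <- empty
  for (p in seq_len(nrow(peaks))) for (t in seq_len(nrow(theo))) {
    err <- (peaks$mz[p] - theo$mz[t]) / theo$mz[t] * 1e6
    if (abs(err) <= tol_ppm)
      out <- rbind(out, data.frame(rt_min = peaks$rt_min[p],
                                   observed_mz = peaks$mz[p],
                                   candidate = theo$name[t],
                                   adduct = theo$adduct[t],
                                   theoretical_mz = theo$mz[t],
                                   error_ppm = err, stringsAsFactors = FALSE))
  }
  out
}

#' Theoretical adduct m/z table for a candidate list
#' @inheritParams match_peaks
#' @return data frame with columns \code{name}, \code{formula}, \code{adduct},
#'   \code{mz}.
#' @export
theoretical_mz_table <- function(candidates = quinone_candidates(),
                                 adducts = adduct_specs()) {
  rows <- expand.grid(c_i = seq_len(nrow(candidates)),
                      a_i = seq_len(nrow(adducts)))
  masses <- vapply(candidates$formula, function(f) monoisotopic_mass(f), 0)
  data.frame(
    name = candidates$name[rows$c_i],
    formula = candidates$formula[rows$c_i],
    adduct = adducts$name[rows$a_i],
    mz = (masses[rows$c_i] + adducts$mass_delta[rows$a_i]) / adducts$charge[rows$a_i],
    stringsAsFactors = FALSE)
}

#' Read a peak list CSV (\code{rt_min,mz})
#' @param path CSV file with header \code{rt_min,mz}.
#' @return data frame of peaks.
#' @export
read_peaks <- function(path) {
  p <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("rt_min", "mz") %in% names(p)))
    stop("peak list needs columns rt_min, mz", call. = FALSE)
  p
}
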