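#' Natural-abundance isotope table
#'
#' Per-element fractional isotope abundances indexed by nominal mass shift
#' (shift 0 is the lightest isotope). Defaults are IUPAC representative
#' values. All user-facing functions take their constants from an object of
#' this class, so a laboratory can substitute its own calibrated values.
#'
#' @param c13 Fractional abundance of \eqn{^{13}}C.
#' @param h2 Fractional abundance of \eqn{^{2}}H (deuterium).
#' @param n15 Fractional abundance of \eqn{^{15}}N.
#' @param o17,o18 Fractional abundances of \eqn{^{17}}O and \eqn{^{18}}O.
#' @param extra Optional named list of additional elements; each entry is a
#'   numeric vector of abundances by mass shift starting at 0, summing to 1.
#'
#' @return An object of class `isotope_table`: a named list mapping element
#'   symbols to abundance vectors by mass shift.
#' @examples
#' isotope_table()
#' isotope_table(c13 = 0.0109490)  # calibrated against a reference baseline
#' @export
isotope_table <- function(c13 = 0.0107, h2 = 0.000115, n15 = 0.00364,
                          o17 = 0.00038, o18 = 0.00205, extra = NULL) {
  tab <- list(
    C = c(1 - c13, c13),
    H = c(1 - h2, h2),
    N = c(1 - n15, n15),
    O = c(1 - o17 - o18, o17, o18)
  )
  if (!is.null(extra)) {
    stopifnot(is.list(extra), !is.null(names(extra)))
    tab[names(extra)] <- extra
  }
  for (el in names(tab)) {
    ab <- tab[[el]]
    if (any(ab < 0) || abs(sum(ab) - 1) > 1e-12)
      stop("abundances for element '", el,
           "' must be non-negative and sum to 1", call. = FALSE)
  }
  structure(tab, class = "isotope_table")
}

#' @export
print.isotope_table <- function(x, ...) {
  cat("Isotope table (fractional abundance by mass shift)\n")
  for (el in names(x))
    cat(sprintf("  %-2s %s\n", el,
                paste(formatC(x[[el]], format = "g", digits = 6),
                      collapse = "  ")))
  invisible(x)
}

#' Parse a chemical formula
#'
#' Parses a Hill-style elemental formula such as `"C15H22N1O9"` (the glucose
#' methoxyamine-pentaacetate fragment monitored at m/z 360) into per-element
#' atom counts. Explicit counts of 1 are allowed; zero counts are rejected.
#'
#' @param text A formula string: element symbols (one capital letter plus an
#'   optional lower-case letter) each followed by an optional integer count.
#' @param isotopes An [isotope_table()] used to validate element symbols.
#'
#' @return A named integer vector of atom counts, one entry per element, in
#'   order of first appearance.
#' @examples
#' parse_formula("C15H22N1O9")
#' parse_formula("C3H6O")  # acetone
#' @seealso [format_formula()] for the inverse.
#' @export
parse_formula <- function(text, isotopes = isotope_table()) {
  stopifnot(is.character(text), length(text) == 1L)
  counts <- integer(0)
  pos <- 1L
  rest <- text
  while (nzchar(rest)) {
    m <- regexpr("^([A-Z][a-z]?)([0-9]*)", rest)
    if (attr(m, "match.length") < 1L)
      stop("malformed formula '", text, "': unexpected character at position ",
           pos, call. = FALSE)
    tok <- regmatches(rest, m)
    sym <- sub("[0-9]*$", "", tok)
    num <- sub("^[A-Za-z]+", "", tok)
    if (!sym %in% names(isotopes))
      stop("unknown element '", sym, "' at position ", pos,
           " in formula '", text, "'", call. = FALSE)
    n <- if (nzchar(num)) as.integer(num) else 1L
    if (n == 0L)
      stop("zero atom count for element '", sym, "' at position ", pos,
           " in formula '", text, "'", call. = FALSE)
    counts[sym] <- (if (sym %in% names(counts)) counts[[sym]] else 0L) + n
    pos <- pos + nchar(tok)
    rest <- substring(rest, nchar(tok) + 1L)
  }
  if (length(counts) == 0L)
    stop("empty formula", call. = FALSE)
  counts
}

#' Serialize an element composition back to a formula string
#'
#' @param comp Named integer vector of atom counts, as from [parse_formula()].
#' @return A formula string with explicit counts; `parse_formula()` of the
#'   result reproduces `comp`.
#' @examples
#' format_formula(parse_formula("C15H22N1O9"))
#' @export
format_formula <- function(comp) {
  paste0(names(comp), comp, collapse = "")
}

#' Convolve two mass-isotopomer patterns
#'
#' The pattern of a species composed of two independent parts is the
#' convolution of the parts' patterns: entry \eqn{k} is
#' \eqn{\sum_i a_i b_{k-i}}, truncated at `max_shift`.
#'
#' @param a,b Numeric vectors of fractional abundances indexed by mass shift
#'   (first entry is shift 0).
#' @param max_shift Truncation order; the result has `max_shift + 1` entries.
#' @return Numeric abundance vector of length `max_shift + 1`.
#' @examples
#' convolve_patterns(c(0.5, 0.5), c(0.5, 0.5), 2)  # 0.25 0.50 0.25
#' @export
convolve_patterns <- function(a, b, max_shift = length(a) + length(b) - 2L) {
  out <- numeric(max_shift + 1L)
  for (i in seq_along(a)) {
    if (a[i] == 0) next
    jmax <- min(length(b), max_shift + 2L - i)
    if (jmax < 1L) break
    idx <- seq_len(jmax)
    out[i + idx - 1L] <- out[i + idx - 1L] + a[i] * b[idx]
  }
  out
}

# pattern of `count` atoms of one element, by repeated squaring
.element_power <- function(ab, count, max_shift) {
  result <- c(1, numeric(max_shift))
  base <- c(ab, numeric(max(0L, max_shift + 1L - length(ab))))[1:(max_shift + 1L)]
  while (count > 0L) {
    if (count %% 2L == 1L)
      result <- convolve_patterns(result, base, max_shift)
    count <- count %/% 2L
    if (count > 0L) base <- convolve_patterns(base, base, max_shift)
  }
  result
}

#' Natural-abundance isotopologue pattern of a composition
#'
#' Fractional abundances of the M+0, M+1, ... mass isotopomers of an
#' unlabeled molecule, obtained by convolving the isotope distribution of
#' every atom. This is the baseline that all tracer enrichments are measured
#' against.
#'
#' @param comp Named integer vector of atom counts ([parse_formula()]), or a
#'   formula string.
#' @param max_shift Truncation order (default 6). Must be at least 2 so the
#'   monitored M+0..M+2 window is covered.
#' @param isotopes An [isotope_table()].
#' @return Numeric vector `A[0..max_shift]` of fractional abundances. Entries
#'   sum to slightly less than 1 because of truncation; the deficit is far
#'   below measurement noise for `max_shift = 6`.
#' @examples
#' A <- natural_isotope_pattern("C15H22N1O9")
#' round(A, 5)
#' # the baseline excess ratio (A1 - A2) / (A0 - A1):
#' (A[2] - A[3]) / (A[1] - A[2])
#' @export
natural_isotope_pattern <- function(comp, max_shift = 6L,
                                    isotopes = isotope_table()) {
  if (is.character(comp)) comp <- parse_formula(comp, isotopes)
  if (max_shift < 2L) stop("max_shift must be >= 2", call. = FALSE)
  stopifnot(all(comp >= 0), length(comp) >= 1L)
  pat <- c(1, numeric(max_shift))
  for (el in names(comp)) {
    if (!el %in% names(isotopes))
      stop("unknown element '", el, "'", call. = FALSE)
    pat <- convolve_patterns(pat,
                             .element_power(isotopes[[el]], comp[[el]], max_shift),
                             max_shift)
  }
  pat
}

#' Calibrate the carbon-13 abundance against a reference baseline ratio
#'
#' The single most influential natural-abundance constant for the glucose
#' fragment is \eqn{^{13}}C. Published reference tabulations pin down the
#' unlabeled baseline through the excess ratio that a one-site labeled
#' species exhibits (the f(GNG) = 0 column of the EM2/EM1 lookup table,
#' 0.173155, which is independent of the precursor enrichment). This helper
#' solves for the \eqn{^{13}}C abundance that reproduces a given baseline
#' ratio under the chosen window normalization.
#'
#' @param target Baseline excess ratio EM2/EM1 of a one-exchangeable-site
#'   species (default 0.173155).
#' @param comp Composition of the measured fragment.
#' @param window `"three_ion"` (normalize abundances over M+0..M+2, as the
#'   monitored measurement does) or `"full"`.
#' @param range Search interval for the \eqn{^{13}}C abundance.
#' @param isotopes Base [isotope_table()]; only the carbon entry is adjusted.
#' @param max_shift Truncation order.
#' @return The calibrated \eqn{^{13}}C fractional abundance (numeric scalar).
#' @examples
#' calibrate_c13()  # about 0.01095
#' @export
calibrate_c13 <- function(target = 0.173155, comp = "C15H22N1O9",
                          window = c("three_ion", "full"),
                          range = c(0.0107, 0.0111),
                          isotopes = isotope_table(), max_shift = 6L) {
  window <- match.arg(window)
  if (is.character(comp)) comp <- parse_formula(comp, isotopes)
  ratio_at <- function(a13) {
    it <- isotopes
    it$C <- c(1 - a13, a13)
    A <- natural_isotope_pattern(comp, max_shift, it)
    # one-site labeling at a small enrichment; the ratio is p-independent
    lab <- convolve_patterns(A, c(1 - 0.02, 0.02), max_shift)
    .excess_ratio(lab, A, window)
  }
  f <- function(a13) ratio_at(a13) - target
  # widen the bracket if the stated range does not contain the root
  lo <- range[1]; hi <- range[2]
  if (f(lo) * f(hi) > 0) { lo <- 0.009; hi <- 0.013 }
  stats::uniroot(f, c(lo, hi), tol = 1e-12)$root
}

# windowed fractional abundances
.window_fracs <- function(pattern, window) {
  x <- if (window == "three_ion") pattern[1:3] else pattern
  x / sum(x)
}

# excess EM2/EM1 of a labeled pattern against a baseline pattern
.excess_ratio <- function(pattern, baseline, window) {
  em <- .window_fracs(pattern, window) - .window_fracs(baseline, window)
  em[3] / em[2]
}
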