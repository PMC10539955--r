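#' MIDA labeling model for the glucose fragment
#'
#' Bundles everything the mass-isotopomer calculations depend on: the
#' fragment's elemental composition, the natural-abundance constants, the
#' truncation order, the window normalization, and the exchangeable-site
#' counts of the glucose-production pathways. Pass the returned object to the
#' ratio, inversion, estimation and simulation functions so that one
#' consistent set of constants is used throughout an analysis.
#'
#' The canonical site counts are n = 7 for PEPCK gluconeogenesis (all
#' non-acidic C-H positions exchange), n = 2 for glycerol gluconeogenesis
#' (C-5 at triose-phosphate isomerase plus C-2 at phosphoglucose isomerase),
#' n = 1 for glycogenolysis (C-2 only), and n = 6 as the integer effective
#' count for total gluconeogenesis under the one-third glycerol assumption.
#'
#' @param formula Fragment formula (default the methoxyamine-pentaacetate
#'   glucose fragment monitored at m/z 360, `"C15H22N1O9"`).
#' @param isotopes An [isotope_table()].
#' @param calibrate If `TRUE`, replace the \eqn{^{13}}C abundance with the
#'   value from [calibrate_c13()] so the unlabeled baseline matches the
#'   published lookup-table reference ratio 0.173155.
#' @param window `"three_ion"`: fractional abundances are normalized over the
#'   monitored M+0..M+2 ions (the only normalization a three-ion measurement
#'   admits, and the one the published lookup table agrees with most
#'   closely); `"full"`: normalized over the full truncated distribution.
#' @param max_shift Truncation order of all patterns (default 6).
#' @param n_pathways Named integer vector of exchangeable-site counts.
#'
#' @return An object of class `mida_model` with elements `composition`,
#'   `isotopes`, `window`, `max_shift`, `n_pathways` and the precomputed
#'   natural-abundance `baseline` pattern.
#' @examples
#' m <- mida_model()
#' m
#' mida_model(calibrate = TRUE)$isotopes$C[2]
#' @export
mida_model <- function(formula = "C15H22N1O9", isotopes = isotope_table(),
                       calibrate = FALSE, window = c("three_ion", "full"),
                       max_shift = 6L,
                       n_pathways = c(pepck_gng = 7, glycerol_gng = 2,
                                      total_gng = 6, ggl = 1)) {
  window <- match.arg(window)
  comp <- if (is.character(formula)) parse_formula(formula, isotopes) else formula
  if (calibrate) {
    a13 <- calibrate_c13(comp = comp, window = window, isotopes = isotopes,
                         max_shift = max_shift)
    isotopes$C <- c(1 - a13, a13)
  }
  stopifnot(all(n_pathways >= 0), all(n_pathways <= 10))
  structure(list(
    composition = comp,
    isotopes = isotopes,
    window = window,
    max_shift = as.integer(max_shift),
    n_pathways = n_pathways,
    baseline = natural_isotope_pattern(comp, max_shift, isotopes)
  ), class = "mida_model")
}

#' @export
print.mida_model <- function(x, ...) {
  cat("MIDA labeling model\n")
  cat("  fragment:      ", format_formula(x$composition), "\n")
  cat("  13C abundance: ", formatC(x$isotopes$C[2], digits = 6, format = "g"), "\n")
  cat("  window:        ", x$window, "\n")
  cat("  site counts:   ",
      paste(names(x$n_pathways), x$n_pathways, sep = "=", collapse = ", "), "\n")
  b <- .window_fracs(x$baseline, x$window)
  cat("  baseline M+0..M+2:", paste(round(b[1:3], 5), collapse = " "), "\n")
  invisible(x)
}

.as_model <- function(model) {
  if (inherits(model, "mida_model")) model else stop("'model' must be a mida_model",
                                                     call. = FALSE)
}

#' Label-site mass distribution
#'
#' Distribution of the number of deuterium labels on a molecule with `n`
#' solvent-exchangeable sites when the precursor (body water) enrichment is
#' `p`: entry \eqn{k} is \eqn{\binom{n}{k} p^k (1-p)^{n-k}}. Non-integer `n`
#' is supported through the generalized binomial coefficient, which is what
#' the equivalent-site-count analysis interpolates with.
#'
#' @param n Exchangeable-site count (0 to 10; may be fractional).
#' @param p Precursor deuterium enrichment as a fraction in `[0, 0.5]`.
#' @param max_shift Truncation order.
#' @return Numeric vector of probabilities by label count (mass shift).
#' @examples
#' label_site_distribution(2, 0.5)       # 0.25 0.50 0.25 ...
#' label_site_distribution(6, 0.08)[2]   # 6 * 0.08 * 0.92^5
#' @export
label_site_distribution <- function(n, p, max_shift = 6L) {
  if (p < 0 || p > 0.5)
    stop("precursor enrichment p must lie in [0, 0.5], got ", p, call. = FALSE)
  if (n < 0 || n > 10)
    stop("site count n must lie in [0, 10], got ", n, call. = FALSE)
  k <- 0:max_shift
  cf <- vapply(k, function(kk) {
    if (kk == 0) return(1)
    prod(n - seq_len(kk) + 1) / factorial(kk)
  }, numeric(1))
  if (n == round(n)) cf[k > n] <- 0
  out <- cf * p^k * (1 - p)^(n - k)
  out[p == 0 & k > 0] <- 0
  out
}

#' Labeled mass-isotopomer pattern of a pathway
#'
#' Pattern of a population produced entirely through a pathway with `n`
#' exchangeable sites at precursor enrichment `p`: the convolution of the
#' fragment's natural-abundance baseline with the label-site distribution.
#'
#' @param n Exchangeable-site count, or a pathway name from
#'   `model$n_pathways` (e.g. `"ggl"`, `"total_gng"`).
#' @param p Precursor enrichment (fraction).
#' @param model A [mida_model()].
#' @return Numeric abundance vector by mass shift (`max_shift + 1` entries).
#' @examples
#' m <- mida_model()
#' labeled_pattern("ggl", 0.04, m)
#' @export
labeled_pattern <- function(n, p, model = mida_model()) {
  model <- .as_model(model)
  n <- .resolve_n(n, model)
  convolve_patterns(model$baseline, label_site_distribution(n, p, model$max_shift),
                    model$max_shift)
}

.resolve_n <- function(n, model) {
  if (is.character(n)) {
    if (!n %in% names(model$n_pathways))
      stop("unknown pathway '", n, "'; available: ",
           paste(names(model$n_pathways), collapse = ", "), call. = FALSE)
    n <- model$n_pathways[[n]]
  }
  n
}

#' Excess mass-isotopomer enrichments
#'
#' Fractional abundances of a measured or modeled pattern over the monitored
#' window, minus the baseline fractions: EM\eqn{_x} = A\eqn{_x}(labeled) -
#' A\eqn{_x}(baseline). The ratio R = EM2/EM1 is the method's core
#' observable; it is undefined (flagged) when EM1 is not positive.
#'
#' @param pattern Abundance vector by mass shift (raw areas are fine; only
#'   ratios are used), or a vector of exactly three monitored-ion abundances.
#' @param model A [mida_model()] supplying the baseline, or a baseline
#'   abundance vector.
#' @param window Overrides the model's window normalization.
#' @param em1_floor EM1 values at or below this floor flag R as unreliable
#'   (default 0: only non-positive EM1 is flagged).
#' @return An object of class `excess_enrichments`: list with `EM` (vector
#'   over the window), `EM1`, `EM2`, `R`, and `flags` (character vector).
#' @examples
#' m <- mida_model()
#' excess_enrichments(labeled_pattern(6, 0.015, m), m)$R
#' @export
excess_enrichments <- function(pattern, model = mida_model(), window = NULL,
                               em1_floor = 0) {
  if (inherits(model, "mida_model")) {
    baseline <- model$baseline
    if (is.null(window)) window <- model$window
  } else {
    baseline <- model
    if (is.null(window)) window <- "three_ion"
  }
  if (any(pattern < 0) || pattern[1] <= 0)
    stop("pattern abundances must be non-negative with M+0 > 0", call. = FALSE)
  if (window == "three_ion" && length(pattern) > 3) pattern <- pattern[1:3]
  if (window == "full" && length(pattern) < length(baseline))
    stop("full-window enrichments need the full pattern", call. = FALSE)
  fr <- if (window == "three_ion") pattern[1:3] / sum(pattern[1:3])
        else pattern / sum(pattern)
  bf <- .window_fracs(baseline, window)
  em <- fr - bf[seq_along(fr)]
  flags <- character(0)
  R <- NA_real_
  if (em[2] <= em1_floor) flags <- c(flags, "low_EM1")
  else R <- em[3] / em[2]
  structure(list(EM = em, EM1 = em[2], EM2 = em[3], R = R, flags = flags),
            class = "excess_enrichments")
}

#' @export
print.excess_enrichments <- function(x, ...) {
  cat(sprintf("EM1 = %.6g  EM2 = %.6g  R = EM2/EM1 = %s%s\n",
              x$EM1, x$EM2,
              if (is.na(x$R)) "undefined" else formatC(x$R, digits = 6, format = "g"),
              if (length(x$flags)) paste0("  [", paste(x$flags, collapse = ","), "]")
              else ""))
  invisible(x)
}

#' Excess ratio of a pure pathway population
#'
#' R = EM2/EM1 for a population produced entirely through a single pathway
#' with `n` exchangeable sites at enrichment `p` (the f = 1 limit).
#'
#' @inheritParams labeled_pattern
#' @param window Overrides the model's window normalization.
#' @return Numeric scalar R.
#' @examples
#' pathway_ratio("ggl", 0.04)   # p-independent baseline ratio, about 0.173
#' pathway_ratio(6, 0.08)
#' @export
pathway_ratio <- function(n, p, model = mida_model(), window = NULL) {
  model <- .as_model(model)
  if (is.null(window)) window <- model$window
  if (p == 0) stop("pathway_ratio is undefined at p = 0 (no enrichment)",
                   call. = FALSE)
  .excess_ratio(labeled_pattern(n, p, model), model$baseline, window)
}

# linear-form coefficients of the two-population mixture:
# EM2(f) = c2 + f*d2, EM1(f) = c1 + f*d1 (window-normalized)
.mixture_coefs <- function(p, model, n_hi, n_lo, window) {
  a <- labeled_pattern(n_hi, p, model)
  b <- labeled_pattern(n_lo, p, model)
  if (window == "three_ion") { a <- a[1:3]; b <- b[1:3] }
  bf <- .window_fracs(model$baseline, window)
  Sa <- sum(a); Sb <- sum(b)
  list(c1 = b[2] - bf[2] * Sb, d1 = (a[2] - b[2]) - bf[2] * (Sa - Sb),
       c2 = b[3] - bf[3] * Sb, d2 = (a[3] - b[3]) - bf[3] * (Sa - Sb),
       norm = Sb, dnorm = Sa - Sb)
}

#' Mixture excess ratio for gluconeogenesis vs glycogenolysis
#'
#' R = EM2/EM1 of a molecule-level mixture in which a fraction `f_gng` of the
#' glucose population is produced through total gluconeogenesis (default
#' n = 6) and the rest through glycogenolysis (n = 1). Excess enrichments mix
#' linearly with the population weights, so R is a ratio of linear forms in
#' `f_gng`, strictly increasing for p > 0. At `f_gng = 0` the value is the
#' p-independent baseline ratio of the one-site pathway.
#'
#' @param f_gng Fraction of glucose from gluconeogenesis, in `[0, 1]`.
#' @param p Precursor (body water) deuterium enrichment, fraction.
#' @param model A [mida_model()].
#' @param n_gng,n_ggl Site counts of the two populations.
#' @param window Overrides the model's window normalization.
#' @return Numeric scalar R.
#' @examples
#' m <- mida_model(calibrate = TRUE)
#' mixture_ratio(0, 0.005, m)    # 0.173155, the baseline column
#' mixture_ratio(1, 0.08, m)     # about 0.4453
#' mixture_ratio(0.5, 0.04, m)   # about 0.279
#' @export
mixture_ratio <- function(f_gng, p, model = mida_model(), n_gng = NULL,
                          n_ggl = NULL, window = NULL) {
  model <- .as_model(model)
  if (is.null(window)) window <- model$window
  if (is.null(n_gng)) n_gng <- model$n_pathways[["total_gng"]]
  if (is.null(n_ggl)) n_ggl <- model$n_pathways[["ggl"]]
  if (any(f_gng < 0 | f_gng > 1))
    stop("f_gng must lie in [0, 1]", call. = FALSE)
  co <- .mixture_coefs(p, model, n_gng, n_ggl, window)
  (co$c2 + f_gng * co$d2) / (co$c1 + f_gng * co$d1)
}

#' Mixture excess ratio for the gluconeogenic subpathways
#'
#' R = EM2/EM1 of a molecule-level mixture of PEPCK gluconeogenesis (n = 7)
#' and glycerol gluconeogenesis (n = 2), weighted by the fraction `f_pepck`
#' of triose-phosphate-derived glucose that traversed the PEPCK arm. Used for
#' fasted samples, where glycogenolysis is negligible and the two GNG arms
#' sum to one.
#'
#' @param f_pepck Fraction of the population from the PEPCK arm, `[0, 1]`.
#' @inheritParams mixture_ratio
#' @return Numeric scalar R, strictly increasing in `f_pepck`.
#' @examples
#' subpathway_mixture_ratio(2/3, 0.05)
#' @export
subpathway_mixture_ratio <- function(f_pepck, p, model = mida_model(),
                                     window = NULL) {
  model <- .as_model(model)
  if (is.null(window)) window <- model$window
  if (any(f_pepck < 0 | f_pepck > 1))
    stop("f_pepck must lie in [0, 1]", call. = FALSE)
  co <- .mixture_coefs(p, model, model$n_pathways[["pepck_gng"]],
                       model$n_pathways[["glycerol_gng"]], window)
  (co$c2 + f_pepck * co$d2) / (co$c1 + f_pepck * co$d1)
}

#' Equivalent homogeneous site count for a measured ratio
#'
#' Every site count n has a unique R = EM2/EM1 at a given p for a pure
#' (f = 1) population. Reading a measured R back onto the n scale gives the
#' "equivalent n": the homogeneous site count that would generate the same
#' ratio. Because R(n) is very nearly linear in n, the default follows the
#' straight-line convention — ordinary least squares of n against R over
#' integer n = 1..7 — evaluated at the measured R. `method = "exact"` instead
#' solves R(n) = R for real-valued n through the generalized binomial.
#'
#' @param R Measured excess ratio EM2/EM1.
#' @param p Precursor enrichment (fraction).
#' @param model A [mida_model()].
#' @param method `"line"` (default) or `"exact"`.
#' @param n_fit Integer site counts the line is fitted over.
#' @param window Overrides the model's window normalization.
#' @return Real-valued equivalent n. Errors if `R` lies outside the
#'   calibration range `[R(n = 1), R(n = 8)]`, reporting the valid interval.
#' @examples
#' m <- mida_model()
#' equivalent_n(pathway_ratio(4, 0.05, m), 0.05, m)  # about 4
#' @export
equivalent_n <- function(R, p, model = mida_model(),
                         method = c("line", "exact"), n_fit = 1:7,
                         window = NULL) {
  model <- .as_model(model)
  method <- match.arg(method)
  if (is.null(window)) window <- model$window
  lo <- pathway_ratio(1, p, model, window)
  hi <- pathway_ratio(8, p, model, window)
  if (R < lo - 1e-12 || R > hi + 1e-12)
    stop(sprintf("R = %.6g outside the calibration range [%.6g, %.6g] at p = %g",
                 R, lo, hi, p), call. = FALSE)
  if (method == "exact")
    return(stats::uniroot(function(n) pathway_ratio(n, p, model, window) - R,
                          c(1, 8), tol = 1e-10)$root)
  Rn <- vapply(n_fit, function(n) pathway_ratio(n, p, model, window), numeric(1))
  fit <- stats::lm(n ~ R, data = data.frame(n = n_fit, R = Rn))
  unname(stats::predict(fit, data.frame(R = R)))
}

#' Invert a measured ratio to fractional gluconeogenesis
#'
#' Solves mixture_ratio(f, p) = R for the fraction of glucose produced
#' through gluconeogenesis. Because excess enrichments are linear in the
#' mixture weight, the inversion is exact (a ratio of linear forms solved in
#' closed form); it agrees with monotone root bracketing to well below 1e-6
#' and with the tabular lookup method ([tabular_fgng()]) to the table's
#' interpolation error.
#'
#' Measured ratios a little outside the model range `[R(f=0), R(f=1)]` (from
#' replicate noise near the boundaries) are clamped to `[0, 1]` and flagged
#' when within `slack`; beyond the slack the result is flagged
#' `out_of_model`. Use `clamp = FALSE` to obtain the raw unclamped solution
#' (as the sensitivity simulations do).
#'
#' @param R Measured excess ratio EM2/EM1.
#' @inheritParams mixture_ratio
#' @param slack Tolerance, in R units, for clamping just-out-of-range ratios
#'   (use about twice the replicate SE of R).
#' @param clamp Clamp the estimate to `[0, 1]`?
#' @param details If `TRUE`, return a list with `f_gng`, `f_raw` and `flags`;
#'   otherwise the (possibly clamped) numeric estimate with flags attached as
#'   an attribute.
#' @return Numeric estimate of f(GNG), or a list when `details = TRUE`.
#' @examples
#' m <- mida_model()
#' invert_fgng(mixture_ratio(0.37, 0.045, m), 0.045, m)  # 0.37
#' @export
invert_fgng <- function(R, p, model = mida_model(), n_gng = NULL, n_ggl = NULL,
                        window = NULL, slack = 0.002, clamp = TRUE,
                        details = FALSE) {
  model <- .as_model(model)
  if (is.null(window)) window <- model$window
  if (is.null(n_gng)) n_gng <- model$n_pathways[["total_gng"]]
  if (is.null(n_ggl)) n_ggl <- model$n_pathways[["ggl"]]
  co <- .mixture_coefs(p, model, n_gng, n_ggl, window)
  f_raw <- (R * co$c1 - co$c2) / (co$d2 - R * co$d1)
  r0 <- co$c2 / co$c1
  r1 <- (co$c2 + co$d2) / (co$c1 + co$d1)
  flags <- character(0)
  if (R < r0 - slack || R > r1 + slack) flags <- c(flags, "out_of_model")
  else if (R < r0 || R > r1) flags <- c(flags, "clamped")
  f <- if (clamp) min(max(f_raw, 0), 1) else f_raw
  if (details) return(list(f_gng = f, f_raw = f_raw, flags = flags,
                           R_range = c(r0, r1)))
  if (length(flags)) attr(f, "flags") <- flags
  f
}

# closed-form inversion of the PEPCK/glycerol subpathway mixture
.invert_subpathway <- function(R, p, model, window = model$window,
                               slack = 0.002, clamp = TRUE) {
  co <- .mixture_coefs(p, model, model$n_pathways[["pepck_gng"]],
                       model$n_pathways[["glycerol_gng"]], window)
  f_raw <- (R * co$c1 - co$c2) / (co$d2 - R * co$d1)
  r0 <- co$c2 / co$c1
  r1 <- (co$c2 + co$d2) / (co$c1 + co$d1)
  flags <- character(0)
  if (R < r0 - slack || R > r1 + slack) flags <- c(flags, "out_of_model")
  else if (R < r0 || R > r1) flags <- c(flags, "clamped")
  list(f_pepck = if (clamp) min(max(f_raw, 0), 1) else f_raw,
       f_raw = f_raw, flags = flags, R_range = c(r0, r1))
}

#' EM2/EM1 lookup table over p and f(GNG)
#'
#' Tabulates the mixture ratio over a grid of body-water enrichments (rows)
#' and gluconeogenesis fractions (columns), mirroring the published
#' reference-table layout: p from 0.5% to 8% in 0.5% steps, f(GNG) from 0 to
#' 100% in 10% steps. The f = 0 column is constant down the rows (the
#' p-independent baseline ratio); every row is strictly increasing.
#'
#' @param p_grid Enrichments (fractions) for the rows.
#' @param f_grid Gluconeogenesis fractions for the columns.
#' @param model A [mida_model()].
#' @param long If `TRUE` return a long-format data frame `(p, f_gng, R)`
#'   instead of the wide matrix-style data frame.
#' @return A data frame; wide format has a `p_percent` column followed by one
#'   column per f(GNG) percentage.
#' @examples
#' tab <- mida_table(model = mida_model(calibrate = TRUE))
#' tab[tab$p_percent == 4, "f50"]  # about 0.279
#' @export
mida_table <- function(p_grid = seq(0.005, 0.08, by = 0.005),
                       f_grid = seq(0, 1, by = 0.1),
                       model = mida_model(), long = FALSE) {
  model <- .as_model(model)
  vals <- outer(p_grid, f_grid,
                Vectorize(function(p, f) mixture_ratio(f, p, model)))
  if (long) {
    out <- data.frame(p = rep(p_grid, times = length(f_grid)),
                      f_gng = rep(f_grid, each = length(p_grid)),
                      R = as.vector(vals))
    return(out)
  }
  out <- data.frame(p_percent = p_grid * 100, vals)
  names(out)[-1] <- paste0("f", round(f_grid * 100))
  out
}

#' Write a lookup table as delimited text
#'
#' @param table A wide-format table from [mida_table()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_mida_table <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Tabular inversion of a measured ratio (lookup-table method)
#'
#' The bench workflow locates a measured EM2/EM1 in the reference table at
#' the measured p: within each of the two bracketing p rows (on the 0.5%
#' grid) the f value is interpolated from the tabulated R values, and the
#' arithmetic mean of the two row results is taken — accurate in the small
#' windows between the tabulated enrichments. Programmatic analyses should
#' prefer [invert_fgng()], which recomputes at the exact p; the two agree to
#' about 0.01 in f.
#'
#' @param R Measured excess ratio.
#' @param p Measured body-water enrichment (fraction).
#' @param table Long-format lookup table ([mida_table()] with `long = TRUE`);
#'   built from the default grid when omitted.
#' @param model Model used to build the default table.
#' @return Estimated f(GNG) in `[0, 1]` (clamped at the table edges).
#' @examples
#' m <- mida_model()
#' tabular_fgng(mixture_ratio(0.5, 0.042, m), 0.042, model = m)
#' @export
tabular_fgng <- function(R, p, table = NULL, model = mida_model()) {
  if (is.null(table))
    table <- mida_table(f_grid = seq(0, 1, by = 0.02), model = model,
                        long = TRUE)
  ps <- sort(unique(table$p))
  if (p < min(ps) || p > max(ps))
    stop("p = ", p, " outside the tabulated range [", min(ps), ", ",
         max(ps), "]", call. = FALSE)
  below <- max(ps[ps <= p]); above <- min(ps[ps >= p])
  row_invert <- function(prow) {
    sub <- table[table$p == prow, ]
    sub <- sub[order(sub$f_gng), ]
    if (R <= min(sub$R)) return(sub$f_gng[which.min(sub$R)])
    if (R >= max(sub$R)) return(sub$f_gng[which.max(sub$R)])
    stats::approx(sub$R, sub$f_gng, xout = R, ties = "ordered")$y
  }
  mean(c(row_invert(below), row_invert(above)))
}
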