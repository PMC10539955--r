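#' Baseline specification for enrichment calculations
#'
#' The enrichments are measured against the unlabeled baseline. By default
#' the theoretical natural-abundance pattern of the fragment is used. Because
#' the measured isotopomer fractions depend on the amount of analyte ionized
#' (the concentration effect), a bench workflow injects unlabeled standards
#' at matched concentration; supplying those spectra switches the baseline to
#' the empirical mean of their fractional abundances, which takes precedence
#' over the theoretical pattern.
#'
#' @param mode `"theoretical"` or `"empirical"`.
#' @param standards For the empirical mode, a data frame of unlabeled
#'   standard spectra with columns `m360`, `m361`, `m362` (or a numeric
#'   matrix with three columns of raw areas).
#' @return Object of class `baseline_spec`.
#' @examples
#' baseline_spec()
#' baseline_spec("empirical",
#'               data.frame(m360 = c(1e6, 2e6), m361 = c(178e3, 356e3),
#'                          m362 = c(28e3, 56e3)))
#' @export
baseline_spec <- function(mode = c("theoretical", "empirical"),
                          standards = NULL) {
  mode <- match.arg(mode)
  if (!is.null(standards) && missing(mode)) mode <- "empirical"
  fracs <- NULL
  if (mode == "empirical") {
    if (is.null(standards))
      stop("empirical baseline needs unlabeled standard spectra", call. = FALSE)
    m <- .spectra_matrix(standards)
    fr <- m / rowSums(m)
    fracs <- colMeans(fr)
    if (abs(sum(fracs) - 1) > 1e-9)
      stop("empirical baseline fractions must sum to 1 over the window",
           call. = FALSE)
  }
  structure(list(mode = mode, fracs = fracs), class = "baseline_spec")
}

.spectra_matrix <- function(x) {
  if (is.matrix(x)) {
    stopifnot(ncol(x) == 3)
    m <- x
  } else {
    cols <- intersect(c("m360", "m361", "m362"), names(x))
    if (length(cols) < 3) {
      miss <- setdiff(c("m360", "m361", "m362"), names(x))
      stop("spectra are missing column(s): ", paste(miss, collapse = ", "),
           call. = FALSE)
    }
    m <- as.matrix(x[, c("m360", "m361", "m362")])
  }
  if (any(m < 0) || any(m[, 1] <= 0))
    stop("ion abundances must be non-negative with M+0 > 0", call. = FALSE)
  m
}

# baseline fractions over the three-ion window for a given spec + model
.baseline_fracs <- function(baseline, model) {
  if (is.null(baseline)) baseline <- baseline_spec()
  if (baseline$mode == "empirical") baseline$fracs
  else .window_fracs(model$baseline, "three_ion")
}

#' Enrichments of measured three-ion spectra
#'
#' Converts raw integrated ion abundances at the monitored M+0..M+2 masses
#' into excess mass-isotopomer enrichments: abundances are normalized over
#' the three-ion window and the baseline fractions subtracted. Scaling all
#' three areas by a common factor leaves the enrichments unchanged, so
#' arbitrary area units are fine. With replicates, per-replicate values plus
#' the mean, SE and CV of each EM and of R are reported (R is computed per
#' replicate and then averaged).
#'
#' @param spectra Data frame with columns `m360`, `m361`, `m362` and
#'   optionally `sample_id`, `replicate`; or a numeric vector of three areas.
#' @param baseline A [baseline_spec()] (default: theoretical).
#' @param model A [mida_model()].
#' @param em1_floor EM1 at or below this floor flags R unreliable.
#' @return For a single spectrum, an `excess_enrichments` object. For a
#'   replicate set, a list with `replicates` (per-replicate data frame) and
#'   `summary` (mean/SE/CV of EM1, EM2, R).
#' @examples
#' m <- mida_model()
#' truth <- labeled_pattern(6, 0.0125, m)[1:3] * 1e6
#' spectrum_to_enrichments(truth, model = m)
#' @export
spectrum_to_enrichments <- function(spectra, baseline = baseline_spec(),
                                    model = mida_model(), em1_floor = 0) {
  model <- .as_model(model)
  bf <- .baseline_fracs(baseline, model)
  one <- function(areas) {
    fr <- areas / sum(areas)
    em <- fr - bf
    flags <- character(0)
    R <- NA_real_
    if (em[2] <= em1_floor) flags <- "low_EM1" else R <- em[3] / em[2]
    structure(list(EM = em, EM1 = em[2], EM2 = em[3], R = R, flags = flags),
              class = "excess_enrichments")
  }
  if (is.numeric(spectra) && is.null(dim(spectra))) {
    stopifnot(length(spectra) == 3)
    return(one(spectra))
  }
  m <- .spectra_matrix(spectra)
  if (nrow(m) == 1L) return(one(m[1, ]))
  reps <- do.call(rbind, lapply(seq_len(nrow(m)), function(i) {
    e <- one(m[i, ])
    data.frame(replicate = i, EM1 = e$EM1, EM2 = e$EM2, R = e$R)
  }))
  sumfun <- function(x) {
    x <- x[is.finite(x)]
    c(mean = mean(x), se = stats::sd(x) / sqrt(length(x)),
      cv = stats::sd(x) / abs(mean(x)))
  }
  list(replicates = reps,
       summary = rbind(EM1 = sumfun(reps$EM1), EM2 = sumfun(reps$EM2),
                       R = sumfun(reps$R)))
}

#' Estimate fractional gluconeogenesis from a measured spectrum
#'
#' Composes [spectrum_to_enrichments()] with [invert_fgng()]: the measured
#' three-ion abundances give R = EM2/EM1, which is located on the mixture
#' model at the measured body-water enrichment. Both the exact (root-found)
#' and the lookup-table estimates are reported, along with the equivalent
#' homogeneous site count of the measured ratio.
#'
#' @param spectra Data frame or 3-vector as in [spectrum_to_enrichments()];
#'   multiple rows are treated as technical replicates of one sample.
#' @param p Body-water deuterium enrichment (fraction, in `(0, 0.08]`).
#' @param baseline A [baseline_spec()].
#' @param model A [mida_model()].
#' @param slack Out-of-range clamping tolerance in R units; when replicates
#'   are available, twice the replicate SE of R is used if larger.
#' @return A one-row data frame: `p`, `EM1`, `EM2`, `R`, `R_se`, `f_gng`,
#'   `f_gng_tabular`, `f_se`, `n_equiv`, `flags`.
#' @examples
#' m <- mida_model()
#' areas <- labeled_pattern(6, 0.045, m)[1:3] * 5e5
#' estimate_fgng(areas, p = 0.045, model = m)
#' @export
estimate_fgng <- function(spectra, p, baseline = baseline_spec(),
                          model = mida_model(), slack = 0.002) {
  model <- .as_model(model)
  if (p <= 0 || p > 0.08)
    stop("body-water enrichment p must lie in (0, 0.08], got ", p,
         call. = FALSE)
  enr <- spectrum_to_enrichments(spectra, baseline, model)
  if (inherits(enr, "excess_enrichments")) {
    R <- enr$R; R_se <- NA_real_; flags <- enr$flags
    EM1 <- enr$EM1; EM2 <- enr$EM2; f_se <- NA_real_
    f_reps <- NULL
  } else {
    R <- mean(enr$replicates$R, na.rm = TRUE)
    R_se <- enr$summary["R", "se"]
    EM1 <- enr$summary["EM1", "mean"]; EM2 <- enr$summary["EM2", "mean"]
    flags <- if (any(is.na(enr$replicates$R))) "low_EM1" else character(0)
    slack <- max(slack, 2 * R_se, na.rm = TRUE)
    f_reps <- vapply(enr$replicates$R, function(r) {
      if (is.na(r)) return(NA_real_)
      invert_fgng(r, p, model, slack = Inf)
    }, numeric(1))
    f_se <- stats::sd(f_reps, na.rm = TRUE) /
      sqrt(sum(is.finite(f_reps)))
  }
  if (is.na(R)) {
    return(data.frame(p = p, EM1 = EM1, EM2 = EM2, R = NA_real_,
                      R_se = R_se, f_gng = NA_real_,
                      f_gng_tabular = NA_real_, f_se = f_se,
                      n_equiv = NA_real_, flags = paste(flags, collapse = ";"),
                      stringsAsFactors = FALSE))
  }
  inv <- invert_fgng(R, p, model, slack = slack, details = TRUE)
  flags <- c(flags, inv$flags)
  f_tab <- tabular_fgng(R, p, model = model)
  n_eq <- tryCatch(equivalent_n(R, p, model), error = function(e) NA_real_)
  data.frame(p = p, EM1 = EM1, EM2 = EM2, R = R, R_se = R_se,
             f_gng = inv$f_gng, f_gng_tabular = f_tab, f_se = f_se,
             n_equiv = n_eq, flags = paste(flags, collapse = ";"),
             stringsAsFactors = FALSE)
}

#' Split fasted-state gluconeogenesis into PEPCK vs glycerol arms
#'
#' In the fasted state essentially all glucose production is gluconeogenic
#' (f(GNG) above 95%), so the measured ratio reflects the mixture of the two
#' GNG arms alone and can be inverted for the PEPCK share of the
#' triose-phosphate pool; the glycerol share is its complement. Any residual
#' glycogen contribution (below about 5%) is ignored and flagged as an
#' assumption of the analysis.
#'
#' @inheritParams estimate_fgng
#' @return One-row data frame with `R`, `f_pepck`, `f_glycerol`, `flags`.
#' @examples
#' m <- mida_model()
#' gng <- 0.7 * labeled_pattern(7, 0.045, m) + 0.3 * labeled_pattern(2, 0.045, m)
#' estimate_subpathways_fasted(gng[1:3] * 1e6, p = 0.045, model = m)
#' @export
estimate_subpathways_fasted <- function(spectra, p, baseline = baseline_spec(),
                                        model = mida_model(), slack = 0.002) {
  model <- .as_model(model)
  enr <- spectrum_to_enrichments(spectra, baseline, model)
  if (inherits(enr, "excess_enrichments")) {
    R <- enr$R; flags <- enr$flags
  } else {
    R <- mean(enr$replicates$R, na.rm = TRUE)
    flags <- character(0)
    slack <- max(slack, 2 * enr$summary["R", "se"], na.rm = TRUE)
  }
  if (is.na(R))
    return(data.frame(R = NA_real_, f_pepck = NA_real_, f_glycerol = NA_real_,
                      flags = paste(flags, collapse = ";")))
  inv <- .invert_subpathway(R, p, model, slack = slack)
  flags <- c(flags, inv$flags, "assumes_fgng_near_1")
  data.frame(R = R, f_pepck = inv$f_pepck, f_glycerol = 1 - inv$f_pepck,
             flags = paste(flags, collapse = ";"), stringsAsFactors = FALSE)
}

#' Triose-phosphate precursor enrichment from a 2-13C-glycerol experiment
#'
#' Glucose is a condensation product of two triose subunits, so in a
#' labeled-glycerol experiment it behaves as a two-subunit polymer: each
#' subunit carries one carbon-13 with probability q, the enrichment of the
#' triose-phosphate precursor pool. q is solved from the measured EM2/EM1
#' through the same convolution machinery (two label sites at enrichment q).
#' Comparing q with the plasma glycerol enrichment gives the fraction of
#' the triose-phosphate pool derived from plasma glycerol, and multiplying
#' by f(GNG) gives the glycerol contribution to endogenous glucose
#' production.
#'
#' @inheritParams estimate_fgng
#' @param plasma_glycerol_enrichment Measured carbon-13 enrichment of plasma
#'   glycerol (fraction in `(0, 1)`).
#' @param f_gng Fractional gluconeogenesis of the same condition (from the
#'   heavy-water arm of the study).
#' @return One-row data frame with `q` (triose-phosphate pool enrichment),
#'   `f_glycerol_to_tp = q / plasma_glycerol_enrichment`, `egp_contribution =
#'   f_glycerol_to_tp * f_gng`, and `flags` (flagged when q exceeds the
#'   plasma enrichment, which violates the precursor-product model).
#' @examples
#' m <- mida_model()
#' pat <- convolve_patterns(m$baseline, label_site_distribution(2, 0.10), 6)
#' triose_precursor_13c(pat[1:3] * 1e6, plasma_glycerol_enrichment = 0.3,
#'                      f_gng = 0.69, model = m)
#' @export
triose_precursor_13c <- function(spectra, baseline = baseline_spec(),
                                 plasma_glycerol_enrichment, f_gng,
                                 model = mida_model()) {
  model <- .as_model(model)
  stopifnot(plasma_glycerol_enrichment > 0, plasma_glycerol_enrichment < 1)
  enr <- spectrum_to_enrichments(spectra, baseline, model)
  R <- if (inherits(enr, "excess_enrichments")) enr$R
       else mean(enr$replicates$R, na.rm = TRUE)
  flags <- character(0)
  if (is.na(R))
    return(data.frame(q = NA_real_, f_glycerol_to_tp = NA_real_,
                      egp_contribution = NA_real_, flags = "low_EM1"))
  ratio_q <- function(q)
    .excess_ratio(convolve_patterns(model$baseline,
                                    label_site_distribution(2, q, model$max_shift),
                                    model$max_shift),
                  model$baseline, model$window)
  r0 <- .excess_ratio(convolve_patterns(model$baseline, c(0.999, 0.001),
                                        model$max_shift),
                      model$baseline, model$window)
  if (R <= r0) q <- 0
  else q <- stats::uniroot(function(q) ratio_q(q) - R, c(1e-8, 0.5),
                           tol = 1e-10)$root
  if (q > plasma_glycerol_enrichment)
    flags <- c(flags, "q_exceeds_plasma_enrichment")
  f_tp <- q / plasma_glycerol_enrichment
  data.frame(q = q, f_glycerol_to_tp = f_tp,
             egp_contribution = f_tp * f_gng,
             flags = paste(flags, collapse = ";"), stringsAsFactors = FALSE)
}

#' Body-water enrichment by the acetone exchange method
#'
#' Body water is assayed by base-catalyzed exchange into acetone and GC-MS
#' of the m/z 57..59 ions. A standard curve of fractional M+1 abundance
#' against known water enrichment is fitted by ordinary least squares and
#' inverted at the sample's response. Curves whose residual badness of fit
#' (1 - R squared) exceeds `max_rsq_deficit` are rejected unless overridden;
#' sample responses outside the calibrated range are flagged as
#' extrapolation.
#'
#' @param curve Data frame with columns `p_known` (water enrichment,
#'   fraction) and `m1_fraction` (acetone M+1 fractional abundance); at least
#'   3 points.
#' @param m1_fraction Sample response(s): fractional M+1 abundance, i.e.
#'   `m58 / (m57 + m58 + m59)`.
#' @param max_rsq_deficit Maximum tolerated 1 - R squared (default 0.003).
#' @param override Proceed despite a poor curve fit?
#' @return Data frame with `p`, `rsq_deficit` and `flags` for each sample
#'   response.
#' @examples
#' curve <- data.frame(p_known = c(0, 0.01, 0.02, 0.04),
#'                     m1_fraction = 0.05 + 1.8 * c(0, 0.01, 0.02, 0.04))
#' body_water_enrichment(curve, 0.05 + 1.8 * 0.025)
#' @export
body_water_enrichment <- function(curve, m1_fraction,
                                  max_rsq_deficit = 0.003, override = FALSE) {
  stopifnot(all(c("p_known", "m1_fraction") %in% names(curve)))
  if (nrow(curve) < 3)
    stop("standard curve needs at least 3 points", call. = FALSE)
  if (any(curve$p_known < 0 | curve$p_known > 0.3))
    stop("standard-curve enrichments must lie in [0, 0.3]", call. = FALSE)
  fit <- stats::lm(m1_fraction ~ p_known, data = curve)
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum((curve$m1_fraction - mean(curve$m1_fraction))^2)
  deficit <- ss_res / ss_tot
  if (deficit > max_rsq_deficit && !override)
    stop(sprintf(
      "standard curve rejected: 1 - R^2 = %.4g exceeds the quality bound %.4g (set override = TRUE to force)",
      deficit, max_rsq_deficit), call. = FALSE)
  b <- stats::coef(fit)
  p_hat <- (m1_fraction - b[[1]]) / b[[2]]
  flags <- vapply(m1_fraction, function(y) {
    fl <- character(0)
    if (y < min(curve$m1_fraction) || y > max(curve$m1_fraction))
      fl <- c(fl, "extrapolated")
    if (deficit > max_rsq_deficit) fl <- c(fl, "poor_curve_fit")
    paste(fl, collapse = ";")
  }, character(1))
  data.frame(p = p_hat, rsq_deficit = deficit, flags = flags,
             stringsAsFactors = FALSE)
}
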