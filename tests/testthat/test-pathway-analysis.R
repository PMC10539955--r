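mcal <- mida_model(calibrate = TRUE)

test_that("spectrum enrichments are scale-invariant and vanish at baseline", {
  m <- mcal
  bf <- labeled_pattern(0, 0.01, m)[1:3]  # the baseline itself
  e0 <- spectrum_to_enrichments(bf * 7.3e5, model = m)
  expect_equal(e0$EM1, 0, tolerance = 1e-12)
  expect_equal(e0$EM2, 0, tolerance = 1e-12)
  expect_true("low_EM1" %in% e0$flags)
  a <- labeled_pattern(6, 0.0125, m)[1:3] * 1e6
  e1 <- spectrum_to_enrichments(a, model = m)
  e2 <- spectrum_to_enrichments(a * 0.0037, model = m)
  expect_equal(e1$EM, e2$EM, tolerance = 1e-12)
})

test_that("noise-free synthetic spectra reproduce the generator's ratio", {
  m <- mcal
  pat <- labeled_pattern(6, 0.0125, m)
  want <- excess_enrichments(pat, m)$R
  got <- spectrum_to_enrichments(pat[1:3] * 2e6, model = m)$R
  expect_equal(got, want, tolerance = 1e-9)
})

test_that("f(GNG) is recovered noise-free across the parameter grid", {
  m <- mcal
  for (p in c(0.01, 0.045)) for (f in seq(0.1, 0.9, by = 0.2)) {
    d <- simulate_spectra(p = p, f_gng = f, ion_cv = 0, model = m)
    est <- estimate_fgng(d, p = p, model = m)
    expect_equal(est$f_gng, f, tolerance = 1e-4)
  }
  # the fasted condition: nearly pure gluconeogenesis
  d <- simulate_spectra(p = 0.045, f_gng = 0.983, ion_cv = 0, model = m)
  expect_equal(estimate_fgng(d, p = 0.045, model = m)$f_gng, 0.983,
               tolerance = 1e-4)
  # pure glycogenolysis
  d0 <- simulate_spectra(p = 0.03, f_gng = 0, ion_cv = 0, model = m)
  expect_equal(estimate_fgng(d0, p = 0.03, model = m)$f_gng, 0,
               tolerance = 1e-6)
})

test_that("estimates are immune to dilution with unlabeled glucose", {
  m <- mcal
  base <- simulate_spectra(p = 0.045, f_gng = 0.6, ion_cv = 0, model = m)
  dil <- simulate_spectra(p = 0.045, f_gng = 0.6, dilution = 0.8,
                          ion_cv = 0, model = m)
  R0 <- spectrum_to_enrichments(base, model = m)$R
  R1 <- spectrum_to_enrichments(dil, model = m)$R
  expect_equal(R0, R1, tolerance = 1e-9)
  expect_equal(estimate_fgng(dil, p = 0.045, model = m)$f_gng, 0.6,
               tolerance = 1e-6)
})

test_that("fasted-state subpathway split round-trips and hits the endpoints", {
  m <- mcal
  p <- 0.045
  d <- simulate_spectra(p = p, f_gng = 1, f_pepck_within_gng = 0.70,
                        ion_cv = 0, model = m)
  est <- estimate_subpathways_fasted(d, p = p, model = m)
  expect_equal(est$f_pepck, 0.70, tolerance = 1e-6)
  expect_equal(est$f_glycerol, 0.30, tolerance = 1e-6)
  expect_match(est$flags, "assumes_fgng_near_1")
  # ratio exactly at a pure arm maps to 0 or 1
  for (fp in c(0, 1)) {
    d <- simulate_spectra(p = p, f_gng = 1, f_pepck_within_gng = fp,
                          ion_cv = 0, model = m)
    expect_equal(estimate_subpathways_fasted(d, p = p, model = m)$f_pepck,
                 fp, tolerance = 1e-6)
  }
})

test_that("the 13C-glycerol condensation analysis recovers q and composes", {
  m <- mcal
  d <- simulate_spectra(tracer = "glycerol13c", q = 0.10, ion_cv = 0,
                        model = m)
  res <- triose_precursor_13c(d, plasma_glycerol_enrichment = 0.3,
                              f_gng = 0.9, model = m)
  expect_equal(res$q, 0.10, tolerance = 1e-6)
  # arithmetic contract of the composition
  d2 <- simulate_spectra(tracer = "glycerol13c", q = 0.05, ion_cv = 0,
                         model = m)
  res2 <- triose_precursor_13c(d2, plasma_glycerol_enrichment = 0.15,
                               f_gng = 0.69, model = m)
  expect_equal(res2$f_glycerol_to_tp, 1/3, tolerance = 1e-5)
  expect_equal(res2$egp_contribution, 0.23, tolerance = 1e-4)
  # q above the plasma enrichment violates the precursor-product model
  d3 <- simulate_spectra(tracer = "glycerol13c", q = 0.2, ion_cv = 0,
                         model = m)
  res3 <- triose_precursor_13c(d3, plasma_glycerol_enrichment = 0.1,
                               f_gng = 0.5, model = m)
  expect_match(res3$flags, "q_exceeds_plasma_enrichment")
})

test_that("as q shrinks the glycerol-tracer ratio approaches the baseline ratio", {
  m <- mcal
  A <- m$baseline
  target <- oracle_excess_ratio(
    convolve_patterns(A, c(1 - 1e-6, 1e-6), 6L), A)
  qs <- c(0.05, 0.01, 0.002)
  rs <- vapply(qs, function(q) {
    pat <- convolve_patterns(A, label_site_distribution(2, q), 6L)
    excess_enrichments(pat, m)$R
  }, numeric(1))
  expect_true(all(diff(abs(rs - target)) < 0))
  expect_equal(rs[3], target, tolerance = 0.01)
})

test_that("body-water enrichment recovers exact linear standard curves", {
  curve <- data.frame(p_known = c(0, 0.005, 0.01, 0.02, 0.04),
                      m1_fraction = 0.048 + 1.75 * c(0, 0.005, 0.01, 0.02, 0.04))
  res <- body_water_enrichment(curve, 0.048 + 1.75 * 0.0125)
  expect_equal(res$p, 0.0125, tolerance = 1e-12)
  # a sample response equal to a curve point returns that point's p
  res2 <- body_water_enrichment(curve, curve$m1_fraction[3])
  expect_equal(res2$p, 0.01, tolerance = 1e-12)
  expect_equal(res2$flags, "")
  # extrapolation beyond the curve is flagged
  res3 <- body_water_enrichment(curve, 0.048 + 1.75 * 0.06)
  expect_match(res3$flags, "extrapolated")
})

test_that("poor standard curves are rejected by the quality bound", {
  set.seed(3)
  p <- c(0, 0.01, 0.02, 0.03, 0.04)
  y <- 0.05 + 1.8 * p
  noisy <- y + rnorm(5, 0, 0.08 * diff(range(y)))
  curve <- data.frame(p_known = p, m1_fraction = noisy)
  # this noise realization has 1 - R^2 of about 0.0136, above the bound
  expect_error(body_water_enrichment(curve, y[2]), "quality bound")
  res <- body_water_enrichment(curve, y[2], override = TRUE)
  expect_match(res$flags, "poor_curve_fit")
})

test_that("empirical baselines take precedence and absorb a concentration offset", {
  m <- mcal
  # instrument baseline shifted away from theory (the concentration effect)
  shift <- c(-0.002, 0.0015, 0.0005)
  bfrac <- m$baseline[1:3] / sum(m$baseline[1:3]) + shift
  standards <- data.frame(m360 = bfrac[1] * c(1e6, 2e6),
                          m361 = bfrac[2] * c(1e6, 2e6),
                          m362 = bfrac[3] * c(1e6, 2e6))
  bl <- baseline_spec("empirical", standards)
  # a sample proportional to the shifted baseline reads as unlabeled
  e <- spectrum_to_enrichments(bfrac * 3e6, baseline = bl, model = m)
  expect_lt(abs(e$EM1), 1e-12)
  expect_true("low_EM1" %in% e$flags)
})

test_that("replicate aggregation reports per-replicate ratios and their spread", {
  m <- mcal
  d <- simulate_spectra(p = 0.045, f_gng = 0.5, n_replicates = 8,
                        ion_cv = 0.0009, seed = 11, model = m)
  enr <- spectrum_to_enrichments(d, model = m)
  expect_equal(nrow(enr$replicates), 8)
  expect_equal(enr$summary["R", "mean"], mean(enr$replicates$R))
  est <- estimate_fgng(d, p = 0.045, model = m)
  expect_true(is.finite(est$f_se))
  expect_equal(est$f_gng, 0.5, tolerance = 0.05)
})

test_that("replicate SE of the estimate shrinks as enrichment rises", {
  m <- mcal
  se_at <- function(p, seed) {
    ses <- vapply(1:12, function(i) {
      d <- simulate_spectra(p = p, f_gng = 0.5, n_replicates = 10,
                            ion_cv = 0.0009, seed = seed + i, model = m)
      estimate_fgng(d, p = p, model = m)$f_se
    }, numeric(1))
    mean(ses)
  }
  expect_gt(se_at(0.0125, 100), se_at(0.045, 200))
  expect_gt(se_at(0.045, 200), se_at(0.08, 300))
})
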