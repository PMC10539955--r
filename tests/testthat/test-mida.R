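model_cal <- mida_model(calibrate = TRUE)

test_that("label-site distribution is the site binomial", {
  expect_equal(label_site_distribution(4, 0), c(1, rep(0, 6)))
  expect_equal(label_site_distribution(2, 0.5)[1:3], c(0.25, 0.5, 0.25))
  expect_equal(label_site_distribution(6, 0.08)[2], 6 * 0.08 * 0.92^5,
               tolerance = 1e-14)
  expect_equal(sum(label_site_distribution(6, 0.3)), 1, tolerance = 1e-12)
  expect_error(label_site_distribution(2, 0.7), "0, 0.5")
  expect_error(label_site_distribution(12, 0.1), "0, 10")
})

test_that("labeled patterns match joint exhaustive enumeration", {
  it <- isotope_table()
  for (case in list(list(f = c(C = 2L, O = 1L), n = 2, p = 0.08),
                    list(f = c(C = 3L), n = 3, p = 0.2),
                    list(f = c(C = 1L, H = 2L, O = 1L), n = 1, p = 0.005))) {
    m <- mida_model(formula = case$f, isotopes = it)
    got <- labeled_pattern(case$n, case$p, m)
    want <- enum_labeled_pattern(case$f, case$n, case$p, it, 6L)
    expect_equal(got, want, tolerance = 1e-13)
  }
})

test_that("one-site labeling gives the p-independent baseline ratio", {
  m <- model_cal
  ps <- c(0.005, 0.01, 0.04, 0.08)
  r3 <- vapply(ps, function(p) pathway_ratio(1, p, m, window = "three_ion"),
               numeric(1))
  rf <- vapply(ps, function(p) pathway_ratio(1, p, m, window = "full"),
               numeric(1))
  expect_lt(max(rf) - min(rf), 1e-9)   # exact under full normalization
  expect_lt(max(r3) - min(r3), 1e-3)   # near-exact over the monitored window
  # and equals the analytic (A1 - A2)/(A0 - A1) up to the truncation tail
  A <- m$baseline
  expect_equal(rf[1], (A[2] - A[3]) / (A[1] - A[2]), tolerance = 1e-6)
})

test_that("pure-pathway and mixture ratios reproduce reference cells", {
  m <- model_cal
  expect_equal(pathway_ratio(6, 0.015, m), 0.219303, tolerance = 0.02)
  expect_equal(mixture_ratio(0, 0.005, m), 0.173155, tolerance = 0.001)
  expect_equal(mixture_ratio(1, 0.08, m), 0.445287, tolerance = 0.02)
  expect_equal(mixture_ratio(0.5, 0.04, m), 0.279059, tolerance = 0.02)
})

test_that("excess enrichments are linear in the mixture weight", {
  m <- model_cal
  p <- 0.045
  a <- labeled_pattern(6, p, m); b <- labeled_pattern(1, p, m)
  for (f in c(0.1, 0.5, 0.9)) {
    mix <- f * a + (1 - f) * b
    em_mix <- mix - m$baseline
    em_lin <- f * (a - m$baseline) + (1 - f) * (b - m$baseline)
    expect_equal(em_mix, em_lin, tolerance = 1e-12)
  }
})

test_that("mixture ratio is strictly increasing in f and bounded by the pure pathways", {
  m <- model_cal
  for (p in c(0.0125, 0.045, 0.08)) {
    fs <- seq(0, 1, by = 0.05)
    rs <- vapply(fs, mixture_ratio, numeric(1), p = p, model = m)
    expect_true(all(diff(rs) > 0))
    expect_equal(rs[1], pathway_ratio(1, p, m), tolerance = 1e-12)
    expect_equal(rs[length(rs)], pathway_ratio(6, p, m), tolerance = 1e-12)
  }
})

test_that("subpathway mixture interpolates n=2..n=7 with enrichment weighting", {
  m <- model_cal
  p <- 0.05
  r2 <- pathway_ratio(2, p, m); r7 <- pathway_ratio(7, p, m)
  expect_equal(subpathway_mixture_ratio(0, p, m), r2, tolerance = 1e-12)
  expect_equal(subpathway_mixture_ratio(1, p, m), r7, tolerance = 1e-12)
  rmix <- subpathway_mixture_ratio(2/3, p, m)
  expect_gt(rmix, r2); expect_lt(rmix, r7)
  # the higher-n population dominates the enrichments, so the mixture sits
  # closer to r7 than the naive 2/3 weighting of the ratios themselves
  expect_gt(rmix, 2/3 * r7 + 1/3 * r2)
})

test_that("equivalent n round-trips integers and is monotone in R", {
  m <- model_cal
  for (p in c(0.045, 0.08)) {
    for (n in 2:7)
      expect_equal(equivalent_n(pathway_ratio(n, p, m), p, m), n,
                   tolerance = 0.05)
    rs <- seq(pathway_ratio(1.2, p, m), pathway_ratio(7.8, p, m),
              length.out = 25)
    ns <- vapply(rs, equivalent_n, numeric(1), p = p, model = m)
    expect_true(all(diff(ns) > 0))
    # the exact continuous-n solve agrees with the line to the fit residual
    expect_equal(equivalent_n(pathway_ratio(4.5, p, m), p, m, "exact"), 4.5,
                 tolerance = 1e-6)
  }
  expect_error(equivalent_n(10, 0.045, m), "outside the calibration range")
})

test_that("inversion round-trips f over the full grid", {
  m <- model_cal
  for (p in c(0.005, 0.0125, 0.045, 0.08)) {
    for (f in seq(0, 1, by = 0.1)) {
      R <- mixture_ratio(f, p, m)
      expect_equal(invert_fgng(R, p, m), f, tolerance = 1e-6)
    }
  }
})

test_that("closed-form inversion agrees with monotone root bracketing", {
  m <- model_cal
  for (p in c(0.0125, 0.045)) for (f in c(0.13, 0.5, 0.87)) {
    R <- mixture_ratio(f, p, m)
    f_root <- uniroot(function(x) mixture_ratio(x, p, m) - R, c(0, 1),
                      tol = 1e-12)$root
    expect_equal(invert_fgng(R, p, m), f_root, tolerance = 1e-9)
  }
})

test_that("inversion flags and clamps out-of-range ratios", {
  m <- model_cal
  p <- 0.045
  r1 <- mixture_ratio(1, p, m)
  just_out <- invert_fgng(r1 + 5e-4, p, m, slack = 0.002, details = TRUE)
  expect_true("clamped" %in% just_out$flags)
  expect_identical(just_out$f_gng, 1)
  expect_gt(just_out$f_raw, 1)
  far_out <- invert_fgng(r1 + 0.05, p, m, details = TRUE)
  expect_true("out_of_model" %in% far_out$flags)
})

test_that("tabular lookup agrees with exact inversion to 0.01 on the p grid", {
  m <- model_cal
  set.seed(42)
  tab <- mida_table(f_grid = seq(0, 1, by = 0.02), model = m, long = TRUE)
  # on the tabulated 0.5% p grid the only error is the in-row interpolation
  ps <- seq(0.005, 0.08, by = 0.005)
  fs <- runif(length(ps), 0.05, 0.95)
  for (i in seq_along(ps)) {
    R <- mixture_ratio(fs[i], ps[i], m)
    expect_lt(abs(tabular_fgng(R, ps[i], tab, m) - fs[i]), 0.01)
  }
  # between rows the arithmetic mean of the bracketing rows stays serviceable
  # at moderate f; exact recomputation is preferred programmatically
  for (p in c(0.0425, 0.0675)) for (f in c(0.2, 0.5))
    expect_lt(abs(tabular_fgng(mixture_ratio(f, p, m), p, tab, m) - f), 0.025)
})

test_that("the lookup table has the reference layout and structure", {
  m <- model_cal
  tab <- mida_table(model = m)
  expect_equal(dim(tab), c(16, 12))
  expect_equal(tab$p_percent, seq(0.5, 8, by = 0.5))
  # f = 0 column constant down the rows
  expect_lt(diff(range(tab$f0)) / mean(tab$f0), 1e-6)
  # rows strictly increasing left to right
  for (i in seq_len(nrow(tab)))
    expect_true(all(diff(as.numeric(tab[i, -1])) > 0))
  # long format carries the same values
  lng <- mida_table(model = m, long = TRUE)
  expect_equal(lng$R[lng$p == 0.04 & lng$f_gng == 0.5],
               tab[tab$p_percent == 4, "f50"])
})
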