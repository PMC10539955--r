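sim_model <- mida_model(calibrate = TRUE)

test_that("the equivalent-n mixing curve is curvilinear with exact endpoints", {
  nc <- n_equivalence_curve(p = 0.08, f_pepck_grid = seq(0, 1, by = 0.1),
                            model = sim_model)
  expect_equal(nc$n_equiv[nc$f_pepck == 0], 2, tolerance = 0.05)
  expect_equal(nc$n_equiv[nc$f_pepck == 1], 7, tolerance = 0.05)
  expect_true(all(diff(nc$R) > 0))
  expect_true(all(diff(nc$n_equiv) > 0))
  # above the chord joining the endpoints by more than 0.1 somewhere
  chord <- nc$n_equiv[1] +
    (nc$n_equiv[11] - nc$n_equiv[1]) * nc$f_pepck
  expect_gt(max(nc$n_equiv - chord), 0.1)
})

test_that("the two-thirds PEPCK mixture reads as an equivalent n slightly above 6", {
  for (mth in c("line", "exact")) {
    nc <- n_equivalence_curve(p = 0.08, f_pepck_grid = 2/3,
                              model = sim_model, method = mth)
    expect_gt(nc$n_equiv, 6.0)
    expect_lt(nc$n_equiv, 6.35)
  }
  # the equivalent count falls with p: steeper windows compress the scale
  n45 <- n_equivalence_curve(p = 0.045, f_pepck_grid = 2/3, model = sim_model)
  n80 <- n_equivalence_curve(p = 0.08, f_pepck_grid = 2/3, model = sim_model)
  expect_gt(n45$n_equiv, n80$n_equiv)
})

test_that("glycerol-variation error vanishes exactly at the one-third assumption", {
  g <- glycerol_variation_error(f_gng_grid = c(0.2, 0.5, 0.8),
                                g_grid = c(0.25, 1/3, 0.42),
                                p = 0.08, model = sim_model)
  expect_equal(nrow(g), 9)
  expect_true(all(abs(g$delta_pp[abs(g$g_true - 1/3) < 1e-9]) < 1e-9))
  # deterministic
  g2 <- glycerol_variation_error(f_gng_grid = c(0.2, 0.5, 0.8),
                                 g_grid = c(0.25, 1/3, 0.42),
                                 p = 0.08, model = sim_model)
  expect_identical(g, g2)
  # less glycerol -> higher effective n -> overestimate; and vice versa
  expect_true(all(g$delta_pp[g$g_true < 0.3] > 0))
  expect_true(all(g$delta_pp[g$g_true > 0.4] < 0))
  # the error magnitude grows with f(GNG) at the low-glycerol edge
  edge <- g[g$g_true < 0.3, ]
  expect_true(all(diff(edge$delta_pp[order(edge$f_gng_true)]) > 0))
})

test_that("the integer-6 inversion convention carries a residual at one-third", {
  g6 <- glycerol_variation_error(f_gng_grid = c(0.2, 0.8), g_grid = 1/3,
                                 p = 0.08, assumed = "integer_n6",
                                 model = sim_model)
  # the 2/3:1/3 mixture is equivalent to n slightly above 6, so the integer
  # table misreads the mixture even when the glycerol assumption holds
  expect_true(all(abs(g6$delta_pp) > 0.5))
  expect_gt(g6$delta_pp[g6$f_gng_true == 0.8], 0)
})

test_that("the glycerol-variation maximum sits at the f(GNG) = 0.8 corner", {
  g <- glycerol_variation_error(model = sim_model)
  am <- attr(g, "argmax")
  expect_equal(am$f_gng_true, 0.8)
  expect_gt(attr(g, "max_abs_delta"), attr(g, "max_abs_delta_f_le_60"))
})

test_that("transaldolase exchange error is zero at t = 0 and shrinks with f", {
  ta0 <- ta_exchange_error(f_gng_grid = c(0, 0.3, 0.7, 1), t = 0,
                           p = 0.08, model = sim_model)
  expect_true(all(abs(ta0$delta_pp) < 1e-9))
  ta <- ta_exchange_error(f_gng_grid = seq(0, 1, by = 0.05), t = 0.06,
                          p = 0.08, model = sim_model)
  # overestimation is largest with no true gluconeogenesis
  d0 <- ta$delta_pp[ta$f_gng_true == 0]
  expect_gt(d0, 0)
  expect_gt(d0, ta$delta_pp[ta$f_gng_true == 0.1])
  # no glycogen-derived molecules, no exchange effect
  expect_lt(abs(ta$delta_pp[ta$f_gng_true == 1]), 1e-9)
  # the extra-site occupation probability exceeds p itself
  p <- 0.08
  expect_gt(2 * p * (1 - p), p)
})

test_that("whole-population exchange mode grows with f instead", {
  ta_all <- ta_exchange_error(f_gng_grid = c(0.2, 0.9), t = 0.06, p = 0.08,
                              mode = "all", model = sim_model)
  expect_gt(ta_all$delta_pp[2], ta_all$delta_pp[1])
  ta_ggl <- ta_exchange_error(f_gng_grid = c(0.2, 0.9), t = 0.06, p = 0.08,
                              model = sim_model)
  expect_lt(max(abs(ta_ggl$delta_pp)), max(abs(ta_all$delta_pp)))
})
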