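# Independent oracle: the least-squares slope equals the
# distance-squared-weighted average of all pairwise secant slopes.
pairwise_slope_oracle <- function(t, y) {
  num <- 0; den <- 0
  for (i in seq_along(t)) for (j in seq_along(t)) if (j > i) {
    w <- (t[j] - t[i])^2
    num <- num + w * (y[j] - y[i]) / (t[j] - t[i])
    den <- den + w
  }
  num / den
}

test_that("phase segmentation finds the diauxic structure", {
  seg <- segment_phases(diauxic_tc())
  expect_equal(seg$glucose_phase, c(0, 40))
  expect_equal(seg$xylose_phase[1], 64)
  expect_equal(seg$diauxic_lag, 24)

  flat <- tiny_tc(seq(0, 96, 24), glucose_g_l = 50,
                  xylose_g_l = 50, a620 = 1)
  seg2 <- segment_phases(flat)
  expect_true("glucose never depleted" %in% seg2$flags)
  expect_null(seg2$xylose_phase)
  expect_true(is.na(seg2$diauxic_lag))

  expect_ferm_error(
    segment_phases(tiny_tc(c(0, 1, 2), glucose_g_l = c(5, NA, NA),
                           xylose_g_l = c(5, 4, 3))),
    "fermscreen_segmentation_error")
})

test_that("segmentation agrees with simulator switch times within one sampling interval", {
  tc <- simulate_fermentation(isolate_profile(), odm_75_75(), seed = 7,
                              inoculum_a620 = 0.1, duration = 144)
  truth <- attr(tc, "truth")
  seg <- segment_phases(tc)
  expect_lt(abs(seg$glucose_phase[2] - truth$t_glucose_depleted), 24)
  expect_lt(abs(seg$xylose_phase[1] - truth$t_xylose_onset), 24)
})

test_that("uptake rate is the negated regression slope, floored at zero", {
  tc <- tiny_tc(c(0, 10, 20), glucose_g_l = c(50, 40, 30))
  expect_equal(uptake_rate(tc, "glucose_g_l", c(0, 10)), 1.0)
  flat <- tiny_tc(c(0, 10, 20), glucose_g_l = 20)
  expect_equal(uptake_rate(flat, "glucose_g_l", c(0, 20)), 0)
  rising <- tiny_tc(c(0, 10, 20), glucose_g_l = c(1, 5, 9))
  expect_equal(uptake_rate(rising, "glucose_g_l", c(0, 20)), 0)

  set.seed(42)
  t <- seq(0, 40, 10); y <- 60 - 0.8 * t + rnorm(5, 0, 0.5)
  tc5 <- tiny_tc(t, glucose_g_l = y)
  expect_equal(uptake_rate(tc5, "glucose_g_l", c(0, 40)),
               -pairwise_slope_oracle(t, y), tolerance = 1e-9)
  expect_ferm_error(uptake_rate(tc5, "glucose_g_l", c(100, 120)),
                    "fermscreen_computation_error")
})

test_that("uptake rate is invariant to concentration offsets and time shifts", {
  set.seed(5)
  t <- seq(0, 96, 24); y <- pmax(0, 70 - 0.6 * t + rnorm(5, 0, 1))
  r0 <- uptake_rate(tiny_tc(t, xylose_g_l = y), "xylose_g_l", c(0, 96))
  r_off <- uptake_rate(tiny_tc(t, xylose_g_l = y + 13), "xylose_g_l",
                       c(0, 96))
  r_shift <- uptake_rate(tiny_tc(t + 50, xylose_g_l = y), "xylose_g_l",
                         c(50, 146))
  expect_equal(r_off, r0)
  expect_equal(r_shift, r0)
})

test_that("normalization divides by mean phase absorbance and reconstructs", {
  tc <- tiny_tc(c(0, 10, 20), a620 = 10, glucose_g_l = c(9, 6, 3))
  expect_equal(normalized_rate(0.6, tc, c(0, 20)), 0.06)
  expect_equal(normalized_rate(0, tc, c(0, 20)), 0)
  tc4 <- tiny_tc(c(0, 10, 20, 30), a620 = c(8, 10, 12, 14),
                 glucose_g_l = 1)
  r <- 0.37
  expect_equal(normalized_rate(r, tc4, c(0, 30)), r / 11)
  expect_equal(normalized_rate(r, tc4, c(0, 30)) * 11, r)
  dark <- tiny_tc(c(0, 10, 20), a620 = 0, glucose_g_l = 1)
  expect_ferm_error(normalized_rate(1, dark, c(0, 20)),
                    "fermscreen_computation_error")
})

test_that("ethanol productivity: phase slope and peak-based overall", {
  tc <- tiny_tc(c(0, 50, 100), ethanol_g_l = c(0, 20, 35))
  expect_equal(ethanol_productivity(tc), 0.35)
  flat <- tiny_tc(c(0, 50, 100), ethanol_g_l = 5)
  expect_equal(ethanol_productivity(flat, c(0, 100)), 0)
  # declining after the peak: overall uses the peak time, not run end
  decl <- tiny_tc(c(0, 50, 100, 150), ethanol_g_l = c(0, 30, 45, 40))
  expect_equal(ethanol_productivity(decl), 45 / 100)

  tc_sim <- simulate_fermentation(
    isolate_profile("adapted", q_max_xylose = 0.14 * 1.3,
                    ethanol_repression_threshold = 40),
    odm_75_75(), seed = 3, noise_cv = 0, duration = 300)
  truth <- attr(tc_sim, "truth")
  expected <- truth$final_ethanol /
    tc_sim$time_h[which.max(tc_sim$ethanol_g_l)]
  expect_equal(ethanol_productivity(tc_sim), expected, tolerance = 0.1)
})

test_that("yields are per total initial sugar with the biomass conversion", {
  tc <- tiny_tc(c(0, 50, 100), glucose_g_l = c(75, 10, 0),
                xylose_g_l = c(75, 75, 30), ethanol_g_l = c(0, 20, 45),
                a620 = c(0.5, 10, 20))
  expect_equal(yield_per_initial_sugar(tc, "ethanol_g_l"), 45 / 150)
  expect_equal(yield_per_initial_sugar(tc, "biomass"),
               0.167 * (20 - 0.5) / 150)
  never <- tiny_tc(c(0, 50, 100), glucose_g_l = c(75, 40, 5),
                   ethanol_g_l = c(3, 3, 3))
  expect_equal(yield_per_initial_sugar(never, "ethanol_g_l"), 0)
  nosugar <- tiny_tc(c(0, 1, 2), glucose_g_l = 0, ethanol_g_l = c(0, 1, 2))
  expect_ferm_error(yield_per_initial_sugar(nosugar, "ethanol_g_l"),
                    "fermscreen_computation_error")

  # simulator truth: measured yield ~ true yield x fraction consumed
  tc_sim <- simulate_fermentation(isolate_profile(), odm_75_75(),
                                  seed = 9, noise_cv = 0, duration = 300)
  truth <- attr(tc_sim, "truth")
  expected <- truth$final_ethanol / 150
  expect_equal(yield_per_initial_sugar(tc_sim, "ethanol_g_l"), expected,
               tolerance = 0.02)
})

test_that("specific growth rate recovers an exact exponential", {
  t <- seq(0, 48, 6)
  tc <- tiny_tc(t, a620 = 0.1 * exp(0.25 * t))
  expect_equal(specific_growth_rate(tc), 0.25, tolerance = 1e-12)
  flat <- tiny_tc(c(0, 10, 20, 30), a620 = 2)
  expect_equal(specific_growth_rate(flat), 0)
})

test_that("auto growth window equals brute-force enumeration", {
  brute <- function(t, a) {
    best <- 0
    for (i in seq_along(t)) for (j in seq_along(t)) if (j >= i + 2) {
      s <- coef(lm(log(a[i:j]) ~ t[i:j]))[2]
      if (s > best) best <- s
    }
    unname(best)
  }
  set.seed(11)
  for (k in 1:5) {
    t <- seq(0, 96, 12)
    a <- 0.1 * exp(0.2 * pmin(t, 48)) * exp(rnorm(length(t), 0, 0.05))
    tc <- tiny_tc(t, a620 = a)
    expect_equal(specific_growth_rate(tc), brute(t, a), tolerance = 1e-9)
  }
})

test_that("growth inhibition ratio divides inhibited by uninhibited rate", {
  expect_equal(growth_inhibition_ratio(0.24, 0.24), 1)
  expect_equal(growth_inhibition_ratio(0.12, 0.24), 0.5)
  expect_ferm_error(growth_inhibition_ratio(0.1, 0),
                    "fermscreen_domain_error")
})

test_that("lag time interpolates the fold-change crossing", {
  tc <- tiny_tc(c(0, 4, 8), a620 = c(0.1, 0.15, 0.25))
  expect_equal(as.numeric(lag_time(tc)), 6)
  never <- tiny_tc(c(0, 24, 48), a620 = c(0.1, 0.11, 0.12))
  l <- lag_time(never)
  expect_equal(as.numeric(l), 48)
  expect_equal(attr(l, "flag"), "never crossed")
  dead <- tiny_tc(c(0, 1, 2), a620 = c(0, 0, 0))
  expect_ferm_error(lag_time(dead), "fermscreen_domain_error")
})

test_that("furfural dormancy is recovered as lag within one sampling interval", {
  m <- medium_composition("ODM+furfural", glucose = 50, furfural = 25)
  tc <- simulate_fermentation(isolate_profile(), m, seed = 2,
                              noise_cv = 0, sample_interval = 6)
  expect_lt(abs(as.numeric(lag_time(tc)) - 37.6), 6 + 1e-9)
})

test_that("continuous-culture and comparison arithmetic", {
  expect_equal(generation_time(log(2)), 1)
  expect_equal(percent_change(5, 5), 0)
  expect_equal(percent_change(44, 57), -29.5, tolerance = 0.01)
  expect_ferm_error(generation_time(0), "fermscreen_domain_error")
  expect_ferm_error(percent_change(0, 1), "fermscreen_domain_error")
})

test_that("the kinetic summary assembles all per-run parameters", {
  tc <- simulate_fermentation(isolate_profile(), odm_75_75(), seed = 4,
                              inoculum_a620 = 0.1)
  row <- kinetic_summary(tc)
  expect_equal(nrow(row), 1)
  expect_true(all(c("glucose_uptake_rate", "xylose_uptake_rate",
                    "yield_ethanol", "mu", "diauxic_lag", "max_ethanol",
                    "flags") %in% names(row)))
  expect_gt(row$glucose_uptake_rate, 0)
  expect_lte(row$yield_ethanol, 0.511)
  batch <- summarize_kinetics(list(tc, tc))
  expect_equal(nrow(batch), 2)
})

test_that("noise-free simulator output yields accurate kinetics recovery", {
  # mu within 5% on an uninhibited, dilute, glucose-only culture
  m <- medium_composition("G50", glucose = 50)
  p <- isolate_profile()
  tc <- simulate_fermentation(p, m, inoculum_a620 = 0.1, noise_cv = 0,
                              sample_interval = 4, duration = 96)
  expect_equal(specific_growth_rate(tc), p$mu_max_glucose,
               tolerance = 0.05)
  # phase-level uptake rate within 10% of the mean rate over the
  # detected phase (>= 5 samples per phase)
  tc2 <- simulate_fermentation(p, odm_75_75(), noise_cv = 0,
                               sample_interval = 8, duration = 300)
  seg <- segment_phases(tc2)
  sel <- tc2$time_h >= seg$glucose_phase[1] &
    tc2$time_h <= seg$glucose_phase[2]
  expect_gte(sum(sel), 5)
  g <- tc2$glucose_g_l[sel]; tt <- tc2$time_h[sel]
  mean_rate <- (g[1] - g[length(g)]) / (tt[length(tt)] - tt[1])
  expect_equal(uptake_rate(tc2, "glucose_g_l", seg$glucose_phase),
               mean_rate, tolerance = 0.1)
})
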