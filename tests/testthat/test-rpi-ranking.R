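test_that("standard scores are within-group z-scores with n-1 sd", {
  g <- c(1, 2, 3)
  expect_equal(standard_score(3, g), 1)
  expect_equal(standard_score(mean(g), g), 0)
  f_all <- standard_score(g, g)
  expect_equal(mean(f_all), 0)
  expect_equal(sd(f_all), 1)
  expect_ferm_error(standard_score(1, c(2, 2, 2)),
                    "fermscreen_degenerate_group")
  expect_ferm_error(standard_score(1, 5), "fermscreen_degenerate_group")
})

test_that("the RPI map sends F = -2, 0, +2 to 0, 50, 100 without clamping", {
  expect_equal(rpi_from_f(c(-2, 0, 2)), c(0, 50, 100))
  expect_equal(rpi_from_f(3), 125)  # outliers exceed the nominal range
})

test_that("per-medium RPI is the weighted mean of yield and rate scores", {
  expect_equal(rpi_per_medium(60, 40), 50)
  expect_equal(rpi_per_medium(60, 40, 1, 0), 60)
  expect_equal(rpi_per_medium(62.3, 47.7), (62.3 + 47.7) / 2)
  expect_ferm_error(rpi_per_medium(60, 40, -1, 1),
                    "fermscreen_domain_error")
})

test_that("overall RPI averages all 2n components", {
  expect_equal(rpi_overall(rep(55, 6)), 55)
  expect_equal(rpi_overall(c(60, 40, 70, 30)), 50)
  comps <- matrix(c(60, 70, 40, 30), ncol = 2)  # Y then R per medium
  expect_equal(rpi_overall(comps),
               mean(rpi_per_medium(comps[, 1], comps[, 2])))
  expect_ferm_error(rpi_overall(numeric()), "fermscreen_computation_error")
  expect_ferm_error(rpi_overall(c(50, NA)), "fermscreen_computation_error")
})

test_that("dispersion diagnostics give s and relative s", {
  comps <- c(30, 60, 55, 49)
  d <- rpi_dispersion(comps)
  expect_equal(d$s, sd(comps))
  expect_equal(d$rel_s, sd(comps) / mean(comps) * 100)
  expect_equal(rpi_dispersion(c(47, 47, 47))$s, 0)
  expect_equal(rpi_dispersion(c(47, 47, 47))$rel_s, 0)
  z <- rpi_dispersion(c(-10, 10))
  expect_true(is.na(z$rel_s))
})

test_that("ranking orders a uniformly better isolate first", {
  m <- toy_matrix(n = 2)
  rep <- rank_isolates(m)
  expect_equal(rep$isolate_id, c("i02", "i01"))
  expect_equal(rep$rank, 1:2)
  comp_cols <- grep("^rpi_[YR]\\.", names(rep), value = TRUE)
  expect_true(all(rep[1, comp_cols] > 50))
  expect_true(all(rep[2, comp_cols] < 50))
})

test_that("ranking is invariant to input order and affine trait rescaling", {
  set.seed(21)
  m <- toy_matrix(n = 6)
  m$value <- m$value + rnorm(nrow(m))
  r1 <- rank_isolates(m)
  r2 <- rank_isolates(m[sample(nrow(m)), ])
  expect_equal(as.data.frame(r1), as.data.frame(r2), ignore_attr = TRUE)

  m2 <- m
  for (md in unique(m2$medium_id)) for (tr in c("Y", "R")) {
    sel <- m2$medium_id == md & m2$trait == tr
    m2$value[sel] <- 7.3 * m2$value[sel] + 11  # positive affine map
  }
  r3 <- rank_isolates(m2)
  expect_equal(as.data.frame(r3), as.data.frame(r1), tolerance = 1e-10,
               ignore_attr = TRUE)
})

test_that("mean RPI across isolates within each group is exactly 50", {
  set.seed(8)
  m <- toy_matrix(n = 9)
  m$value <- rlnorm(nrow(m))
  comp <- attr(rank_isolates(m), "components")
  means <- aggregate(rpi ~ medium_id + trait, comp, mean)
  expect_equal(means$rpi, rep(50, nrow(means)))
})

test_that("overall RPI responds monotonically to a component increase", {
  set.seed(3)
  m <- toy_matrix(n = 5)
  m$value <- m$value + rnorm(nrow(m), 0, 2)
  base <- rank_isolates(m)
  i <- which(m$isolate_id == "i03" & m$medium_id == "M1" & m$trait == "R")
  m$value[i] <- m$value[i] + 5
  bumped <- rank_isolates(m)
  expect_gt(bumped$rpi_overall[bumped$isolate_id == "i03"],
            base$rpi_overall[base$isolate_id == "i03"])
})

test_that("degenerate groups score 50 with a flag; incomplete isolates drop", {
  m <- toy_matrix(n = 3)
  m$value[m$trait == "Y"] <- 4  # zero spread in every Y group
  rep <- rank_isolates(m)
  expect_true(all(unlist(rep[grep("^rpi_Y", names(rep))]) == 50))
  expect_true(any(grepl("degenerate", attr(rep, "flags"))))

  m2 <- toy_matrix(n = 3)
  m2 <- m2[!(m2$isolate_id == "i02" & m2$medium_id == "M2"), ]
  rep2 <- rank_isolates(m2)
  expect_false("i02" %in% rep2$isolate_id)
  expect_equal(attr(rep2, "excluded"), "i02")
})

test_that("replicate values average before scoring unless asked otherwise", {
  m <- toy_matrix(n = 3, reps = 2)
  set.seed(2); m$value <- m$value + rnorm(nrow(m), 0, 0.1)
  r_avg <- rank_isolates(m)
  agg <- aggregate(value ~ isolate_id + medium_id + trait, m, mean)
  expect_equal(as.data.frame(rank_isolates(agg)),
               as.data.frame(r_avg), ignore_attr = TRUE)
  r_rep <- rank_isolates(m, score_replicates = TRUE)
  expect_s3_class(r_rep, "rpi_report")
})

test_that("superior and specialist selection follows the thresholds", {
  m <- toy_matrix(n = 4)
  set.seed(1); m$value <- m$value + rnorm(nrow(m), 0, 0.2)
  rep <- select_superior(rank_isolates(m), overall_min = 60,
                         specialist_min = 55, rel_s_max = 40)
  expect_true(all(rep$superior ==
    (rep$rpi_overall > 60 & rep$rel_s < 40)))
  # an isolate strong on one medium only lists it as specialist
  spec <- strsplit(rep$specialist_media[1], ";")[[1]]
  med_rpi <- unlist(rep[1, grep("^rpi\\.", names(rep))])
  expect_setequal(spec, sub("^rpi\\.", "", names(med_rpi)[med_rpi > 55]))
})

test_that("planted superior strains are recovered by the ranking (seed 11)", {
  cohort <- make_cohort(n_isolates = 30, n_superior = 5, seed = 11)
  tcs <- simulate_cohort(cohort)
  rep <- rank_isolates(build_screen_matrix(summarize_kinetics(tcs)))
  top6 <- head(rep$isolate_id, 6)
  planted <- cohort$truth$isolate_id[cohort$truth$superior]
  expect_gte(sum(planted %in% top6), 4)
})
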