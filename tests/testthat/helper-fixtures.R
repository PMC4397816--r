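# Small fixtures built in code.

# A clean diauxic time course: glucose falls linearly and crosses the
# 1 g/L depletion threshold at t = 40 h; xylose holds at 75 g/L until it
# starts falling after t = 56 h (first sample showing a > 2 g/L drop is
# t = 64 h), giving a diauxic lag of 24 h.
diauxic_tc <- function() {
  t <- seq(0, 96, by = 8)
  glc <- pmax(0, 75 - 1.875 * t)
  xyl <- ifelse(t <= 56, 75, pmax(0, 75 - 0.625 * (t - 56)))
  timecourse("iso", "ODM", 1,
             data.frame(time_h = t, a620 = 0.1 * exp(pmin(t, 48) * 0.05),
                        glucose_g_l = glc, xylose_g_l = xyl,
                        ethanol_g_l = 0.41 * (75 - glc + 75 - xyl)))
}

# Minimal three-sample run with given channel vectors.
tiny_tc <- function(time_h, ..., isolate = "iso", medium = "M",
                    replicate = 1) {
  timecourse(isolate, medium, replicate,
             data.frame(time_h = time_h, ...))
}

# A balanced two-trait, two-media screen matrix for n isolates where
# isolate i has trait value base + i * slope (plus optional noise).
toy_matrix <- function(n = 4, media = c("M1", "M2"), slope = 1,
                       reps = 1) {
  grid <- expand.grid(isolate_id = sprintf("i%02d", seq_len(n)),
                      medium_id = media, replicate = seq_len(reps),
                      trait = c("Y", "R"), stringsAsFactors = FALSE)
  grid$value <- 10 + slope * as.integer(sub("i", "", grid$isolate_id))
  grid
}

# ODM-like defined medium, 75 + 75 g/L mixed sugars, no inhibitors.
odm_75_75 <- function() {
  medium_composition("ODM", glucose = 75, xylose = 75)
}

expect_ferm_error <- function(expr, class) {
  expect_error(expr, class = class)
}
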