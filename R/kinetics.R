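# Kinetic parameter extraction from fermentation time courses.
#
# All rates are least-squares slopes over a detected consumption phase
# rather than maximum two-point slopes: with sparse (daily) sampling a
# two-point estimate is noise-dominated, while the regression slope is the
# minimum-variance linear estimate over the window.

# Least-squares slope of y vs t, skipping missing pairs. Returns NA when
# fewer than 2 complete pairs remain.
ls_slope <- function(t, y) {
  ok <- complete.cases(t, y)
  if (sum(ok) < 2) return(NA_real_)
  t <- t[ok]; y <- y[ok]
  sum((t - mean(t)) * (y - mean(y))) / sum((t - mean(t))^2)
}

in_phase <- function(tc, phase) {
  tc$time_h >= phase[1] & tc$time_h <= phase[2]
}

#' Segment a diauxic time course into glucose and xylose phases
#'
#' The glucose phase runs from the first sample to the first sample where
#' glucose falls below the depletion threshold (or to the last sample,
#' with a flag, if glucose is never depleted). The xylose phase begins at
#' the first post-depletion sample where xylose has dropped more than the
#' noise threshold below its running maximum, and ends at xylose depletion
#' or the last sample. The diauxic lag is the gap between glucose
#' depletion and xylose onset; it is undefined (`NA`), not zero, when
#' xylose consumption never starts.
#'
#' @param tc a [timecourse()].
#' @param glucose_depletion glucose considered depleted below this
#'   concentration (g/L, default 1).
#' @param xylose_drop xylose consumption onset requires a fall of more
#'   than this much (g/L, default 2) below the running maximum, so that
#'   measurement noise does not trigger a phantom onset.
#' @return list of class `phase_segmentation`: `glucose_phase` and
#'   `xylose_phase` as `c(t_start, t_end)` (xylose phase `NULL` when
#'   undefined), `diauxic_lag` (h or `NA`), and a character vector
#'   `flags`.
#' @export
segment_phases <- function(tc, glucose_depletion = 1, xylose_drop = 2) {
  flags <- character()
  for (ch in c("glucose_g_l", "xylose_g_l"))
    if (sum(!is.na(tc[[ch]])) < 2)
      abort_ferm(sprintf("fewer than 2 usable %s points", ch),
                 "fermscreen_segmentation_error")
  t <- tc$time_h
  glc <- tc$glucose_g_l
  dep <- which(!is.na(glc) & glc < glucose_depletion)
  if (length(dep) == 0) {
    glucose_phase <- c(t[1], t[length(t)])
    flags <- c(flags, "glucose never depleted")
    xylose_phase <- NULL
  } else {
    glucose_phase <- c(t[1], t[dep[1]])
    after <- which(t > t[dep[1]] | seq_along(t) >= dep[1])
    xyl <- tc$xylose_g_l
    runmax <- cummax(ifelse(is.na(xyl), -Inf, xyl))
    onset <- which(seq_along(t) >= dep[1] & !is.na(xyl) &
                     runmax - xyl > xylose_drop)
    if (length(onset) == 0) {
      xylose_phase <- NULL
      flags <- c(flags, "xylose never consumed")
    } else {
      i0 <- onset[1]
      xdep <- which(seq_along(t) >= i0 & !is.na(xyl) &
                      xyl < glucose_depletion)
      i1 <- if (length(xdep)) xdep[1] else length(t)
      xylose_phase <- c(t[i0], t[i1])
      if (i1 == length(t) && length(xdep) == 0)
        flags <- c(flags, "xylose not depleted by end of run")
    }
  }
  diauxic_lag <- if (is.null(xylose_phase) ||
                     "glucose never depleted" %in% flags) NA_real_
                 else xylose_phase[1] - glucose_phase[2]
  structure(list(glucose_phase = glucose_phase,
                 xylose_phase = xylose_phase,
                 diauxic_lag = diauxic_lag, flags = flags),
            class = "phase_segmentation")
}

#' Volumetric sugar uptake rate over a phase
#'
#' Minus the least-squares slope of concentration versus time over the
#' phase window, floored at 0 (a rising channel has no uptake).
#'
#' @param tc a [timecourse()].
#' @param analyte channel name, e.g. `"glucose_g_l"` or `"xylose_g_l"`.
#' @param phase `c(t_start, t_end)` in hours, typically from
#'   [segment_phases()].
#' @return uptake rate in g/L/h.
#' @export
uptake_rate <- function(tc, analyte, phase) {
  stopifnot(analyte %in% CONC_CHANNELS)
  sel <- in_phase(tc, phase)
  s <- ls_slope(tc$time_h[sel], tc[[analyte]][sel])
  if (is.na(s))
    abort_ferm(sprintf("fewer than 2 non-missing %s points in phase [%g, %g]",
                       analyte, phase[1], phase[2]),
               "fermscreen_computation_error")
  max(0, -s)
}

#' Normalize a volumetric rate by mean culture absorbance
#'
#' Rates are made comparable across runs of different cell density by
#' dividing by the arithmetic mean 620-nm absorbance over the samples in
#' the corresponding consumption phase.
#'
#' @param rate volumetric rate, g/L/h.
#' @param tc a [timecourse()].
#' @param phase `c(t_start, t_end)` hours.
#' @return rate per absorbance unit, g/L/h/A620.
#' @export
normalized_rate <- function(rate, tc, phase) {
  a <- tc$a620[in_phase(tc, phase)]
  a <- a[!is.na(a)]
  if (length(a) == 0 || mean(a) <= 0)
    abort_ferm("no positive absorbance readings in phase",
               "fermscreen_computation_error")
  rate / mean(a)
}

#' Ethanol productivity over a phase or overall
#'
#' Phase productivity is the least-squares slope of ethanol versus time
#' over the window, floored at 0. Overall productivity is peak ethanol
#' divided by the time at which the peak is reached (ethanol often
#' declines after its maximum, so end-of-run values would understate it).
#'
#' @param tc a [timecourse()].
#' @param phase `c(t_start, t_end)` in hours, or `NULL` for the overall
#'   (peak-based) variant.
#' @return productivity in g/L/h.
#' @export
ethanol_productivity <- function(tc, phase = NULL) {
  if (is.null(phase)) {
    e <- tc$ethanol_g_l
    if (sum(!is.na(e)) < 2)
      abort_ferm("fewer than 2 ethanol points",
                 "fermscreen_computation_error")
    imax <- which.max(e)
    if (tc$time_h[imax] <= 0) return(0)
    return(max(0, e[imax] / tc$time_h[imax]))
  }
  sel <- in_phase(tc, phase)
  s <- ls_slope(tc$time_h[sel], tc$ethanol_g_l[sel])
  if (is.na(s))
    abort_ferm("fewer than 2 ethanol points in phase",
               "fermscreen_computation_error")
  max(0, s)
}

#' Product yield per total initial sugar
#'
#' Peak product concentration minus its initial concentration, divided by
#' the total sugar supplied at inoculation ([total_initial_sugar()]).
#' `product = "biomass"` converts absorbance to dry mass at 0.167 g/L per
#' A620 unit first.
#'
#' @param tc a [timecourse()].
#' @param product `"ethanol_g_l"`, `"xylitol_g_l"`, or `"biomass"`.
#' @return yield, g product per g initial sugar.
#' @export
yield_per_initial_sugar <- function(tc, product = "ethanol_g_l") {
  s0 <- as.numeric(total_initial_sugar(tc))
  if (s0 <= 0)
    abort_ferm("total initial sugar is zero",
               "fermscreen_computation_error")
  conc <- if (identical(product, "biomass"))
    absorbance_to_biomass(tc$a620) else tc[[product]]
  if (all(is.na(conc)))
    abort_ferm(sprintf("product channel %s empty", product),
               "fermscreen_computation_error")
  p0 <- conc[which(!is.na(conc))[1]]
  max(0, max(conc, na.rm = TRUE) - p0) / s0
}

#' Residual xylose fraction
#'
#' Minimum xylose concentration observed at or after the start of the
#' xylose phase (or after glucose depletion when no xylose phase was
#' detected), per g total initial sugar.
#'
#' @param tc a [timecourse()].
#' @param seg a [segment_phases()] result; computed if omitted.
#' @return residual xylose, g per g initial sugar.
#' @export
residual_xylose <- function(tc, seg = segment_phases(tc)) {
  s0 <- as.numeric(total_initial_sugar(tc))
  if (s0 <= 0)
    abort_ferm("total initial sugar is zero",
               "fermscreen_computation_error")
  t0 <- if (!is.null(seg$xylose_phase)) seg$xylose_phase[1]
        else seg$glucose_phase[2]
  xyl <- tc$xylose_g_l[tc$time_h >= t0]
  if (all(is.na(xyl))) return(NA_real_)
  min(xyl, na.rm = TRUE) / s0
}

#' Maximum specific growth rate from absorbance
#'
#' Slope of `ln(a620)` versus time. In `"auto"` mode every window of at
#' least 3 consecutive positive-absorbance samples is scanned and the
#' maximal slope is returned (the exponential-phase estimate); an explicit
#' `c(t_start, t_end)` window uses exactly the samples inside it.
#'
#' @param tc a [timecourse()].
#' @param window `"auto"` or `c(t_start, t_end)` in hours.
#' @param min_points smallest window length scanned in auto mode.
#' @return specific growth rate mu, 1/h (0 for a non-growing culture).
#' @export
specific_growth_rate <- function(tc, window = "auto", min_points = 3) {
  if (!identical(window, "auto")) {
    sel <- in_phase(tc, window) & !is.na(tc$a620)
    if (any(tc$a620[sel] <= 0, na.rm = TRUE))
      abort_ferm("nonpositive absorbance in growth window",
                 "fermscreen_computation_error")
    if (sum(sel) < 3)
      abort_ferm("fewer than 3 absorbance points in window",
                 "fermscreen_computation_error")
    return(max(0, ls_slope(tc$time_h[sel], log(tc$a620[sel]))))
  }
  ok <- which(!is.na(tc$a620) & tc$a620 > 0)
  if (length(ok) < min_points)
    abort_ferm("fewer than 3 positive absorbance points",
               "fermscreen_computation_error")
  t <- tc$time_h[ok]; la <- log(tc$a620[ok])
  best <- 0
  n <- length(ok)
  for (i in seq_len(n - min_points + 1))
    for (j in seq(i + min_points - 1, n)) {
      s <- ls_slope(t[i:j], la[i:j])
      if (!is.na(s) && s > best) best <- s
    }
  best
}

#' Growth inhibition ratio
#'
#' Ratio of the specific growth rate with an inhibitor present to the
#' uninhibited rate; 1 means no inhibition.
#'
#' @param mu_i growth rate with inhibitor, 1/h.
#' @param mu_o growth rate without inhibitor, 1/h; must be positive.
#' @return dimensionless ratio `mu_i / mu_o`.
#' @export
growth_inhibition_ratio <- function(mu_i, mu_o) {
  if (any(mu_o <= 0))
    abort_ferm("uninhibited growth rate must be positive",
               "fermscreen_domain_error")
  mu_i / mu_o
}

#' Growth lag time by fold-change crossing
#'
#' Time at which absorbance first reaches `fold` times its initial value,
#' linearly interpolated between samples. If the culture never crosses,
#' the last sampling time is returned with attribute `flag =
#' "never crossed"`.
#'
#' @param tc a [timecourse()].
#' @param fold fold-increase defining the end of lag (default 2).
#' @return lag time in hours.
#' @export
lag_time <- function(tc, fold = 2) {
  a <- tc$a620; t <- tc$time_h
  ok <- !is.na(a)
  a <- a[ok]; t <- t[ok]
  if (length(a) == 0 || a[1] <= 0)
    abort_ferm("initial absorbance must be positive",
               "fermscreen_domain_error")
  target <- fold * a[1]
  above <- which(a >= target)
  if (length(above) == 0) {
    out <- t[length(t)]
    attr(out, "flag") <- "never crossed"
    return(out)
  }
  i <- above[1]
  if (i == 1) return(t[1])
  t[i - 1] + (target - a[i - 1]) / (a[i] - a[i - 1]) * (t[i] - t[i - 1])
}

#' Generation time from a continuous-culture dilution rate
#'
#' @param dilution_rate dilution rate D (feed flow over culture volume),
#'   1/h; must be positive.
#' @return generation (doubling) time `ln(2)/D` in hours.
#' @examples
#' generation_time(0.012)  # ~58 h, one generation per ~2.4 days
#' @export
generation_time <- function(dilution_rate) {
  if (any(dilution_rate <= 0))
    abort_ferm("dilution rate must be positive", "fermscreen_domain_error")
  log(2) / dilution_rate
}

#' Percent change relative to a reference value
#'
#' Positive for a reduction: `percent_change(200, 150)` is 25 (a 25%
#' reduction from the 200-h reference).
#'
#' @param reference nonzero reference value.
#' @param new new value.
#' @return percent change, `(reference - new)/reference * 100`.
#' @export
percent_change <- function(reference, new) {
  if (any(reference == 0))
    abort_ferm("reference must be nonzero", "fermscreen_domain_error")
  (reference - new) / reference * 100
}

#' Extract the full kinetic summary of one run
#'
#' Segments the run ([segment_phases()]) and computes every per-run
#' kinetic parameter: phase uptake rates and their absorbance-normalized
#' variants, ethanol productivities (per phase and overall peak-based),
#' yields per total initial sugar (ethanol, biomass, xylitol), residual
#' xylose, maximum specific growth rate, lag and diauxic lag, and the
#' ethanol peak. Parameters whose phase is undefined are `NA`.
#'
#' @param tc a [timecourse()].
#' @param glucose_depletion,xylose_drop thresholds passed to
#'   [segment_phases()].
#' @return one-row data frame with the run identifiers, all parameters,
#'   and a `flags` column collecting segmentation warnings.
#' @export
kinetic_summary <- function(tc, glucose_depletion = 1, xylose_drop = 2) {
  seg <- segment_phases(tc, glucose_depletion, xylose_drop)
  gp <- seg$glucose_phase; xp <- seg$xylose_phase
  try_na <- function(expr) tryCatch(expr, fermscreen_error = function(e) NA_real_)
  glc_rate <- try_na(uptake_rate(tc, "glucose_g_l", gp))
  xyl_rate <- if (is.null(xp)) NA_real_
              else try_na(uptake_rate(tc, "xylose_g_l", xp))
  e <- tc$ethanol_g_l
  has_eth <- sum(!is.na(e)) >= 2
  imax <- if (has_eth) which.max(e) else NA_integer_
  data.frame(
    isolate_id = attr(tc, "isolate_id"),
    medium_id = attr(tc, "medium_id"),
    replicate = attr(tc, "replicate"),
    glucose_uptake_rate = glc_rate,
    xylose_uptake_rate = xyl_rate,
    glucose_uptake_rate_norm = try_na(normalized_rate(glc_rate, tc, gp)),
    xylose_uptake_rate_norm = if (is.null(xp) || is.na(xyl_rate)) NA_real_
      else try_na(normalized_rate(xyl_rate, tc, xp)),
    ethanol_productivity_glucose = if (has_eth)
      try_na(ethanol_productivity(tc, gp)) else NA_real_,
    ethanol_productivity_xylose = if (has_eth && !is.null(xp))
      try_na(ethanol_productivity(tc, xp)) else NA_real_,
    ethanol_productivity_overall = if (has_eth)
      try_na(ethanol_productivity(tc)) else NA_real_,
    yield_ethanol = try_na(yield_per_initial_sugar(tc, "ethanol_g_l")),
    yield_biomass = try_na(yield_per_initial_sugar(tc, "biomass")),
    yield_xylitol = try_na(yield_per_initial_sugar(tc, "xylitol_g_l")),
    residual_xylose = try_na(residual_xylose(tc, seg)),
    mu = try_na(specific_growth_rate(tc)),
    lag_time = try_na(as.numeric(lag_time(tc))),
    diauxic_lag = seg$diauxic_lag,
    max_ethanol = if (has_eth) e[imax] else NA_real_,
    time_to_max_ethanol = if (has_eth) tc$time_h[imax] else NA_real_,
    flags = paste(seg$flags, collapse = "; "),
    stringsAsFactors = FALSE
  )
}

#' Kinetic summaries for a batch of runs
#'
#' @param tcs list of [timecourse()] objects.
#' @param ... passed to [kinetic_summary()].
#' @return data frame, one row per run.
#' @export
summarize_kinetics <- function(tcs, ...) {
  if (inherits(tcs, "timecourse")) tcs <- list(tcs)
  out <- do.call(rbind, lapply(tcs, kinetic_summary, ...))
  rownames(out) <- NULL
  out
}
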