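# Mechanistic generator of diauxic fermentation time courses with known
# ground truth.
#
# The model is deliberately simple: Monod uptake of glucose and xylose by
# a growing biomass, ethanol produced at a fixed yield on all sugar
# consumed, a xylitol side fraction of xylose, and three inhibition
# mechanisms that reproduce the screening phenomenology -- (i) xylose
# uptake is gated by an induction state that only rises after glucose
# depletion and whose rise is linearly repressed by ethanol between a
# threshold (~15 g/L for the parent strain) and a ceiling (~50 g/L),
# producing the diauxic lag; (ii) acetic acid reduces the specific growth
# rate linearly, more steeply on xylose than on glucose; (iii) furfural
# imposes a detoxification dormancy proportional to its concentration.
# Integration is a fixed-step 4th-order Runge-Kutta scheme (step <= 0.1 h)
# compiled in C++; measurement noise is multiplicative Gaussian applied to
# the sampled values in R under R's seeded RNG.

#' Default acetic-acid inhibition slopes
#'
#' Fractional specific-growth-rate loss per g/L acetic acid, chosen so
#' that growth at 15 g/L acetic acid is reduced to 79% of the uninhibited
#' rate on glucose and to 68% on xylose.
#' @name acetic_slopes
#' @export
ACETIC_SLOPE_GLUCOSE <- (1 - 0.79) / 15

#' @rdname acetic_slopes
#' @export
ACETIC_SLOPE_XYLOSE <- (1 - 0.68) / 15

#' Ground-truth kinetic profile of a simulated isolate
#'
#' Defaults describe an unadapted parent-like strain: maximum specific
#' growth rates ~0.25/h (glucose) and 0.23/h (xylose), an ethanol yield
#' of 0.41 g/g sugar consumed, xylose induction repressed by ethanol
#' above 15 g/L (fully blocked at 50 g/L), and a furfural detoxification
#' lag of 37.6 h at 25 mM. Adapted phenotypes are expressed by raising
#' `ethanol_repression_threshold` (reduced diauxic lag) and/or
#' `q_max_xylose` (faster xylose uptake).
#'
#' @param isolate_id character label.
#' @param mu_max_glucose,mu_max_xylose maximum specific growth rates, 1/h.
#' @param K_glucose,K_xylose Monod half-saturation constants, g/L.
#' @param q_max_glucose,q_max_xylose maximum specific uptake rates,
#'   g sugar / g biomass / h. Defaults correspond to the typical
#'   per-absorbance normalized rates of hydrolyzate fermentations
#'   (0.09 and 0.023 g/L/h per A620 unit, divided by 0.167 g/L biomass
#'   per unit).
#' @param yield_ethanol_consumed ethanol yield on consumed sugar, g/g
#'   (stoichiometric ceiling 0.511).
#' @param yield_biomass nominal biomass yield bound used in the
#'   mass-balance audit, g/g.
#' @param xylitol_fraction fraction of consumed xylose excreted as
#'   xylitol, g/g.
#' @param ethanol_repression_threshold ethanol concentration (g/L) above
#'   which xylose induction slows.
#' @param ethanol_repression_ceiling ethanol concentration (g/L) at which
#'   induction stops entirely.
#' @param induction_rate first-order rate of the xylose induction state,
#'   1/h (acts only once glucose is depleted).
#' @param biomass_cap nitrogen-limited biomass ceiling, g/L dry cells:
#'   growth slows logistically as the culture approaches it (hydrolyzates
#'   are nitrogen-poor, so cultures stop growing long before sugars are
#'   exhausted while fermentation continues).
#' @param acetic_slope_glucose,acetic_slope_xylose fractional growth-rate
#'   loss per g/L acetic acid.
#' @param furfural_detox_lag dormancy imposed by 25 mM furfural, h
#'   (scaled linearly with furfural concentration).
#' @param ethanol_growth_cap ethanol concentration (g/L) at which growth
#'   (not fermentation) ceases; growth tolerance of the species is well
#'   below its fermentation tolerance, so cultures stop growing in the
#'   mid-30s g/L while ethanol keeps accumulating.
#' @return object of class `isolate_profile` (named list).
#' @export
isolate_profile <- function(isolate_id = "parent",
                            mu_max_glucose = 0.25,
                            mu_max_xylose = 0.23,
                            K_glucose = 0.5,
                            K_xylose = 1.0,
                            q_max_glucose = 0.54,
                            q_max_xylose = 0.14,
                            yield_ethanol_consumed = 0.41,
                            yield_biomass = 0.3,
                            xylitol_fraction = 0.02,
                            ethanol_repression_threshold = 15,
                            ethanol_repression_ceiling = 50,
                            induction_rate = 0.04,
                            biomass_cap = 5,
                            acetic_slope_glucose = ACETIC_SLOPE_GLUCOSE,
                            acetic_slope_xylose = ACETIC_SLOPE_XYLOSE,
                            furfural_detox_lag = 37.6,
                            ethanol_growth_cap = 35) {
  p <- list(isolate_id = as.character(isolate_id),
            mu_max_glucose = mu_max_glucose,
            mu_max_xylose = mu_max_xylose,
            K_glucose = K_glucose, K_xylose = K_xylose,
            q_max_glucose = q_max_glucose, q_max_xylose = q_max_xylose,
            yield_ethanol_consumed = yield_ethanol_consumed,
            yield_biomass = yield_biomass,
            xylitol_fraction = xylitol_fraction,
            ethanol_repression_threshold = ethanol_repression_threshold,
            ethanol_repression_ceiling = ethanol_repression_ceiling,
            induction_rate = induction_rate,
            biomass_cap = biomass_cap,
            acetic_slope_glucose = acetic_slope_glucose,
            acetic_slope_xylose = acetic_slope_xylose,
            furfural_detox_lag = furfural_detox_lag,
            ethanol_growth_cap = ethanol_growth_cap)
  num <- unlist(p[-1])
  if (any(!is.finite(num)) || any(num < 0))
    abort_ferm("profile parameters must be finite and nonnegative",
               "fermscreen_domain_error")
  if (yield_ethanol_consumed > 0.511)
    abort_ferm("ethanol yield exceeds the stoichiometric ceiling 0.511",
               "fermscreen_domain_error")
  if (ethanol_repression_ceiling <= ethanol_repression_threshold)
    abort_ferm("repression ceiling must exceed the threshold",
               "fermscreen_domain_error")
  structure(p, class = "isolate_profile")
}

#' Growth-rate multiplier under acetic acid
#'
#' Linear dose response `max(0, 1 - slope * acetic)`. With the default
#' slopes the factor at 15 g/L acetic acid is 0.79 on glucose and 0.68 on
#' xylose.
#'
#' @param profile an [isolate_profile()] (its slopes may be
#'   strain-specific).
#' @param acetic acetic acid concentration, g/L.
#' @param sugar `"glucose"` or `"xylose"`.
#' @return multiplier in \[0, 1\].
#' @export
acetic_inhibition_factor <- function(profile = isolate_profile(),
                                     acetic, sugar = c("glucose", "xylose")) {
  sugar <- match.arg(sugar)
  if (any(acetic < 0))
    abort_ferm("acetic acid concentration must be >= 0",
               "fermscreen_domain_error")
  slope <- if (sugar == "glucose") profile$acetic_slope_glucose
           else profile$acetic_slope_xylose
  pmax(0, 1 - slope * acetic)
}

#' Simulate one diauxic fermentation run
#'
#' Integrates the biomass/glucose/xylose/ethanol/xylitol/induction
#' dynamics for one isolate on one medium with a fixed-step RK4 scheme,
#' samples the trajectory at the given interval, applies multiplicative
#' Gaussian measurement noise (truncated at 0), and returns a
#' [timecourse()] whose `"truth"` attribute carries the noise-free ground
#' truth (switch times, consumed sugars, realized yields).
#'
#' @param profile an [isolate_profile()].
#' @param medium a [medium_composition()].
#' @param inoculum_a620 initial culture absorbance (620 nm,
#'   Genesys-equivalent); biomass at 0.167 g/L per unit.
#' @param duration run length, h. The default, 144 h (six days of daily
#'   samples), emulates a screen harvested while slower strains are still
#'   mid-xylose, which is what makes residual xylose and yield per
#'   initial sugar discriminate strains.
#' @param sample_interval sampling interval, h (default 24: daily).
#' @param noise_cv coefficient of variation of the multiplicative
#'   measurement noise (default 0.03).
#' @param seed integer RNG seed (mandatory when `noise_cv > 0`).
#' @param replicate replicate number recorded on the time course.
#' @param step integration step, h (<= 0.1).
#' @return a [timecourse()] with attribute `"truth"`.
#' @export
simulate_fermentation <- function(profile, medium, inoculum_a620 = 0.5,
                                  duration = 144, sample_interval = 24,
                                  noise_cv = 0.03, seed = NULL,
                                  replicate = 1, step = 0.1) {
  stopifnot(inherits(profile, "isolate_profile"),
            inherits(medium, "medium_composition"))
  if (inoculum_a620 < 0 || duration <= 0)
    abort_ferm("inoculum and duration must be positive",
               "fermscreen_domain_error")
  if (step > 0.1) abort_ferm("integration step must be <= 0.1 h",
                             "fermscreen_domain_error")
  if (noise_cv > 0 && is.null(seed))
    abort_ferm("a seed is required when noise_cv > 0",
               "fermscreen_domain_error")
  X0 <- absorbance_to_biomass(inoculum_a620)
  state0 <- c(X = X0, G = medium$glucose, Xy = medium$xylose, E = 0,
              Xol = 0, I = 0)
  pars <- c(mu_max_glucose = profile$mu_max_glucose,
            mu_max_xylose = profile$mu_max_xylose,
            K_glucose = profile$K_glucose,
            K_xylose = profile$K_xylose,
            q_max_glucose = profile$q_max_glucose,
            q_max_xylose = profile$q_max_xylose,
            yield_ethanol_consumed = profile$yield_ethanol_consumed,
            xylitol_fraction = profile$xylitol_fraction,
            ethanol_repression_threshold = profile$ethanol_repression_threshold,
            ethanol_repression_ceiling = profile$ethanol_repression_ceiling,
            induction_rate = profile$induction_rate,
            biomass_cap = profile$biomass_cap,
            glucose_gate = 1.0,
            f_acetic_glucose =
              acetic_inhibition_factor(profile, medium$acetic_acid, "glucose"),
            f_acetic_xylose =
              acetic_inhibition_factor(profile, medium$acetic_acid, "xylose"),
            ethanol_growth_cap = profile$ethanol_growth_cap,
            detox_lag = profile$furfural_detox_lag * medium$furfural / 25)
  times <- seq(0, duration, by = sample_interval)
  res <- .ferment_rk4(state0, pars, times, step)
  st <- res$states

  # stoichiometric audit on the noise-free trajectory
  consumed <- (state0["G"] - st[nrow(st), "G"]) +
    (state0["Xy"] - st[nrow(st), "Xy"])
  if (consumed > 1e-9) {
    if (st[nrow(st), "E"] > 0.511 * consumed + 1e-6)
      abort_ferm("mass balance violated: ethanol exceeds 0.511 g/g consumed",
                 "fermscreen_integration_error")
    if (st[nrow(st), "X"] - X0 > 0.6 * consumed + 1e-6)
      abort_ferm("mass balance violated: biomass exceeds 0.6 g/g consumed",
                 "fermscreen_integration_error")
  }

  noisy <- function(v) {
    if (noise_cv <= 0) return(v)
    pmax(0, v * (1 + rnorm(length(v), 0, noise_cv)))
  }
  if (!is.null(seed)) set.seed(as.integer(seed %% 2147483647))
  samples <- data.frame(
    time_h = times,
    a620 = noisy(st[, "X"] / A620_BIOMASS_SLOPE),
    glucose_g_l = noisy(st[, "G"]),
    xylose_g_l = noisy(st[, "Xy"]),
    arabinose_g_l = noisy(rep(medium$arabinose, length(times))),
    galactose_g_l = noisy(rep(medium$galactose, length(times))),
    mannose_g_l = noisy(rep(medium$mannose, length(times))),
    fructose_g_l = noisy(rep(medium$fructose, length(times))),
    ethanol_g_l = noisy(st[, "E"]),
    xylitol_g_l = noisy(st[, "Xol"]),
    acetic_g_l = noisy(rep(medium$acetic_acid, length(times)))
  )
  tc <- timecourse(profile$isolate_id, medium$medium_id, replicate,
                   samples)
  glc_consumed <- state0[["G"]] - st[nrow(st), "G"]
  xyl_consumed <- state0[["Xy"]] - st[nrow(st), "Xy"]
  attr(tc, "truth") <- list(
    profile = profile, medium_id = medium$medium_id, seed = seed,
    t_glucose_depleted = res$t_glucose_depleted,
    t_xylose_onset = res$t_xylose_onset,
    detox_lag = unname(pars["detox_lag"]),
    glucose_consumed = unname(glc_consumed),
    xylose_consumed = unname(xyl_consumed),
    final_ethanol = unname(st[nrow(st), "E"]),
    final_biomass = unname(st[nrow(st), "X"]),
    ethanol_at_glucose_depletion = res$ethanol_at_glucose_depletion)
  tc
}

#' Build a simulated screening cohort with planted superior strains
#'
#' Draws baseline isolate profiles from log-normal spreads (CV ~10%)
#' around the parent defaults and plants `n_superior` superior strains
#' carrying trait multipliers (by default 1.3x xylose uptake capacity and
#' an ethanol-repression threshold raised to 40 g/L, i.e. reduced diauxic
#' lag). The true identity of the planted strains is returned so that
#' ranking recovery can be scored.
#'
#' @param n_isolates cohort size.
#' @param n_superior number of planted superior strains
#'   (`<= n_isolates`).
#' @param effect_sizes named list of superior-strain effects:
#'   `xylose_rate` multiplier on `q_max_xylose` (default 1.3) and
#'   `repression_threshold` replacement value in g/L (default 40).
#' @param media list of [medium_composition()] objects (default: the
#'   three secondary-screen hydrolyzates from [study_media()]).
#' @param replicates fermentation replicates per isolate x medium.
#' @param seed integer seed; identical seeds regenerate the cohort
#'   exactly.
#' @param baseline_cv coefficient of variation of the log-normal
#'   strain-to-strain parameter spread (default 0.1).
#' @return object of class `simulated_cohort`: list with `profiles`,
#'   `media`, `design` (a [screen_design()]), `truth` (data frame with
#'   `isolate_id`, `superior`), and `seed`.
#' @export
make_cohort <- function(n_isolates = 30, n_superior = 5,
                        effect_sizes = list(xylose_rate = 1.3,
                                            repression_threshold = 40),
                        media = NULL, replicates = 2, seed = 1,
                        baseline_cv = 0.1) {
  if (n_superior > n_isolates)
    abort_ferm("n_superior must be <= n_isolates",
               "fermscreen_domain_error")
  if (any(unlist(effect_sizes) <= 0))
    abort_ferm("effect multipliers must be positive",
               "fermscreen_domain_error")
  if (is.null(media))
    media <- study_media()[c("AFEX-CSH-6", "SGH-N1", "SGH-N2")]
  set.seed(as.integer(seed %% 2147483647))
  sdlog <- sqrt(log(1 + baseline_cv^2))
  ids <- sprintf("iso%02d", seq_len(n_isolates))
  superior_ids <- if (n_superior > 0) sample(ids, n_superior) else character()
  profiles <- lapply(ids, function(id) {
    jitter <- function(x, s = sdlog) x * rlnorm(1, -s^2 / 2, s)
    p <- isolate_profile(
      isolate_id = id,
      mu_max_glucose = jitter(0.25),
      mu_max_xylose = jitter(0.23),
      q_max_glucose = jitter(0.54),
      q_max_xylose = jitter(0.14),
      yield_ethanol_consumed = min(0.51, 0.41 * rlnorm(1, 0, 0.05)),
      biomass_cap = jitter(5),
      induction_rate = jitter(0.04))
    if (id %in% superior_ids) {
      # the adapted phenotype is faster xylose utilization as a whole:
      # transport capacity and growth on xylose scale together
      mult <- effect_sizes$xylose_rate %||% 1.3
      p$q_max_xylose <- p$q_max_xylose * mult
      p$mu_max_xylose <- p$mu_max_xylose * mult
      p$ethanol_repression_threshold <-
        effect_sizes$repression_threshold %||% 40
    }
    p
  })
  names(profiles) <- ids
  runs <- expand.grid(isolate_id = ids,
                      medium_id = vapply(media, `[[`, "", "medium_id"),
                      replicate = seq_len(replicates),
                      stringsAsFactors = FALSE)
  structure(list(profiles = profiles, media = media,
                 design = screen_design(runs),
                 truth = data.frame(isolate_id = ids,
                                    superior = ids %in% superior_ids,
                                    stringsAsFactors = FALSE),
                 seed = seed),
            class = "simulated_cohort")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Simulate every run of a cohort
#'
#' Runs [simulate_fermentation()] for each (isolate, medium, replicate)
#' triple of the cohort design with a per-run seed derived
#' deterministically from the cohort seed.
#'
#' @param cohort a [make_cohort()] result.
#' @param ... passed to [simulate_fermentation()] (duration,
#'   sample_interval, noise_cv, step).
#' @return list of [timecourse()] objects.
#' @export
simulate_cohort <- function(cohort, ...) {
  stopifnot(inherits(cohort, "simulated_cohort"))
  media <- setNames(cohort$media,
                    vapply(cohort$media, `[[`, "", "medium_id"))
  runs <- cohort$design$runs
  lapply(seq_len(nrow(runs)), function(i) {
    r <- runs[i, ]
    run_seed <- (as.numeric(cohort$seed) * 1000003 + i) %% 2147483647
    simulate_fermentation(cohort$profiles[[r$isolate_id]],
                          media[[r$medium_id]],
                          replicate = r$replicate, seed = run_seed, ...)
  })
}
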