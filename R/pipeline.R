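# End-to-end screen orchestration: simulate -> kinetics -> rank -> stats.

#' Dilute a medium composition
#'
#' Scales every concentration field by `fraction` (hydrolyzate strength),
#' e.g. 60% and 75% liquor formulations of the same hydrolyzate.
#'
#' @param medium a [medium_composition()].
#' @param fraction dilution factor in (0, 1].
#' @param medium_id label for the diluted medium (default
#'   `"<id>-<pct>"`).
#' @return a [medium_composition()].
#' @export
dilute_medium <- function(medium, fraction,
                          medium_id = sprintf("%s-%d", medium$medium_id,
                                              round(100 * fraction))) {
  stopifnot(fraction > 0, fraction <= 1)
  m <- medium
  for (f in c("glucose", "xylose", "arabinose", "galactose", "mannose",
              "fructose", "acetic_acid", "hmf", "furfural", "pan",
              "urea", "ammonia"))
    m[[f]] <- m[[f]] * fraction
  m$medium_id <- medium_id
  m
}

#' Build the two-trait screen matrix from kinetic summaries
#'
#' Extracts the ranking traits -- ethanol yield per initial sugar (Y) and
#' xylose uptake rate (R) -- into the tidy long format consumed by
#' [rank_isolates()].
#'
#' @param kin data frame from [summarize_kinetics()].
#' @return data frame with columns `isolate_id`, `medium_id`,
#'   `replicate`, `trait`, `value`.
#' @export
build_screen_matrix <- function(kin) {
  long <- rbind(
    data.frame(isolate_id = kin$isolate_id, medium_id = kin$medium_id,
               replicate = kin$replicate, trait = "Y",
               value = kin$yield_ethanol, stringsAsFactors = FALSE),
    data.frame(isolate_id = kin$isolate_id, medium_id = kin$medium_id,
               replicate = kin$replicate, trait = "R",
               value = kin$xylose_uptake_rate, stringsAsFactors = FALSE))
  rownames(long) <- NULL
  long
}

# Replicate-level RPI components for the ANOVA/SNK stage: z-score the
# replicate values within each (medium, trait) group.
replicate_rpi <- function(matrix) {
  m <- matrix[!is.na(matrix$value), , drop = FALSE]
  key <- interaction(m$medium_id, m$trait, drop = TRUE)
  do.call(rbind, lapply(split(m, key), function(g) {
    g$rpi <- if (nrow(g) < 2 || sd(g$value) == 0) rep(50, nrow(g))
             else rpi_from_f(standard_score(g$value, g$value))
    g
  }))
}

#' Configuration for an end-to-end screen
#'
#' @param seed integer seed driving cohort generation and measurement
#'   noise.
#' @param n_isolates,n_superior,replicates cohort shape (see
#'   [make_cohort()]).
#' @param primary_media,secondary_media lists of [medium_composition()]
#'   objects; defaults are the two selection-liquor strengths (60% and
#'   75% dilutions of the xylose-rich liquor) for the primary screen and
#'   the three saccharified hydrolyzates for the secondary screen.
#' @param top_fraction fraction of isolates surviving the primary screen
#'   (default 0.2).
#' @param w_y,w_r RPI trait weights.
#' @param glucose_depletion,xylose_drop segmentation thresholds, g/L.
#' @param overall_min,specialist_min,rel_s_max selection thresholds (see
#'   [select_superior()]).
#' @param alpha ANOVA/SNK significance criterion.
#' @param duration,sample_interval,noise_cv simulation settings (see
#'   [simulate_fermentation()]).
#' @return list of class `pipeline_config`.
#' @export
screen_config <- function(seed = 1, n_isolates = 30, n_superior = 5,
                          replicates = 2, primary_media = NULL,
                          secondary_media = NULL, top_fraction = 0.2,
                          w_y = 1, w_r = 1, glucose_depletion = 1,
                          xylose_drop = 2, overall_min = 60,
                          specialist_min = 55, rel_s_max = 40,
                          alpha = 0.05, duration = 144,
                          sample_interval = 24, noise_cv = 0.03) {
  if (alpha <= 0 || alpha >= 1)
    abort_ferm("alpha must be in (0, 1)", "fermscreen_domain_error")
  if (top_fraction <= 0 || top_fraction > 1)
    abort_ferm("top_fraction must be in (0, 1]", "fermscreen_domain_error")
  if (is.null(primary_media) || is.null(secondary_media)) {
    media <- study_media()
    if (is.null(primary_media))
      primary_media <- list(dilute_medium(media$PSGHL, 0.60),
                            dilute_medium(media$PSGHL, 0.75))
    if (is.null(secondary_media))
      secondary_media <- media[c("AFEX-CSH-6", "SGH-N1", "SGH-N2")]
    rm(media)
  }
  structure(as.list(environment()), class = "pipeline_config")
}

rank_stage <- function(tcs, cfg) {
  kin <- summarize_kinetics(tcs, glucose_depletion = cfg$glucose_depletion,
                            xylose_drop = cfg$xylose_drop)
  mat <- build_screen_matrix(kin)
  report <- select_superior(
    rank_isolates(mat, w_y = cfg$w_y, w_r = cfg$w_r),
    overall_min = cfg$overall_min, specialist_min = cfg$specialist_min,
    rel_s_max = cfg$rel_s_max)
  list(kinetics = kin, matrix = mat, report = report)
}

#' Run the full simulated screening pipeline
#'
#' Generates a cohort with planted superior strains, ferments every
#' isolate on the primary (selection-liquor) media, ranks by RPI, carries
#' the top fraction into the secondary screen on the saccharified
#' hydrolyzates, ranks again, and runs the two-way ANOVA (isolate x
#' medium, with interaction) plus SNK letter display on the
#' replicate-level RPI components of the secondary screen.
#'
#' @param config a [screen_config()].
#' @param out_dir optional directory; when given, kinetics tables, RPI
#'   reports (CSV and JSON), the ANOVA table, the SNK grouping, and a run
#'   log are written there.
#' @return list with `cohort`, `primary` and `secondary` stage results
#'   (each with `kinetics`, `matrix`, `report`), `anova`, `snk`, and
#'   `survivors`.
#' @export
run_screen <- function(config = screen_config(), out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  log_lines <- sprintf("screen start: seed %d, %d isolates",
                       config$seed, config$n_isolates)
  cohort <- make_cohort(n_isolates = config$n_isolates,
                        n_superior = config$n_superior,
                        media = c(config$primary_media,
                                  config$secondary_media),
                        replicates = config$replicates,
                        seed = config$seed)
  all_tcs <- simulate_cohort(cohort, duration = config$duration,
                             sample_interval = config$sample_interval,
                             noise_cv = config$noise_cv)
  med_of <- vapply(all_tcs, attr, "", "medium_id")
  prim_ids <- vapply(config$primary_media, `[[`, "", "medium_id")
  sec_ids <- vapply(config$secondary_media, `[[`, "", "medium_id")

  primary <- rank_stage(all_tcs[med_of %in% prim_ids], config)
  n_top <- max(2, ceiling(nrow(primary$report) * config$top_fraction))
  survivors <- head(primary$report$isolate_id, n_top)
  log_lines <- c(log_lines,
                 sprintf("primary: %d ranked, %d enter secondary",
                         nrow(primary$report), length(survivors)))

  sec_tcs <- all_tcs[med_of %in% sec_ids &
                       vapply(all_tcs, attr, "", "isolate_id") %in% survivors]
  secondary <- rank_stage(sec_tcs, config)

  comp <- replicate_rpi(secondary$matrix)
  stats_tab <- tryCatch(
    screen_anova(comp, "rpi", c("isolate_id", "medium_id"),
                 alpha = config$alpha),
    fermscreen_error = function(e) NULL)
  snk <- tryCatch(
    snk_letters(comp, "rpi", "isolate_id", alpha = config$alpha),
    fermscreen_error = function(e) NULL)
  log_lines <- c(log_lines,
                 sprintf("secondary: %d ranked, %d flagged superior",
                         nrow(secondary$report),
                         sum(secondary$report$superior)))

  bundle <- list(cohort = cohort, primary = primary,
                 secondary = secondary, survivors = survivors,
                 anova = stats_tab, snk = snk, log = log_lines,
                 config = config)
  if (!is.null(out_dir)) write_screen_bundle(bundle, out_dir)
  bundle
}

write_screen_bundle <- function(bundle, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  wr <- function(df, name)
    write.csv(df, file.path(out_dir, name), row.names = FALSE)
  wr(bundle$primary$kinetics, "kinetics_primary.csv")
  wr(bundle$secondary$kinetics, "kinetics_secondary.csv")
  wr(as.data.frame(bundle$primary$report), "rpi_primary.csv")
  wr(as.data.frame(bundle$secondary$report), "rpi_secondary.csv")
  if (!is.null(bundle$anova)) wr(as.data.frame(bundle$anova), "anova.csv")
  if (!is.null(bundle$snk)) wr(as.data.frame(bundle$snk), "snk_groups.csv")
  jsonlite::write_json(
    list(seed = bundle$config$seed,
         survivors = bundle$survivors,
         report = as.data.frame(bundle$secondary$report)),
    file.path(out_dir, "rpi_report.json"), auto_unbox = TRUE, digits = NA)
  writeLines(bundle$log, file.path(out_dir, "run_log.txt"))
  invisible(out_dir)
}
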