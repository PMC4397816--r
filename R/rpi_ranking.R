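# Relative Performance Index (RPI) ranking.
#
# Each trait value is z-scored within its (medium, trait) group across
# isolates, F = (X - Xavg)/s, and mapped to a percentile-like score
# RPI = (2 + F) * 100/4, so a group-average isolate scores 50 and scores
# run approximately 0-100 (they are deliberately NOT clamped: extreme
# outliers land outside the nominal range, which the dispersion
# diagnostics should reveal rather than hide). Per-medium RPIs average the
# yield (Y) and rate (R) components, and RPI_overall averages all 2n
# components across the n media. The dispersion s of those components,
# and its ratio to RPI_overall (Rel. s), flag isolates whose rank is an
# artifact of one favourable environment.

#' Within-group standard score
#'
#' `F = (x - mean(group)) / sd(group)` with the sample (n-1) standard
#' deviation. For a trait normally distributed across the screened group,
#' F effectively ranges over about -2 to +2.
#'
#' @param x value(s) to score.
#' @param group the trait values of all isolates in the (medium, trait)
#'   group; length >= 2 with positive standard deviation.
#' @return dimensionless score(s).
#' @export
standard_score <- function(x, group) {
  if (length(group) < 2)
    abort_ferm("group must have >= 2 values", "fermscreen_degenerate_group")
  s <- sd(group)
  if (!is.finite(s) || s == 0)
    abort_ferm("group standard deviation is zero",
               "fermscreen_degenerate_group")
  (x - mean(group)) / s
}

#' Map a standard score to a Relative Performance Index
#'
#' `RPI = (2 + F) * 100/4`: F = -2, 0, +2 map to 0, 50, 100. Values are
#' not clamped; an isolate more than 2 standard deviations from its group
#' mean scores outside the nominal 0-100 range.
#'
#' @param f standard score(s) from [standard_score()].
#' @return RPI score(s), percentile-like.
#' @examples
#' rpi_from_f(c(-2, 0, 2))  # 0 50 100
#' @export
rpi_from_f <- function(f) (2 + f) * 100 / 4

#' Combine yield and rate RPI components for one medium
#'
#' Weighted mean of the yield and rate components; equal weighting by
#' default, but the weights can be set to reflect the relative economic
#' importance of the two traits.
#'
#' @param rpi_y,rpi_r yield and rate RPI components.
#' @param w_y,w_r nonnegative weights, positive sum.
#' @return per-medium RPI.
#' @export
rpi_per_medium <- function(rpi_y, rpi_r, w_y = 1, w_r = 1) {
  if (any(c(w_y, w_r) < 0) || w_y + w_r <= 0)
    abort_ferm("weights must be nonnegative with positive sum",
               "fermscreen_domain_error")
  (w_y * rpi_y + w_r * rpi_r) / (w_y + w_r)
}

#' Overall RPI across media
#'
#' Mean of all 2n per-medium (yield, rate) components over the n media
#' tested: `[(RPI_Y + RPI_R)_1 + ... + (RPI_Y + RPI_R)_n] / 2n`, or its
#' weighted generalization.
#'
#' @param components numeric vector of per-medium RPI components (the
#'   yield and rate scores of one isolate on every medium), or a
#'   two-column matrix with columns Y and R.
#' @param w_y,w_r trait weights as in [rpi_per_medium()].
#' @return overall RPI.
#' @export
rpi_overall <- function(components, w_y = 1, w_r = 1) {
  if (is.matrix(components)) {
    if (nrow(components) == 0)
      abort_ferm("no components", "fermscreen_computation_error")
    return(mean(rpi_per_medium(components[, 1], components[, 2], w_y, w_r)))
  }
  if (length(components) == 0 || any(is.na(components)))
    abort_ferm("no components or missing components",
               "fermscreen_computation_error")
  mean(components)
}

#' Dispersion of RPI components
#'
#' Sample standard deviation `s` of the component scores entering the
#' overall RPI, and the relative dispersion `Rel. s = s / RPI_overall *
#' 100` (%). A low overall RPI with high Rel. s marks an isolate whose
#' ranking is unstable across environments.
#'
#' @param components numeric vector of the RPI components (>= 2).
#' @param overall the overall RPI; recomputed from `components` if
#'   omitted.
#' @return list with `s` and `rel_s` (%); `rel_s` is `NA` with a flag
#'   when the overall RPI is 0.
#' @export
rpi_dispersion <- function(components, overall = mean(components)) {
  if (length(components) < 2)
    abort_ferm(">= 2 components needed", "fermscreen_computation_error")
  s <- sd(components)
  if (overall == 0)
    return(list(s = s, rel_s = NA_real_, flag = "zero overall RPI"))
  list(s = s, rel_s = s / overall * 100)
}

#' Rank isolates by Relative Performance Index
#'
#' Builds the full RPI report from a screen matrix of trait observations.
#' Replicate values are averaged to one value per isolate within each
#' (medium, trait) group before z-scoring (set `score_replicates = TRUE`
#' to z-score replicate-level values instead). Isolates missing any
#' (medium, trait) component are excluded from the overall ranking and
#' listed in the `excluded` attribute. A degenerate group (zero spread)
#' assigns RPI 50 to all its members with a flag.
#'
#' @param matrix data frame with columns `isolate_id`, `medium_id`,
#'   `replicate`, `trait` (`"Y"` for yield, `"R"` for rate), `value`.
#' @param design optional [screen_design()] carrying the trait weights.
#' @param w_y,w_r trait weights (overridden by `design` if given).
#' @param score_replicates z-score replicate-level values instead of
#'   isolate means.
#' @return data frame of class `rpi_report`, one row per isolate:
#'   per-medium component columns `rpi_Y.<medium>` / `rpi_R.<medium>`,
#'   `rpi_overall`, `s`, `rel_s`, `rank`, and `flags`; attribute
#'   `components` holds the tidy component table, attribute `excluded`
#'   the isolates dropped for missing components.
#' @export
rank_isolates <- function(matrix, design = NULL, w_y = 1, w_r = 1,
                          score_replicates = FALSE) {
  req <- c("isolate_id", "medium_id", "trait", "value")
  stopifnot(all(req %in% names(matrix)))
  if (!is.null(design)) { w_y <- design$w_y; w_r <- design$w_r }
  m <- matrix[!is.na(matrix$value), , drop = FALSE]
  if (!score_replicates) {
    m <- aggregate(value ~ isolate_id + medium_id + trait, data = m,
                   FUN = mean)
  }
  flags <- character()
  score_group <- function(g) {
    vals <- g$value
    if (length(vals) < 2 || sd(vals) == 0) {
      g$rpi <- rep(50, length(vals))
      flags <<- c(flags, sprintf("degenerate group %s/%s: RPI set to 50",
                                 g$medium_id[1], g$trait[1]))
    } else {
      g$rpi <- rpi_from_f(standard_score(vals, vals))
    }
    g
  }
  key <- interaction(m$medium_id, m$trait, drop = TRUE)
  comp <- do.call(rbind, lapply(split(m, key), score_group))
  if (score_replicates)  # one component per (isolate, medium, trait)
    comp <- aggregate(rpi ~ isolate_id + medium_id + trait, data = comp,
                      FUN = mean)
  media <- sort(unique(comp$medium_id))
  isolates <- sort(unique(comp$isolate_id))
  wt <- c(Y = w_y, R = w_r)
  rows <- list(); excluded <- character()
  for (iso in isolates) {
    ci <- comp[comp$isolate_id == iso, ]
    full <- all(vapply(media, function(md) {
      all(c("Y", "R") %in% ci$trait[ci$medium_id == md])
    }, logical(1)))
    if (!full) { excluded <- c(excluded, iso); next }
    comps <- ci$rpi
    wts <- wt[ci$trait]
    # weighted mean of components; with equal weights this is exactly
    # sum(components) / 2n
    overall <- sum(wts * comps) / sum(wts)
    disp <- rpi_dispersion(comps, overall)
    row <- data.frame(isolate_id = iso, rpi_overall = overall,
                      s = disp$s, rel_s = disp$rel_s,
                      stringsAsFactors = FALSE)
    for (md in media) {
      y <- ci$rpi[ci$medium_id == md & ci$trait == "Y"]
      r <- ci$rpi[ci$medium_id == md & ci$trait == "R"]
      row[[paste0("rpi_Y.", md)]] <- y
      row[[paste0("rpi_R.", md)]] <- r
      row[[paste0("rpi.", md)]] <- rpi_per_medium(y, r, w_y, w_r)
    }
    rows[[iso]] <- row
  }
  if (length(rows) == 0)
    abort_ferm("no isolate has complete components",
               "fermscreen_computation_error")
  rep_df <- do.call(rbind, rows)
  ord <- order(-rep_df$rpi_overall, rep_df$rel_s, rep_df$isolate_id)
  rep_df <- rep_df[ord, , drop = FALSE]
  rep_df$rank <- seq_len(nrow(rep_df))
  rownames(rep_df) <- NULL
  structure(rep_df, class = c("rpi_report", "data.frame"),
            components = comp, excluded = excluded,
            flags = unique(flags), weights = c(w_y = w_y, w_r = w_r))
}

#' Flag superior and specialist isolates in an RPI report
#'
#' An isolate is *superior* when its overall RPI exceeds `overall_min`
#' and its relative dispersion stays below `rel_s_max` (broad, stable
#' performance). Independently, media on which its per-medium RPI exceeds
#' `specialist_min` are listed as its specialist media, even when the
#' overall criterion fails.
#'
#' @param report an [rank_isolates()] result.
#' @param overall_min overall RPI threshold (default 60).
#' @param specialist_min per-medium RPI threshold (default 55).
#' @param rel_s_max maximum relative dispersion, % (default 40).
#' @return the report with logical `superior` and character
#'   `specialist_media` columns added.
#' @export
select_superior <- function(report, overall_min = 60,
                            specialist_min = 55, rel_s_max = 40) {
  med_cols <- grep("^rpi\\.", names(report), value = TRUE)
  report$superior <- !is.na(report$rel_s) &
    report$rpi_overall > overall_min & report$rel_s < rel_s_max
  report$specialist_media <- vapply(seq_len(nrow(report)), function(i) {
    hits <- med_cols[unlist(report[i, med_cols]) > specialist_min]
    paste(sub("^rpi\\.", "", hits), collapse = ";")
  }, character(1))
  report
}
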