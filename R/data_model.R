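# Domain types and delimited-text I/O shared by every pipeline stage.
#
# Units policy: time in hours, concentrations in g/L, furans in mM,
# absorbance in Genesys-equivalent units at 620 nm. Microplate absorbance
# readings must be converted at ingest (see
# microplate_to_reference_absorbance).

#' Dry biomass per unit culture absorbance (g/L per A620 unit)
#'
#' Calibration constant of the reference spectrophotometer: 0.167 g/L dry
#' cell mass per absorbance unit at 620 nm in a 1-cm cuvette.
#' @export
A620_BIOMASS_SLOPE <- 0.167

#' Microplate-to-reference absorbance divisor
#'
#' Plate-reader absorbances (200 uL/well) divided by 0.438 give
#' Genesys-equivalent cuvette absorbance units.
#' @export
MICROPLATE_DIVISOR <- 0.438

#' Concentration channels carried on a fermentation time course
#' @keywords internal
SUGAR_CHANNELS <- c("glucose_g_l", "xylose_g_l", "arabinose_g_l",
                    "galactose_g_l", "mannose_g_l", "fructose_g_l")

CONC_CHANNELS <- c(SUGAR_CHANNELS, "ethanol_g_l", "xylitol_g_l",
                   "acetic_g_l")

TC_COLUMNS <- c("isolate_id", "medium_id", "replicate", "time_h", "a620",
                CONC_CHANNELS, "viable_cfu_ml")

#' Construct a fermentation time course
#'
#' A `timecourse` is one fermentation run of one isolate on one medium:
#' an ordered series of samples with absorbance (620 nm,
#' Genesys-equivalent units) and concentration channels in g/L. Missing
#' measurements are carried as `NA` and never imputed; downstream kinetics
#' operations skip them pairwise.
#'
#' @param isolate_id,medium_id character labels identifying the run.
#' @param replicate positive integer replicate number.
#' @param samples data frame with column `time_h` (nonnegative, strictly
#'   increasing) plus any of `a620`, `glucose_g_l`, `xylose_g_l`,
#'   `arabinose_g_l`, `galactose_g_l`, `mannose_g_l`, `fructose_g_l`,
#'   `ethanol_g_l`, `xylitol_g_l`, `acetic_g_l`, `viable_cfu_ml`.
#'   Unlisted channels are filled with `NA`. At least 3 samples.
#' @return An object of class `timecourse`: the sample table with run
#'   metadata attached as attributes.
#' @examples
#' tc <- timecourse("Y-7124", "ODM", 1,
#'   data.frame(time_h = c(0, 24, 48), a620 = c(0.1, 2, 10),
#'              glucose_g_l = c(75, 30, 0)))
#' total_initial_sugar(tc)
#' @export
timecourse <- function(isolate_id, medium_id, replicate, samples) {
  stopifnot(is.data.frame(samples), "time_h" %in% names(samples))
  for (ch in setdiff(TC_COLUMNS[-(1:3)], names(samples)))
    samples[[ch]] <- NA_real_
  for (ch in TC_COLUMNS[-(1:3)])
    samples[[ch]] <- as.numeric(samples[[ch]])
  samples <- samples[order(samples$time_h),
                     TC_COLUMNS[-(1:3)], drop = FALSE]
  rownames(samples) <- NULL
  tc <- structure(samples,
                  class = c("timecourse", "data.frame"),
                  isolate_id = as.character(isolate_id),
                  medium_id = as.character(medium_id),
                  replicate = as.integer(replicate))
  validate_timecourse(tc)
  tc
}

#' @export
print.timecourse <- function(x, ...) {
  cat(sprintf("<timecourse> isolate %s on %s, replicate %d: %d samples over %g h\n",
              attr(x, "isolate_id"), attr(x, "medium_id"),
              attr(x, "replicate"), nrow(x), max(x$time_h)))
  print.data.frame(x, ...)
  invisible(x)
}

validate_timecourse <- function(tc) {
  id <- sprintf("%s/%s/r%d", attr(tc, "isolate_id"),
                attr(tc, "medium_id"), attr(tc, "replicate"))
  if (nrow(tc) < 3)
    abort_ferm(sprintf("time course %s has %d samples; need >= 3", id,
                       nrow(tc)), "fermscreen_validation_error")
  if (any(diff(tc$time_h) <= 0))
    abort_ferm(sprintf("times not strictly increasing in %s", id),
               "fermscreen_validation_error")
  if (tc$time_h[1] < 0)
    abort_ferm(sprintf("negative time in %s", id),
               "fermscreen_validation_error")
  for (ch in c("a620", CONC_CHANNELS, "viable_cfu_ml")) {
    v <- tc[[ch]]
    if (any(!is.na(v) & v < 0))
      abort_ferm(sprintf("negative %s in %s", ch, id),
                 "fermscreen_validation_error")
  }
  invisible(tc)
}

#' Read fermentation time courses from a delimited text file
#'
#' One row per sample; runs are identified by the
#' (`isolate_id`, `medium_id`, `replicate`) triple. The field separator is
#' sniffed (comma default, tab accepted). Missing cells stay missing.
#'
#' @param path path to a UTF-8 delimited text file.
#' @param schema optional named character vector mapping the canonical
#'   column names (`isolate_id`, `medium_id`, `replicate`, `time_h`,
#'   `a620`, `glucose_g_l`, ...) to the names used in the file, for files
#'   with non-default headers.
#' @return A list of [timecourse()] objects, one per run, samples sorted
#'   by time.
#' @export
read_timecourses <- function(path, schema = NULL) {
  if (!file.exists(path))
    abort_ferm(sprintf("file not found: %s", path), "fermscreen_io_error")
  sep <- if (grepl("\t", readLines(path, n = 1L))) "\t" else ","
  df <- read.csv(path, sep = sep, stringsAsFactors = FALSE,
                 check.names = FALSE)
  if (!is.null(schema)) {
    for (canon in names(schema)) {
      if (!schema[[canon]] %in% names(df))
        abort_ferm(sprintf("schema names column '%s' (for '%s') but file lacks it",
                           schema[[canon]], canon), "fermscreen_schema_error")
      names(df)[names(df) == schema[[canon]]] <- canon
    }
  }
  required <- c("isolate_id", "medium_id", "replicate", "time_h")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols))
    abort_ferm(sprintf("required column(s) missing: %s",
                       paste(missing_cols, collapse = ", ")),
               "fermscreen_schema_error")
  keys <- interaction(df$isolate_id, df$medium_id, df$replicate,
                      drop = TRUE, lex.order = TRUE)
  lapply(split(df, keys), function(g) {
    timecourse(g$isolate_id[1], g$medium_id[1], g$replicate[1],
               g[setdiff(names(g), c("isolate_id", "medium_id", "replicate"))])
  })
}

#' Write time courses to a delimited text file
#'
#' Inverse of [read_timecourses()]: writes the tidy one-row-per-sample
#' schema so that read -> write -> read is an identity on valid files.
#'
#' @param tcs a `timecourse` or list of them.
#' @param path output path; `.tsv` extension selects tab separation.
#' @return `path`, invisibly.
#' @export
write_timecourses <- function(tcs, path) {
  if (inherits(tcs, "timecourse")) tcs <- list(tcs)
  rows <- lapply(tcs, function(tc) {
    cbind(data.frame(isolate_id = attr(tc, "isolate_id"),
                     medium_id = attr(tc, "medium_id"),
                     replicate = attr(tc, "replicate")),
          as.data.frame(tc))
  })
  out <- do.call(rbind, rows)
  sep <- if (grepl("\\.tsv$", path)) "\t" else ","
  write.table(out, path, sep = sep, row.names = FALSE, quote = FALSE,
              na = "")
  invisible(path)
}

#' Convert microplate absorbance to reference (cuvette) absorbance
#'
#' Plate-reader 620-nm absorbances are put on the reference
#' spectrophotometer scale by dividing by 0.438, so all absorbance data
#' are reported in the same units.
#'
#' @param a_plate nonnegative microplate absorbance(s).
#' @return Genesys-equivalent absorbance, `a_plate / 0.438`.
#' @examples
#' microplate_to_reference_absorbance(0.438)  # 1
#' @export
microplate_to_reference_absorbance <- function(a_plate) {
  if (any(!is.na(a_plate) & a_plate < 0))
    abort_ferm("absorbance must be >= 0", "fermscreen_domain_error")
  a_plate / MICROPLATE_DIVISOR
}

#' Convert culture absorbance to dry biomass concentration
#'
#' Uses the cuvette calibration 0.167 g/L dry cells per 620-nm
#' absorbance unit.
#'
#' @param a620 nonnegative absorbance(s), Genesys-equivalent units.
#' @return dry biomass in g/L, `0.167 * a620`.
#' @examples
#' absorbance_to_biomass(40)  # a dense 6.7 g/L culture
#' @export
absorbance_to_biomass <- function(a620) {
  if (any(!is.na(a620) & a620 < 0))
    abort_ferm("absorbance must be >= 0", "fermscreen_domain_error")
  A620_BIOMASS_SLOPE * a620
}

#' Construct a medium composition record
#'
#' Sugar and inhibitor composition of a cultivation medium or hydrolyzate.
#' Sugar and acid concentrations in g/L, furans in mM, nitrogen sources in
#' mg N/L.
#'
#' @param medium_id character label.
#' @param glucose,xylose,arabinose,galactose,mannose,fructose sugars, g/L.
#' @param acetic_acid acetic acid, g/L.
#' @param hmf,furfural furan aldehydes, mM.
#' @param pan,urea,ammonia nitrogen sources, mg N/L (optional, `NA` allowed).
#' @return An object of class `medium_composition` (a one-row list).
#' @export
medium_composition <- function(medium_id, glucose = 0, xylose = 0,
                               arabinose = 0, galactose = 0, mannose = 0,
                               fructose = 0, acetic_acid = 0, hmf = 0,
                               furfural = 0, pan = NA_real_,
                               urea = NA_real_, ammonia = NA_real_) {
  num <- c(glucose = glucose, xylose = xylose, arabinose = arabinose,
           galactose = galactose, mannose = mannose, fructose = fructose,
           acetic_acid = acetic_acid, hmf = hmf, furfural = furfural)
  if (any(num < 0, na.rm = TRUE))
    abort_ferm(sprintf("negative composition value in medium %s", medium_id),
               "fermscreen_validation_error")
  structure(c(list(medium_id = as.character(medium_id)), as.list(num),
              list(pan = pan, urea = urea, ammonia = ammonia)),
            class = "medium_composition")
}

#' @export
print.medium_composition <- function(x, ...) {
  cat(sprintf("<medium_composition> %s: %.1f g/L total sugar, %.1f g/L acetic, %.1f mM furfural\n",
              x$medium_id, total_initial_sugar(x), x$acetic_acid,
              x$furfural))
  invisible(x)
}

#' Read a media composition table
#'
#' One row per medium with columns `medium_id`, `glucose`, `xylose`,
#' `arabinose`, `galactose`, `mannose`, `fructose`, `acetic_acid`, `hmf`,
#' `furfural` and optionally `pan`, `urea`, `ammonia`.
#'
#' @param path delimited text file (comma or tab).
#' @return named list of [medium_composition()] objects.
#' @export
read_media_table <- function(path) {
  if (!file.exists(path))
    abort_ferm(sprintf("file not found: %s", path), "fermscreen_io_error")
  sep <- if (grepl("\t", readLines(path, n = 1L))) "\t" else ","
  df <- read.csv(path, sep = sep, stringsAsFactors = FALSE)
  if (!"medium_id" %in% names(df))
    abort_ferm("required column(s) missing: medium_id",
               "fermscreen_schema_error")
  out <- lapply(seq_len(nrow(df)), function(i)
    do.call(medium_composition, as.list(df[i, , drop = FALSE])))
  setNames(out, df$medium_id)
}

#' Hydrolyzate compositions used in the screening study
#'
#' Mean compositions of the six cultivation media (two AFEX-pretreated
#' corn stover hydrolyzate strengths, dilute-acid switchgrass hydrolyzate
#' liquor, and saccharified switchgrass hydrolyzate with three nitrogen
#' regimes), shipped as a plain-text fixture.
#'
#' @return named list of [medium_composition()] objects.
#' @export
study_media <- function() {
  read_media_table(system.file("extdata", "hydrolyzate_media.csv",
                               package = "fermscreen", mustWork = TRUE))
}

#' Total initial sugar of a run or medium
#'
#' Sum of the six monosaccharide channels (glucose, xylose, arabinose,
#' galactose, mannose, fructose). For a time course the first sample
#' defines the initial concentrations; missing channels count as 0 and
#' are recorded in the `"missing_channels"` attribute of the result.
#'
#' @param x a [timecourse()] or [medium_composition()].
#' @return total sugar in g/L.
#' @export
total_initial_sugar <- function(x) UseMethod("total_initial_sugar")

#' @export
total_initial_sugar.timecourse <- function(x) {
  first <- unlist(x[1, SUGAR_CHANNELS])
  if (all(is.na(first)))
    abort_ferm("all sugar channels missing at time 0",
               "fermscreen_computation_error")
  out <- sum(first, na.rm = TRUE)
  attr(out, "missing_channels") <- SUGAR_CHANNELS[is.na(first)]
  out
}

#' @export
total_initial_sugar.medium_composition <- function(x) {
  sum(unlist(x[c("glucose", "xylose", "arabinose", "galactose",
                 "mannose", "fructose")]))
}

#' Define the expected runs and trait weights of a screen
#'
#' @param runs data frame with columns `isolate_id`, `medium_id`,
#'   `replicate`; one row per expected fermentation run, no duplicates.
#' @param w_y,w_r nonnegative weights for the yield (Y) and rate (R)
#'   traits in the RPI composite; equal weighting by default.
#' @return object of class `screen_design`.
#' @export
screen_design <- function(runs, w_y = 1, w_r = 1) {
  stopifnot(is.data.frame(runs),
            all(c("isolate_id", "medium_id", "replicate") %in% names(runs)))
  if (anyDuplicated(runs[c("isolate_id", "medium_id", "replicate")]))
    abort_ferm("duplicate (isolate, medium, replicate) triples in design",
               "fermscreen_validation_error")
  if (!is.finite(w_y) || !is.finite(w_r) || w_y < 0 || w_r < 0 ||
      w_y + w_r <= 0)
    abort_ferm("weights must be nonnegative with positive sum",
               "fermscreen_domain_error")
  structure(list(runs = runs, w_y = w_y, w_r = w_r),
            class = "screen_design")
}
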