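# Factorial ANOVA and Student-Newman-Keuls multiple comparison with
# compact letter displays.
#
# The SNK procedure sorts the level means and tests ranges step-down with
# the studentized range statistic: the critical value q(1-alpha, p, df)
# depends on the span p of each comparison, so wider ranges face larger
# critical values. A range found non-significant protects all of its
# sub-ranges (they are declared non-significant without testing), which
# keeps the letter display coherent.

#' Factorial analysis of variance for screen responses
#'
#' Fits a fixed-effects linear model of the response on 1-3 categorical
#' factors and reports an F test per effect. Unbalanced designs use
#' marginal (Type-II) sums of squares, the conventional choice when
#' interactions are of interest.
#'
#' @param data data frame containing the response and factor columns.
#' @param response name of the response column.
#' @param factors character vector of 1-3 factor column names.
#' @param interactions include all interaction terms (default `TRUE`
#'   when every factor-level combination is observed).
#' @param alpha significance criterion recorded on the result (default
#'   0.05).
#' @return data frame of class `screen_anova` with columns `effect`,
#'   `df`, `sumsq`, `statistic` (F) and `p.value`, plus residual df /
#'   mean square in attributes (used by [snk_letters()]).
#' @export
screen_anova <- function(data, response, factors, interactions = NULL,
                         alpha = 0.05) {
  stopifnot(response %in% names(data), all(factors %in% names(data)),
            length(factors) >= 1, length(factors) <= 3)
  for (f in factors) {
    data[[f]] <- factor(data[[f]])
    if (nlevels(data[[f]]) < 2)
      abort_ferm(sprintf("factor %s has < 2 levels", f),
                 "fermscreen_model_error")
  }
  cells <- interaction(data[factors], drop = FALSE)
  full_cells <- all(table(data[factors]) > 0)
  if (is.null(interactions)) interactions <- full_cells
  if (interactions && !full_cells) {
    empty <- names(which(table(cells) == 0))[1]
    abort_ferm(sprintf("interaction inestimable: empty cell %s", empty),
               "fermscreen_model_error")
  }
  op <- if (interactions && length(factors) > 1) " * " else " + "
  fml <- stats::as.formula(paste(response, "~",
                                 paste(factors, collapse = op)))
  fit <- lm(fml, data = data)
  if (stats::df.residual(fit) < 1)
    abort_ferm("model not estimable: no residual degrees of freedom",
               "fermscreen_model_error")
  tab <- if (length(factors) == 1) stats::anova(fit)
         else car::Anova(fit, type = 2)
  tab <- as.data.frame(tab)
  keep <- !(rownames(tab) %in% c("Residuals"))
  out <- data.frame(effect = rownames(tab)[keep],
                    df = tab$Df[keep],
                    sumsq = tab$`Sum Sq`[keep],
                    statistic = tab$`F value`[keep],
                    p.value = tab$`Pr(>F)`[keep],
                    stringsAsFactors = FALSE)
  res <- tab[rownames(tab) == "Residuals", ]
  structure(out, class = c("screen_anova", "data.frame"),
            alpha = alpha, fit = fit,
            df_residual = res$Df, ms_residual = res$`Sum Sq` / res$Df)
}

# Core SNK engine on summary statistics. means/n named by level.
# Returns the symmetric logical "not significantly different" matrix.
snk_nonsig_matrix <- function(means, n, ms_error, df_error, alpha) {
  k <- length(means)
  ord <- order(means, decreasing = TRUE)
  m <- means[ord]; nn <- n[ord]
  nonsig <- matrix(FALSE, k, k, dimnames = list(names(m), names(m)))
  diag(nonsig) <- TRUE
  if (ms_error <= 0) {
    # degenerate: levels differ iff their means differ at all
    for (i in seq_len(k)) for (j in seq_len(k))
      nonsig[i, j] <- m[i] == m[j]
    return(nonsig[names(means), names(means)])
  }
  # significant[i, j]: range from sorted position i to j rejected
  decided_nonsig <- matrix(FALSE, k, k)
  # process spans from widest to narrowest so protection propagates
  for (p in seq(k, 2)) {
    for (i in seq_len(k - p + 1)) {
      j <- i + p - 1
      if (decided_nonsig[i, j]) next
      n_h <- 2 / (1 / nn[i] + 1 / nn[j])  # harmonic mean of the pair
      q_stat <- (m[i] - m[j]) / sqrt(ms_error / n_h)
      q_crit <- qtukey(1 - alpha, nmeans = p, df = df_error)
      if (q_stat <= q_crit) {
        # whole range homogeneous; protect all nested ranges
        for (a in i:j) for (b in a:j) decided_nonsig[a, b] <- TRUE
      }
    }
  }
  for (i in seq_len(k)) for (j in seq_len(k))
    if (decided_nonsig[min(i, j), max(i, j)]) nonsig[i, j] <- TRUE
  nonsig[names(means), names(means)]
}

# Compact letter display from a non-significance relation: letters are
# maximal sets of mutually non-different levels. The SNK relation is
# interval-shaped on the mean ordering, so maximal homogeneous intervals
# suffice; they are found directly.
cld_from_nonsig <- function(means, nonsig) {
  ord <- order(means, decreasing = TRUE)
  lv <- names(means)[ord]
  ns <- nonsig[lv, lv, drop = FALSE]
  k <- length(lv)
  intervals <- list()
  for (i in seq_len(k)) {
    j <- i
    while (j < k && all(ns[i:(j + 1), i:(j + 1)])) j <- j + 1
    intervals[[length(intervals) + 1L]] <- i:j
  }
  # drop intervals nested in an earlier (therefore longer) one
  keep <- rep(TRUE, length(intervals))
  for (a in seq_along(intervals)) for (b in seq_along(intervals))
    if (a != b && keep[b] && all(intervals[[a]] %in% intervals[[b]]))
      keep[a] <- FALSE
  intervals <- intervals[keep]
  letters_out <- setNames(vector("list", k), lv)
  for (idx in seq_along(intervals))
    for (pos in intervals[[idx]])
      letters_out[[lv[pos]]] <- c(letters_out[[lv[pos]]], LETTERS[idx])
  letters_out[names(means)]
}

#' Student-Newman-Keuls grouping with compact letter display
#'
#' Applies the SNK stepwise studentized-range procedure to the level
#' means of one factor, using the residual mean square of a supporting
#' ANOVA as the error term. Unequal group sizes are handled through the
#' harmonic mean of each pair's sizes. Levels sharing no letter are
#' significantly different at `alpha`; the letter A is attached to the
#' top-mean group.
#'
#' @param data data frame with the response and factor.
#' @param response name of the response column.
#' @param factor_name name of the factor column whose levels are
#'   compared.
#' @param alpha significance criterion (default 0.05).
#' @param error_anova optional [screen_anova()] fit supplying the
#'   residual mean square (e.g. a factorial model); defaults to the
#'   one-way ANOVA on `factor_name`.
#' @return data frame of class `snk_grouping`, one row per level, sorted
#'   by descending mean, with columns `level`, `n`, `mean`, `letters`;
#'   the non-significance matrix is attached as attribute `nonsig`.
#' @export
snk_letters <- function(data, response, factor_name, alpha = 0.05,
                        error_anova = NULL) {
  f <- factor(data[[factor_name]])
  if (nlevels(f) < 2)
    abort_ferm("need >= 2 factor levels", "fermscreen_model_error")
  y <- data[[response]]
  ok <- !is.na(y) & !is.na(f)
  y <- y[ok]; f <- droplevels(f[ok])
  means <- tapply(y, f, mean)
  n <- tapply(y, f, length)
  if (is.null(error_anova))
    error_anova <- suppressWarnings(
      screen_anova(data.frame(y = y, f = f), "y", "f", alpha = alpha))
  ms <- attr(error_anova, "ms_residual")
  df <- attr(error_anova, "df_residual")
  nonsig <- snk_nonsig_matrix(means, n, ms, df, alpha)
  cl <- cld_from_nonsig(means, nonsig)
  out <- data.frame(level = names(means), n = as.vector(n),
                    mean = as.vector(means),
                    letters = vapply(cl, paste, character(1), collapse = ""),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$mean), ]
  rownames(out) <- NULL
  structure(out, class = c("snk_grouping", "data.frame"),
            alpha = alpha, nonsig = nonsig,
            ms_residual = ms, df_residual = df)
}
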