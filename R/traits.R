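#' Percent difference of a test value against a reference
#'
#' `100 * (test - reference) / reference`, the "Difference" convention of
#' cultivar-comparison tables: the second (reference) cultivar's mean is the
#' denominator. Vectorized; exact internally, use [round_half_up()] at 2
#' decimals only for display.
#'
#' @param mean_test Test-cultivar mean(s).
#' @param mean_reference Reference-cultivar mean(s); must be non-zero.
#' @return Percent difference(s).
#' @export
#' @examples
#' percent_difference(105.91, 92.33)   # 14.71 after display rounding
percent_difference <- function(mean_test, mean_reference) {
  stopifnot(is.numeric(mean_test), is.numeric(mean_reference))
  if (any(mean_reference == 0)) stop("reference mean must be non-zero")
  100 * (mean_test - mean_reference) / mean_reference
}

#' Two-sample t-test between cultivar replicate sets
#'
#' Thin wrapper around [stats::t.test()] giving the two-sided pooled-variance
#' test by default (the convention of the comparison tables), with Welch's
#' unequal-variance variant available.
#'
#' @param sample_a,sample_b Replicate values, each of length >= 2.
#' @param variant `"pooled"` (default) or `"welch"`.
#' @return A list with `t_statistic`, `df`, `p_value`, `mean_a`, `mean_b`.
#' @export
t_test_two_sample <- function(sample_a, sample_b,
                              variant = c("pooled", "welch")) {
  variant <- match.arg(variant)
  if (length(sample_a) < 2 || length(sample_b) < 2)
    stop("each sample needs at least 2 values")
  tt <- stats::t.test(sample_a, sample_b, var.equal = variant == "pooled")
  list(t_statistic = unname(tt$statistic), df = unname(tt$parameter),
       p_value = tt$p.value, mean_a = mean(sample_a), mean_b = mean(sample_b))
}

significance_level <- function(p) {
  if (is.na(p)) NA_character_
  else if (p < 0.01) "0.01"
  else if (p < 0.05) "0.05"
  else "ns"
}

#' Replicated trait table constructor
#'
#' Long-format container for field-trial trait observations: one row per
#' cultivar x year x replicate x trait.
#'
#' @param cultivar,year,replicate,trait Identifier vectors (recycled to the
#'   longest length).
#' @param value Observed values.
#' @param unit Unit string per trait (recycled).
#' @return A data frame of class `trait_table`.
#' @export
trait_table <- function(cultivar, year, replicate, trait, value,
                        unit = NA_character_) {
  df <- data.frame(cultivar = as.character(cultivar), year = as.character(year),
                   replicate = as.character(replicate),
                   trait = as.character(trait), value = as.numeric(value),
                   unit = as.character(unit))
  if (any(!is.finite(df$value))) stop("trait values must be finite")
  structure(df, class = c("trait_table", "data.frame"))
}

#' Balanced two-way ANOVA for a trait
#'
#' Classical fixed-effects decomposition of one trait into cultivar (A),
#' year (B), their interaction and error, via [stats::aov()]. The design
#' must be complete and balanced (equal replicates in every cultivar x year
#' cell), in which case the sequential sums of squares equal the classical
#' ones and `SS_total = SS_A + SS_B + SS_AB + SS_E` exactly. Cells with zero
#' within-cell variance everywhere give an undefined F, reported as `NaN`
#' (degenerate), not an error.
#'
#' @param table A [trait_table()].
#' @param trait Trait name to analyse (may be omitted when the table holds a
#'   single trait).
#' @return An object of class `trait_anova`: a data frame with rows
#'   `cultivar`, `year`, `cultivar:year`, `residuals` and columns `ss`, `df`,
#'   `ms`, `f`, `p`, plus attributes `ms_error`, `df_error`, `n_per_cell`
#'   and `cell_means` used by [lsd_groups()].
#' @export
anova_two_way <- function(table, trait = NULL) {
  stopifnot(is.data.frame(table))
  if (!is.null(trait)) table <- table[table$trait == trait, , drop = FALSE]
  if (!nrow(table)) stop("no rows for the requested trait")
  if (length(unique(table$trait)) > 1)
    stop("multiple traits present; pass 'trait'")
  counts <- table(table$cultivar, table$year)
  if (any(counts == 0)) stop("incomplete design: empty cultivar x year cell")
  if (length(unique(c(counts))) != 1)
    stop("unbalanced design: unequal replicates per cell")

  d <- data.frame(cultivar = factor(table$cultivar),
                  year = factor(table$year), value = table$value)
  # a single-level factor degrades to a one-way layout (0-df rows kept)
  form <- if (nlevels(d$year) < 2) value ~ cultivar
          else if (nlevels(d$cultivar) < 2) value ~ year
          else value ~ cultivar * year
  # F columns are recomputed below, so anova.lm's perfect-fit warning is moot
  an <- suppressWarnings(stats::anova(stats::aov(form, data = d)))
  pick <- function(term) {
    i <- match(term, rownames(an))
    if (is.na(i)) c(0, 0) else c(an$`Sum Sq`[i], an$Df[i])
  }
  sdf <- rbind(pick("cultivar"), pick("year"), pick("cultivar:year"),
               c(an$`Sum Sq`[nrow(an)], an$Df[nrow(an)]))
  # clean floating-point dust so the all-zero (degenerate) case is exact
  scale <- mean(d$value^2) + 1
  ss <- ifelse(sdf[, 1] < 1e-20 * scale, 0, sdf[, 1])
  df <- sdf[, 2]
  ms <- ifelse(df > 0, ss / df, NA_real_)
  f <- ms[1:3] / ms[4]          # 0/0 = NaN marks a degenerate table
  p <- ifelse(is.finite(f) & df[1:3] > 0,
              stats::pf(f, df[1:3], df[4], lower.tail = FALSE), NaN)
  out <- data.frame(term = c("cultivar", "year", "cultivar:year", "residuals"),
                    ss = ss, df = df, ms = ms, f = c(f, NA), p = c(p, NA))
  cm <- tapply(d$value, list(d$cultivar, d$year), mean)
  structure(out, class = c("trait_anova", "data.frame"),
            ms_error = out$ms[4], df_error = out$df[4],
            n_per_cell = unname(c(counts)[1]), cell_means = cm,
            trait = if (is.null(trait)) unique(table$trait) else trait)
}

#' @export
print.trait_anova <- function(x, ...) {
  cat(sprintf("Two-way ANOVA (cultivar x year)%s\n",
              if (!is.null(attr(x, "trait"))) paste0(": ", attr(x, "trait"))
              else ""))
  df <- as.data.frame(x)
  df$stars <- ifelse(is.na(df$p), "",
                     ifelse(df$p < 0.01, "**", ifelse(df$p < 0.05, "*", "NS")))
  print(df, row.names = FALSE, digits = 5)
  invisible(x)
}

#' LSD letter groupings of treatment means
#'
#' Fisher's least significant difference applied after an ANOVA:
#' `LSD = t(1 - alpha/2, df_error) * sqrt(2 * ms_error / n)`. Means are
#' sorted descending; every maximal run of means whose extremes differ by
#' less than the LSD shares a letter, letters assigned in order (`a` to the
#' run starting at the largest mean).
#'
#' @param means Named vector of treatment (cell) means.
#' @param ms_error,df_error Error mean square and its degrees of freedom from
#'   the ANOVA.
#' @param n_per_cell Replicates behind each mean.
#' @param alpha Significance level in (0, 1).
#' @return Character vector of letter groups, named like `means` and in the
#'   original order.
#' @export
#' @examples
#' lsd_groups(c(a1 = 10, a2 = 9.5, b1 = 7, b2 = 6.8),
#'            ms_error = 0.18, df_error = 8, n_per_cell = 3)
lsd_groups <- function(means, ms_error, df_error, n_per_cell, alpha = 0.05) {
  if (df_error <= 0) stop("'df_error' must be positive")
  if (alpha <= 0 || alpha >= 1) stop("'alpha' must lie in (0, 1)")
  lsd <- stats::qt(1 - alpha / 2, df_error) * sqrt(2 * ms_error / n_per_cell)
  k <- length(means)
  ord <- order(means, decreasing = TRUE)
  sorted <- means[ord]
  # maximal windows of mutually-indistinguishable means
  runs <- lapply(seq_len(k), function(i) {
    j <- max(which(sorted[i] - sorted < lsd))
    c(i, j)
  })
  runs <- unique(runs)
  keep <- vapply(seq_along(runs), function(r) {
    !any(vapply(runs[-r], function(s)
      s[1] <= runs[[r]][1] && runs[[r]][2] <= s[2], logical(1)))
  }, logical(1))
  runs <- runs[keep]
  lab <- rep("", k)
  for (r in seq_along(runs)) {
    idx <- runs[[r]][1]:runs[[r]][2]
    lab[idx] <- paste0(lab[idx], letters[r])
  }
  out <- character(k)
  out[ord] <- lab
  names(out) <- names(means)
  out
}

#' Harvest index
#'
#' Grain weight as a fraction of total aboveground biomass. Values above 1
#' are physically impossible and flagged with a warning rather than rejected
#' (measurement error happens).
#'
#' @param grain_weight Grain dry weight (g), non-negative.
#' @param aboveground_biomass Total aboveground dry biomass (g), positive.
#' @return Dimensionless ratio.
#' @export
harvest_index <- function(grain_weight, aboveground_biomass) {
  if (any(aboveground_biomass <= 0))
    stop("'aboveground_biomass' must be positive")
  if (any(grain_weight < 0)) stop("'grain_weight' must be non-negative")
  hi <- grain_weight / aboveground_biomass
  if (any(hi > 1)) warning("harvest index > 1: check inputs")
  hi
}

#' Dry-matter partitioning among organs
#'
#' Percentages of aboveground biomass in leaf, sheath, stem and panicle.
#' The panicle share is computed by closure (100 minus the others) so the
#' four ratios sum to exactly 100.
#'
#' @param leaf,sheath,stem,panicle Organ dry weights (g), non-negative, not
#'   all zero.
#' @return Named numeric vector of four percentages summing to 100.
#' @export
#' @examples
#' organ_partition(3, 2, 4, 1)
organ_partition <- function(leaf, sheath, stem, panicle) {
  w <- c(leaf = leaf, sheath = sheath, stem = stem, panicle = panicle)
  if (any(w < 0)) stop("organ weights must be non-negative")
  total <- sum(w)
  if (total <= 0) stop("total biomass must be positive")
  out <- 100 * w / total
  out["panicle"] <- 100 - sum(out[c("leaf", "sheath", "stem")])
  out
}

#' Productive tiller percentage
#'
#' Panicle-bearing tillers at the yellow-ripe stage as a percentage of the
#' maximum tiller number at tillering; values above 100% are flagged.
#'
#' @param panicles Productive panicle count per hill at yellow-ripe stage.
#' @param max_tillers Maximum tiller count per hill at tillering stage (> 0).
#' @return Percentage.
#' @export
productive_tiller_pct <- function(panicles, max_tillers) {
  if (any(max_tillers <= 0)) stop("'max_tillers' must be positive")
  if (any(panicles < 0)) stop("'panicles' must be non-negative")
  pct <- 100 * panicles / max_tillers
  if (any(pct > 100)) warning("productive tiller percentage > 100%")
  pct
}

#' Compare two cultivars for one trait in one year
#'
#' The table row of a cultivar-comparison report: replicate means, percent
#' difference (test vs reference, reference in the denominator), pooled
#' two-sided t-test and significance class. With single-replicate cells the
#' percent difference is still reported but the test is unavailable.
#'
#' @param table A [trait_table()].
#' @param trait Trait name.
#' @param year Year.
#' @param cultivar Test cultivar id.
#' @param reference Reference cultivar id (denominator of the percent
#'   difference).
#' @param variant t-test variant, see [t_test_two_sample()].
#' @return An object of class `cultivar_comparison`: a list with `trait`,
#'   `year`, `mean_a`, `mean_b`, `percent_difference`, `t_statistic`, `df`,
#'   `p_value`, `significant_at`, `n_a`, `n_b`.
#' @export
compare_cultivars <- function(table, trait, year, cultivar, reference,
                              variant = "pooled") {
  stopifnot(is.data.frame(table))
  pick <- function(cv) table$value[table$trait == trait &
                                     table$year == as.character(year) &
                                     table$cultivar == cv]
  a <- pick(cultivar)
  b <- pick(reference)
  if (!length(a) || !length(b))
    stop("missing cultivar x year cell for trait '", trait, "'")
  res <- list(trait = trait, year = as.character(year),
              cultivar = cultivar, reference = reference,
              mean_a = mean(a), mean_b = mean(b),
              percent_difference = percent_difference(mean(a), mean(b)),
              n_a = length(a), n_b = length(b))
  tt <- if (length(a) >= 2 && length(b) >= 2)
    tryCatch(t_test_two_sample(a, b, variant),   # constant data: no test
             error = function(e) NULL) else NULL
  if (!is.null(tt)) {
    res$t_statistic <- tt$t_statistic
    res$df <- tt$df
    res$p_value <- tt$p_value
  } else {
    res$t_statistic <- NA_real_
    res$df <- NA_real_
    res$p_value <- NA_real_
  }
  res$significant_at <- significance_level(res$p_value)
  structure(res, class = "cultivar_comparison")
}

#' @export
print.cultivar_comparison <- function(x, ...) {
  cat(sprintf("%s, %s: %s %.4g vs %s %.4g  (difference %s%%)\n",
              x$trait, x$year, x$cultivar, x$mean_a, x$reference, x$mean_b,
              format(round_half_up(x$percent_difference, 2), nsmall = 2)))
  if (is.na(x$p_value)) cat("  t-test unavailable (single replicate)\n")
  else cat(sprintf("  t = %.4g, df = %g, p = %.4g  [%s]\n", x$t_statistic,
                   x$df, x$p_value, x$significant_at))
  invisible(x)
}
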