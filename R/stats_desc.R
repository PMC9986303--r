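#' Median and interquartile range
#'
#' The `"stata"` convention matches the analysis software of the study:
#' for percentile p with n*p integral, the percentile is the average of
#' order statistics n*p and n*p + 1; otherwise it is order statistic
#' `ceiling(n*p)`.  The `"linear"` convention is R's default
#' linear-interpolation quantile (type 7), provided for comparison.
#'
#' @param values numeric vector (NAs dropped)
#' @param convention `"stata"` or `"linear"`
#' @return named numeric `c(median, q1, q3)`
#' @export
median_iqr <- function(values, convention = c("stata", "linear")) {
  convention <- match.arg(convention)
  x <- sort(values[is.finite(values)])
  if (!length(x)) stop("median_iqr needs at least one finite value")
  if (convention == "linear") {
    q <- stats::quantile(x, c(0.5, 0.25, 0.75), type = 7, names = FALSE)
    return(c(median = q[1L], q1 = q[2L], q3 = q[3L]))
  }
  pct <- function(p) {
    np <- length(x) * p
    if (abs(np - round(np)) < 1e-9) (x[np] + x[min(length(x), np + 1L)]) / 2
    else x[ceiling(np)]
  }
  c(median = pct(0.5), q1 = pct(0.25), q3 = pct(0.75))
}

#' Session and group comparisons
#'
#' Thin, unified front end to the study's univariate tests: a
#' Kruskal-Wallis test across three or more groups, a Mann-Whitney U test
#' (Wilcoxon rank-sum; the reported U statistic is the rank-sum form) for
#' two groups, and a one-way repeated-measures ANOVA with subject as the
#' error stratum.  Asymptotic p-values with tie correction are used for
#' the rank tests (exact where R's defaults allow).
#'
#' @param values numeric outcome vector
#' @param groups group/session factor, same length
#' @param design `"kruskal_wallis"`, `"mann_whitney"` or `"rm_anova"`
#' @param subjects subject factor, required for `"rm_anova"`
#' @return list with `statistic`, `p_value` and `design`
#' @export
compare_sessions <- function(values, groups,
                             design = c("kruskal_wallis", "mann_whitney",
                                        "rm_anova"),
                             subjects = NULL) {
  design <- match.arg(design)
  groups <- factor(groups, levels = unique(groups))  # occurrence order
  if (any(table(groups) == 0L) || nlevels(groups) < 2L)
    stop("each group must be non-empty and there must be at least two")
  if (design == "kruskal_wallis") {
    kt <- stats::kruskal.test(values, groups)
    return(list(statistic = unname(kt$statistic), p_value = kt$p.value,
                design = design))
  }
  if (design == "mann_whitney") {
    if (nlevels(groups) != 2L) stop("mann_whitney needs exactly two groups")
    wt <- stats::wilcox.test(values[groups == levels(groups)[1L]],
                             values[groups == levels(groups)[2L]],
                             exact = NULL)
    return(list(statistic = unname(wt$statistic), p_value = wt$p.value,
                design = design))
  }
  if (is.null(subjects)) stop("rm_anova needs a subjects factor")
  df <- data.frame(y = values, g = groups, s = factor(subjects))
  fit <- stats::aov(y ~ g + Error(s), data = df)
  tab <- summary(fit)[["Error: Within"]][[1L]]
  list(statistic = tab["g", "F value"], p_value = tab["g", "Pr(>F)"],
       design = design)
}

#' Velocity adjustment of a measure by linear regression
#'
#' Regresses a measure on the trial walking speed (one slope across all
#' cells of the analysis set) and replaces each value by its residual
#' plus the grand mean, removing the confounding effect of self-selected
#' walking speed.  With (near-)constant velocity the slope is undefined
#' and the table is returned unadjusted with a warning.
#'
#' @param table an [study_table()]
#' @param measure measure name to adjust
#' @param velocity_measure name of the global velocity measure
#' @return the study table with the measure's rows adjusted; attribute
#'   `"r_squared"` carries the regression fit
#' @export
velocity_adjust <- function(table, measure,
                            velocity_measure = "mean_forward_velocity") {
  df <- as.data.frame(table)
  vel <- df[df$measure == velocity_measure, c("animal", "session", "value")]
  names(vel)[3L] <- "velocity"
  tgt <- df$measure == measure
  if (!any(tgt)) stop("measure ", measure, " not present in table")
  sub <- merge(df[tgt, ], vel, by = c("animal", "session"))
  if (nrow(sub) < 3L) stop("too few matched cells to adjust")
  if (stats::sd(sub$velocity) < 1e-12) {
    warning("velocity is constant; returning unadjusted values")
    attr(table, "r_squared") <- NA_real_
    return(table)
  }
  fit <- stats::lm(value ~ velocity, data = sub)
  sub$adjusted <- stats::residuals(fit) + mean(sub$value)
  key <- paste(df$animal, df$session, df$limb, df$measure, sep = "\r")
  skey <- paste(sub$animal, sub$session, sub$limb, sub$measure, sep = "\r")
  df$value[match(skey, key)] <- sub$adjusted
  out <- study_table(df$animal, df$session, df$limb, df$measure, df$value,
                     df$units)
  attr(out, "r_squared") <- summary(fit)$r.squared
  out
}
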