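#' Pre/post linear mixed model with a random animal effect
#'
#' Fits, by REML, `value ~ time * side + (1 | animal)` to the session
#' means of a limb-pair measure, where `time` is pre (mean of the
#' baseline sessions, one value per animal and side) vs post, and `side`
#' is left vs right.  The time-by-side interaction captures the expected
#' side-dependent effect of the right-sided lesion.  Optionally the
#' session walking velocity enters as a covariate, or a grouping factor
#' (e.g. sex or infarct-size class) replaces time for between-group
#' analyses.  Wald normal-approximation intervals and p-values are
#' reported (a fixed software choice, stated in the output).
#'
#' @param table an [study_table()] in long format
#' @param measure measure name (must exist for both limbs of the pair)
#' @param limbs the limb pair, left then right (default forelimbs)
#' @param baseline_sessions,post_sessions session labels
#' @param adjust_velocity include the global mean forward velocity as a
#'   covariate
#' @param group a named per-animal factor replacing the time term (then
#'   sessions are restricted to `group_sessions`)
#' @param group_sessions sessions used for a group analysis
#' @return object of class `ovigait_lmm`: fixed-effect table, variance
#'   components and per-side post-minus-pre (or between-group) contrasts
#'   with 95% CI and p
#' @export
fit_prepost_lmm <- function(table, measure, limbs = c("FL_L", "FL_R"),
                            baseline_sessions = c("B1", "B2", "B3"),
                            post_sessions = "D3",
                            adjust_velocity = FALSE,
                            group = NULL, group_sessions = post_sessions) {
  df <- as.data.frame(table)
  sub <- df[df$measure == measure & df$limb %in% limbs, ]
  if (!nrow(sub)) stop("measure ", measure, " not found for limbs ",
                       paste(limbs, collapse = ", "))
  sub$side <- factor(ifelse(sub$limb == limbs[1L], "L", "R"),
                     levels = c("L", "R"))
  if (adjust_velocity) {
    vel <- df[df$measure == "mean_forward_velocity",
              c("animal", "session", "value")]
    names(vel)[3L] <- "velocity"
    sub <- merge(sub, vel, by = c("animal", "session"))
  }

  if (is.null(group)) {
    pre <- sub[sub$session %in% baseline_sessions, ]
    post <- sub[sub$session %in% post_sessions, ]
    if (!nrow(pre) || !nrow(post))
      stop("need both baseline and post sessions for a pre/post model")
    agg <- function(d, label) {
      f <- stats::aggregate(value ~ animal + side, d, mean)
      if (adjust_velocity)
        f <- merge(f, stats::aggregate(velocity ~ animal + side, d, mean),
                   by = c("animal", "side"))
      f$time <- label
      f
    }
    dat <- rbind(agg(pre, "pre"), agg(post, "post"))
    dat$time <- factor(dat$time, levels = c("pre", "post"))
    form <- if (adjust_velocity)
      value ~ time * side + velocity + (1 | animal)
    else value ~ time * side + (1 | animal)
    term <- "timepost"
    inter <- "timepost:sideR"
  } else {
    dat <- sub[sub$session %in% group_sessions, ]
    dat <- stats::aggregate(value ~ animal + side, dat, mean)
    if (adjust_velocity) {
      v <- sub[sub$session %in% group_sessions, ]
      dat <- merge(dat, stats::aggregate(velocity ~ animal + side, v, mean),
                   by = c("animal", "side"))
    }
    dat$group <- factor(group[dat$animal])
    if (nlevels(dat$group) != 2L) stop("group must have two levels")
    form <- if (adjust_velocity)
      value ~ group * side + velocity + (1 | animal)
    else value ~ group * side + (1 | animal)
    term <- paste0("group", levels(dat$group)[2L])
    inter <- paste0(term, ":sideR")
  }

  fit <- suppressMessages(lme4::lmer(form, data = dat, REML = TRUE))
  singular <- lme4::isSingular(fit)
  if (singular)
    warning("singular fit: animal variance estimated as zero")
  beta <- lme4::fixef(fit)
  V <- as.matrix(stats::vcov(fit))
  fe <- data.frame(term = names(beta), estimate = unname(beta),
                   se = sqrt(diag(V)))
  fe$ci_low <- fe$estimate - stats::qnorm(0.975) * fe$se
  fe$ci_high <- fe$estimate + stats::qnorm(0.975) * fe$se
  fe$p_value <- 2 * stats::pnorm(-abs(fe$estimate / fe$se))

  contrast <- function(w) {
    est <- sum(w * beta)
    se <- sqrt(drop(t(w) %*% V %*% w))
    c(estimate = est, se = se,
      ci_low = est - stats::qnorm(0.975) * se,
      ci_high = est + stats::qnorm(0.975) * se,
      p_value = 2 * stats::pnorm(-abs(est / se)))
  }
  wL <- stats::setNames(rep(0, length(beta)), names(beta)); wL[term] <- 1
  wR <- wL; wR[inter] <- 1
  contrasts <- rbind(L = contrast(wL), R = contrast(wR))

  vc <- as.data.frame(lme4::VarCorr(fit))
  structure(list(
    fixed = fe,
    contrasts = as.data.frame(contrasts),
    var_animal = vc$vcov[vc$grp == "animal"],
    var_residual = vc$vcov[vc$grp == "Residual"],
    singular = singular, measure = measure, limbs = limbs,
    adjust_velocity = adjust_velocity,
    group_analysis = !is.null(group),
    inference = "Wald normal approximation",
    fit = fit),
    class = "ovigait_lmm")
}

#' @export
print.ovigait_lmm <- function(x, ...) {
  kind <- if (x$group_analysis) "between-group" else "post - pre"
  cat(sprintf("Linear mixed model for %s (%s%s)\n", x$measure,
              paste(x$limbs, collapse = "/"),
              if (x$adjust_velocity) ", velocity-adjusted" else ""))
  cat(sprintf("  random animal intercept variance %.4g, residual %.4g%s\n",
              x$var_animal, x$var_residual,
              if (x$singular) " (singular fit)" else ""))
  cat(sprintf("  %s contrasts:\n", kind))
  print(round(x$contrasts, 4))
  invisible(x)
}
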