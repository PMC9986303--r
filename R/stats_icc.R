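#' Intraclass correlation ICC(A,k): absolute agreement, mean of k ratings
#'
#' Repeatability of a measure across the k repeated sessions, from the
#' two-way (subject x session) mean-squares decomposition under the
#' absolute-agreement, mean-rating, two-way mixed-effects definition:
#'
#'   ICC(A,k) = (MSR - MSE) / (MSR + (MSC - MSE) / n)
#'
#' with MSR the between-subject, MSC the between-rater and MSE the
#' residual mean square.  Parametric confidence limits follow the
#' F-based single-rating bounds mapped through the Spearman-Brown
#' relation; bootstrap limits resample subjects with replacement
#' (percentile method, seeded).
#'
#' @param data numeric matrix, subjects x raters (sessions); rows with
#'   missing cells are dropped with a warning
#' @param ci_method `"parametric"` or `"bootstrap"`
#' @param n_boot bootstrap resamples
#' @param seed RNG seed for the bootstrap
#' @param conf confidence level
#' @return object of class `ovigait_icc` with `icc`, `ci_low`, `ci_high`,
#'   `method`, `n_subjects`, `k_raters` and the mean squares
#' @export
icc_ak <- function(data, ci_method = c("parametric", "bootstrap"),
                   n_boot = 2000, seed = 1L, conf = 0.95) {
  ci_method <- match.arg(ci_method)
  x <- as.matrix(data)
  keep <- stats::complete.cases(x)
  if (!all(keep)) {
    warning(sum(!keep), " subject(s) with missing cells dropped")
    x <- x[keep, , drop = FALSE]
  }
  n <- nrow(x); k <- ncol(x)
  if (k < 2L) stop("need at least 2 raters/sessions")
  if (n < 3L) stop("need at least 3 subjects")
  ms <- icc_mean_squares(x)
  if (ms$MSR < 1e-300 && ms$MSE < 1e-300)
    stop("zero between-subject and error variance; ICC undefined")
  icc <- icc_from_ms(ms, n, k)

  alpha <- 1 - conf
  if (ci_method == "parametric") {
    ci <- icc_parametric_ci(ms, n, k, alpha)
  } else {
    old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
    on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
    set.seed(seed)
    boots <- vapply(seq_len(n_boot), function(i) {
      xb <- x[sample.int(n, n, replace = TRUE), , drop = FALSE]
      msb <- icc_mean_squares(xb)
      icc_from_ms(msb, n, k)
    }, 0)
    boots <- boots[is.finite(boots)]
    q <- stats::quantile(boots, c(alpha / 2, 1 - alpha / 2), names = FALSE)
    # percentile interval, widened if needed to contain the point estimate
    ci <- c(min(q[1L], icc), max(q[2L], icc))
  }
  structure(list(icc = icc, ci_low = ci[1L], ci_high = ci[2L],
                 method = ci_method, n_subjects = n, k_raters = k,
                 mean_squares = ms, conf = conf),
            class = "ovigait_icc")
}

icc_mean_squares <- function(x) {
  n <- nrow(x); k <- ncol(x)
  g <- mean(x)
  rm_ <- rowMeans(x); cm <- colMeans(x)
  SSR <- k * sum((rm_ - g)^2)
  SSC <- n * sum((cm - g)^2)
  SST <- sum((x - g)^2)
  SSE <- SST - SSR - SSC
  list(MSR = SSR / (n - 1), MSC = SSC / (k - 1),
       MSE = SSE / ((n - 1) * (k - 1)))
}

icc_from_ms <- function(ms, n, k) {
  (ms$MSR - ms$MSE) / (ms$MSR + (ms$MSC - ms$MSE) / n)
}

# F-based limits for ICC(A,1), mapped to (A,k) via Spearman-Brown
icc_parametric_ci <- function(ms, n, k, alpha) {
  MSR <- ms$MSR; MSC <- ms$MSC; MSE <- ms$MSE
  icc1 <- (MSR - MSE) / (MSR + (k - 1) * MSE + k * (MSC - MSE) / n)
  a <- k * icc1 / (n * (1 - icc1))
  b <- 1 + k * icc1 * (n - 1) / (n * (1 - icc1))
  v <- (a * MSC + b * MSE)^2 /
    ((a * MSC)^2 / (k - 1) + (b * MSE)^2 / ((n - 1) * (k - 1)))
  FL <- stats::qf(1 - alpha / 2, n - 1, v)
  FU <- stats::qf(1 - alpha / 2, v, n - 1)
  low1 <- n * (MSR - FL * MSE) /
    (FL * (k * MSC + (k * n - k - n) * MSE) + n * MSR)
  up1 <- n * (FU * MSR - MSE) /
    (k * MSC + (k * n - k - n) * MSE + n * FU * MSR)
  sb <- function(r) k * r / (1 + (k - 1) * r)
  c(sb(low1), sb(up1))
}

#' @export
print.ovigait_icc <- function(x, ...) {
  cat(sprintf("ICC(A,%d) = %.3f, %d%% CI [%.3f, %.3f] (%s; n = %d subjects)\n",
              x$k_raters, x$icc, round(100 * x$conf), x$ci_low, x$ci_high,
              x$method, x$n_subjects))
  invisible(x)
}

#' Population ICC(A,k) from variance components
#'
#' Closed form `sigma_r^2 / (sigma_r^2 + (sigma_c^2 + sigma_e^2) / k)`
#' used as the simulation oracle for the estimator.
#'
#' @param sigma_subject,sigma_rater,sigma_error component SDs
#' @param k number of ratings averaged
#' @export
icc_ak_population <- function(sigma_subject, sigma_rater, sigma_error, k) {
  s2 <- sigma_subject^2
  s2 / (s2 + (sigma_rater^2 + sigma_error^2) / k)
}

#' ICC of one measure across baseline sessions of a study table
#'
#' Reshapes a long study table into the subjects x sessions matrix for
#' one (measure, limb) and computes [icc_ak()].
#'
#' @param table an [study_table()]
#' @param measure measure name
#' @param limb limb id or `"global"`
#' @param sessions session labels used as raters
#' @param ... passed to [icc_ak()]
#' @export
session_icc <- function(table, measure, limb = "global",
                        sessions = c("B1", "B2", "B3"), ...) {
  df <- as.data.frame(table)
  df <- df[df$measure == measure & df$limb == limb &
             df$session %in% sessions, ]
  if (!nrow(df)) stop("no rows for measure ", measure, ", limb ", limb)
  wide <- stats::reshape(df[c("animal", "session", "value")],
                         idvar = "animal", timevar = "session",
                         direction = "wide")
  m <- as.matrix(wide[, -1L, drop = FALSE])
  rownames(m) <- wide$animal
  icc_ak(m, ...)
}
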