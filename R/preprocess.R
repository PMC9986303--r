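#' Low-pass filter specification
#'
#' The trajectory conditioning convention is a fourth-order low-pass
#' Butterworth filter with a 10 Hz cut-off, applied forward and backward
#' (zero net phase).  The cut-off is specified as the single-pass -3 dB
#' point; the combined forward-backward response is the squared magnitude,
#' so the effective -3 dB point of the two-pass filter is slightly lower
#' (about 8.0 Hz for a 4th-order design) — this matches common biomechanics
#' practice, where the design cut-off is quoted per pass.
#'
#' @param order filter order (even, >= 2)
#' @param cutoff single-pass -3 dB cut-off in Hz
#' @param zero_lag apply forward-backward (default) or single pass
#' @return object of class `filter_spec`
#' @export
filter_spec <- function(order = 4, cutoff = 10, zero_lag = TRUE) {
  if (order < 2 || order %% 2 != 0) stop("filter order must be even and >= 2")
  if (cutoff <= 0) stop("cutoff must be positive")
  structure(list(order = order, cutoff = cutoff, zero_lag = zero_lag),
            class = "filter_spec")
}

# direct-form II transposed IIR with explicit initial state
iir_filter <- function(b, a, x, zi = NULL) {
  nb <- length(b); na <- length(a)
  m <- max(nb, na) - 1L
  b <- c(b, rep(0, m + 1L - nb))
  a <- c(a, rep(0, m + 1L - na))
  z <- if (is.null(zi)) rep(0, m) else zi
  y <- numeric(length(x))
  for (i in seq_along(x)) {
    y[i] <- b[1L] * x[i] + z[1L]
    if (m > 1L)
      for (j in 1:(m - 1L))
        z[j] <- b[j + 1L] * x[i] + z[j + 1L] - a[j + 1L] * y[i]
    z[m] <- b[m + 1L] * x[i] - a[m + 1L] * y[i]
  }
  y
}

# steady-state filter delays for a unit step (scaled by the first sample
# before filtering) so a constant signal passes through exactly
iir_steady_state <- function(b, a) {
  m <- max(length(b), length(a)) - 1L
  b <- c(b, rep(0, m + 1L - length(b)))
  a <- c(a, rep(0, m + 1L - length(a)))
  A <- diag(m)
  comp <- rbind(-a[-1L], cbind(diag(m - 1L), 0))
  B <- b[-1L] - a[-1L] * b[1L]
  solve(A - t(comp), B)
}

zero_lag_filter <- function(x, b, a, order) {
  n <- length(x)
  pad <- 3L * order
  if (n <= pad) stop("signal too short for the reflective padding (needs > ",
                     pad, " frames)")
  # odd (point) reflection about the end samples
  xp <- c(2 * x[1L] - x[(pad + 1L):2L], x, 2 * x[n] - x[(n - 1L):(n - pad)])
  zi <- iir_steady_state(b, a)
  y <- iir_filter(b, a, xp, zi * xp[1L])
  y <- rev(iir_filter(b, a, rev(y), zi * y[length(y)]))
  y[(pad + 1L):(pad + n)]
}

#' Low-pass filter a marker trajectory
#'
#' Each coordinate is filtered with the Butterworth design of `spec`; with
#' `zero_lag` the filter is run forward then backward so the pass band has
#' zero net phase.  Endpoints are handled by odd-reflection padding of
#' `3 * order` samples with steady-state initial conditions, so constant
#' signals are reproduced exactly.
#'
#' @param traj a [marker_trajectory()] with no occluded frames (fill first)
#' @param spec a [filter_spec()]
#' @param sample_rate sampling rate, Hz
#' @return filtered `marker_trajectory`
#' @export
lowpass <- function(traj, spec = filter_spec(), sample_rate) {
  if (any(traj$occluded))
    stop("trajectory still has occluded frames; run fill_gaps() first")
  if (spec$cutoff >= sample_rate / 2)
    stop("cutoff must be below the Nyquist frequency")
  n <- nrow(traj$positions)
  if (n < 3L * spec$order + 1L)
    stop("need more than ", 3L * spec$order, " frames to filter")
  bf <- signal::butter(spec$order, spec$cutoff / (sample_rate / 2), "low")
  pos <- traj$positions
  for (j in 1:3) {
    pos[, j] <- if (spec$zero_lag) {
      zero_lag_filter(pos[, j], bf$b, bf$a, spec$order)
    } else {
      pad <- 3L * spec$order
      x <- pos[, j]
      xp <- c(2 * x[1L] - x[(pad + 1L):2L], x)
      zi <- iir_steady_state(bf$b, bf$a)
      iir_filter(bf$b, bf$a, xp, zi * xp[1L])[(pad + 1L):(pad + n)]
    }
  }
  marker_trajectory(traj$label, pos, occluded = rep(FALSE, n))
}

#' Fill occlusion gaps in a marker trajectory
#'
#' Occluded runs no longer than `max_gap` frames are replaced; longer runs
#' are left occluded and reported.  Two methods are provided.  `"spline"`
#' interpolates each coordinate with a cubic spline through the
#' non-occluded frames.  `"cyclic"` copies the displacement pattern of the
#' corresponding phase one period away (or of a donor marker), linearly
#' offset-matched at the gap edges so the fill joins the observed frames
#' continuously; the period is estimated from the autocorrelation of the
#' observed signal unless a donor is given.
#'
#' @param traj a [marker_trajectory()]
#' @param method `"spline"` or `"cyclic"`
#' @param max_gap longest run, in frames, that will be filled (default 20,
#'   i.e. 0.1 s at 200 Hz)
#' @param donor optional complete `marker_trajectory` whose shape is copied
#'   by the cyclic method
#' @return a `marker_trajectory`; attribute `"unfilled"` lists any runs
#'   left occluded as a two-column matrix of start/end frames
#' @export
fill_gaps <- function(traj, method = c("spline", "cyclic"), max_gap = 20,
                      donor = NULL) {
  method <- match.arg(method)
  occ <- traj$occluded
  if (all(occ)) stop("trajectory is entirely occluded and cannot be filled")
  if (sum(!occ) < 2L) stop("need at least 2 non-occluded frames")
  pos <- traj$positions
  n <- nrow(pos)
  runs <- occlusion_runs(occ)
  unfilled <- NULL
  for (k in seq_len(nrow(runs))) {
    s <- runs[k, 1L]; e <- runs[k, 2L]
    if (e - s + 1L > max_gap) { unfilled <- rbind(unfilled, runs[k, ]); next }
    idx <- s:e
    if (method == "spline") {
      good <- which(!occ)
      for (j in 1:3)
        pos[idx, j] <- stats::spline(good, pos[good, j], xout = idx,
                                     method = "natural")$y
    } else {
      pos[idx, ] <- cyclic_fill(pos, occ, s, e, donor)
    }
    occ[idx] <- FALSE
  }
  out <- marker_trajectory(traj$label, pos, occluded = occ)
  attr(out, "unfilled") <- unfilled
  out
}

occlusion_runs <- function(occ) {
  r <- rle(occ)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  cbind(start = starts[r$values], end = ends[r$values])
}

# phase-matched pattern copy: values one period away, plus a linear offset
# correction so the fill meets the flanking observed frames
cyclic_fill <- function(pos, occ, s, e, donor = NULL) {
  n <- nrow(pos)
  idx <- s:e
  if (!is.null(donor)) {
    src <- donor$positions
    if (nrow(src) != n) stop("donor trajectory frame count mismatch")
    ref <- idx
  } else {
    period <- estimate_period(pos, occ)
    if (is.na(period))
      stop("cyclic fill needs a donor or >= 2 complete cycles flanking the gap")
    ref <- if (s - period >= 1L && !any(occ[idx - period])) idx - period
           else if (e + period <= n && !any(occ[idx + period])) idx + period
           else stop("no complete cycle flanks the gap at the estimated period (",
                     period, " frames)")
    src <- pos
  }
  lo <- s - 1L; hi <- e + 1L
  filled <- src[ref, , drop = FALSE]
  # offsets that the copy must absorb at each edge
  d_lo <- if (lo >= 1L && !occ[lo]) pos[lo, ] - src[ref[1L] - (idx[1L] - lo), ]
          else c(0, 0, 0)
  d_hi <- if (hi <= n && !occ[hi]) pos[hi, ] - src[ref[length(ref)] + (hi - idx[length(idx)]), ]
          else d_lo
  if (lo < 1L || occ[lo]) d_lo <- d_hi
  w <- if (length(idx) == 1L) 0.5 else (seq_along(idx) - 1) / (length(idx) - 1)
  filled + outer(1 - w, d_lo) + outer(w, d_hi)
}

# dominant period (frames) of the observed part of the signal, from the
# first prominent autocorrelation peak of the detrended z coordinate
estimate_period <- function(pos, occ) {
  x <- pos[, 3L]
  x[occ] <- NA
  good <- which(!occ)
  x[occ] <- stats::approx(good, pos[good, 3L], xout = which(occ), rule = 2)$y
  x <- x - mean(x)
  if (stats::sd(x) == 0) {
    x <- pos[, 2L]; x[occ] <- stats::approx(good, pos[good, 2L],
                                            xout = which(occ), rule = 2)$y
    x <- stats::residuals(stats::lm(x ~ seq_along(x)))
  }
  n <- length(x)
  maxlag <- floor(n / 2)
  ac <- stats::acf(x, lag.max = maxlag, plot = FALSE, demean = TRUE)$acf[-1L]
  # first local maximum above 0.2 after the initial decay
  cand <- which(diff(sign(diff(ac))) == -2) + 1L
  cand <- cand[ac[cand] > 0.2]
  if (!length(cand)) return(NA_integer_)
  as.integer(cand[1L])
}

#' Differentiate a marker trajectory
#'
#' Central differences at interior frames, one-sided at the ends, with
#' millimetre positions converted to metres per second.
#'
#' @param traj a [marker_trajectory()] with no occluded frames
#' @param sample_rate sampling rate, Hz
#' @return n x 3 matrix of velocities (m/s), columns x, y, z
#' @export
differentiate <- function(traj, sample_rate) {
  if (any(traj$occluded)) stop("cannot differentiate across occluded frames")
  pos <- traj$positions / 1000          # mm -> m
  n <- nrow(pos)
  if (n < 2L) stop("need at least 2 frames to differentiate")
  v <- matrix(0, n, 3L, dimnames = list(NULL, c("x", "y", "z")))
  v[1L, ] <- (pos[2L, ] - pos[1L, ]) * sample_rate
  v[n, ] <- (pos[n, ] - pos[n - 1L, ]) * sample_rate
  if (n > 2L)
    v[2:(n - 1L), ] <- (pos[3:n, ] - pos[1:(n - 2L), ]) * (sample_rate / 2)
  v
}

#' Condition every marker of a trial
#'
#' Fills occlusion gaps (spline method) and applies the zero-lag low-pass
#' filter to every marker.  Trials whose gaps exceed `max_gap` frames are
#' flagged via the returned attribute `"unfilled"`.
#'
#' @param trial an `ovigait_trial`
#' @param spec a [filter_spec()]
#' @param max_gap longest fillable occlusion run, frames
#' @return the conditioned trial; attribute `"unfilled"` names markers with
#'   remaining gaps
#' @export
preprocess_trial <- function(trial, spec = filter_spec(), max_gap = 20) {
  flagged <- character(0)
  trial$markers <- lapply(trial$markers, function(m) {
    if (any(m$occluded)) {
      m <- fill_gaps(m, "spline", max_gap = max_gap)
      if (!is.null(attr(m, "unfilled"))) {
        flagged <<- c(flagged, m$label)
        return(m)                      # cannot filter across remaining gaps
      }
    }
    lowpass(m, spec, trial$sample_rate)
  })
  attr(trial, "unfilled") <- flagged
  trial
}
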