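# shared builders for constructed fixtures (generated in code, never stored)

# straight-line constant-velocity trajectory, mm
linear_traj <- function(label = "T1", n = 100, slope = c(0, 1, 0),
                        start = c(0, 0, 500)) {
  pos <- outer(0:(n - 1), slope) + matrix(start, n, 3, byrow = TRUE)
  marker_trajectory(label, pos)
}

# static trial with HEAD/T1/T13/L7 at fixed offsets (cm arguments)
static_global_trial <- function(n = 60, head_up_cm = 10, head_right_cm = 0) {
  at <- function(label, x, y, z)
    marker_trajectory(label, matrix(c(x, y, z), n, 3, byrow = TRUE))
  trial(list(
    HEAD = at("HEAD", head_right_cm * 10, 150, 800 + head_up_cm * 10),
    T1 = at("T1", 0, 0, 800),
    T13 = at("T13", 0, -300, 740),
    L7 = at("L7", 0, -550, 700)),
    sample_rate = 200)
}

# forelimb fetlock chain with a prescribed distal rotation (degrees);
# proximal segment METAR->PPHAL points straight down
fetlock_trial <- function(angle_deg, n = 10, limb = "FL_L") {
  rot <- function(v, deg) {
    th <- deg * pi / 180
    c(v[1] * cos(th) - v[2] * sin(th), v[1] * sin(th) + v[2] * cos(th))
  }
  u_prox <- c(0, -1)                      # (y, z): straight down
  u_dist <- rot(u_prox, angle_deg)
  metar <- c(0, 0, 200)
  pphal <- metar + c(0, 80 * u_prox[1], 80 * u_prox[2])
  phal <- pphal + c(0, 40 * u_dist[1], 40 * u_dist[2])
  at <- function(label, p)
    marker_trajectory(label, matrix(p, n, 3, byrow = TRUE))
  trial(stats::setNames(list(
    at(paste0("METAR_", limb), metar),
    at(paste0("PPHAL_", limb), pphal),
    at(paste0("PHAL_", limb), phal)),
    paste0(c("METAR_", "PPHAL_", "PHAL_"), limb)),
    sample_rate = 200)
}

# square-wave sagittal speed profile: `low_s` seconds at 0 then `high_s`
# seconds at `high` m/s, repeated; returns an n x 3 velocity matrix
square_speed <- function(low_s, high_s, n_cycles = 3, high = 0.5, fs = 200) {
  lo <- round(low_s * fs); hi <- round(high_s * fs)
  vy <- rep(c(rep(0, lo), rep(high, hi)), n_cycles)
  cbind(x = 0 * vy, y = vy, z = 0 * vy)
}

# all-zero neurological score sheet for one animal-session
zero_sheet <- function(animal = "A1", session = "B1") {
  rub <- neuro_rubric()
  rows <- list()
  for (cr in rub)
    for (cp in ovigait:::criterion_components(cr))
      rows[[length(rows) + 1]] <- data.frame(
        animal = animal, session = session, criterion = cr$id,
        component = cp, value = 0)
  do.call(rbind, rows)
}

sheet_set <- function(sheet, criterion, component, value) {
  i <- sheet$criterion == criterion & sheet$component == component
  stopifnot(sum(i) == 1)
  sheet$value[i] <- value
  sheet
}

# independent mean-squares oracle for the two-way ICC decomposition,
# via R's linear-model machinery rather than the package's own sums
anova_mean_squares <- function(x) {
  d <- data.frame(y = as.vector(x),
                  subj = factor(rep(seq_len(nrow(x)), ncol(x))),
                  rater = factor(rep(seq_len(ncol(x)), each = nrow(x))))
  tab <- anova(stats::lm(y ~ subj + rater, data = d))
  list(MSR = tab["subj", "Mean Sq"], MSC = tab["rater", "Mean Sq"],
       MSE = tab["Residuals", "Mean Sq"])
}

# brute-force order-statistic percentile under the Stata convention
stata_pct_oracle <- function(x, p) {
  x <- sort(x); n <- length(x); np <- n * p
  if (abs(np - round(np)) < 1e-9) (x[np] + x[np + 1]) / 2 else x[ceiling(np)]
}
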