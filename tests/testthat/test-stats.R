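test_that("Stata-convention quartiles match the order-statistic oracle", {
  set.seed(10)
  for (n in c(5, 8, 12, 20, 33)) {
    x <- round(rnorm(n, 10, 4), 2)
    got <- median_iqr(x)
    expect_equal(unname(got["median"]), stata_pct_oracle(x, 0.5))
    expect_equal(unname(got["q1"]), stata_pct_oracle(x, 0.25))
    expect_equal(unname(got["q3"]), stata_pct_oracle(x, 0.75))
  }
  expect_equal(unname(median_iqr(5)), c(5, 5, 5))
  expect_error(median_iqr(numeric(0)), "at least one")
  # the linear variant differs from the Stata one where n*p is non-integral
  x <- 1:8
  expect_false(isTRUE(all.equal(median_iqr(x, "stata")[["q1"]],
                                median_iqr(x, "linear")[["q1"]])))
})

test_that("infarct volumes of the shipped cohort reproduce the printed summary", {
  iv <- poststroke_pca_table()$infarct_volume_cm3
  expect_length(iv, 20)
  q <- median_iqr(iv, "stata")
  expect_equal(unname(round(q, 1)), c(2.7, 1.4, 11.9))
})

test_that("session comparison tests wrap the standard machinery", {
  # identical groups cannot be distinguished
  v <- rep(c(1, 2, 3, 4), 3)
  g <- rep(c("B1", "B2", "B3"), each = 4)
  kw <- compare_sessions(v, g, "kruskal_wallis")
  expect_gte(kw$p_value, 0.99)

  # complete separation gives U = 0 for the lower group listed second
  mw <- compare_sessions(c(1, 2, 3, 10, 11, 12),
                         rep(c("b", "a"), each = 3), "mann_whitney")
  expect_equal(unname(mw$statistic), 0)

  # Kruskal-Wallis H equals the explicit rank-sum computation
  set.seed(2)
  v <- rnorm(18); g <- rep(c("B1", "B2", "B3"), each = 6)
  kw <- compare_sessions(v, g, "kruskal_wallis")
  r <- rank(v); n <- length(v)
  H <- 12 / (n * (n + 1)) *
    sum(tapply(r, g, function(z) sum(z)^2 / length(z))) - 3 * (n + 1)
  expect_equal(unname(kw$statistic), H, tolerance = 1e-10)

  # repeated-measures ANOVA runs with a subject stratum
  subj <- rep(1:6, 3)
  rm <- compare_sessions(v, g, "rm_anova", subjects = subj)
  expect_true(is.finite(rm$statistic) && rm$p_value >= 0 && rm$p_value <= 1)
  expect_error(compare_sessions(v, g, "rm_anova"), "subjects")
  expect_error(compare_sessions(1:3, c("a", "a", "a")), "at least two")
})

test_that("velocity adjustment removes a linear speed confound", {
  animals <- sprintf("A%02d", 1:12)
  vel <- seq(0.8, 1.6, length.out = 12)
  measure <- 1 - 0.4 * vel                    # perfectly linear in velocity
  tab <- study_table(
    c(animals, animals), rep("B1", 24), rep(c("global", "FL_L"), each = 12),
    rep(c("mean_forward_velocity", "stance_duration"), each = 12),
    c(vel, measure), rep(c("m/s", "s"), each = 12))
  adj <- suppressWarnings(velocity_adjust(tab, "stance_duration"))
  a <- adj$value[adj$measure == "stance_duration"]
  expect_equal(a, rep(mean(measure), 12), tolerance = 1e-9)
  expect_equal(attr(adj, "r_squared"), 1)

  # independent measure: essentially unchanged, r^2 ~ 0
  set.seed(5)
  indep <- rnorm(12, 0.4, 0.02)
  tab2 <- study_table(
    c(animals, animals), rep("B1", 24), rep(c("global", "FL_L"), each = 12),
    rep(c("mean_forward_velocity", "stance_duration"), each = 12),
    c(vel, indep), rep(c("m/s", "s"), each = 12))
  adj2 <- velocity_adjust(tab2, "stance_duration")
  expect_lt(attr(adj2, "r_squared"), 0.3)
  expect_equal(adj2$value[adj2$measure == "stance_duration"], indep,
               tolerance = 0.05)

  # constant velocity: unadjusted with a warning
  tab3 <- study_table(
    c(animals, animals), rep("B1", 24), rep(c("global", "FL_L"), each = 12),
    rep(c("mean_forward_velocity", "stance_duration"), each = 12),
    c(rep(1, 12), indep), rep(c("m/s", "s"), each = 12))
  expect_warning(adj3 <- velocity_adjust(tab3, "stance_duration"), "constant")
  expect_equal(adj3$value, tab3$value)
})

test_that("velocity adjustment raises repeatability of speed-driven measures", {
  # stride duration = a - b * velocity + noise; velocity varies within
  # animal across sessions, so adjusting removes session-level noise
  reps <- 50
  better <- logical(reps)
  for (r in seq_len(reps)) {
    set.seed(100 + r)
    n <- 24
    trait <- rnorm(n, 0.77, 0.04)             # animal-intrinsic duration
    rows <- list()
    for (s in c("B1", "B2", "B3")) {
      vel <- rnorm(n, 1.28, 0.15)             # self-selected session speed
      dur <- trait - 0.35 * (vel - 1.28) + rnorm(n, 0, 0.01)
      rows[[length(rows) + 1]] <- data.frame(
        animal = sprintf("A%02d", 1:n), session = s,
        limb = "global", measure = "mean_forward_velocity", value = vel,
        units = "m/s")
      rows[[length(rows) + 1]] <- data.frame(
        animal = sprintf("A%02d", 1:n), session = s,
        limb = "FL_L", measure = "stride_duration", value = dur, units = "s")
    }
    df <- do.call(rbind, rows)
    tab <- study_table(df$animal, df$session, df$limb, df$measure, df$value,
                       df$units)
    un <- session_icc(tab, "stride_duration", "FL_L")
    ad <- session_icc(velocity_adjust(tab, "stride_duration"),
                      "stride_duration", "FL_L")
    better[r] <- ad$icc >= un$icc
  }
  expect_gte(mean(better), 0.9)
})

test_that("correlation pruning removes the more redundant variable", {
  set.seed(3)
  z <- rnorm(50)
  dup <- data.frame(a = z, b = z)
  out <- prune_correlated(dup)
  expect_length(out$retained, 1)

  ortho <- data.frame(a = rnorm(50), b = rnorm(50), c = rnorm(50))
  expect_equal(prune_correlated(ortho)$retained, c("a", "b", "c"))

  # x2 correlates with both x1 (r > 0.85) and x3: x2 has the larger mean
  # absolute correlation, so it is the one removed
  x1 <- rnorm(200)
  x3 <- rnorm(200)
  x2 <- 0.95 * x1 + 0.25 * x3 + 0.05 * rnorm(200)
  out3 <- prune_correlated(data.frame(x1 = x1, x2 = x2, x3 = x3))
  expect_equal(out3$log$removed, "x2")
  expect_setequal(out3$retained, c("x1", "x3"))
})

test_that("KMO follows its closed forms and conventions", {
  expect_warning(k0 <- kmo(diag(3)), "no common variance")
  expect_equal(k0$overall, 0)
  expect_equal(unname(k0$per_variable), c(0, 0, 0))

  # two variables: the partial correlation equals the correlation, so
  # every KMO is exactly 1/2 whatever r is
  for (r in c(0.2, 0.5, 0.8)) {
    R <- matrix(c(1, r, r, 1), 2)
    k <- kmo(R)
    expect_equal(k$overall, 0.5, tolerance = 1e-12)
    expect_equal(unname(k$per_variable), c(0.5, 0.5))
  }

  sing <- matrix(1, 3, 3)
  expect_error(kmo(sing), "singular")
})

test_that("iterative KMO screening drops the weakest variable first", {
  set.seed(8)
  f <- rnorm(80)
  x <- data.frame(a = f + rnorm(80, 0, 0.5), b = f + rnorm(80, 0, 0.5),
                  c = f + rnorm(80, 0, 0.5), junk = rnorm(80))
  sc <- kmo_screen(x, min_kmo = 0.5)
  expect_false("junk" %in% sc$retained)
  expect_true(all(c("a", "b", "c") %in% sc$retained))
  expect_equal(sc$log$removed[1], "junk")
})

test_that("Bartlett sphericity matches its closed form and limits", {
  b0 <- bartlett_sphericity(diag(4), 20)
  expect_equal(b0$chi2, 0)
  expect_equal(b0$p_value, 1)
  expect_equal(b0$df, 6)

  # strictly increasing in |r| for a 2-variable family
  chis <- vapply(c(0.1, 0.3, 0.5, 0.7),
                 function(r) bartlett_sphericity(
                   matrix(c(1, r, r, 1), 2), 15)$chi2, 0)
  expect_true(all(diff(chis) > 0))

  # closed form against an independently computed determinant
  r <- 0.2063202                              # makes det close to 0.5
  R <- matrix(r, 3, 3); diag(R) <- 1
  d <- prod(eigen(R, symmetric = TRUE, only.values = TRUE)$values)
  b <- bartlett_sphericity(R, 10)
  expect_equal(b$chi2, -(10 - 1 - 11 / 6) * log(d), tolerance = 1e-10)
  expect_error(bartlett_sphericity(diag(5), 4), "more observations")
})

test_that("correlation PCA matches an independent eigendecomposition", {
  set.seed(21)
  x <- as.data.frame(matrix(rnorm(200), 25, 8))
  p <- pca_correlation(x)
  pr <- prcomp(x, center = TRUE, scale. = TRUE)
  expect_equal(p$eigenvalues, unname(pr$sdev^2), tolerance = 1e-9)
  for (j in 1:8) {
    a <- p$loadings[, j]; b <- pr$rotation[, j]
    expect_lt(min(max(abs(a - b)), max(abs(a + b))), 1e-9)
  }
  # eigenvalues sum to p; loadings orthonormal
  expect_equal(sum(p$eigenvalues), 8, tolerance = 1e-9)
  expect_equal(crossprod(p$loadings), diag(8), tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_equal(p$pct_variance, p$eigenvalues / 8 * 100)
})

test_that("PCA is invariant to observation order and variable rescaling", {
  set.seed(22)
  x <- as.data.frame(matrix(rnorm(120), 30, 4))
  names(x) <- letters[1:4]
  p1 <- pca_correlation(x, sign_anchor = "a")
  p2 <- pca_correlation(x[sample.int(30), ], sign_anchor = "a")
  expect_equal(p2$eigenvalues, p1$eigenvalues, tolerance = 1e-9)
  expect_equal(p2$loadings, p1$loadings, tolerance = 1e-9)
  x3 <- x; x3$b <- 1000 * x3$b - 7            # affine rescale
  p3 <- pca_correlation(x3, sign_anchor = "a")
  expect_equal(p3$eigenvalues, p1$eigenvalues, tolerance = 1e-9)
  expect_equal(abs(p3$loadings), abs(p1$loadings), tolerance = 1e-9)
})

test_that("two perfectly correlated variables collapse onto one component", {
  z <- rnorm(30)
  p <- pca_correlation(data.frame(a = z, b = 2 * z + 1))
  expect_equal(p$eigenvalues, c(2, 0), tolerance = 1e-12)
  expect_equal(p$pct_variance[1], 100)
  expect_equal(p$n_components, 1)
  expect_error(pca_correlation(data.frame(a = c(1, NA, 3), b = c(1, 2, 3))),
               "missing")
  expect_error(pca_correlation(data.frame(a = 1:5)), "at least 2")
})

test_that("PC1 sign is anchored to the requested variable", {
  x <- poststroke_pca_table(); x$animal <- NULL
  p <- pca_correlation(x, sign_anchor = "total_neuroscore")
  expect_gt(p$loadings["total_neuroscore", 1], 0)
  expect_error(pca_correlation(x, sign_anchor = "nope"), "not a variable")
})
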