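#' Study run configuration
#'
#' Assembles the configuration of a full study run: either a simulation
#' layout (cohort size, sessions, design, stroke effect, noise) or a
#' directory of trial files, plus the processing settings and the
#' statistics plan.  Any field can be overridden; the defaults reproduce
#' the study conditions (three baselines and one 3-day post-stroke
#' session, 200 Hz, 10 Hz zero-lag filtering, 50 mm/s event threshold).
#'
#' @param simulate list of arguments for [generate_cohort()] (set to
#'   `NULL` when `trial_dir` is given)
#' @param trial_dir directory of TSV/C3D trials named
#'   `<animal>_<session>_<k>.<ext>` (alternative to simulation)
#' @param baseline_sessions,post_sessions session labels
#' @param filter [filter_spec()]
#' @param events [event_spec()]
#' @param volume_centre capture-volume centre along progression, m
#' @param max_x_range straight-line walking tolerance: trials whose T1
#'   lateral range exceeds this (m) are excluded
#' @param icc_measures measures to assess for baseline repeatability
#' @param lmm_measures limb-pair measures for the pre/post mixed models
#' @param seed RNG seed for the whole run
#' @param out_dir output directory (`NULL` = no files written)
#' @return list of class `run_config`
#' @export
run_config <- function(simulate = list(n_animals = 4),
                       trial_dir = NULL,
                       baseline_sessions = c("B1", "B2", "B3"),
                       post_sessions = "D3",
                       filter = filter_spec(),
                       events = event_spec(),
                       volume_centre = NULL,
                       max_x_range = 0.5,
                       icc_measures = c("mean_forward_velocity",
                                        "head_to_T1_vertical",
                                        "stance_duration", "swing_duration",
                                        "stride_duration", "stride_length"),
                       lmm_measures = c("stance_duration", "swing_duration",
                                        "stride_duration"),
                       seed = 1L,
                       out_dir = NULL) {
  cfg <- list(simulate = simulate, trial_dir = trial_dir,
              baseline_sessions = baseline_sessions,
              post_sessions = post_sessions, filter = filter,
              events = events, volume_centre = volume_centre,
              max_x_range = max_x_range, icc_measures = icc_measures,
              lmm_measures = lmm_measures, seed = as.integer(seed),
              out_dir = out_dir)
  class(cfg) <- "run_config"
  cfg
}

#' Load a run configuration from a YAML file
#'
#' Scalar fields of [run_config()] can be set from a YAML mapping;
#' `filter` and `events` sub-mappings are passed to their constructors.
#'
#' @param path YAML file
#' @return a `run_config`
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  args <- y
  if (!is.null(y$filter)) args$filter <- do.call(filter_spec, y$filter)
  if (!is.null(y$events)) args$events <- do.call(event_spec, y$events)
  do.call(run_config, args)
}

# stable polynomial hash (31-bit) of the serialized configuration
config_hash <- function(cfg) {
  cfg$out_dir <- NULL
  bytes <- as.integer(serialize(cfg, NULL, version = 2L))
  h <- 0
  for (b in bytes) h <- (h * 257 + b) %% 2147483629
  sprintf("%08x", h)
}

#' Run the full study pipeline
#'
#' Orchestrates simulate (or load) -> preprocess -> gait events ->
#' kinematics -> statistics into one reproducible run: produces the
#' session-level study table, baseline ICC tables (unadjusted and
#' velocity-adjusted), pre/post mixed-model contrast tables, the
#' neuroscore summary and the PCA of post-stroke outcomes against
#' infarct volume.  Deterministic for a fixed seed; every output carries
#' the configuration hash.
#'
#' @param config a [run_config()]
#' @return list of class `study_run` with elements `study_table`, `icc`,
#'   `icc_velocity_adjusted`, `lmm`, `neuroscores`, `pca`, `log`,
#'   `config_hash`
#' @export
run_study <- function(config = run_config()) {
  t0 <- Sys.time()
  hash <- config_hash(config)
  log <- list()
  note <- function(stage, msg) log[[length(log) + 1L]] <<-
    data.frame(stage = stage, message = msg)

  ## ---- inputs ----
  if (!is.null(config$trial_dir)) {
    files <- list.files(config$trial_dir, pattern = "\\.(tsv|c3d)$",
                        full.names = TRUE)
    if (!length(files)) stop("[input] no trial files in ", config$trial_dir)
    trials <- lapply(files, load_trial)
    meta <- strsplit(sub("\\.(tsv|c3d)$", "", basename(files)), "_")
    for (i in seq_along(trials)) {
      trials[[i]]$animal_id <- meta[[i]][1L]
      trials[[i]]$session <- meta[[i]][2L]
    }
    names(trials) <- sub("\\.(tsv|c3d)$", "", basename(files))
    neuro <- NULL; infarct <- NULL
    note("input", sprintf("loaded %d trials from %s", length(trials),
                          config$trial_dir))
  } else {
    sim_args <- config$simulate
    sim_args$sessions <- c(config$baseline_sessions, config$post_sessions)
    sim_args$seed <- config$seed
    cohort <- do.call(generate_cohort, sim_args)
    trials <- cohort$trials
    neuro <- cohort$neuroscores
    infarct <- cohort$infarct_volumes
    note("simulate", sprintf("generated %d trials for %d animals",
                             length(trials), sim_args$n_animals))
  }

  ## ---- preprocess + exclusion ----
  keep <- list()
  for (nm in names(trials)) {
    tr <- tryCatch(preprocess_trial(trials[[nm]], config$filter),
                   error = function(e)
                     stop("[preprocess] trial ", nm, ": ",
                          conditionMessage(e)))
    unf <- attr(tr, "unfilled")
    if (length(unf)) {
      note("preprocess", sprintf("trial %s: unfillable gaps on %s; excluded",
                                 nm, paste(unf, collapse = ",")))
      next
    }
    x_range <- diff(range(marker_positions(tr, "T1")[, "x"])) / 1000
    if (x_range > config$max_x_range) {
      note("exclusion", sprintf(
        "trial %s: T1 lateral range %.2f m exceeds %.2f m; excluded",
        nm, x_range, config$max_x_range))
      next
    }
    keep[[nm]] <- tr
  }
  if (!length(keep)) stop("[preprocess] no usable trials remain")

  ## ---- events + kinematics ----
  tables <- list()
  for (nm in names(keep)) {
    tr <- keep[[nm]]
    centre <- config$volume_centre
    if (is.null(centre))
      centre <- mean(range(marker_positions(tr, "T1")[, "y"])) / 1000
    cycles <- list()
    for (limb in LIMBS) {
      det <- tryCatch({
        v <- differentiate(tr$markers[[hoof_marker(limb)]], tr$sample_rate)
        detect_phases(v, config$events, tr$sample_rate)
      }, error = function(e) NULL)
      if (is.null(det) || nrow(det$events) == 0L) {
        note("events", sprintf("trial %s: no complete cycle for %s", nm, limb))
        next
      }
      cycles[[limb]] <- extract_cycle(det, tr, limb, centre)
    }
    if (!length(cycles)) { note("events", sprintf(
      "trial %s unusable (no cycles); dropped", nm)); next }
    tables[[nm]] <- trial_parameters(tr, cycles)
  }
  if (!length(tables)) stop("[kinematics] no trial produced parameters")
  study <- aggregate_trials(tables)

  ## ---- statistics ----
  sessions_present <- unique(study$session)
  have_post <- any(config$post_sessions %in% sessions_present)

  icc_rows <- list(); icc_adj_rows <- list()
  for (ms in config$icc_measures) {
    sub <- study[study$measure == ms, ]
    for (lb in unique(sub$limb)) {
      res <- tryCatch(session_icc(study, ms, lb,
                                  sessions = config$baseline_sessions),
                      error = function(e) NULL)
      if (is.null(res)) next
      icc_rows[[length(icc_rows) + 1L]] <- data.frame(
        measure = ms, limb = lb, icc = res$icc, ci_low = res$ci_low,
        ci_high = res$ci_high)
      if (lb != "global") {
        adj <- tryCatch({
          at <- velocity_adjust(study, ms)
          session_icc(at, ms, lb, sessions = config$baseline_sessions)
        }, error = function(e) NULL)
        if (!is.null(adj))
          icc_adj_rows[[length(icc_adj_rows) + 1L]] <- data.frame(
            measure = ms, limb = lb, icc = adj$icc, ci_low = adj$ci_low,
            ci_high = adj$ci_high)
      }
    }
  }
  icc_tab <- if (length(icc_rows)) do.call(rbind, icc_rows) else NULL
  icc_adj_tab <- if (length(icc_adj_rows)) do.call(rbind, icc_adj_rows) else NULL

  lmm_res <- NULL
  if (have_post) {
    lmm_res <- list()
    for (ms in config$lmm_measures) {
      for (pair in list(c("FL_L", "FL_R"), c("HL_L", "HL_R"))) {
        res <- tryCatch(
          fit_prepost_lmm(study, ms, limbs = pair,
                          baseline_sessions = config$baseline_sessions,
                          post_sessions = config$post_sessions),
          error = function(e) NULL)
        if (!is.null(res))
          lmm_res[[paste(ms, substr(pair[1L], 1, 2), sep = "_")]] <- res
      }
    }
  } else note("stats", "no post session present; pre/post models skipped")

  neuro_summary <- NULL
  if (!is.null(neuro)) {
    scores <- read_score_sheet(neuro)
    neuro_summary <- subscore_summary(
      scores, baseline_sessions = config$baseline_sessions,
      post_sessions = config$post_sessions)
  }

  pca_res <- NULL
  if (have_post && !is.null(infarct) && !is.null(neuro_summary)) {
    post_wide <- build_pca_table(study, neuro_summary, infarct,
                                 config$post_sessions)
    if (!is.null(post_wide) && nrow(post_wide) >= 4L)
      pca_res <- tryCatch(
        pca_pipeline(post_wide, sign_anchor = "total_neuroscore"),
        error = function(e) { note("pca", conditionMessage(e)); NULL })
  }

  run <- structure(list(
    study_table = study, icc = icc_tab, icc_velocity_adjusted = icc_adj_tab,
    lmm = lmm_res, neuroscores = neuro_summary, pca = pca_res,
    log = if (length(log)) do.call(rbind, log) else NULL,
    config_hash = hash,
    elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs"))),
    class = "study_run")

  if (!is.null(config$out_dir)) write_study_run(run, config$out_dir)
  run
}

build_pca_table <- function(study, neuro_summary, infarct, post_sessions) {
  post <- study[study$session %in% post_sessions, ]
  pull <- function(ms, lb) {
    s <- post[post$measure == ms & post$limb == lb, c("animal", "value")]
    stats::setNames(s$value, s$animal)
  }
  animals <- sort(unique(post$animal))
  tot <- neuro_summary[neuro_summary$subscore == "total", ]
  df <- data.frame(
    animal = animals,
    infarct_volume = unname(infarct[animals]),
    total_neuroscore = tot$post[match(animals, tot$animal)],
    mean_velocity = pull("mean_forward_velocity", "global")[animals],
    mean_head_to_t1 = pull("head_to_T1_vertical", "global")[animals],
    swing_duration_right = pull("swing_duration", "FL_R")[animals],
    swing_duration_left = pull("swing_duration", "FL_L")[animals],
    stance_duration_left = pull("stance_duration", "FL_L")[animals])
  df <- df[stats::complete.cases(df), ]
  if (nrow(df) < 4L) return(NULL)
  rownames(df) <- df$animal
  df$animal <- NULL
  df
}

#' @export
print.study_run <- function(x, ...) {
  cat(sprintf("<study_run> config %s, %.1f s\n", x$config_hash, x$elapsed_s))
  cat(sprintf("  study table: %d rows, %d animals, sessions %s\n",
              nrow(x$study_table), length(unique(x$study_table$animal)),
              paste(sort(unique(x$study_table$session)), collapse = "/")))
  if (!is.null(x$icc)) cat(sprintf("  ICC table: %d measures\n", nrow(x$icc)))
  if (!is.null(x$lmm)) cat(sprintf("  pre/post LMMs: %d\n", length(x$lmm)))
  if (!is.null(x$pca)) cat(sprintf("  PCA: %d retained variables, %d components\n",
                                   length(x$pca$pca$variables),
                                   x$pca$pca$n_components))
  if (!is.null(x$log)) cat(sprintf("  log: %d entries\n", nrow(x$log)))
  invisible(x)
}

write_study_run <- function(run, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stamp <- function(df) { df$config_hash <- run$config_hash; df }
  write_study_table(run$study_table, file.path(out_dir, "study_table.csv"))
  if (!is.null(run$icc))
    utils::write.csv(stamp(run$icc), file.path(out_dir, "icc.csv"),
                     row.names = FALSE)
  if (!is.null(run$icc_velocity_adjusted))
    utils::write.csv(stamp(run$icc_velocity_adjusted),
                     file.path(out_dir, "icc_velocity_adjusted.csv"),
                     row.names = FALSE)
  if (!is.null(run$lmm)) {
    con_rows <- do.call(rbind, lapply(names(run$lmm), function(nm) {
      d <- run$lmm[[nm]]$contrasts
      d$model <- nm; d$side <- rownames(d); d
    }))
    utils::write.csv(stamp(con_rows), file.path(out_dir, "lmm_contrasts.csv"),
                     row.names = FALSE)
  }
  if (!is.null(run$neuroscores))
    utils::write.csv(stamp(run$neuroscores),
                     file.path(out_dir, "neuroscores.csv"), row.names = FALSE)
  if (!is.null(run$pca)) {
    p <- run$pca
    jsonlite::write_json(list(
      config_hash = run$config_hash,
      retained_variables = p$pca$variables,
      eigenvalues = p$pca$eigenvalues,
      pct_variance = p$pca$pct_variance,
      cumulative_pct = p$pca$cumulative_pct,
      n_components = p$pca$n_components,
      kmo_overall = p$kmo$overall,
      kmo_per_variable = as.list(p$kmo$per_variable),
      bartlett = p$bartlett,
      loadings = as.data.frame(p$pca$loadings)),
      file.path(out_dir, "pca.json"), auto_unbox = TRUE, digits = NA)
  }
  if (!is.null(run$log))
    utils::write.csv(stamp(run$log), file.path(out_dir, "log.csv"),
                     row.names = FALSE)
  report <- c(
    sprintf("# Study run %s", run$config_hash),
    "",
    sprintf("- trials aggregated into %d study-table rows", nrow(run$study_table)),
    sprintf("- baseline ICC rows: %s",
            if (is.null(run$icc)) "none" else nrow(run$icc)),
    sprintf("- pre/post mixed models: %s",
            if (is.null(run$lmm)) "skipped (no post session)" else length(run$lmm)),
    sprintf("- PCA: %s",
            if (is.null(run$pca)) "not run" else sprintf(
              "%d components from %d variables",
              run$pca$pca$n_components, length(run$pca$pca$variables))))
  writeLines(report, file.path(out_dir, "report.md"))
  invisible(out_dir)
}
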