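#' The ten-criterion composite neurological scoring rubric
#'
#' Encodes the assessment rubric: 0 is normal throughout and higher scores
#' indicate worse deficit.  Criterion 1 (demeanour) runs 0-3; criteria 2-6
#' (behaviour: food debris, torticollis, partial fetlock/carpus flexion,
#' ataxia/dysmetria, circling) run 0-1/0-1/0-1/0-3/0-2; the postural
#' reaction tests are lateralised — hemi-standing (7) is scored 0-4 per
#' side with a 0.25 knuckling modifier per limb (two limbs per side),
#' forelimb hopping (8) 0-2 per side with one 0.25 knuckling modifier, and
#' lateral dragging (9) 0-2 per limb (two limbs per side) with 0.25
#' partial-correction and 0.25 drag-on-return modifiers per limb;
#' wheelbarrowing (10) runs 0-2.  The rubric maximum is always computed
#' from this structure, never hard-coded: it evaluates to 36.5 (per-side
#' postural maximum 11.75), while the source protocol states a total of
#' 36 — the half-point discrepancy in the published rubric is surfaced by
#' [rubric_max()] rather than silently resolved.
#'
#' @return object of class `neuro_rubric`: list of criterion descriptors
#' @export
neuro_rubric <- function() {
  crit <- function(id, name, group, base_max, laterality = "none",
                   units_per_side = 1L, modifiers = list()) {
    list(id = id, name = name, group = group, base_max = base_max,
         laterality = laterality, units_per_side = units_per_side,
         modifiers = modifiers)
  }
  structure(list(
    crit(1L, "state of activity/consciousness", "demeanour", 3),
    crit(2L, "food debris in the mouth", "behaviour", 1),
    crit(3L, "torticollis", "behaviour", 1),
    crit(4L, "partial flexion of fetlock and/or carpus", "behaviour", 1),
    crit(5L, "ataxia/dysmetria", "behaviour", 3),
    crit(6L, "circling movements", "behaviour", 2),
    crit(7L, "hemi-standing", "postural", 4, "per_side", 1L,
         modifiers = list(knuckling = list(step = 0.25, limbs = 2L))),
    crit(8L, "forelimb hopping", "postural", 2, "per_side", 1L,
         modifiers = list(knuckling = list(step = 0.25, limbs = 1L))),
    crit(9L, "lateral dragging", "postural", 2, "per_limb", 2L,
         modifiers = list(partial = list(step = 0.25, limbs = 1L),
                          drag = list(step = 0.25, limbs = 1L))),
    crit(10L, "wheelbarrowing", "wheelbarrow", 2)),
    class = "neuro_rubric")
}

criterion_side_max <- function(cr) {
  mods <- sum(vapply(cr$modifiers, function(m) m$step * m$limbs, 0))
  cr$units_per_side * (cr$base_max + mods)
}

#' Rubric maxima computed from the rubric structure
#'
#' @param rubric a [neuro_rubric()]
#' @return list with `per_side_postural`, `total`, the protocol's stated
#'   total (`stated_total = 36`) and their `discrepancy`
#' @export
rubric_max <- function(rubric = neuro_rubric()) {
  groups <- vapply(rubric, `[[`, "", "group")
  per_side <- sum(vapply(rubric[groups == "postural"], criterion_side_max, 0))
  total <- sum(vapply(rubric[groups == "demeanour"], `[[`, 0, "base_max")) +
    sum(vapply(rubric[groups == "behaviour"], `[[`, 0, "base_max")) +
    2 * per_side +
    sum(vapply(rubric[groups == "wheelbarrow"], `[[`, 0, "base_max"))
  list(per_side_postural = per_side, total = total,
       stated_total = 36, discrepancy = total - 36)
}

# expected sheet components per criterion
criterion_components <- function(cr) {
  if (cr$laterality == "none") return("base")
  sides <- c("left", "right")
  if (cr$laterality == "per_side") {
    comp <- paste0("base_", sides)
    for (mn in names(cr$modifiers)) comp <- c(comp, paste0(mn, "_", sides))
    return(comp)
  }
  limbs <- c("fore", "hind")[seq_len(cr$units_per_side)]
  comp <- as.vector(outer(sides, limbs, function(s, l) paste("base", s, l, sep = "_")))
  for (mn in names(cr$modifiers))
    comp <- c(comp, as.vector(outer(sides, limbs,
                                    function(s, l) paste(mn, s, l, sep = "_"))))
  comp
}

component_max <- function(cr, component) {
  if (startsWith(component, "base")) return(cr$base_max)
  mn <- sub("_(left|right).*$", "", component)
  m <- cr$modifiers[[mn]]
  if (is.null(m)) return(NA_real_)
  m$step * m$limbs
}

#' Validate a raw score sheet into a neurological score
#'
#' The sheet is a long-format table with columns `animal`, `session`,
#' `criterion`, `component`, `value` (one animal-session per call).
#' Components are `base` for unlateralised criteria, `base_left`/
#' `base_right` (plus e.g. `knuckling_left`) for per-side criteria, and
#' `base_left_fore` etc. for per-limb ones.  Base scores must be integers
#' within the criterion range; modifiers must be multiples of 0.25 within
#' their per-limb allowance.  Missing modifier rows default to 0; missing
#' base rows are an error.
#'
#' @param raw data.frame score sheet for one animal-session
#' @param rubric a [neuro_rubric()]
#' @return object of class `neuro_score` with per-criterion entries and
#'   the derived subscores: `demeanour`, `behaviour`, `postural_left`,
#'   `postural_right`, `wheelbarrow` and `total`
#' @export
validate_sheet <- function(raw, rubric = neuro_rubric()) {
  need <- c("animal", "session", "criterion", "component", "value")
  if (!all(need %in% names(raw)))
    stop("score sheet needs columns ", paste(need, collapse = ", "))
  if (length(unique(raw$animal)) != 1L || length(unique(raw$session)) != 1L)
    stop("validate_sheet() expects a single animal-session sheet")
  errs <- character(0)
  entries <- list()
  for (cr in rubric) {
    comps <- criterion_components(cr)
    got <- raw[raw$criterion == cr$id, ]
    vals <- stats::setNames(rep(NA_real_, length(comps)), comps)
    for (cp in comps) {
      row <- got[got$component == cp, ]
      if (nrow(row) > 1L) {
        errs <- c(errs, sprintf("criterion %d: duplicate component '%s'",
                                cr$id, cp))
        next
      }
      if (nrow(row) == 0L) {
        if (startsWith(cp, "base"))
          errs <- c(errs, sprintf("criterion %d (%s): missing component '%s'",
                                  cr$id, cr$name, cp))
        else vals[[cp]] <- 0
        next
      }
      v <- row$value
      cmax <- component_max(cr, cp)
      if (!is.finite(v) || v < 0 || v > cmax)
        errs <- c(errs, sprintf(
          "criterion %d (%s): component '%s' value %s outside [0, %s]",
          cr$id, cr$name, cp, format(v), format(cmax)))
      else if (abs(v * 4 - round(v * 4)) > 1e-9)
        errs <- c(errs, sprintf(
          "criterion %d (%s): component '%s' value %s not on the 0.25 grid",
          cr$id, cr$name, cp, format(v)))
      else if (startsWith(cp, "base") && abs(v - round(v)) > 1e-9)
        errs <- c(errs, sprintf(
          "criterion %d (%s): base score %s must be an integer",
          cr$id, cr$name, format(v)))
      else vals[[cp]] <- v
    }
    entries[[as.character(cr$id)]] <- vals
  }
  if (length(errs)) stop("invalid score sheet:\n  ",
                         paste(errs, collapse = "\n  "))
  groups <- vapply(rubric, `[[`, "", "group")
  ids <- vapply(rubric, `[[`, 0L, "id")
  side_sum <- function(side) {
    s <- 0
    for (cr in rubric[groups == "postural"]) {
      v <- entries[[as.character(cr$id)]]
      s <- s + sum(v[grepl(paste0("_", side, "(_|$)"), names(v))])
    }
    s
  }
  sub <- list(
    demeanour = sum(unlist(entries[as.character(ids[groups == "demeanour"])])),
    behaviour = sum(unlist(entries[as.character(ids[groups == "behaviour"])])),
    postural_left = side_sum("left"),
    postural_right = side_sum("right"),
    wheelbarrow = sum(unlist(entries[as.character(ids[groups == "wheelbarrow"])])))
  sub$total <- sub$demeanour + sub$behaviour + sub$postural_left +
    sub$postural_right + sub$wheelbarrow
  structure(c(list(animal = as.character(raw$animal[1L]),
                   session = as.character(raw$session[1L]),
                   entries = entries), sub),
            class = "neuro_score")
}

#' @export
print.neuro_score <- function(x, ...) {
  cat(sprintf("<neuro_score> %s %s: total %.2f (demeanour %.2f, behaviour %.2f, postural L %.2f / R %.2f, wheelbarrow %.2f)\n",
              x$animal, x$session, x$total, x$demeanour, x$behaviour,
              x$postural_left, x$postural_right, x$wheelbarrow))
  invisible(x)
}

#' Read and validate a multi-animal score-sheet CSV
#'
#' @param path CSV with columns `animal,session,criterion,component,value`
#'   (or a data.frame in the same layout)
#' @param rubric a [neuro_rubric()]
#' @return list of [validate_sheet()] results, one per animal-session
#' @export
read_score_sheet <- function(path, rubric = neuro_rubric()) {
  raw <- if (is.data.frame(path)) path
         else utils::read.csv(path, stringsAsFactors = FALSE)
  keys <- unique(raw[c("animal", "session")])
  out <- list()
  for (i in seq_len(nrow(keys))) {
    sub <- raw[raw$animal == keys$animal[i] & raw$session == keys$session[i], ]
    out[[paste(keys$animal[i], keys$session[i], sep = "_")]] <-
      validate_sheet(sub, rubric)
  }
  out
}

#' Per-animal baseline means and post values of the subscores
#'
#' The repeated baseline sessions are averaged into a single pre-stroke
#' value per animal and subscore, paired with the post-stroke session
#' value for downstream comparison.  Animals with no post session are
#' excluded with a warning.
#'
#' @param scores list of `neuro_score` objects
#' @param baseline_sessions labels counting as baseline
#' @param post_sessions labels counting as post-stroke
#' @return data.frame: animal, subscore, mean_baseline, post
#' @export
subscore_summary <- function(scores, baseline_sessions = c("B1", "B2", "B3"),
                             post_sessions = "D3") {
  subs <- c("demeanour", "behaviour", "postural_left", "postural_right",
            "wheelbarrow", "total")
  df <- do.call(rbind, lapply(scores, function(s)
    data.frame(animal = s$animal, session = s$session,
               t(vapply(subs, function(k) s[[k]], 0)))))
  animals <- unique(df$animal)
  rows <- list()
  for (a in animals) {
    base <- df[df$animal == a & df$session %in% baseline_sessions, ]
    post <- df[df$animal == a & df$session %in% post_sessions, ]
    if (nrow(base) == 0L) stop("animal ", a, " has no baseline session")
    if (nrow(post) == 0L) {
      warning("animal ", a, " has no post session; excluded")
      next
    }
    for (k in subs)
      rows[[length(rows) + 1L]] <- data.frame(
        animal = a, subscore = k, mean_baseline = mean(base[[k]]),
        post = mean(post[[k]]))
  }
  do.call(rbind, rows)
}
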