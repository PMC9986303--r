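#' Marker set and coordinate conventions
#'
#' The capture volume uses a global coordinate system with the z-axis
#' vertical (positive up), the y-axis along the direction of progression
#' (positive forward) and the x-axis lateral (positive towards the animal's
#' right).  All positions are stored in millimetres.  Axial markers (HEAD,
#' T1, T13, L7) are unsuffixed; limb markers carry a `_FL`/`_HL` limb tag
#' and a `_L`/`_R` side suffix, e.g. `DPHAL_FL_L` for the fore-left distal
#' phalange hoof marker.
#'
#' @name marker-conventions
NULL

AXIAL_MARKERS <- c("HEAD", "T1", "T13", "L7")

# distal phalange (DPHAL) is the hoof marker used for gait-event detection
FORELIMB_CHAIN <- c("GTUB", "LEPIRAD", "ULNA", "METAR", "PPHAL", "PHAL", "DPHAL")
HINDLIMB_CHAIN <- c("ILIUM", "ISCHTUB", "GTROC", "LEPI", "LTIB", "TIB", "CALC",
                    "LMAL", "FTAR", "PPHAL", "PHAL", "DPHAL")

LIMBS <- c("FL_L", "FL_R", "HL_L", "HL_R")

#' Default axis convention record
#' @return list naming the up, forward and lateral axes and the sign of x
#' @export
default_axes <- function() {
  list(up = "z", forward = "y", lateral = "x", positive_x = "right")
}

#' Marker labels for one limb
#'
#' @param limb one of `"FL_L"`, `"FL_R"`, `"HL_L"`, `"HL_R"`
#' @return character vector of marker labels, proximal to distal
#' @export
limb_markers <- function(limb) {
  limb <- match.arg(limb, LIMBS)
  chain <- if (startsWith(limb, "FL")) FORELIMB_CHAIN else HINDLIMB_CHAIN
  tag <- sub("^(FL|HL)_(L|R)$", "\\1_\\2", limb)
  paste0(chain, "_", tag)
}

#' The full 42-marker landmark set
#' @return character vector of 42 marker labels
#' @export
full_marker_set <- function() {
  c(AXIAL_MARKERS, unlist(lapply(LIMBS, limb_markers), use.names = FALSE))
}

#' Hoof marker label for a limb
#' @inheritParams limb_markers
#' @export
hoof_marker <- function(limb) {
  limb <- match.arg(limb, LIMBS)
  paste0("DPHAL_", limb)
}

#' Construct a marker trajectory
#'
#' @param label marker name
#' @param positions numeric n x 3 matrix (columns x, y, z), millimetres
#' @param occluded logical vector of length n; `TRUE` where the marker was
#'   not observed
#' @return object of class `marker_trajectory`
#' @export
marker_trajectory <- function(label, positions, occluded = NULL) {
  positions <- as.matrix(positions)
  if (ncol(positions) != 3L)
    stop("positions must have three columns (x, y, z)")
  colnames(positions) <- c("x", "y", "z")
  n <- nrow(positions)
  if (n < 2L) stop("a marker trajectory needs at least 2 frames")
  if (is.null(occluded)) occluded <- rowSums(!is.finite(positions)) > 0L
  occluded <- as.logical(occluded)
  if (length(occluded) != n)
    stop("occluded mask length must equal the frame count")
  if (any(!is.finite(positions[!occluded, , drop = FALSE])))
    stop("non-occluded frames must contain finite coordinates (marker ",
         label, ")")
  structure(list(label = label, positions = positions, occluded = occluded),
            class = "marker_trajectory")
}

#' Construct a walking trial
#'
#' A trial holds the labelled marker trajectories of one straight walking
#' pass, the session it belongs to, the sampling rate and the axis
#' convention.  All trajectories must share one frame count.
#'
#' @param markers named list of [marker_trajectory()] objects
#' @param animal_id animal identifier
#' @param session session label; the study design uses `B1`, `B2`, `B3`
#'   (8-, 5- and 1-day pre-stroke baselines) and `D3` (3 days post-stroke)
#' @param sample_rate sampling rate in Hz (capture default 200)
#' @param axes axis convention record, see [default_axes()]
#' @return object of class `ovigait_trial`
#' @export
trial <- function(markers, animal_id = "A1", session = "B1",
                  sample_rate = 200, axes = default_axes()) {
  if (length(markers) == 0L) stop("a trial needs at least one marker")
  if (is.null(names(markers)) || any(names(markers) == ""))
    markers <- stats::setNames(markers, vapply(markers, `[[`, "", "label"))
  nf <- vapply(markers, function(m) nrow(m$positions), 0L)
  if (length(unique(nf)) != 1L)
    stop("all marker trajectories must share one frame count; got ",
         paste(unique(nf), collapse = ", "))
  if (sample_rate <= 0) stop("sample_rate must be positive")
  structure(list(animal_id = animal_id, session = session,
                 sample_rate = sample_rate, markers = markers, axes = axes),
            class = "ovigait_trial")
}

#' @export
print.ovigait_trial <- function(x, ...) {
  cat(sprintf("<ovigait_trial> animal %s, session %s: %d markers x %d frames @ %g Hz\n",
              x$animal_id, x$session, length(x$markers), n_frames(x),
              x$sample_rate))
  occ <- sum(vapply(x$markers, function(m) sum(m$occluded), 0L))
  if (occ > 0) cat(sprintf("  %d occluded marker-frames\n", occ))
  invisible(x)
}

#' Number of frames in a trial
#' @param trial an `ovigait_trial`
#' @export
n_frames <- function(trial) nrow(trial$markers[[1L]]$positions)

#' Positions matrix of one marker
#' @param trial an `ovigait_trial`
#' @param label marker label
#' @return n x 3 matrix (x, y, z), mm
#' @export
marker_positions <- function(trial, label) {
  m <- trial$markers[[label]]
  if (is.null(m)) stop("marker ", label, " is not present in the trial")
  m$positions
}

required_markers <- function(analysis = c("global", "forelimb", "hindlimb", "full")) {
  analysis <- match.arg(analysis)
  switch(analysis,
         global = AXIAL_MARKERS,
         forelimb = c(limb_markers("FL_L"), limb_markers("FL_R")),
         hindlimb = c(limb_markers("HL_L"), limb_markers("HL_R")),
         full = full_marker_set())
}

#' Validate the marker complement of a trial for a given analysis
#'
#' Report-only check that the marker subset required by an analysis is
#' present: global parameters need the axial markers (HEAD, T1, T13, L7);
#' limb analyses need the full marker chain of each limb.
#'
#' @param trial an `ovigait_trial`
#' @param analysis one of `"global"`, `"forelimb"`, `"hindlimb"`, `"full"`
#' @return list with `pass` (logical), `missing`, `extra` label vectors and,
#'   for limb analyses, a per-side pass flag
#' @export
validate_marker_set <- function(trial,
                                analysis = c("global", "forelimb", "hindlimb", "full")) {
  analysis <- match.arg(analysis)
  need <- required_markers(analysis)
  have <- names(trial$markers)
  missing <- setdiff(need, have)
  extra <- setdiff(have, full_marker_set())
  out <- list(analysis = analysis, pass = length(missing) == 0L,
              missing = missing, extra = extra)
  if (analysis %in% c("forelimb", "hindlimb")) {
    tag <- if (analysis == "forelimb") "FL" else "HL"
    out$per_side <- c(
      L = all(limb_markers(paste0(tag, "_L")) %in% have),
      R = all(limb_markers(paste0(tag, "_R")) %in% have))
  }
  out
}
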