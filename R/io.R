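#' Read a walking trial from disk
#'
#' Two on-disk formats are supported.  The TSV dialect is a UTF-8
#' tab-separated file with header `frame time <LABEL>_x <LABEL>_y <LABEL>_z ...`,
#' positions in millimetres, a 0-based frame column, and blank cells marking
#' occluded frames.  The C3D format is the standard binary 3D biomechanics
#' container; a minimal reader is implemented covering labelled point data
#' with float or integer storage and invalid-point residuals as the
#' occlusion flag.
#'
#' @param path file path
#' @param format `"tsv"` or `"c3d"`; guessed from the extension by default
#' @return an [trial()] object
#' @export
load_trial <- function(path, format = c("auto", "tsv", "c3d")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file does not exist: ", path)
  if (format == "auto")
    format <- if (grepl("\\.c3d$", path, ignore.case = TRUE)) "c3d" else "tsv"
  switch(format, tsv = read_trial_tsv(path), c3d = read_trial_c3d(path))
}

#' Write a walking trial to disk
#'
#' Round-trips through [load_trial()] reproduce positions to better than
#' 1e-6 mm and occlusion masks exactly (TSV stores full double precision;
#' C3D stores single-precision floats of millimetre values, reported
#' round-trip tolerance 1e-3 mm).
#'
#' @param trial an `ovigait_trial`
#' @param path output path
#' @param format `"tsv"` or `"c3d"`
#' @return `path`, invisibly
#' @export
write_trial <- function(trial, path, format = c("auto", "tsv", "c3d")) {
  format <- match.arg(format)
  if (!inherits(trial, "ovigait_trial")) stop("trial must be an ovigait_trial")
  if (length(trial$markers) == 0L) stop("trial has no markers")
  if (format == "auto")
    format <- if (grepl("\\.c3d$", path, ignore.case = TRUE)) "c3d" else "tsv"
  switch(format,
         tsv = write_trial_tsv(trial, path),
         c3d = write_trial_c3d(trial, path))
  invisible(path)
}

## ---- TSV dialect -----------------------------------------------------------

write_trial_tsv <- function(trial, path) {
  n <- n_frames(trial)
  labs <- names(trial$markers)
  cols <- vector("list", 2L + 3L * length(labs))
  cols[[1L]] <- 0:(n - 1L)                      # frame column is 0-based
  cols[[2L]] <- (0:(n - 1L)) / trial$sample_rate
  nms <- c("frame", "time")
  k <- 3L
  for (lab in labs) {
    m <- trial$markers[[lab]]
    pos <- m$positions
    pos[m$occluded, ] <- NA_real_               # blank cell = occluded
    for (j in 1:3) {
      cols[[k]] <- pos[, j]
      nms <- c(nms, paste0(lab, "_", c("x", "y", "z")[j]))
      k <- k + 1L
    }
  }
  df <- stats::setNames(as.data.frame(cols), nms)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE,
                     na = "", fileEncoding = "UTF-8")
  invisible(path)
}

read_trial_tsv <- function(path, sample_rate = NULL) {
  df <- tryCatch(
    utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                      fileEncoding = "UTF-8"),
    error = function(e) stop("unreadable TSV trial file: ", path, " (",
                             conditionMessage(e), ")"))
  if (!all(c("frame", "time") %in% names(df)))
    stop("TSV trial file must have 'frame' and 'time' columns: ", path)
  coord_cols <- setdiff(names(df), c("frame", "time"))
  if (length(coord_cols) == 0L || length(coord_cols) %% 3L != 0L)
    stop("TSV trial file must have <LABEL>_{x,y,z} column triples: ", path)
  labs <- unique(sub("_(x|y|z)$", "", coord_cols))
  if (is.null(sample_rate)) {
    dt <- diff(df$time)
    sample_rate <- if (length(dt) && all(dt > 0)) 1 / stats::median(dt) else 200
    sample_rate <- round(sample_rate, 6)
  }
  known <- full_marker_set()
  unknown <- setdiff(labs, known)
  if (length(unknown))
    warning("unknown marker labels retained under their raw names: ",
            paste(unknown, collapse = ", "))
  markers <- lapply(labs, function(lab) {
    need <- paste0(lab, "_", c("x", "y", "z"))
    if (!all(need %in% names(df)))
      stop("incomplete coordinate triple for marker ", lab, " in ", path)
    pos <- as.matrix(df[, need])
    marker_trajectory(lab, pos, occluded = rowSums(is.na(pos)) > 0L)
  })
  names(markers) <- labs
  trial(markers, sample_rate = sample_rate)
}

## ---- minimal C3D subset ----------------------------------------------------
## 512-byte blocks; header block, parameter section (POINT group), then
## frame-ordered point data.  Written as Intel (processor 84) float data
## with a negative POINT:SCALE; occluded frames carry residual -1.

C3D_BLOCK <- 512L

write_trial_c3d <- function(trial, path) {
  labs <- names(trial$markers)
  np <- length(labs)
  nf <- n_frames(trial)
  if (nf > 32760L) stop("C3D writer supports at most 32760 frames")
  rate <- trial$sample_rate

  param <- c3d_param_section(labs, nf, rate)
  n_param_blocks <- length(param) / C3D_BLOCK
  data_start <- 2L + n_param_blocks          # 1-based block index

  con <- tryCatch(file(path, "wb"), error = function(e)
    stop("cannot open for writing: ", path))
  on.exit(close(con))

  hdr <- raw(C3D_BLOCK)
  w <- function(off, val, what = c("int2", "float")) {
    what <- match.arg(what)
    bytes <- if (what == "int2") writeBin(as.integer(val), raw(), size = 2L,
                                          endian = "little")
             else writeBin(as.numeric(val), raw(), size = 4L, endian = "little")
    hdr[(off + 1L):(off + length(bytes))] <<- bytes
  }
  hdr[1L] <- as.raw(2L)       # first parameter block
  hdr[2L] <- as.raw(0x50)     # C3D magic
  w(2L, np); w(4L, 0L)        # points; analog channels per frame
  w(6L, 1L); w(8L, nf)        # first / last frame
  w(10L, 10L)                 # max interpolation gap (informational)
  w(12L, -1, "float")         # 3D scale; negative => float storage
  w(16L, data_start)
  w(18L, 0L)                  # analog samples per frame
  w(20L, rate, "float")
  writeBin(hdr, con)
  writeBin(param, con)

  # frame-ordered point data: x, y, z, residual (floats)
  dat <- array(0, dim = c(4L, np, nf))
  for (j in seq_along(labs)) {
    m <- trial$markers[[j]]
    pos <- t(m$positions)
    pos[, m$occluded] <- 0
    dat[1:3, j, ] <- pos
    dat[4L, j, ] <- ifelse(m$occluded, -1, 0)
  }
  writeBin(as.numeric(dat), con, size = 4L, endian = "little")
  pad <- (-(4L * np * nf * 4L)) %% C3D_BLOCK
  if (pad > 0L) writeBin(raw(pad), con)
  invisible(path)
}

# build the POINT parameter group as raw bytes padded to whole blocks.
# entry offsets follow the C3D convention: bytes from the end of the
# 2-byte offset field to the start of the next entry.
c3d_param_section <- function(labs, nf, rate) {
  lab_w <- max(nchar(labs))
  labs_pad <- formatC(labs, width = lab_w, flag = "-")
  int8 <- function(x) as.raw(bitwAnd(as.integer(x), 255L))

  grp <- function(name, desc = "") {
    nm <- charToRaw(name)
    c(int8(length(nm)), int8(-1L),                 # group id -1 => POINT
      nm,
      writeBin(as.integer(1L + nchar(desc)), raw(), size = 2L,
               endian = "little"),
      int8(nchar(desc)), charToRaw(desc))
  }
  par <- function(name, value, type = c("int2", "float", "char"), dims = NULL) {
    type <- match.arg(type)
    nm <- charToRaw(name)
    if (type == "char") {
      data <- charToRaw(paste(value, collapse = ""))
      el <- -1L
      if (is.null(dims)) dims <- nchar(value[1L])
    } else if (type == "int2") {
      data <- writeBin(as.integer(value), raw(), size = 2L, endian = "little")
      el <- 2L
      if (is.null(dims)) dims <- if (length(value) > 1L) length(value) else integer(0)
    } else {
      data <- writeBin(as.numeric(value), raw(), size = 4L, endian = "little")
      el <- 4L
      if (is.null(dims)) dims <- if (length(value) > 1L) length(value) else integer(0)
    }
    body <- c(int8(el),
              int8(length(dims)),
              if (length(dims)) int8(dims),
              data,
              int8(0L))                            # empty description
    c(int8(length(nm)), int8(1L),                  # parameter of group 1
      nm,
      writeBin(as.integer(length(body)), raw(), size = 2L, endian = "little"),
      body)
  }

  body <- c(
    grp("POINT"),
    par("USED", length(labs)),
    par("FRAMES", nf),
    par("SCALE", -1, "float"),
    par("RATE", rate, "float"),
    par("UNITS", "mm", "char", dims = 2L),
    par("LABELS", labs_pad, "char", dims = c(lab_w, length(labs))),
    int8(c(0L, 0L)),                               # terminator entry
    writeBin(0L, raw(), size = 2L, endian = "little"))
  n_blocks <- ceiling((4L + length(body)) / C3D_BLOCK)
  head4 <- writeBin(as.integer(c(1L, 0x50, n_blocks, 84L)), raw(), size = 1L)
  sec <- c(head4, body)
  c(sec, raw(n_blocks * C3D_BLOCK - length(sec)))
}

read_trial_c3d <- function(path) {
  bytes <- readBin(path, raw(), n = file.info(path)$size)
  if (length(bytes) < C3D_BLOCK || bytes[2L] != as.raw(0x50))
    stop("not a C3D file: ", path)
  int2 <- function(off) readBin(bytes[(off + 1L):(off + 2L)], integer(),
                                size = 2L, endian = "little")
  flt4 <- function(off) readBin(bytes[(off + 1L):(off + 4L)], numeric(),
                                size = 4L, endian = "little")
  np <- int2(2L); first <- int2(6L); last <- int2(8L)
  scale <- flt4(12L); data_start <- int2(16L); rate <- flt4(20L)
  nf <- last - first + 1L

  # parameter section: walk entries for POINT:LABELS and POINT:SCALE
  poff <- (as.integer(bytes[1L]) - 1L) * C3D_BLOCK
  proc <- as.integer(bytes[poff + 4L])
  if (proc != 84L) stop("unsupported C3D processor type ", proc,
                        " (only Intel/PC is handled)")
  labs <- NULL; point_gid <- NA_integer_
  pending <- list()
  pos <- poff + 4L
  repeat {
    nname <- readBin(bytes[pos + 1L], integer(), size = 1L, signed = TRUE)
    gid <- readBin(bytes[pos + 2L], integer(), size = 1L, signed = TRUE)
    if (nname == 0L) break
    name <- rawToChar(bytes[(pos + 3L):(pos + 2L + abs(nname))])
    cur <- pos + 2L + abs(nname)
    offset <- int2(cur)
    nxt <- cur + 2L + offset
    if (gid < 0L) {                           # group record
      if (toupper(name) == "POINT") point_gid <- -gid
    } else {                                  # parameter record
      el <- readBin(bytes[cur + 3L], integer(), size = 1L, signed = TRUE)
      nd <- as.integer(bytes[cur + 4L])
      dims <- if (nd > 0L) as.integer(bytes[(cur + 5L):(cur + 4L + nd)]) else integer(0)
      dstart <- cur + 4L + nd
      count <- prod(c(dims, 1L))
      pending[[length(pending) + 1L]] <-
        list(gid = gid, name = toupper(name), el = el, dims = dims,
             raw = bytes[(dstart + 1L):(dstart + count * abs(el))])
    }
    if (offset == 0L) break
    pos <- nxt
  }
  for (p in pending) {
    if (!is.na(point_gid) && p$gid == point_gid && p$name == "LABELS") {
      s <- rawToChar(p$raw)
      w <- p$dims[1L]
      labs <- trimws(substring(s, seq(1L, nchar(s), by = w),
                               seq(w, nchar(s), by = w)))
    }
    if (!is.na(point_gid) && p$gid == point_gid && p$name == "SCALE")
      scale <- readBin(p$raw, numeric(), size = 4L, endian = "little")
  }
  if (is.null(labs)) labs <- paste0("M", seq_len(np))
  if (length(labs) < np) labs <- c(labs, paste0("M", seq_len(np - length(labs))))
  labs <- labs[seq_len(np)]

  doff <- (data_start - 1L) * C3D_BLOCK
  if (scale < 0) {
    vals <- readBin(bytes[(doff + 1L):length(bytes)], numeric(),
                    n = 4L * np * nf, size = 4L, endian = "little")
    arr <- array(vals, dim = c(4L, np, nf))
    coords <- arr[1:3, , , drop = FALSE]
    resid <- arr[4L, , ]
  } else {
    vals <- readBin(bytes[(doff + 1L):length(bytes)], integer(),
                    n = 4L * np * nf, size = 2L, endian = "little")
    arr <- array(vals, dim = c(4L, np, nf))
    coords <- arr[1:3, , , drop = FALSE] * scale
    resid <- arr[4L, , ]
  }
  resid <- matrix(resid, nrow = np, ncol = nf)
  markers <- lapply(seq_len(np), function(j) {
    pos <- t(matrix(coords[, j, ], nrow = 3L))
    occ <- resid[j, ] < 0
    pos[occ, ] <- NA_real_
    marker_trajectory(labs[j], pos, occluded = occ)
  })
  names(markers) <- labs
  trial(markers, sample_rate = rate)
}

## ---- study tables ----------------------------------------------------------

#' Assemble a study table
#'
#' Long-format table of outcome measures: one row per animal x session x
#' limb x measure, with units attached per measure.  Global measures use
#' limb `"global"`.  The (animal, session, limb, measure) key must be
#' unique.
#'
#' @param animal,session,limb,measure,value,units vectors of equal length
#' @return a `data.frame` with class `ovigait_study_table`
#' @export
study_table <- function(animal, session, limb, measure, value, units) {
  df <- data.frame(animal = as.character(animal),
                   session = as.character(session),
                   limb = as.character(limb),
                   measure = as.character(measure),
                   value = as.numeric(value),
                   units = as.character(units),
                   stringsAsFactors = FALSE)
  key <- do.call(paste, c(df[c("animal", "session", "limb", "measure")],
                          sep = "\r"))
  if (anyDuplicated(key))
    stop("duplicate (animal, session, limb, measure) rows in study table")
  class(df) <- c("ovigait_study_table", "data.frame")
  df
}

#' @rdname study_table
#' @param tables list of study tables to combine
#' @export
bind_study_tables <- function(tables) {
  df <- do.call(rbind, lapply(tables, as.data.frame))
  study_table(df$animal, df$session, df$limb, df$measure, df$value, df$units)
}

#' @rdname study_table
#' @param path CSV path with header `animal,session,limb,measure,value,units`
#' @export
read_study_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  study_table(df$animal, df$session, df$limb, df$measure, df$value, df$units)
}

#' @rdname study_table
#' @param table a study table
#' @export
write_study_table <- function(table, path) {
  utils::write.csv(as.data.frame(table), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
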