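#' RF sequence container
#'
#' A temporal sequence of RF frames with acquisition metadata. Frames are
#' matrices (axial samples x scan lines); metadata defaults describe the
#' simulator's 5 MHz-equivalent texture (0.25 cycles/sample at a 20 MHz
#' sampling rate, speed of sound 1540 m/s).
#'
#' @param frames list of RF matrices of equal shape.
#' @param id sequence identifier.
#' @param axial_spacing mm per axial sample.
#' @param lateral_spacing mm per scan line.
#' @param center_frequency,sampling_frequency MHz.
#' @param timestamps acquisition times (seconds), one per frame.
#' @param provenance free-text origin note (e.g. a spec hash).
#' @export
rf_sequence <- function(frames, id = "seq001",
                        axial_spacing = 0.0385, lateral_spacing = 0.3,
                        center_frequency = 5, sampling_frequency = 20,
                        timestamps = NULL, provenance = "simulated") {
  stopifnot(is.list(frames), length(frames) >= 2)
  d <- dim(frames[[1]])
  for (f in frames) {
    if (!all(dim(f) == d)) stop("rf_sequence: frames differ in shape")
    if (!all(is.finite(f))) stop("rf_sequence: non-finite samples")
  }
  if (axial_spacing <= 0 || lateral_spacing <= 0)
    stop("rf_sequence: spacings must be positive")
  if (is.null(timestamps)) timestamps <- (seq_along(frames) - 1) / 20
  structure(list(frames = frames, id = id,
                 meta = list(axial_spacing = axial_spacing,
                             lateral_spacing = lateral_spacing,
                             center_frequency = center_frequency,
                             sampling_frequency = sampling_frequency,
                             timestamps = timestamps,
                             provenance = provenance)),
            class = "rf_sequence")
}

#' @export
print.rf_sequence <- function(x, ...) {
  d <- dim(x$frames[[1]])
  cat(sprintf("<rf_sequence '%s'> %d frames of %d x %d\n", x$id,
              length(x$frames), d[1], d[2]))
  invisible(x)
}

# On-disk layout (HDF5): /sequences/<id>/rf is (frames x axial x lateral) in
# file (C) order, float32; metadata as group attributes; optional ground
# truth under /sequences/<id>/gt, predictions under /sequences/<id>/pred;
# /manifest holds id/length/split/provenance columns.
#
# rhdf5 reverses dimension order between R and the file, so an R array with
# dim (lateral, axial, frames) appears as (frames, axial, lateral) on disk.
to_disk <- function(a3) aperm(a3, c(2, 1, 3))
from_disk <- function(a3) aperm(a3, c(2, 1, 3))

#' Write a dataset of RF sequences (with optional ground truth) to HDF5
#'
#' @param sequences list of [rf_sequence()] objects (bare frame lists are
#'   wrapped with default metadata).
#' @param path output file (overwritten).
#' @param ground_truth optional list parallel to `sequences`, each element
#'   the per-step ground-truth list produced by [simulate_sequence()].
#' @param split optional character vector of split labels per sequence.
#' @export
write_dataset <- function(sequences, path, ground_truth = NULL, split = NULL) {
  seqs <- lapply(seq_along(sequences), function(i) {
    s <- sequences[[i]]
    if (inherits(s, "rf_sequence")) s
    else rf_sequence(sequence_frames(s), id = sprintf("seq%03d", i))
  })
  ids <- vapply(seqs, function(s) s$id, character(1))
  if (anyDuplicated(ids)) stop("write_dataset: duplicate sequence ids")
  if (file.exists(path)) unlink(path)
  rhdf5::h5createFile(path)
  rhdf5::h5createGroup(path, "sequences")
  for (k in seq_along(seqs)) {
    s <- seqs[[k]]
    g <- paste0("sequences/", s$id)
    rhdf5::h5createGroup(path, g)
    d <- dim(s$frames[[1]])
    arr <- array(unlist(s$frames), c(d[1], d[2], length(s$frames)))
    rhdf5::h5createDataset(path, paste0(g, "/rf"),
                           dims = c(d[2], d[1], length(s$frames)),
                           H5type = "H5T_IEEE_F32LE")
    rhdf5::h5write(to_disk(arr), path, paste0(g, "/rf"))
    fid <- rhdf5::H5Fopen(path)
    gid <- rhdf5::H5Gopen(fid, g)
    for (nm in c("axial_spacing", "lateral_spacing", "center_frequency",
                 "sampling_frequency", "timestamps"))
      rhdf5::h5writeAttribute(s$meta[[nm]], gid, nm)
    rhdf5::h5writeAttribute(s$meta$provenance, gid, "provenance")
    rhdf5::H5Gclose(gid); rhdf5::H5Fclose(fid)
    if (!is.null(ground_truth) && !is.null(ground_truth[[k]])) {
      gt <- ground_truth[[k]]
      gg <- paste0(g, "/gt")
      rhdf5::h5createGroup(path, gg)
      ns <- length(gt)
      dsp <- array(0, c(d[1], d[2], 2L, ns))
      psp <- array(0, c(d[1], d[2], 2L, ns))
      stn <- array(0, c(d[1], d[2], ns))
      for (t in seq_len(ns)) {
        dsp[, , 1, t] <- gt[[t]]$displacement$axial
        dsp[, , 2, t] <- gt[[t]]$displacement$lateral
        psp[, , 1, t] <- gt[[t]]$pair_displacement$axial
        psp[, , 2, t] <- gt[[t]]$pair_displacement$lateral
        stn[, , t] <- strain_values(gt[[t]]$strain)
      }
      rhdf5::h5write(dsp, path, paste0(gg, "/displacement"))
      rhdf5::h5write(psp, path, paste0(gg, "/pair_displacement"))
      rhdf5::h5write(stn, path, paste0(gg, "/strain"))
    }
  }
  man <- data.frame(
    id = ids,
    length = vapply(seqs, function(s) length(s$frames), integer(1)),
    split = if (is.null(split)) rep("train", length(seqs)) else split,
    provenance = vapply(seqs, function(s) s$meta$provenance, character(1)),
    stringsAsFactors = FALSE)
  rhdf5::h5createGroup(path, "manifest")
  for (cl in names(man)) rhdf5::h5write(man[[cl]], path, paste0("manifest/", cl))
  rhdf5::h5closeAll()
  invisible(path)
}

#' Read a dataset of RF sequences from HDF5
#'
#' @param path HDF5 file written by [write_dataset()].
#' @param with_gt also load ground truth when present.
#' @return list with `sequences`, `ground_truth` (or `NULL`s) and `manifest`.
#' @export
read_dataset <- function(path, with_gt = TRUE) {
  if (!file.exists(path)) stop("read_dataset: no such file: ", path)
  ls <- rhdf5::h5ls(path)
  if (!any(ls$group == "/" & ls$name == "sequences"))
    stop("read_dataset: format error, missing group /sequences")
  ids <- sort(ls$name[ls$group == "/sequences"])
  man <- NULL
  if (any(ls$group == "/" & ls$name == "manifest")) {
    man <- data.frame(
      id = as.character(rhdf5::h5read(path, "manifest/id")),
      length = as.integer(rhdf5::h5read(path, "manifest/length")),
      split = as.character(rhdf5::h5read(path, "manifest/split")),
      provenance = as.character(rhdf5::h5read(path, "manifest/provenance")),
      stringsAsFactors = FALSE)
  }
  sequences <- list(); gts <- list()
  for (id in ids) {
    g <- paste0("/sequences/", id)
    if (!any(ls$group == g & ls$name == "rf"))
      stop("read_dataset: format error, missing dataset ", g, "/rf")
    arr <- from_disk(rhdf5::h5read(path, paste0(g, "/rf"))) * 1.0
    at <- rhdf5::h5readAttributes(path, g)
    frames <- lapply(seq_len(dim(arr)[3]), function(t) arr[, , t])
    sequences[[id]] <- rf_sequence(
      frames, id = id,
      axial_spacing = as.numeric(at$axial_spacing %||% 0.0385),
      lateral_spacing = as.numeric(at$lateral_spacing %||% 0.3),
      center_frequency = as.numeric(at$center_frequency %||% 5),
      sampling_frequency = as.numeric(at$sampling_frequency %||% 20),
      timestamps = as.numeric(at$timestamps %||% seq_along(frames)),
      provenance = as.character(at$provenance %||% "unknown"))
    gts[[id]] <- NULL
    if (with_gt && any(ls$group == paste0(g, "/gt"))) {
      dsp <- rhdf5::h5read(path, paste0(g, "/gt/displacement"))
      psp <- rhdf5::h5read(path, paste0(g, "/gt/pair_displacement"))
      stn <- rhdf5::h5read(path, paste0(g, "/gt/strain"))
      gts[[id]] <- lapply(seq_len(dim(dsp)[4]), function(t)
        list(displacement = displacement_field(dsp[, , 1, t], dsp[, , 2, t]),
             pair_displacement = displacement_field(psp[, , 1, t], psp[, , 2, t]),
             strain = strain_field(stn[, , t])))
    }
  }
  rhdf5::h5closeAll()
  list(sequences = sequences, ground_truth = gts, manifest = man)
}

# write per-pair predictions under /sequences/<id>/pred (never touches /rf)
write_predictions <- function(path, id, displacements, strains) {
  g <- paste0("sequences/", id, "/pred")
  ls <- rhdf5::h5ls(path)
  if (any(ls$group == paste0("/sequences/", id) & ls$name == "pred")) {
    rhdf5::h5delete(path, g)
  }
  rhdf5::h5createGroup(path, g)
  d <- dim(as_displacement_field(displacements[[1]])$axial)
  ns <- length(displacements)
  dsp <- array(0, c(d[1], d[2], 2L, ns)); stn <- array(0, c(d[1], d[2], ns))
  for (t in seq_len(ns)) {
    df <- as_displacement_field(displacements[[t]])
    dsp[, , 1, t] <- df$axial; dsp[, , 2, t] <- df$lateral
    stn[, , t] <- strain_values(strains[[t]])
  }
  rhdf5::h5write(dsp, path, paste0(g, "/displacement"))
  rhdf5::h5write(stn, path, paste0(g, "/strain"))
  rhdf5::h5closeAll()
  invisible(path)
}

#' B-mode conversion of an RF frame
#'
#' Per scan line, the analytic-signal envelope (Hilbert transform via FFT) is
#' log-compressed (`20 log10(env / max)`), clipped to
#' `[-dynamic_range_db, 0]` and rescaled to `[0, 1]` for display.
#'
#' @param rf RF frame matrix (>= 8 axial samples).
#' @param dynamic_range_db displayed dynamic range in dB.
#' @export
bmode <- function(rf, dynamic_range_db = 50) {
  rf <- as.matrix(rf)
  h <- nrow(rf)
  if (h < 8) stop("bmode: need at least 8 axial samples")
  wts <- rep(0, h); wts[1] <- 1
  if (h %% 2 == 0) { wts[h / 2 + 1] <- 1; wts[2:(h / 2)] <- 2 }
  else wts[2:((h + 1) / 2)] <- 2
  env <- apply(rf, 2, function(col)
    Mod(fft(fft(col) * wts, inverse = TRUE) / h))
  mx <- max(env)
  if (mx == 0) return(matrix(0, h, ncol(rf)))
  db <- 20 * log10(pmax(env / mx, 10^(-dynamic_range_db / 20 - 2)))
  db <- pmin(pmax(db, -dynamic_range_db), 0)
  db / dynamic_range_db + 1
}

#' Read / write landmark files
#'
#' Plain CSV with columns `case, pair, frame, axial, lateral`; `frame` is
#' `"first"` or `"last"`, coordinates are 0-based sample units. Reading
#' returns, per case, the wide data frame accepted by [tre()].
#'
#' @param path CSV path.
#' @export
read_landmarks <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("case", "pair", "frame", "axial", "lateral")
  if (!all(need %in% names(df)))
    stop("read_landmarks: need columns ", paste(need, collapse = ", "))
  out <- list()
  for (cs in unique(df$case)) {
    d <- df[df$case == cs, ]
    fi <- d[d$frame == "first", ]; la <- d[d$frame == "last", ]
    fi <- fi[order(fi$pair), ]; la <- la[order(la$pair), ]
    if (!identical(fi$pair, la$pair))
      stop("read_landmarks: unpaired landmarks in case ", cs)
    out[[as.character(cs)]] <- data.frame(
      pair = fi$pair,
      first_axial = fi$axial, first_lateral = fi$lateral,
      last_axial = la$axial, last_lateral = la$lateral)
  }
  out
}

#' @rdname read_landmarks
#' @param landmarks named list of per-case wide data frames.
#' @export
write_landmarks <- function(landmarks, path) {
  rows <- list()
  for (cs in names(landmarks)) {
    d <- landmarks[[cs]]
    rows[[length(rows) + 1L]] <- data.frame(
      case = cs, pair = d$pair, frame = "first",
      axial = d$first_axial, lateral = d$first_lateral)
    rows[[length(rows) + 1L]] <- data.frame(
      case = cs, pair = d$pair, frame = "last",
      axial = d$last_axial, lateral = d$last_lateral)
  }
  write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}
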