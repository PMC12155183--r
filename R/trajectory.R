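#' Molecule table for a system of three-site waters
#'
#' Site order within each molecule is fixed as (O, H1, H2).
#'
#' @param n_molecules number of water molecules
#' @param q_H hydrogen partial charge, e; the oxygen carries -2*q_H so each
#'   molecule is neutral.
#' @return data.frame with one row per molecule (index, masses and charges of
#'   the three sites).
#' @export
water_molecule_table <- function(n_molecules, q_H = 0.33) {
  stopifnot(n_molecules >= 1)
  data.frame(
    index = seq_len(n_molecules),
    m_O = water_constants$mass_O, m_H1 = water_constants$mass_H,
    m_H2 = water_constants$mass_H,
    q_O = -2 * q_H, q_H1 = q_H, q_H2 = q_H
  )
}

#' Per-site masses for a trajectory (O, H, H repeating)
#' @param n_molecules number of molecules
#' @return numeric vector of length 3*n_molecules, u
#' @export
site_masses <- function(n_molecules) {
  rep(c(water_constants$mass_O, water_constants$mass_H, water_constants$mass_H),
      n_molecules)
}

#' Per-site charges for a trajectory (O, H, H repeating)
#' @param n_molecules number of molecules
#' @param q_H hydrogen partial charge, e
#' @return numeric vector of length 3*n_molecules, e
#' @export
site_charges <- function(n_molecules, q_H = 0.33) {
  rep(c(-2 * q_H, q_H, q_H), n_molecules)
}

#' Single simulation frame
#'
#' @param positions n_sites x 3 matrix, nm (wrapped into the box on creation)
#' @param box a [simulation_box()]
#' @param velocities optional n_sites x 3 matrix, nm/fs
#' @param time frame time, fs
#' @return object of class `md_frame`
#' @export
md_frame <- function(positions, box, velocities = NULL, time = 0) {
  positions <- as.matrix(positions)
  if (ncol(positions) != 3) stop("positions must have 3 columns")
  if (nrow(positions) %% 3 != 0)
    stop("site count must be a multiple of 3 (O,H,H per molecule)")
  if (!all(is.finite(positions))) stop("non-finite positions")
  if (!is.null(velocities)) {
    velocities <- as.matrix(velocities)
    if (!identical(dim(velocities), dim(positions)))
      stop("positions and velocities must have identical dimensions")
    if (!all(is.finite(velocities))) stop("non-finite velocities")
  }
  structure(list(
    time = time,
    positions = wrap_coordinates(positions, box),
    velocities = velocities,
    box = box,
    n_molecules = nrow(positions) / 3
  ), class = "md_frame")
}

#' @export
print.md_frame <- function(x, ...) {
  cat(sprintf("md_frame: %d molecules (%d sites), t = %g fs, L = %.4g nm%s\n",
              x$n_molecules, 3 * x$n_molecules, x$time, x$box$edge_length,
              if (is.null(x$velocities)) " [positions only]" else ""))
  invisible(x)
}

#' Trajectory of three-site water frames
#'
#' Stored internally as dense arrays (n_sites x 3 x n_frames) with a shared
#' box and uniform time spacing.
#'
#' @param positions array n_sites x 3 x n_frames, nm
#' @param box a [simulation_box()]
#' @param times frame times, fs (uniformly spaced)
#' @param velocities optional array matching `positions`, nm/fs
#' @return object of class `water_trajectory`
#' @export
water_trajectory <- function(positions, box, times, velocities = NULL) {
  d <- dim(positions)
  if (length(d) != 3 || d[2] != 3) stop("positions must be n_sites x 3 x n_frames")
  if (d[1] %% 3 != 0) stop("site count must be a multiple of 3")
  if (length(times) != d[3]) stop("times must have one entry per frame")
  if (d[3] >= 3) {
    dt <- diff(times)
    if (max(abs(dt - dt[1])) > 1e-9 * max(abs(dt)))
      stop("frames must be uniformly spaced in time")
  }
  if (!is.null(velocities) && !identical(dim(velocities), d))
    stop("velocities must match positions in shape")
  structure(list(
    positions = positions, velocities = velocities, times = as.numeric(times),
    box = box, n_molecules = d[1] / 3, n_frames = d[3],
    sampling_interval = if (d[3] >= 2) times[2] - times[1] else NA_real_,
    molecules = water_molecule_table(d[1] / 3)
  ), class = "water_trajectory")
}

#' @export
print.water_trajectory <- function(x, ...) {
  cat(sprintf(
    "water_trajectory: %d molecules, %d frames every %g fs, L = %.4g nm%s\n",
    x$n_molecules, x$n_frames, x$sampling_interval, x$box$edge_length,
    if (is.null(x$velocities)) " [positions only]" else ""))
  invisible(x)
}

#' Extract one frame from a trajectory
#' @param traj a [water_trajectory()]
#' @param i frame index (1-based)
#' @return an `md_frame`
#' @export
trajectory_frame <- function(traj, i) {
  stopifnot(inherits(traj, "water_trajectory"), i >= 1, i <= traj$n_frames)
  md_frame(traj$positions[, , i],
           box = traj$box,
           velocities = if (!is.null(traj$velocities)) traj$velocities[, , i],
           time = traj$times[i])
}

#' Write a trajectory as extended-XYZ text
#'
#' One block per frame: site-count line, comment line carrying the frame time
#' (`time_fs=<t>`), then one line per site with element symbol, position
#' (nm) and, when available, velocity (nm/fs).
#'
#' @param traj a [water_trajectory()]
#' @param path output file path
#' @return `path`, invisibly
#' @export
write_trajectory <- function(traj, path) {
  stopifnot(inherits(traj, "water_trajectory"))
  n <- 3 * traj$n_molecules
  elem <- rep(c("O", "H", "H"), traj$n_molecules)
  con <- file(path, "w")
  on.exit(close(con))
  for (f in seq_len(traj$n_frames)) {
    writeLines(as.character(n), con)
    writeLines(sprintf("time_fs=%.6f", traj$times[f]), con)
    p <- traj$positions[, , f, drop = FALSE]
    if (!is.null(traj$velocities)) {
      v <- traj$velocities[, , f, drop = FALSE]
      writeLines(sprintf("%s %.9f %.9f %.9f %.9e %.9e %.9e",
                         elem, p[, 1, 1], p[, 2, 1], p[, 3, 1],
                         v[, 1, 1], v[, 2, 1], v[, 3, 1]), con)
    } else {
      writeLines(sprintf("%s %.9f %.9f %.9f",
                         elem, p[, 1, 1], p[, 2, 1], p[, 3, 1]), con)
    }
  }
  invisible(path)
}

#' Read an extended-XYZ trajectory
#'
#' Accepts plain XYZ (positions only; the result is flagged positions-only)
#' or extended XYZ with three velocity columns. Site count must be divisible
#' by 3 with O,H,H ordering.
#'
#' @param path input file
#' @param box a [simulation_box()] (the box is carried in configuration, not
#'   in the file header)
#' @param sampling_interval expected frame spacing, fs; used when the file's
#'   comment lines carry no `time_fs=` tag.
#' @return a [water_trajectory()]
#' @export
read_trajectory <- function(path, box, sampling_interval = 1) {
  lines <- readLines(path)
  lines <- lines[seq_len(max(which(nzchar(trimws(lines))), 0))]
  if (length(lines) == 0) stop("empty trajectory file")
  i <- 1
  frames_p <- list(); frames_v <- list(); times <- numeric(0)
  n_sites <- NA_integer_
  while (i <= length(lines)) {
    n <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(n) || n <= 0) stop("malformed site-count line at line ", i)
    if (is.na(n_sites)) {
      if (n %% 3 != 0) stop("site count ", n, " not divisible by 3 (O,H,H ordering)")
      n_sites <- n
    } else if (n != n_sites) {
      stop("inconsistent site counts across frames (", n_sites, " vs ", n, ")")
    }
    if (i + 1 + n > length(lines)) stop("truncated frame starting at line ", i)
    comment <- lines[i + 1]
    t <- suppressWarnings(as.numeric(sub(".*time_fs=([-0-9.eE+]+).*", "\\1", comment)))
    body <- lines[(i + 2):(i + 1 + n)]
    toks <- strsplit(trimws(body), "[[:space:]]+")
    ncols <- unique(lengths(toks))
    if (length(ncols) != 1 || !(ncols %in% c(4, 7)))
      stop("each site line must have element + 3 or 6 numeric columns")
    elem <- vapply(toks, `[`, "", 1)
    expected <- rep(c("O", "H", "H"), n / 3)
    if (!all(elem == expected)) stop("sites must follow O,H,H ordering per molecule")
    num <- matrix(suppressWarnings(as.numeric(unlist(lapply(toks, `[`, -1)))),
                  nrow = n, byrow = TRUE)
    if (any(!is.finite(num))) stop("non-numeric coordinate in frame at line ", i)
    frames_p[[length(frames_p) + 1]] <- num[, 1:3, drop = FALSE]
    if (ncols == 7) frames_v[[length(frames_v) + 1]] <- num[, 4:6, drop = FALSE]
    times <- c(times, t)
    i <- i + 2 + n
  }
  nf <- length(frames_p)
  if (anyNA(times)) times <- (seq_len(nf) - 1) * sampling_interval
  pos <- array(unlist(frames_p), dim = c(n_sites, 3, nf))
  vel <- NULL
  if (length(frames_v) == nf && nf > 0)
    vel <- array(unlist(frames_v), dim = c(n_sites, 3, nf))
  traj <- water_trajectory(pos, box, times, velocities = vel)
  attr(traj, "positions_only") <- is.null(vel)
  traj
}
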