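# Trial recordings of the virtual peg-insertion task: 3-D end-effector
# position plus grip force, with the 9-peg board geometry.

#' Default 9-peg board geometry
#'
#' Pegs on a 3 x 3 grid and holes on a parallel 3 x 3 grid 150 mm away in
#' y, all in millimetres in the device workspace frame.
#'
#' @param spacing grid spacing in mm.
#' @param offset peg-to-hole board offset in mm (along y).
#' @return List with `pegs` and `holes`, each a 9 x 3 matrix.
#' @export
vpit_board <- function(spacing = 50, offset = 150) {
  g <- expand.grid(x = spacing * (-1:1), y = spacing * (-1:1))
  pegs <- cbind(g$x, g$y, 0)
  holes <- cbind(g$x, g$y + offset, 0)
  colnames(pegs) <- colnames(holes) <- c("x", "y", "z")
  list(pegs = pegs, holes = holes)
}

#' Construct a trial recording
#'
#' @param time strictly increasing time stamps in seconds with uniform
#'   step (the sampling rate is inferred).
#' @param position n x 3 matrix of end-effector coordinates in mm.
#' @param grip_force non-negative grip force in N, length n.
#' @param board board geometry from [vpit_board()].
#' @param n_repetitions number of times the 9-peg sequence is performed
#'   (protocol value 5).
#' @return Object of class `vpit_trial`.
#' @export
vpit_trial <- function(time, position, grip_force, board = vpit_board(),
                       n_repetitions = 5L) {
  position <- as.matrix(position)
  n <- length(time)
  if (n < 2L || nrow(position) != n || length(grip_force) != n) {
    msr_error("time, position and grip_force must share length >= 2",
              "msrehab_validation_error")
  }
  if (ncol(position) != 3L) {
    msr_error("position must have 3 columns", "msrehab_validation_error")
  }
  dts <- diff(time)
  if (any(dts <= 0) || diff(range(dts)) > 1e-6 * mean(dts)) {
    msr_error("time must be strictly increasing with uniform step",
              "msrehab_validation_error")
  }
  if (any(grip_force < 0)) {
    msr_error("grip_force must be non-negative", "msrehab_validation_error")
  }
  structure(list(time = time, position = position,
                 grip_force = as.numeric(grip_force), board = board,
                 n_repetitions = as.integer(n_repetitions),
                 fs = 1 / mean(dts)),
            class = "vpit_trial")
}

#' Read a trial recording from CSV
#'
#' Expects columns `t_s`, `x_mm`, `y_mm`, `z_mm`, `force_N`.
#'
#' @param path CSV path.
#' @param board board geometry (a YAML/JSON sidecar can be read with
#'   [read_board()]).
#' @param n_repetitions protocol repetitions.
#' @return A `vpit_trial`.
#' @export
read_trial <- function(path, board = vpit_board(), n_repetitions = 5L) {
  df <- read.csv(path)
  need <- c("t_s", "x_mm", "y_mm", "z_mm", "force_N")
  if (!all(need %in% names(df))) {
    msr_error(paste("trial CSV must have columns",
                    paste(need, collapse = ", ")), "msrehab_schema_error")
  }
  vpit_trial(df$t_s, cbind(df$x_mm, df$y_mm, df$z_mm), df$force_N,
             board = board, n_repetitions = n_repetitions)
}

#' Read board geometry from YAML
#'
#' The file must contain `pegs` and `holes`, each a list of 3-element
#' xyz coordinates in mm.
#'
#' @param path YAML path.
#' @return Board list as from [vpit_board()].
#' @export
read_board <- function(path) {
  y <- yaml::read_yaml(path)
  to_mat <- function(l) {
    m <- do.call(rbind, lapply(l, as.numeric))
    colnames(m) <- c("x", "y", "z")
    m
  }
  list(pegs = to_mat(y$pegs), holes = to_mat(y$holes))
}

#' Zero-phase low-pass filter a trial recording
#'
#' Applies a zero-phase (forward-backward) 2nd-order Butterworth low-pass
#' to the position channels and grip force, giving an effective 4th-order
#' response with no phase distortion. The time base is unchanged.
#'
#' @param trial a `vpit_trial`.
#' @param kinematic_cutoff low-pass cutoff for position, Hz (default 10).
#' @param force_cutoff low-pass cutoff for grip force, Hz (default 20).
#' @return The filtered `vpit_trial`.
#' @export
preprocess_trial <- function(trial, kinematic_cutoff = 10,
                             force_cutoff = 20) {
  stopifnot(inherits(trial, "vpit_trial"))
  nyq <- trial$fs / 2
  if (kinematic_cutoff >= nyq || force_cutoff >= nyq ||
      kinematic_cutoff <= 0 || force_cutoff <= 0) {
    msr_error("filter cutoffs must lie in (0, Nyquist)",
              "msrehab_parameter_error")
  }
  # odd-reflection padding suppresses the zero-initial-condition edge
  # transients of forward-backward filtering on non-zero-mean signals
  lp <- function(x, fc) {
    bf <- signal::butter(2, fc / nyq, type = "low")
    n <- length(x)
    np <- min(n - 1L, ceiling(6 * trial$fs / fc))
    xp <- c(2 * x[1L] - x[(np + 1L):2L], x, 2 * x[n] - x[(n - 1L):(n - np)])
    as.numeric(signal::filtfilt(bf, xp))[(np + 1L):(np + n)]
  }
  trial$position <- apply(trial$position, 2L, lp, fc = kinematic_cutoff)
  trial$grip_force <- pmax(lp(trial$grip_force, force_cutoff), 0)
  trial
}

#' Segment a trial into movement phases
#'
#' Grasp onsets are upward crossings of the grip force through the force
#' threshold and releases are the matching downward crossings. Per
#' peg-cycle: transport runs from grasp onset to release (peg carried
#' under active grip), return from release to the next grasp onset (or
#' the end of the recording after the last peg), peg approach from entry
#' into the approach radius around the target peg until grasp onset, and
#' hole approach from entry into the radius around the target hole until
#' release. Indices follow the half-open `[start, end)` convention. Pegs
#' are cycled in board order, nine per repetition.
#'
#' @param trial a (preprocessed) `vpit_trial`.
#' @param force_threshold grasp detection threshold in N (protocol 2 N).
#' @param approach_radius radius around pegs/holes opening the approach
#'   phases, mm.
#' @return data.frame with columns `phase`, `start`, `end`, `peg_index`,
#'   `repetition`.
#' @export
segment_phases <- function(trial, force_threshold = 2,
                           approach_radius = 15) {
  stopifnot(inherits(trial, "vpit_trial"))
  f <- trial$grip_force
  n <- length(f)
  above <- f >= force_threshold
  onsets <- which(!above[-n] & above[-1L]) + 1L
  releases <- which(above[-n] & !above[-1L]) + 1L
  if (length(onsets) == 0L) {
    msr_error("no grasp detected: force never crosses the threshold",
              "msrehab_segmentation_error")
  }
  if (above[1L]) onsets <- c(1L, onsets)
  if (above[n]) releases <- c(releases, n)
  if (length(releases) != length(onsets) || any(releases <= onsets)) {
    msr_error("unmatched grasp/release force crossings",
              "msrehab_segmentation_error")
  }
  segs <- list()
  ncyc <- length(onsets)
  for (i in seq_len(ncyc)) {
    peg <- (i - 1L) %% 9L + 1L
    rep_i <- (i - 1L) %/% 9L + 1L
    on <- onsets[i]
    off <- releases[i]
    seg <- function(phase, s, e) data.frame(
      phase = phase, start = s, end = e, peg_index = peg,
      repetition = rep_i, stringsAsFactors = FALSE)
    # peg approach: search backwards from grasp within the preceding gap
    w0 <- if (i == 1L) 1L else releases[i - 1L]
    dpeg <- row_norms(sweep(trial$position[w0:(on - 1L), , drop = FALSE],
                            2L, trial$board$pegs[peg, ]))
    hit <- which(dpeg < approach_radius)
    if (length(hit) == 0L) {
      msr_error(sprintf("no approach into radius of peg %d (cycle %d)",
                        peg, i), "msrehab_segmentation_error")
    }
    segs[[length(segs) + 1L]] <- seg("peg_approach", w0 + hit[1L] - 1L, on)
    # transport: grasp to release
    segs[[length(segs) + 1L]] <- seg("transport", on, off)
    # hole approach: entry into radius of target hole within transport
    dhole <- row_norms(sweep(trial$position[on:(off - 1L), , drop = FALSE],
                             2L, trial$board$holes[peg, ]))
    hhit <- which(dhole < approach_radius)
    if (length(hhit) == 0L) {
      msr_error(sprintf("no approach into radius of hole %d (cycle %d)",
                        peg, i), "msrehab_segmentation_error")
    }
    segs[[length(segs) + 1L]] <- seg("hole_approach", on + hhit[1L] - 1L, off)
    # return: release to next grasp (or end of recording)
    ret_end <- if (i < ncyc) onsets[i + 1L] else n + 1L
    segs[[length(segs) + 1L]] <- seg("return", off, ret_end)
  }
  out <- do.call(rbind, segs)
  rownames(out) <- NULL
  out
}
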