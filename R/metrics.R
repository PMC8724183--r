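# The ten digital health metrics: smoothness (log dimensionless jerk,
# spectral arc length), efficiency (path length ratio), speed, precision
# (RMS jerk during peg approach) and grip-force coordination (force-rate
# peak count, force-rate spectral arc length).

#' Names of the ten core digital health metrics
#' @return Character vector of length 10.
#' @export
vpit_metric_names <- function() {
  c("log_jerk_transport", "log_jerk_return", "sparc_return",
    "path_length_ratio_transport", "path_length_ratio_return",
    "velocity_max_return", "jerk_peg_approach",
    "force_rate_num_peaks_transport", "force_rate_sparc_transport",
    "force_rate_sparc_hole_approach")
}

#' Direction in which each metric worsens
#'
#' `"higher"` means larger values indicate worse performance (jerk
#' metrics, path length ratios, force-rate peak count); `"lower"` means
#' smaller values are worse (spectral arc lengths, maximum return
#' velocity).
#'
#' @return Named character vector over [vpit_metric_names()].
#' @export
metric_directions <- function() {
  c(log_jerk_transport = "higher", log_jerk_return = "higher",
    sparc_return = "lower", path_length_ratio_transport = "higher",
    path_length_ratio_return = "higher", velocity_max_return = "lower",
    jerk_peg_approach = "higher", force_rate_num_peaks_transport = "higher",
    force_rate_sparc_transport = "lower",
    force_rate_sparc_hole_approach = "lower")
}

segment_jerk <- function(positions, dt) {
  v <- deriv_matrix(positions, dt)
  a <- deriv_matrix(v, dt)
  deriv_matrix(a, dt)
}

path_length <- function(positions) {
  sum(row_norms(diff(positions)))
}

#' Log dimensionless jerk of a movement segment
#'
#' `ln( T^5 / L^2 * integral ||d^3x/dt^3||^2 dt )` with segment duration
#' T and traveled path length L. The scaling makes the quantity invariant
#' to spatial and temporal rescaling of the movement; higher values mean
#' less smooth movements.
#'
#' @param positions n x 3 (or n x 1) position matrix, mm.
#' @param dt sampling interval, s.
#' @return Scalar.
#' @export
log_dimensionless_jerk <- function(positions, dt) {
  positions <- as.matrix(positions)
  n <- nrow(positions)
  if (n < 4L) msr_error("segment too short for jerk computation",
                        "msrehab_degenerate_segment")
  L <- path_length(positions)
  if (L == 0) msr_error("no movement in segment (zero path length)",
                        "msrehab_degenerate_segment")
  j <- segment_jerk(positions, dt)
  # trapezoidal integral of squared jerk magnitude
  j2 <- rowSums(j^2)
  int_j2 <- sum((j2[-1L] + j2[-n]) / 2) * dt
  T <- (n - 1L) * dt
  log(T^5 / L^2 * int_j2)
}

#' Spectral arc length (SPARC) of a speed or force-rate profile
#'
#' Arc length of the normalized magnitude spectrum of the profile over
#' the adaptive band from 0 Hz up to the last frequency (below
#' `max_freq`) whose normalized amplitude still reaches `amp_threshold`,
#' negated so that smoother profiles give values closer to 0. The
#' spectrum amplitude is normalized to its peak, making the measure
#' invariant to amplitude scaling.
#'
#' @param profile non-negative profile (speed, |force rate|), length >= 4.
#' @param dt sampling interval, s.
#' @param max_freq upper band edge, Hz.
#' @param amp_threshold adaptive cutoff fraction of the peak amplitude.
#' @param pad_level zero-padding: FFT length `2^ceil(log2(n) + pad_level)`.
#' @return Scalar <= 0.
#' @export
spectral_arc_length <- function(profile, dt, max_freq = 20,
                                amp_threshold = 0.05, pad_level = 4) {
  n <- length(profile)
  if (n < 4L) msr_error("segment too short for spectral analysis",
                        "msrehab_degenerate_segment")
  if (all(profile == 0)) {
    msr_error("all-zero profile: spectrum undefined",
              "msrehab_degenerate_segment")
  }
  fs <- 1 / dt
  nfft <- 2^ceiling(log2(n) + pad_level)
  spec <- abs(fft(c(profile, rep(0, nfft - n))))
  freq <- (seq_len(nfft) - 1L) * fs / nfft
  spec <- spec / max(spec)
  sel <- freq <= max_freq
  f <- freq[sel]
  m <- spec[sel]
  keep <- which(m >= amp_threshold)
  idx <- keep[1L]:keep[length(keep)]
  f <- f[idx]
  m <- m[idx]
  if (length(f) < 2L) return(0)
  -sum(sqrt((diff(f) / (f[length(f)] - f[1L]))^2 + diff(m)^2))
}

#' Path length ratio of a movement segment
#'
#' Traveled path length divided by the straight-line distance between the
#' segment's start and end points; 1 is a perfectly efficient movement.
#'
#' @param positions n x 3 position matrix, mm.
#' @return Scalar >= 1.
#' @export
path_length_ratio <- function(positions) {
  positions <- as.matrix(positions)
  n <- nrow(positions)
  if (n < 2L) msr_error("segment too short", "msrehab_degenerate_segment")
  chord <- sqrt(sum((positions[n, ] - positions[1L, ])^2))
  if (chord == 0) {
    msr_error("segment starts and ends at the same point",
              "msrehab_degenerate_segment")
  }
  path_length(positions) / chord
}

#' Maximum end-effector speed over a segment
#'
#' @param positions n x 3 position matrix, mm.
#' @param dt sampling interval, s.
#' @return Maximum speed in mm/s.
#' @export
velocity_max <- function(positions, dt) {
  positions <- as.matrix(positions)
  if (nrow(positions) < 2L) {
    msr_error("segment too short", "msrehab_degenerate_segment")
  }
  max(row_norms(deriv_matrix(positions, dt)))
}

#' Root-mean-square jerk of a precision-movement segment
#'
#' RMS magnitude of the third position derivative, in mm/s^3. Used for
#' the peg-approach phase, where precise slow positioning is required;
#' unlike the log dimensionless jerk it is not length/duration
#' normalized.
#'
#' @param positions n x 3 position matrix, mm.
#' @param dt sampling interval, s.
#' @return Scalar >= 0.
#' @export
jerk_rms <- function(positions, dt) {
  positions <- as.matrix(positions)
  if (nrow(positions) < 4L) {
    msr_error("segment too short for jerk computation",
              "msrehab_degenerate_segment")
  }
  sqrt(mean(rowSums(segment_jerk(positions, dt)^2)))
}

# Topographic prominence of local maxima: for each peak, extend left and
# right until a higher sample (or the series edge); the prominence is the
# peak height minus the higher of the two interval minima. Flat-topped
# maxima (runs of equal samples) count once.
peak_prominences <- function(x) {
  n <- length(x)
  r <- rle(x)
  k <- length(r$values)
  run_start <- cumsum(r$lengths) - r$lengths + 1L
  is_peak <- logical(k)
  if (k >= 3L) {
    v <- r$values
    is_peak[2:(k - 1L)] <- v[2:(k - 1L)] > v[1:(k - 2L)] &
      v[2:(k - 1L)] > v[3:k]
  }
  peaks <- run_start[is_peak]
  proms <- vapply(peaks, function(p) {
    lmin <- x[p]
    i <- p
    while (i > 1L && x[i - 1L] <= x[p]) {
      i <- i - 1L
      lmin <- min(lmin, x[i])
    }
    rmin <- x[p]
    i <- p
    while (i < n && x[i + 1L] <= x[p]) {
      i <- i + 1L
      rmin <- min(rmin, x[i])
    }
    x[p] - max(lmin, rmin)
  }, numeric(1))
  list(peaks = peaks, prominences = proms)
}

#' Number of prominent peaks in the force-rate profile
#'
#' The force rate is the first derivative of the grip force. Local maxima
#' of the signed force-rate signal are counted if their topographic
#' prominence reaches `prominence_fraction` of the signal's total range;
#' smooth single-burst force modulation yields 0 extra peaks while
#' oscillatory grip control raises the count. The 10% default prominence
#' floor is chosen so that sharp but isolated grasp/release force
#' transients at the segment edges do not register as grip instability.
#'
#' @param force grip-force series, N.
#' @param dt sampling interval, s.
#' @param prominence_fraction minimum prominence as a fraction of the
#'   force-rate range.
#' @return Non-negative integer count.
#' @export
force_rate_num_peaks <- function(force, dt, prominence_fraction = 0.1) {
  if (length(force) < 3L) return(0L)
  fr <- central_diff(force, dt)
  rng <- diff(range(fr))
  # a force-rate range at floating-point jitter scale is flat, not peaky
  if (rng <= 1e-9 * max(abs(fr), 1)) return(0L)
  pp <- peak_prominences(fr)
  sum(pp$prominences >= prominence_fraction * rng)
}

#' Spectral arc length of the force-rate magnitude
#'
#' [spectral_arc_length()] applied to the absolute first derivative of
#' the grip force; captures the smoothness of grip-force modulation
#' during transport and hole approach.
#'
#' @inheritParams force_rate_num_peaks
#' @param ... passed to [spectral_arc_length()].
#' @return Scalar <= 0.
#' @export
force_rate_sparc <- function(force, dt, ...) {
  if (length(force) < 4L) {
    msr_error("segment too short for spectral analysis",
              "msrehab_degenerate_segment")
  }
  fr <- abs(central_diff(force, dt))
  if (all(fr == 0)) {
    msr_error("all-zero force rate: spectrum undefined",
              "msrehab_degenerate_segment")
  }
  spectral_arc_length(fr, dt, ...)
}

#' Configuration for metric extraction
#'
#' @param aggregate function pooling per-movement values into one value
#'   per metric (default median, robust to single outlier movements).
#' @param min_valid_movements minimum number of successfully computed
#'   movement instances per metric.
#' @param max_freq,amp_threshold,pad_level SPARC parameters.
#' @param prominence_fraction force-rate peak prominence fraction.
#' @param force_threshold,approach_radius segmentation parameters.
#' @return List of class `metric_config`.
#' @export
metric_config <- function(aggregate = median, min_valid_movements = 5L,
                          max_freq = 20, amp_threshold = 0.05,
                          pad_level = 4, prominence_fraction = 0.1,
                          force_threshold = 2, approach_radius = 15) {
  structure(list(aggregate = aggregate,
                 min_valid_movements = as.integer(min_valid_movements),
                 max_freq = max_freq, amp_threshold = amp_threshold,
                 pad_level = pad_level,
                 prominence_fraction = prominence_fraction,
                 force_threshold = force_threshold,
                 approach_radius = approach_radius),
            class = "metric_config")
}

#' Compute the ten raw digital health metrics of one trial
#'
#' Segments the trial into phases, computes each metric for every
#' movement instance (per peg-cycle phase) and aggregates across all
#' movements of the repetitions with the configured aggregator (default
#' median). Movement instances whose segment is degenerate for a given
#' metric are dropped; a metric with fewer than `min_valid_movements`
#' valid instances triggers an insufficient-data error.
#'
#' @param trial a preprocessed `vpit_trial` (see [preprocess_trial()]).
#' @param segments optional precomputed [segment_phases()] table.
#' @param config a [metric_config()].
#' @return Named numeric vector of the ten raw metrics (class
#'   `metric_vector`).
#' @export
compute_metric_vector <- function(trial, segments = NULL,
                                  config = metric_config()) {
  stopifnot(inherits(trial, "vpit_trial"))
  if (is.null(segments)) {
    segments <- segment_phases(trial, config$force_threshold,
                               config$approach_radius)
  }
  dt <- 1 / trial$fs
  pos <- function(s) trial$position[s$start:(s$end - 1L), , drop = FALSE]
  frc <- function(s) trial$grip_force[s$start:(s$end - 1L)]
  speed <- function(s) row_norms(deriv_matrix(pos(s), dt))
  per_phase <- function(phase) {
    rows <- segments[segments$phase == phase, , drop = FALSE]
    split(rows, seq_len(nrow(rows)))
  }
  safe <- function(segs, fun) {
    vals <- unlist(lapply(segs, function(s) {
      tryCatch(fun(s), msrehab_degenerate_segment = function(e) NULL)
    }))
    vals
  }
  transports <- per_phase("transport")
  returns <- per_phase("return")
  pegapp <- per_phase("peg_approach")
  holeapp <- per_phase("hole_approach")
  sparc_args <- function(x) spectral_arc_length(
    x, dt, max_freq = config$max_freq,
    amp_threshold = config$amp_threshold, pad_level = config$pad_level)
  raw <- list(
    log_jerk_transport = safe(transports,
                              function(s) log_dimensionless_jerk(pos(s), dt)),
    log_jerk_return = safe(returns,
                           function(s) log_dimensionless_jerk(pos(s), dt)),
    sparc_return = safe(returns, function(s) sparc_args(speed(s))),
    path_length_ratio_transport = safe(transports,
                                       function(s) path_length_ratio(pos(s))),
    path_length_ratio_return = safe(returns,
                                    function(s) path_length_ratio(pos(s))),
    velocity_max_return = safe(returns, function(s) velocity_max(pos(s), dt)),
    jerk_peg_approach = safe(pegapp, function(s) jerk_rms(pos(s), dt)),
    force_rate_num_peaks_transport = safe(transports, function(s)
      force_rate_num_peaks(frc(s), dt, config$prominence_fraction)),
    force_rate_sparc_transport = safe(transports, function(s)
      force_rate_sparc(frc(s), dt, max_freq = config$max_freq,
                       amp_threshold = config$amp_threshold,
                       pad_level = config$pad_level)),
    force_rate_sparc_hole_approach = safe(holeapp, function(s)
      force_rate_sparc(frc(s), dt, max_freq = config$max_freq,
                       amp_threshold = config$amp_threshold,
                       pad_level = config$pad_level))
  )
  short <- names(raw)[vapply(raw, length, integer(1)) <
                        config$min_valid_movements]
  if (length(short) > 0L) {
    msr_error(sprintf("insufficient valid movements for metric(s): %s",
                      paste(short, collapse = ", ")),
              "msrehab_insufficient_data")
  }
  out <- vapply(raw, config$aggregate, numeric(1))
  structure(out[vpit_metric_names()], class = "metric_vector")
}

#' Write a tidy per-dataset metric table
#'
#' Long CSV with columns `dataset_id`, `metric`, `raw`, `normalized_pct`.
#'
#' @param metrics data.frame with `dataset_id` and one column per metric
#'   (raw values); `normalized` an optional matching data.frame of
#'   normalized (%) values.
#' @param path output CSV path.
#' @param normalized optional normalized table.
#' @return `path`, invisibly.
#' @export
write_metric_table <- function(metrics, path, normalized = NULL) {
  long <- do.call(rbind, lapply(vpit_metric_names(), function(m) {
    data.frame(dataset_id = metrics$dataset_id, metric = m,
               raw = metrics[[m]],
               normalized_pct = if (is.null(normalized)) NA_real_
                                else normalized[[m]],
               stringsAsFactors = FALSE)
  }))
  write.csv(long, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
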