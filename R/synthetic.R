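# Synthetic generators: peg-insertion trial signals with controllable
# impairment, a stand-in reference population, and cohorts with planted
# predictor-outcome structure. The kinematic primitive is the minimum-jerk
# point-to-point profile, which has closed-form derivatives and therefore
# serves as an oracle for the smoothness metrics.

#' Parameters for the synthetic trial generator
#'
#' @param fs sampling rate, Hz.
#' @param board board geometry from [vpit_board()].
#' @param transport_duration,return_duration movement durations, s.
#' @param dwell_duration grasp/release dwell duration, s.
#' @param force_peak grip-force plateau during transport, N.
#' @param grip_modulation_amplitude amplitude of the smooth physiological
#'   grip-force bell superimposed on the plateau, N.
#' @param tremor_amplitude,tremor_freq sinusoidal tremor added to the
#'   position channels, mm and Hz (4 Hz default, within the intention
#'   tremor band).
#' @param curvature_gain dimensionless perpendicular path-bulge gain.
#' @param force_osc_amplitude,force_osc_freq oscillatory grip-force
#'   perturbation during transport, N and Hz.
#' @param noise_pos_sd,noise_force_sd observation noise SDs (mm, N).
#' @param n_repetitions number of 9-peg sequences.
#' @param start_pos initial end-effector position, mm.
#' @param seed RNG seed (used only when noise is non-zero).
#' @return List of class `trial_gen_params`.
#' @export
trial_gen_params <- function(fs = 100, board = vpit_board(),
                             transport_duration = 1.0,
                             return_duration = 1.0,
                             dwell_duration = 0.4,
                             force_peak = 10,
                             grip_modulation_amplitude = 1,
                             tremor_amplitude = 0, tremor_freq = 4,
                             curvature_gain = 0,
                             force_osc_amplitude = 0, force_osc_freq = 6,
                             noise_pos_sd = 0, noise_force_sd = 0,
                             n_repetitions = 5L,
                             start_pos = c(0, -150, 50), seed = 1L) {
  p <- list(fs = fs, board = board,
            transport_duration = transport_duration,
            return_duration = return_duration,
            dwell_duration = dwell_duration, force_peak = force_peak,
            grip_modulation_amplitude = grip_modulation_amplitude,
            tremor_amplitude = tremor_amplitude,
            tremor_freq = tremor_freq, curvature_gain = curvature_gain,
            force_osc_amplitude = force_osc_amplitude,
            force_osc_freq = force_osc_freq,
            noise_pos_sd = noise_pos_sd, noise_force_sd = noise_force_sd,
            n_repetitions = as.integer(n_repetitions),
            start_pos = start_pos, seed = as.integer(seed))
  if (any(c(p$transport_duration, p$return_duration,
            p$dwell_duration) <= 0) || p$fs <= 0) {
    msr_error("durations and sampling rate must be positive",
              "msrehab_parameter_error")
  }
  if (any(c(p$tremor_amplitude, p$curvature_gain, p$force_osc_amplitude,
            p$noise_pos_sd, p$noise_force_sd) < 0)) {
    msr_error("amplitudes must be non-negative", "msrehab_parameter_error")
  }
  if (p$force_osc_amplitude >= p$force_peak -
        p$grip_modulation_amplitude - 2) {
    msr_error("force oscillation too large: grip would drop below the grasp threshold mid-transport",
              "msrehab_parameter_error")
  }
  if (round(p$dwell_duration * p$fs) < 4) {
    msr_error("dwell too short: no force threshold crossing can be planted",
              "msrehab_parameter_error")
  }
  class(p) <- "trial_gen_params"
  p
}

min_jerk_s <- function(tau) 10 * tau^3 - 15 * tau^4 + 6 * tau^5

# unit vector perpendicular to dir (for the curvature bulge)
perp_unit <- function(dir) {
  u <- c(-dir[2L], dir[1L], 0)
  if (sum(u^2) < 1e-12) u <- c(1, 0, 0)
  u / sqrt(sum(u^2))
}

#' Generate a synthetic peg-insertion trial with ground-truth events
#'
#' Concatenates minimum-jerk point-to-point movements through the nine
#' peg-to-hole cycles of each repetition, with grasp/release dwells in
#' which the grip force ramps through the 2 N grasp threshold at known
#' sample indices. Impairment knobs add sinusoidal tremor to the
#' position, a perpendicular path bulge (curvature), and oscillatory
#' grip-force perturbations during transport; observation noise is
#' optional. With a fixed seed the recording is bitwise reproducible.
#'
#' @param params a [trial_gen_params()].
#' @return List with `trial` (a [vpit_trial()]) and `events`
#'   (data.frame: `cycle`, `peg_index`, `repetition`, `grasp_onset`,
#'   `release` sample indices; the planted transport is
#'   `[grasp_onset, release)`).
#' @export
gen_trial <- function(params = trial_gen_params()) {
  stopifnot(inherits(params, "trial_gen_params"))
  p <- params
  fs <- p$fs
  pegs <- p$board$pegs
  holes <- p$board$holes
  n_cycles <- 9L * p$n_repetitions
  pos <- list(matrix(p$start_pos, nrow = 1L))
  force <- list(0)
  events <- vector("list", n_cycles)
  cursor <- 1L     # samples emitted so far
  current <- p$start_pos
  move_piece <- function(from, to, duration) {
    m <- round(duration * fs)
    tau <- seq_len(m) / m
    s <- min_jerk_s(tau)
    seg <- outer(s, to - from) + rep(from, each = m)
    if (p$curvature_gain > 0) {
      d <- sqrt(sum((to - from)^2))
      u <- perp_unit(to - from)
      seg <- seg + outer(p$curvature_gain * d * sin(pi * tau), u)
    }
    seg
  }
  for (cyc in seq_len(n_cycles)) {
    peg <- (cyc - 1L) %% 9L + 1L
    # reach/return movement to the peg (zero force)
    seg <- move_piece(current, pegs[peg, ], p$return_duration)
    pos[[length(pos) + 1L]] <- seg
    force[[length(force) + 1L]] <- rep(0, nrow(seg))
    cursor <- cursor + nrow(seg)
    current <- pegs[peg, ]
    # grasp dwell: force rises 0 -> peak along a smoothstep (bell-shaped
    # force rate, as in unimpaired grasp buildup)
    m_d <- round(p$dwell_duration * fs)
    ramp_up <- p$force_peak * min_jerk_s(seq_len(m_d) / m_d)
    grasp_onset <- cursor + which(ramp_up >= 2)[1L]
    pos[[length(pos) + 1L]] <- matrix(current, nrow = m_d, ncol = 3L,
                                      byrow = TRUE)
    force[[length(force) + 1L]] <- ramp_up
    cursor <- cursor + m_d
    # transport movement peg -> hole under grip
    seg <- move_piece(current, holes[peg, ], p$transport_duration)
    m_t <- nrow(seg)
    tau <- seq_len(m_t) / m_t
    f_t <- p$force_peak +
      p$grip_modulation_amplitude * sin(pi * tau) +
      p$force_osc_amplitude *
        sin(2 * pi * p$force_osc_freq * tau * p$transport_duration)
    pos[[length(pos) + 1L]] <- seg
    force[[length(force) + 1L]] <- f_t
    cursor <- cursor + m_t
    current <- holes[peg, ]
    # release dwell: force ramps peak -> 0
    ramp_down <- p$force_peak * (1 - min_jerk_s(seq_len(m_d) / m_d))
    release <- cursor + which(ramp_down < 2)[1L]
    pos[[length(pos) + 1L]] <- matrix(current, nrow = m_d, ncol = 3L,
                                      byrow = TRUE)
    force[[length(force) + 1L]] <- ramp_down
    cursor <- cursor + m_d
    events[[cyc]] <- data.frame(cycle = cyc, peg_index = peg,
                                repetition = (cyc - 1L) %/% 9L + 1L,
                                grasp_onset = grasp_onset,
                                release = release)
  }
  position <- do.call(rbind, pos)
  grip <- unlist(force)
  n <- nrow(position)
  t <- (seq_len(n) - 1L) / fs
  if (p$tremor_amplitude > 0) {
    trem <- p$tremor_amplitude * sin(2 * pi * p$tremor_freq * t)
    position[, 1L] <- position[, 1L] + trem
    position[, 3L] <- position[, 3L] + trem
  }
  if (p$noise_pos_sd > 0 || p$noise_force_sd > 0) {
    set.seed(p$seed)
    position <- position + rnorm(length(position), sd = p$noise_pos_sd)
    grip <- pmax(grip + rnorm(n, sd = p$noise_force_sd), 0)
  }
  list(trial = vpit_trial(t, position, grip, board = p$board,
                          n_repetitions = p$n_repetitions),
       events = do.call(rbind, events))
}

#' Generate a synthetic reference population
#'
#' Builds a stand-in for the normative database used for metric
#' normalization. The healthy center of each metric is calibrated by
#' computing the ten metrics on one clean generated trial; per-subject
#' healthy values are then drawn around that center with planted linear
#' age and sex confound effects (plus dominant-hand and stereo-vision
#' effects) and Gaussian noise, and impaired subjects are shifted along
#' each metric's worse direction by a uniform impairment severity.
#'
#' @param n_healthy number of neurologically intact subjects (>= 10).
#' @param n_impaired number of impaired subjects anchoring the 100% end.
#' @param seed RNG seed.
#' @param trial_params clean-trial parameters used for calibration.
#' @param spread_fraction per-metric dispersion scale as a fraction of
#'   the metric's healthy magnitude (floor 0.5 in native units).
#' @param age_slope planted worse-ward age effect per year, in units of
#'   the dispersion scale.
#' @param sex_effect,dominant_effect,stereo_effect planted effects (same
#'   units; dominant-hand testing improves, i.e. acts better-ward).
#' @param noise_fraction residual SD in units of the dispersion scale.
#' @param impair_range uniform range of impairment severities (in
#'   dispersion-scale units) for the impaired sample.
#' @return List with `reference` (a [vpit_reference()]), `healthy` and
#'   `impaired` per-subject metric tables, and `base` (the calibration
#'   metric vector).
#' @export
gen_reference_population <- function(n_healthy = 120L, n_impaired = 20L,
                                     seed = 1L,
                                     trial_params = trial_gen_params(),
                                     spread_fraction = 0.1,
                                     age_slope = 0.03, sex_effect = 0.5,
                                     dominant_effect = -0.3,
                                     stereo_effect = 0.8,
                                     noise_fraction = 0.2,
                                     impair_range = c(2, 8)) {
  if (n_healthy < 10L) {
    msr_error("need at least 10 healthy subjects", "msrehab_parameter_error")
  }
  base <- compute_metric_vector(preprocess_trial(gen_trial(trial_params)$trial))
  mets <- vpit_metric_names()
  dirs <- metric_directions()
  u <- ifelse(dirs[mets] == "higher", 1, -1)
  s <- pmax(spread_fraction * abs(base), 0.5)
  set.seed(seed)
  draw <- function(n, impaired) {
    age <- runif(n, 20, 80)
    sex <- rbinom(n, 1L, 0.5)
    dom <- rbinom(n, 1L, 0.5)
    ster <- rbinom(n, 1L, if (impaired) 0.3 else 0.1)
    sev <- if (impaired) runif(n, impair_range[1L], impair_range[2L]) else 0
    vals <- vapply(seq_along(mets), function(i) {
      base[i] + u[i] * s[i] *
        (age_slope * (age - 50) + sex_effect * sex +
           dominant_effect * dom + stereo_effect * ster + sev) +
        rnorm(n, sd = noise_fraction * s[i])
    }, numeric(n))
    colnames(vals) <- mets
    df <- data.frame(age = age, sex = sex, dominant_hand_tested = dom,
                     stereo_vision_deficit = ster)
    cbind(df, as.data.frame(vals))
  }
  healthy <- draw(n_healthy, impaired = FALSE)
  impaired <- draw(n_impaired, impaired = TRUE)
  list(reference = vpit_reference(healthy, impaired),
       healthy = healthy, impaired = impaired, base = base,
       planted = list(age_slope = u * s * age_slope,
                      sex_effect = u * s * sex_effect))
}

#' Parameters for the synthetic cohort generator
#'
#' Defaults emulate the statistical structure of the clinical cohort:
#' age ~ Normal(56.7, 14.8^2), chronicity ~ Normal(18.1, 12^2) truncated
#' at 0, 7/11 female, MS types RR/PP/SP at 6/3/2 out of 11, intervention
#' groups at 5/5/1, EDSS ~ Normal(6.1, 1.3^2) rounded to 0.5 steps, 9 of
#' 11 participants contributing both sides, and per-scale baseline
#' responder rates matching the observed 6/20, 9/20 and 6/20.
#'
#' @param n_participants number of participants.
#' @param p_two_sides probability a participant contributes both sides.
#' @param age_mean,age_sd,chronicity_mean,chronicity_sd,edss_mean,edss_sd
#'   covariate distribution parameters.
#' @param sex_p_f probability of female.
#' @param ms_type_probs,group_probs category frequencies.
#' @param beta0 named per-scale intercepts of the logistic responder
#'   model (on the log-odds scale).
#' @param beta named list of per-scale coefficient vectors over
#'   standardized features (`age`, `chronicity` z-scored; `sex` 0/1 with
#'   M = 1; `edss` z-scored); an empty vector is the exact null model.
#' @param responder_margin responder score gaps start at
#'   `(1 + margin) * SRD` and non-responder changes stay below
#'   `(1 - margin) * SRD`, keeping labels unambiguous under rounding.
#' @param thresholds an [srd_thresholds()].
#' @param seed RNG seed.
#' @return List of class `cohort_gen_params`.
#' @export
cohort_gen_params <- function(n_participants = 11L, p_two_sides = 9 / 11,
                              age_mean = 56.7, age_sd = 14.8,
                              chronicity_mean = 18.1, chronicity_sd = 12,
                              sex_p_f = 7 / 11,
                              ms_type_probs = c(RR = 6, PP = 3, SP = 2) / 11,
                              group_probs = c(5, 5, 1) / 11,
                              edss_mean = 6.1, edss_sd = 1.3,
                              beta0 = qlogis(c(arat = 0.3, bbt = 0.45,
                                               nhpt = 0.3)),
                              beta = list(arat = numeric(0),
                                          bbt = numeric(0),
                                          nhpt = numeric(0)),
                              responder_margin = 0.5,
                              thresholds = srd_thresholds(), seed = 1L) {
  p <- as.list(environment())
  prob_ok <- function(x) all(x >= 0) && abs(sum(x) - 1) < 1e-8
  if (!prob_ok(p$ms_type_probs) || !prob_ok(p$group_probs) ||
      p$sex_p_f < 0 || p$sex_p_f > 1 || p$p_two_sides < 0 ||
      p$p_two_sides > 1) {
    msr_error("category probabilities must be valid", "msrehab_parameter_error")
  }
  if (p$responder_margin <= 0 || p$responder_margin >= 1) {
    msr_error("responder_margin must lie in (0, 1)", "msrehab_parameter_error")
  }
  class(p) <- "cohort_gen_params"
  p
}

#' Generate a synthetic cohort with known responder status
#'
#' Draws participant covariates, assigns each dataset a true responder
#' status per scale from the logistic outcome model, and constructs
#' pre/post scores whose SRD labelling reproduces the drawn status
#' exactly: responders change by at least `(1 + margin) * SRD`,
#' non-responders by strictly less than `(1 - margin) * SRD`.
#'
#' @param params a [cohort_gen_params()].
#' @return List with `cohort` (an [ms_cohort()], provenance
#'   "synthetic") and `labels` (data.frame of true per-scale responder
#'   status).
#' @export
gen_cohort <- function(params = cohort_gen_params()) {
  stopifnot(inherits(params, "cohort_gen_params"))
  p <- params
  set.seed(p$seed)
  th <- p$thresholds
  ids <- sprintf("S%03d", seq_len(p$n_participants))
  age <- pmin(pmax(round(rnorm(p$n_participants, p$age_mean, p$age_sd)),
                   18), 90)
  chron <- pmax(round(rnorm(p$n_participants, p$chronicity_mean,
                            p$chronicity_sd)), 0)
  sex <- ifelse(runif(p$n_participants) < p$sex_p_f, "F", "M")
  ms <- sample(names(p$ms_type_probs), p$n_participants, replace = TRUE,
               prob = p$ms_type_probs)
  grp <- sample(seq_along(p$group_probs), p$n_participants, replace = TRUE,
                prob = p$group_probs)
  edss <- pmin(pmax(round(rnorm(p$n_participants, p$edss_mean,
                                p$edss_sd) * 2) / 2, 0), 10)
  two <- runif(p$n_participants) < p$p_two_sides
  rows <- list()
  labs <- list()
  for (i in seq_len(p$n_participants)) {
    sides <- if (two[i]) c("left", "right") else
      sample(c("left", "right"), 1L)
    feats <- c(age = (age[i] - p$age_mean) / p$age_sd,
               chronicity = (chron[i] - p$chronicity_mean) / p$chronicity_sd,
               sex = as.numeric(sex[i] == "M"),
               edss = (edss[i] - p$edss_mean) / p$edss_sd)
    for (sd_ in sides) {
      status <- vapply(c("arat", "bbt", "nhpt"), function(s) {
        b <- p$beta[[s]]
        eta <- p$beta0[[s]] +
          if (length(b) > 0L) sum(b * feats[names(b)]) else 0
        runif(1) < plogis(eta)
      }, logical(1))
      m <- p$responder_margin
      # ARAT (integer 0-57)
      if (status["arat"]) {
        gap <- sample(ceiling(th$arat * (1 + m)):12, 1L)
        a_pre <- sample(20:(57 - 12), 1L)
        a_post <- a_pre + gap
      } else {
        a_pre <- sample(20:57, 1L)
        a_post <- min(max(a_pre + sample(-floor(th$arat * (1 - m)):
                                           floor(th$arat * (1 - m)), 1L),
                          0L), 57L)
      }
      # BBT (blocks/min)
      b_pre <- round(runif(1, 15, 55))
      b_post <- if (status["bbt"]) {
        b_pre + round(runif(1, th$bbt * (1 + m), th$bbt * 2))
      } else {
        max(b_pre + round(runif(1, -th$bbt * (1 - m), th$bbt * (1 - m))), 0)
      }
      # NHPT (seconds)
      n_pre <- runif(1, 18, 90)
      n_post <- if (status["nhpt"]) {
        n_pre - runif(1, th$nhpt * (1 + m), th$nhpt * 3)
      } else {
        n_pre - runif(1, -th$nhpt * (1 - m), th$nhpt * (1 - m))
      }
      rows[[length(rows) + 1L]] <- data.frame(
        participant_id = ids[i], side = sd_, age = age[i], sex = sex[i],
        ms_type = ms[i], chronicity = chron[i], intervention_group = grp[i],
        edss = edss[i], arat_pre = a_pre, arat_post = a_post,
        bbt_pre = b_pre, bbt_post = b_post, nhpt_pre = n_pre,
        nhpt_post = n_post, stringsAsFactors = FALSE)
      labs[[length(labs) + 1L]] <- data.frame(
        dataset_id = paste(ids[i], sd_, sep = "_"),
        arat = unname(status["arat"]), bbt = unname(status["bbt"]),
        nhpt = unname(status["nhpt"]), stringsAsFactors = FALSE)
    }
  }
  list(cohort = ms_cohort(do.call(rbind, rows), provenance = "synthetic"),
       labels = do.call(rbind, labs))
}
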