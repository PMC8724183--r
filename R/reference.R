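# Reference population: healthy anchors, confound models and the
# dual-anchor percentage normalization (0% = healthy median task
# performance, 100% = worst impaired performance).

.confound_covariates <- c("age", "sex", "dominant_hand_tested",
                          "stereo_vision_deficit")

#' Build a reference population from healthy and impaired metric tables
#'
#' Fits, per metric, an ordinary-least-squares confound model on the
#' healthy sample (covariates: age, sex, whether the dominant hand was
#' tested, stereo vision deficit; sex and the two flags coded 0/1), and
#' derives the two normalization anchors: the healthy median of the
#' confound-adjusted metric and the worst confound-adjusted value in the
#' impaired sample along each metric's worse direction.
#'
#' @param healthy data.frame with the four covariate columns and the ten
#'   metric columns, one row per neurologically intact subject.
#' @param impaired data.frame with the same columns for neurologically
#'   affected subjects.
#' @return Object of class `vpit_reference` with elements
#'   `coefficients` (10 x 4 matrix), `covariate_means`,
#'   `covariate_range`, `healthy_median`, `worst_impaired`,
#'   `worse_direction`.
#' @export
vpit_reference <- function(healthy, impaired) {
  mets <- vpit_metric_names()
  for (tab in list(healthy, impaired)) {
    miss <- setdiff(c(.confound_covariates, mets), names(tab))
    if (length(miss) > 0L) {
      msr_error(paste("reference table lacks columns:",
                      paste(miss, collapse = ", ")),
                "msrehab_validation_error")
    }
  }
  if (nrow(healthy) < 10L) {
    msr_error("healthy reference sample too small (need >= 10)",
              "msrehab_parameter_error")
  }
  cov_h <- as.matrix(healthy[, .confound_covariates, drop = FALSE])
  cmeans <- colMeans(cov_h)
  crange <- apply(cov_h, 2L, range)
  coefs <- t(vapply(mets, function(m) {
    fit <- lm(healthy[[m]] ~ cov_h)
    b <- coef(fit)[-1L]
    b[is.na(b)] <- 0
    unname(b)
  }, numeric(length(.confound_covariates))))
  colnames(coefs) <- .confound_covariates
  adjust_tab <- function(tab) {
    cc <- as.matrix(tab[, .confound_covariates, drop = FALSE])
    centered <- sweep(cc, 2L, cmeans)
    as.matrix(tab[, mets, drop = FALSE]) - centered %*% t(coefs)
  }
  adj_h <- adjust_tab(healthy)
  adj_i <- adjust_tab(impaired)
  dirs <- metric_directions()
  med <- apply(adj_h, 2L, median)
  worst <- vapply(mets, function(m) {
    if (dirs[[m]] == "higher") max(adj_i[, m]) else min(adj_i[, m])
  }, numeric(1))
  if (any(worst == med)) {
    msr_error("degenerate reference: worst impaired equals healthy median",
              "msrehab_configuration_error")
  }
  structure(list(coefficients = coefs, covariate_means = cmeans,
                 covariate_range = crange, healthy_median = med,
                 worst_impaired = worst, worse_direction = dirs),
            class = "vpit_reference")
}

covariate_vector <- function(covariates) {
  if (is.list(covariates)) covariates <- unlist(covariates)
  miss <- setdiff(.confound_covariates, names(covariates))
  if (length(miss) > 0L) {
    msr_error(paste("missing covariate(s):", paste(miss, collapse = ", ")),
              "msrehab_validation_error")
  }
  as.numeric(covariates[.confound_covariates])
}

#' Remove modelled confound effects from a raw metric vector
#'
#' Subtracts the reference confound model's predicted contribution of the
#' subject's covariates (relative to the reference covariate means), so
#' that a subject with reference-mean covariates is returned unchanged.
#' Covariates outside the reference support trigger a warning;
#' extrapolation is permitted.
#'
#' @param raw named numeric vector of the ten raw metrics.
#' @param covariates named vector/list with `age`, `sex` (0/1, M = 1),
#'   `dominant_hand_tested` (0/1), `stereo_vision_deficit` (0/1).
#' @param reference a [vpit_reference()].
#' @return Adjusted `metric_vector`.
#' @export
adjust_confounds <- function(raw, covariates, reference) {
  stopifnot(inherits(reference, "vpit_reference"))
  raw <- raw[vpit_metric_names()]
  cv <- covariate_vector(covariates)
  lo <- reference$covariate_range[1L, ]
  hi <- reference$covariate_range[2L, ]
  if (any(cv < lo | cv > hi)) {
    msr_warn("covariates outside the reference support; extrapolating",
             "msrehab_extrapolation")
  }
  adj <- raw - drop(reference$coefficients %*%
                      (cv - reference$covariate_means))
  structure(setNames(adj, vpit_metric_names()), class = "metric_vector")
}

#' Normalize metrics to the dual-anchor percentage scale
#'
#' Affine per-metric map `100 * (value - healthy_median) /
#' (worst_impaired - healthy_median)`: 0% is the healthy reference
#' median, 100% the worst impaired anchor, values better than the
#' healthy median become negative, and the scale is unbounded in both
#' directions. Because the worst anchor lies on each metric's worse
#' side, larger percentages always mean worse performance regardless of
#' the metric's native direction.
#'
#' @param adjusted named numeric vector of confound-adjusted metrics.
#' @param reference a [vpit_reference()].
#' @return Named numeric vector on the percent scale (class
#'   `metric_vector`).
#' @export
normalize_metrics <- function(adjusted, reference) {
  stopifnot(inherits(reference, "vpit_reference"))
  adjusted <- adjusted[vpit_metric_names()]
  span <- reference$worst_impaired - reference$healthy_median
  if (any(span == 0)) {
    msr_error("zero anchor span in reference", "msrehab_configuration_error")
  }
  pct <- 100 * (adjusted - reference$healthy_median) / span
  structure(setNames(pct, vpit_metric_names()), class = "metric_vector")
}
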