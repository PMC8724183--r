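# Smallest-real-difference (SRD) responder labelling of pre/post changes
# in the three activity scales.

#' SRD thresholds for the three activity scales
#'
#' The smallest real difference is the change magnitude below which a
#' score difference cannot be distinguished from measurement noise. The
#' defaults are the published values for neurological subjects: 5.27 ARAT
#' points, 8.11 BBT blocks/min, 5.32 NHPT seconds.
#'
#' @param arat,bbt,nhpt positive thresholds on the raw scale units.
#' @return Named list of class `srd_thresholds`.
#' @export
srd_thresholds <- function(arat = 5.27, bbt = 8.11, nhpt = 5.32) {
  th <- list(arat = arat, bbt = bbt, nhpt = nhpt)
  if (!all(vapply(th, function(x) is.numeric(x) && length(x) == 1L && x > 0,
                  logical(1)))) {
    msr_error("SRD thresholds must be positive scalars",
              "msrehab_validation_error")
  }
  structure(th, class = "srd_thresholds")
}

#' Improvement-signed change of a clinical score
#'
#' Returns the pre-to-post change oriented so that positive means
#' improvement: `post - pre` for ARAT and BBT (higher is better),
#' `pre - post` for NHPT (faster is better).
#'
#' @param pre,post score values at admission and discharge (vectorized).
#' @param scale one of `"arat"`, `"bbt"`, `"nhpt"`.
#' @return Signed numeric change, improvement-positive.
#' @export
improvement_change <- function(pre, post, scale = c("arat", "bbt", "nhpt")) {
  scale <- match.arg(scale)
  if (anyNA(pre) || anyNA(post)) {
    msr_error("missing timepoint in improvement_change",
              "msrehab_labeling_error")
  }
  if (scale == "nhpt") pre - post else post - pre
}

#' Is a change a considerable improvement?
#'
#' Strict comparison: a change counts as a considerable improvement only
#' if it exceeds the SRD (`change > srd`); a change exactly at the
#' threshold is not a response.
#'
#' @param change improvement-signed change (see [improvement_change()]).
#' @param srd positive SRD threshold.
#' @return Logical (vectorized over `change`).
#' @export
is_responder <- function(change, srd) {
  stopifnot(is.numeric(srd), length(srd) == 1L, srd > 0)
  change > srd
}

#' Label a cohort's datasets as responders per scale
#'
#' Applies SRD binarization to each dataset's ARAT, BBT and NHPT changes.
#'
#' @param cohort an `ms_cohort`.
#' @param thresholds an [srd_thresholds()] object.
#' @return A data.frame of class `responder_labels` with columns
#'   `dataset_id`, `participant_id`, `side` and, per scale,
#'   `<scale>_change` (improvement-positive) and `<scale>_improved`
#'   (logical). Per-scale responder counts are attached as attribute
#'   `counts` and returned by [responder_counts()].
#' @export
label_cohort <- function(cohort, thresholds = srd_thresholds()) {
  stopifnot(inherits(cohort, "ms_cohort"),
            inherits(thresholds, "srd_thresholds"))
  out <- data.frame(dataset_id = cohort$dataset_id,
                    participant_id = cohort$participant_id,
                    side = cohort$side,
                    stringsAsFactors = FALSE)
  for (s in c("arat", "bbt", "nhpt")) {
    ch <- improvement_change(cohort[[paste0(s, "_pre")]],
                             cohort[[paste0(s, "_post")]], s)
    out[[paste0(s, "_change")]] <- ch
    out[[paste0(s, "_improved")]] <- is_responder(ch, thresholds[[s]])
  }
  counts <- vapply(c("arat", "bbt", "nhpt"),
                   function(s) sum(out[[paste0(s, "_improved")]]),
                   integer(1))
  structure(out, counts = counts,
            class = c("responder_labels", "data.frame"))
}

#' Per-scale responder counts of a labelled cohort
#'
#' @param labels a `responder_labels` object from [label_cohort()].
#' @return Named integer vector (arat, bbt, nhpt).
#' @export
responder_counts <- function(labels) {
  stopifnot(inherits(labels, "responder_labels"))
  attr(labels, "counts")
}

#' Write responder labels as a tidy long CSV
#'
#' One row per (dataset, scale) with columns `dataset_id`, `scale`,
#' `change`, `responder`.
#'
#' @param labels a `responder_labels` object.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_labels <- function(labels, path) {
  stopifnot(inherits(labels, "responder_labels"))
  long <- do.call(rbind, lapply(c("arat", "bbt", "nhpt"), function(s) {
    data.frame(dataset_id = labels$dataset_id, scale = s,
               change = labels[[paste0(s, "_change")]],
               responder = labels[[paste0(s, "_improved")]],
               stringsAsFactors = FALSE)
  }))
  write.csv(long, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
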