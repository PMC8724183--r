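# Cohort container: one row per dataset (participant-side), wide pre/post
# layout. Mirrors the published per-participant clinical table.

.cohort_required <- c(
  "participant_id", "side", "age", "sex", "ms_type", "chronicity",
  "intervention_group", "edss",
  "arat_pre", "arat_post", "bbt_pre", "bbt_post", "nhpt_pre", "nhpt_post"
)

# Optional columns that only synthetic cohorts (or external tables) carry:
# the disability group used for block randomization and the five
# conventional body-function scales.
.cohort_optional <- c(
  "disability_group", "motricity", "static_fatigue_index",
  "monofilament_index", "sdmt", "fahn_tremor"
)

#' Construct and validate a cohort of participant-side datasets
#'
#' A cohort holds one row per dataset, i.e. per (participant, body side)
#' pair, with demographics and pre/post clinical scores. Participants may
#' contribute one or two sides; a missing side is simply an absent row.
#'
#' @param data data.frame with the columns listed in Details.
#' @param provenance character tag describing where the data came from.
#'
#' @details Required columns: `participant_id`, `side` ("left"/"right"),
#'   `age` (years), `sex` ("F"/"M"), `ms_type` ("RR"/"PP"/"SP"),
#'   `chronicity` (years since diagnosis), `intervention_group` (1/2/3),
#'   `edss` (0-10 in 0.5 steps), and pre/post scores `arat_*` (0-57
#'   integer), `bbt_*` (blocks/min, >= 0), `nhpt_*` (seconds, > 0).
#'   Optional columns `disability_group`, `motricity`,
#'   `static_fatigue_index`, `monofilament_index`, `sdmt`, `fahn_tremor`
#'   are kept if present (used by feature sets 3 and 4).
#'
#' @return An object of class `ms_cohort` (a validated data.frame with a
#'   `dataset_id` column `participant_id "_" side`).
#' @export
ms_cohort <- function(data, provenance = "unspecified") {
  if (!is.data.frame(data)) {
    msr_error("cohort data must be a data.frame", "msrehab_schema_error")
  }
  missing_cols <- setdiff(.cohort_required, names(data))
  if (length(missing_cols) > 0L) {
    msr_error(paste0("missing mandatory column(s): ",
                     paste(missing_cols, collapse = ", ")),
              "msrehab_schema_error")
  }
  if (nrow(data) == 0L) {
    msr_error("cohort table has no rows", "msrehab_schema_error")
  }
  data$participant_id <- as.character(data$participant_id)
  data$side <- as.character(data$side)
  data$sex <- as.character(data$sex)
  data$ms_type <- as.character(data$ms_type)

  check <- function(ok, what) {
    bad <- which(!ok)
    if (length(bad) > 0L) {
      msr_error(sprintf("%s (row %s)", what,
                        paste(bad, collapse = ", ")),
                "msrehab_validation_error")
    }
  }
  check(data$side %in% c("left", "right"), "side must be left/right")
  check(data$sex %in% c("F", "M"), "sex must be F/M")
  check(data$ms_type %in% c("RR", "PP", "SP"), "ms_type must be RR/PP/SP")
  check(data$intervention_group %in% 1:3, "intervention_group must be 1/2/3")
  check(is.finite(data$age) & data$age > 0, "age must be positive")
  check(is.finite(data$chronicity) & data$chronicity >= 0,
        "chronicity must be non-negative")
  check(is.finite(data$edss) & data$edss >= 0 & data$edss <= 10 &
          (data$edss * 2) %% 1 == 0, "edss must be in [0,10] in 0.5 steps")
  for (col in c("arat_pre", "arat_post")) {
    check(is.finite(data[[col]]) & data[[col]] >= 0 & data[[col]] <= 57 &
            data[[col]] %% 1 == 0,
          sprintf("%s must be an integer in [0,57]", col))
  }
  for (col in c("bbt_pre", "bbt_post")) {
    check(is.finite(data[[col]]) & data[[col]] >= 0,
          sprintf("%s must be non-negative", col))
  }
  for (col in c("nhpt_pre", "nhpt_post")) {
    check(is.finite(data[[col]]) & data[[col]] > 0,
          sprintf("%s must be positive", col))
  }
  key <- paste(data$participant_id, data$side, sep = "_")
  if (anyDuplicated(key)) {
    msr_error(sprintf("duplicate (participant_id, side): %s",
                      paste(unique(key[duplicated(key)]), collapse = ", ")),
              "msrehab_validation_error")
  }
  # age/sex etc. must be constant within a participant
  for (col in c("age", "sex", "ms_type", "chronicity",
                "intervention_group", "edss")) {
    per <- tapply(data[[col]], data$participant_id,
                  function(v) length(unique(v)))
    if (any(per > 1L)) {
      msr_error(sprintf("%s differs between sides of participant %s", col,
                        paste(names(per)[per > 1L], collapse = ", ")),
                "msrehab_validation_error")
    }
  }
  keep <- c(.cohort_required, intersect(.cohort_optional, names(data)))
  out <- data[, keep, drop = FALSE]
  out$dataset_id <- key
  rownames(out) <- NULL
  structure(out, provenance = provenance,
            class = c("ms_cohort", "data.frame"))
}

#' Read a cohort from a wide one-row-per-dataset CSV
#'
#' @param path path to a UTF-8 CSV with a header row (see [ms_cohort()] for
#'   the column schema).
#' @param provenance provenance tag; defaults to the file path.
#' @return An `ms_cohort`.
#' @export
read_cohort <- function(path, provenance = path) {
  if (!file.exists(path)) {
    msr_error(sprintf("cohort file not found: %s", path),
              "msrehab_schema_error")
  }
  df <- tryCatch(
    read.csv(path, stringsAsFactors = FALSE,
             colClasses = c(participant_id = "character")),
    error = function(e) {
      msr_error(sprintf("cannot parse cohort file %s: %s", path,
                        conditionMessage(e)), "msrehab_schema_error")
    })
  ms_cohort(df, provenance = provenance)
}

#' Write a cohort back to CSV (round-trip safe)
#'
#' @param cohort an `ms_cohort`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  stopifnot(inherits(cohort, "ms_cohort"))
  df <- as.data.frame(cohort)
  df$dataset_id <- NULL
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' The bundled clinical cohort (20 datasets, 11 participants)
#'
#' Loads the packaged per-participant clinical table of the pwMS cohort:
#' 11 participants, of whom 9 contribute both body sides and 2 a single
#' side, giving 20 datasets with pre/post ARAT, BBT and NHPT scores.
#'
#' @return An `ms_cohort` with 20 rows.
#' @export
table1_cohort <- function() {
  read_cohort(system.file("extdata", "table1_cohort.csv",
                          package = "msrehab"),
              provenance = "bundled clinical table")
}

#' Summary statistics for a cohort
#'
#' Demographic summaries (age, EDSS, chronicity, sex and MS-type counts)
#' are computed over unique participants so that a participant tested on
#' both sides is never double-counted; score summaries are computed over
#' datasets. Standard deviations use the sample (n-1) convention and are
#' `NA` for a single observation.
#'
#' @param cohort an `ms_cohort`.
#' @return A list of class `cohort_summary`.
#' @export
summarize_cohort <- function(cohort) {
  stopifnot(inherits(cohort, "ms_cohort"))
  per <- cohort[!duplicated(cohort$participant_id), , drop = FALSE]
  msd <- function(x) c(mean = mean(x), sd = sd(x))
  scores <- c("arat_pre", "arat_post", "bbt_pre", "bbt_post",
              "nhpt_pre", "nhpt_post")
  out <- list(
    n_participants = nrow(per),
    n_datasets = nrow(cohort),
    age = msd(per$age),
    edss = msd(per$edss),
    chronicity = msd(per$chronicity),
    sex = table(per$sex),
    ms_type = table(per$ms_type),
    intervention_group = table(per$intervention_group),
    scores = t(vapply(scores, function(s) msd(cohort[[s]]), numeric(2)))
  )
  class(out) <- "cohort_summary"
  out
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat(sprintf("Cohort: %d participants, %d datasets\n",
              x$n_participants, x$n_datasets))
  cat(sprintf("  age  %.1f +/- %.1f yrs   EDSS %.1f +/- %.1f   chronicity %.1f +/- %.1f yrs\n",
              x$age["mean"], x$age["sd"], x$edss["mean"], x$edss["sd"],
              x$chronicity["mean"], x$chronicity["sd"]))
  cat("  sex:", paste(names(x$sex), x$sex, sep = "=", collapse = " "),
      "  MS type:", paste(names(x$ms_type), x$ms_type, sep = "=",
                          collapse = " "), "\n")
  cat("  scores (mean +/- sd over datasets):\n")
  for (s in rownames(x$scores)) {
    cat(sprintf("    %-10s %7.2f +/- %.2f\n", s,
                x$scores[s, "mean"], x$scores[s, "sd"]))
  }
  invisible(x)
}
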