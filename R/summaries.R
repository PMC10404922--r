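# guard: summaries operate on normalized confidence
.need_norm <- function(trials, cols) {
  miss <- setdiff(cols, names(trials))
  if (length(miss))
    stop("missing normalized-confidence column(s) ",
         paste(miss, collapse = ", "),
         "; run add_normalized_confidence() on the trial table first")
}

.is_correct6 <- function(trials) trials$response_consonant == trials$consonant
.is_correct_place <- function(trials) trials$percept_place == trials$place_class

# stimulus type within AV trials
.stim_type <- function(trials) ifelse(trials$mcgurk, "McGurk", "AVc")

#' Accuracy and perceptual confidence by sensory modality
#'
#' Per subject and modality (V-only, A-only, AV-congruent): trial count,
#' 6-way consonant accuracy, place-only accuracy (pooled over voicing, kept
#' alongside since the two correctness notions differ on unisensory visual
#' trials), mean normalized perceptual confidence, and confidence split by
#' correct versus incorrect syllable percepts. An empty correctness stratum
#' yields `NA` with `n = 0` rather than an error. McGurk trials are excluded:
#' no 6-way correct response exists for them.
#'
#' @param trials a normalized trial-record tibble.
#' @return A tibble, one row per subject x modality.
#' @export
accuracy_and_confidence_by_modality <- function(trials) {
  .need_norm(trials, "perceptual_confidence_norm")
  t <- dplyr::filter(trials, !.data$mcgurk)
  t$correct <- .is_correct6(t)
  t$correct_place <- .is_correct_place(t)
  out <- dplyr::summarise(
    dplyr::group_by(t, .data$subject, .data$modality),
    n = dplyr::n(),
    accuracy = mean(.data$correct),
    accuracy_place = mean(.data$correct_place),
    mean_confidence = mean(.data$perceptual_confidence_norm),
    n_correct = sum(.data$correct),
    n_incorrect = sum(!.data$correct),
    mean_confidence_correct =
      ifelse(.data$n_correct > 0,
             mean(.data$perceptual_confidence_norm[.data$correct]), NA_real_),
    mean_confidence_incorrect =
      ifelse(.data$n_incorrect > 0,
             mean(.data$perceptual_confidence_norm[!.data$correct]), NA_real_),
    .groups = "drop")
  out
}

#' Response fractions over the three place-of-articulation percepts
#'
#' For a chosen stimulus selection — McGurk trials, unisensory auditory B/P
#' trials, or unisensory visual G/K trials — the per-subject fraction of
#' B/P, D/T and G/K percepts and the mean normalized perceptual confidence
#' within each percept class. Fractions within a subject sum to 1.
#'
#' @param trials a normalized trial-record tibble.
#' @param stimulus_filter one of `"mcgurk"`, `"auditory_bp"`, `"visual_gk"`.
#' @return A tibble, one row per subject x percept class (classes with no
#'   trials appear with fraction 0 and `NA` confidence).
#' @export
percept_fractions <- function(trials,
                              stimulus_filter = c("mcgurk", "auditory_bp",
                                                  "visual_gk")) {
  stimulus_filter <- match.arg(stimulus_filter)
  .need_norm(trials, "perceptual_confidence_norm")
  t <- switch(stimulus_filter,
    mcgurk = dplyr::filter(trials, .data$mcgurk),
    auditory_bp = dplyr::filter(trials, .data$modality == "A",
                                .data$place_class == "B/P"),
    visual_gk = dplyr::filter(trials, .data$modality == "V",
                              .data$place_class == "G/K"))
  if (nrow(t) == 0L) {
    warning("stimulus filter '", stimulus_filter, "' selected no trials")
    return(tibble::tibble(subject = character(), percept_place = character(),
                          n = integer(), fraction = numeric(),
                          mean_confidence = numeric()))
  }
  counts <- dplyr::count(t, .data$subject, .data$percept_place)
  full <- tidyr::expand_grid(subject = unique(t$subject),
                             percept_place = PLACE_LEVELS)
  counts <- dplyr::left_join(full, counts,
                             by = c("subject", "percept_place"))
  counts$n[is.na(counts$n)] <- 0L
  counts <- dplyr::mutate(dplyr::group_by(counts, .data$subject),
                          fraction = .data$n / sum(.data$n))
  conf <- dplyr::summarise(
    dplyr::group_by(t, .data$subject, .data$percept_place),
    mean_confidence = mean(.data$perceptual_confidence_norm),
    .groups = "drop")
  dplyr::ungroup(dplyr::left_join(counts, conf,
                                  by = c("subject", "percept_place")))
}

#' Causal-response fractions and causal confidence
#'
#' Audiovisual trials only. With `grouping = "correctness"` (congruent
#' trials) the grouping levels are correct versus incorrect syllable
#' percepts; with `grouping = "percept"` (McGurk trials) they are the three
#' place-percept classes. Within each subject x level, the fractions of
#' common-cause (C=1) and separate-cause (C=2) reports and the mean
#' normalized causal confidence per causal response.
#'
#' @param trials a normalized trial-record tibble.
#' @param grouping `"correctness"` or `"percept"`.
#' @return A tibble, one row per subject x grouping level x causal response.
#'   Cells absent for a subject are present with `n = 0`, fraction 0 and
#'   `NA` confidence (marked missing).
#' @export
causal_fractions_and_confidence <- function(trials,
                                            grouping = c("correctness",
                                                         "percept")) {
  grouping <- match.arg(grouping)
  .need_norm(trials, "causal_confidence_norm")
  t <- dplyr::filter(trials, .data$modality == "AV")
  if (grouping == "correctness") {
    t <- dplyr::filter(t, !.data$mcgurk)
    t$level <- ifelse(.is_correct6(t), "correct", "incorrect")
    levels_all <- c("correct", "incorrect")
  } else {
    t <- dplyr::filter(t, .data$mcgurk)
    t$level <- t$percept_place
    levels_all <- PLACE_LEVELS
  }
  counts <- dplyr::count(t, .data$subject, .data$level, .data$causal_response)
  full <- tidyr::expand_grid(subject = unique(t$subject), level = levels_all,
                             causal_response = c("C=1", "C=2"))
  counts <- dplyr::left_join(full, counts,
                             by = c("subject", "level", "causal_response"))
  counts$n[is.na(counts$n)] <- 0L
  counts <- dplyr::mutate(
    dplyr::group_by(counts, .data$subject, .data$level),
    n_level = sum(.data$n),
    fraction = ifelse(.data$n_level > 0, .data$n / .data$n_level, NA_real_))
  conf <- dplyr::summarise(
    dplyr::group_by(t, .data$subject, .data$level, .data$causal_response),
    mean_causal_confidence = mean(.data$causal_confidence_norm),
    .groups = "drop")
  dplyr::ungroup(dplyr::left_join(counts, conf,
                                  by = c("subject", "level", "causal_response")))
}

#' Median split of trials by causal confidence
#'
#' Within each subject x stimulus type (congruent / McGurk) x causal-response
#' category, audiovisual trials are split at the median normalized causal
#' confidence (ties go to the low stratum). Each stratum reports percept
#' fractions, 6-way accuracy (congruent trials; `NA` for McGurk, which has no
#' 6-way correct response), and mean normalized perceptual confidence.
#' Categories with fewer than two trials are flagged undefined.
#'
#' @param trials a normalized trial-record tibble.
#' @return A tibble, one row per subject x stimulus type x causal response x
#'   stratum, with a `defined` flag.
#' @export
median_split_by_causal_confidence <- function(trials) {
  .need_norm(trials, c("causal_confidence_norm", "perceptual_confidence_norm"))
  t <- dplyr::filter(trials, .data$modality == "AV")
  t$stimulus <- .stim_type(t)
  t$correct <- ifelse(t$mcgurk, NA, .is_correct6(t))
  t <- dplyr::group_by(t, .data$subject, .data$stimulus, .data$causal_response)
  t <- dplyr::mutate(t,
    stratum = ifelse(.data$causal_confidence_norm <=
                       stats::median(.data$causal_confidence_norm),
                     "low", "high"),
    defined = dplyr::n() >= 2L)
  out <- dplyr::summarise(dplyr::group_by(
      dplyr::ungroup(t), .data$subject, .data$stimulus,
      .data$causal_response, .data$stratum, .data$defined),
    n = dplyr::n(),
    accuracy = mean(.data$correct),
    frac_bp = mean(.data$percept_place == "B/P"),
    frac_dt = mean(.data$percept_place == "D/T"),
    frac_gk = mean(.data$percept_place == "G/K"),
    mean_perceptual_confidence = mean(.data$perceptual_confidence_norm),
    mean_causal_confidence = mean(.data$causal_confidence_norm),
    .groups = "drop")
  out
}

#' Select perceptual and causal metamers
#'
#' Metamers are congruent and McGurk trials with identical decisional
#' outcomes: congruent trials with a correct syllable response and a
#' common-cause (C=1) report, and McGurk trials with a correct voicing
#' response (judged against the auditory component) and a C=1 report. Within
#' each subject x percept class x source, the distribution over the four
#' perceptual-confidence levels and the mean normalized causal confidence
#' per level. Percept classes with no trials in either subset are omitted
#' with a warning.
#'
#' @param trials a normalized trial-record tibble.
#' @return A tibble, one row per subject x percept class x source x
#'   confidence level.
#' @export
select_metamers <- function(trials) {
  .need_norm(trials, "causal_confidence_norm")
  t <- dplyr::filter(trials, .data$modality == "AV",
                     .data$causal_response == "C=1")
  cong <- dplyr::filter(t, !.data$mcgurk)
  cong <- cong[.is_correct6(cong), ]
  mcg <- dplyr::filter(t, .data$mcgurk)
  mcg <- mcg[mcg$percept_voicing == mcg$voicing, ]
  sel <- dplyr::bind_rows(
    dplyr::mutate(cong, source = "congruent"),
    dplyr::mutate(mcg, source = "mcgurk"))
  present <- unique(sel$percept_place)
  missing_classes <- setdiff(PLACE_LEVELS, present)
  if (length(missing_classes))
    warning("no metamer pairs for percept class(es): ",
            paste(missing_classes, collapse = ", "))
  counts <- dplyr::count(sel, .data$subject, .data$percept_place,
                         .data$source, .data$perceptual_confidence_level)
  full <- tidyr::expand_grid(subject = unique(sel$subject),
                             percept_place = present,
                             source = c("congruent", "mcgurk"),
                             perceptual_confidence_level = 1:4)
  counts <- dplyr::left_join(full, counts,
    by = c("subject", "percept_place", "source",
           "perceptual_confidence_level"))
  counts$n[is.na(counts$n)] <- 0L
  counts <- dplyr::mutate(
    dplyr::group_by(counts, .data$subject, .data$percept_place, .data$source),
    n_cell = sum(.data$n),
    fraction = ifelse(.data$n_cell > 0, .data$n / .data$n_cell, NA_real_))
  conf <- dplyr::summarise(
    dplyr::group_by(sel, .data$subject, .data$percept_place, .data$source,
                    .data$perceptual_confidence_level),
    mean_causal_confidence = mean(.data$causal_confidence_norm),
    .groups = "drop")
  dplyr::ungroup(dplyr::left_join(counts, conf,
    by = c("subject", "percept_place", "source",
           "perceptual_confidence_level")))
}

#' Voicing classification accuracy by condition
#'
#' Per subject and condition (A-only, V-only, AV-congruent, McGurk): the
#' fraction of correct voiced/unvoiced classifications. On McGurk trials the
#' auditory component defines the correct voicing (its voicing class is
#' shared with the visual component by construction).
#'
#' @param trials a trial-record tibble (normalization not required).
#' @return A tibble, one row per subject x condition.
#' @export
voicing_accuracy <- function(trials) {
  t <- trials
  t$condition_v <- ifelse(t$modality == "AV", .stim_type(t), t$modality)
  dplyr::summarise(
    dplyr::group_by(t, .data$subject, condition = .data$condition_v),
    n = dplyr::n(),
    accuracy = mean(.data$percept_voicing == .data$voicing),
    .groups = "drop")
}

#' Across-subject aggregation of a per-subject summary table
#'
#' Group-level values are means of the per-subject values (subject-level
#' first, then across subjects), keeping the per-subject spread as quantiles
#' for box-plot-style presentation.
#'
#' @param tab a per-subject summary tibble.
#' @param value name of the value column to aggregate.
#' @param keys grouping columns (everything except `subject`, the value and
#'   count columns by default).
#' @return A tibble of across-subject mean, median, quartiles and n subjects.
#' @export
aggregate_subjects <- function(tab, value,
                               keys = setdiff(names(tab),
                                              c("subject", value, "n",
                                                "n_cell", "n_level"))) {
  g <- dplyr::group_by(tab, dplyr::across(dplyr::all_of(keys)))
  dplyr::summarise(g,
    n_subjects = sum(!is.na(.data[[value]])),
    mean = mean(.data[[value]], na.rm = TRUE),
    median = stats::median(.data[[value]], na.rm = TRUE),
    q1 = stats::quantile(.data[[value]], 0.25, na.rm = TRUE, names = FALSE),
    q3 = stats::quantile(.data[[value]], 0.75, na.rm = TRUE, names = FALSE),
    min = suppressWarnings(min(.data[[value]], na.rm = TRUE)),
    max = suppressWarnings(max(.data[[value]], na.rm = TRUE)),
    .groups = "drop")
}
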