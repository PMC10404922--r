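#' Cumulative-distribution confidence normalization
#'
#' Raw confidence scales differ in mean and spread across participants. Each
#' raw value `x` is mapped onto its value under the empirical cumulative
#' distribution of the participant's own reports,
#' `normalized(x) = 0.5 * (P(X < x) + P(X <= x))`,
#' the midpoint convention assigning tied values the average of their
#' normalized values. For example, if 30% of a participant's reports sit at
#' the shared maximum, those reports all map to the mean of 0.7 and 1, i.e.
#' 0.85. The transform is rank-based: the output mean is exactly 0.5 for any
#' input, outputs lie strictly inside (0, 1), and any strictly increasing
#' transform of the raw values leaves the result unchanged.
#'
#' @param values numeric vector of raw confidence values (4-level integers or
#'   continuous reports); must be non-empty and finite.
#' @return Numeric vector of normalized confidences, same length.
#' @examples
#' normalize_confidence(c(1, 2, 3, 4))          # 0.125 0.375 0.625 0.875
#' normalize_confidence(c(1, 1, 1, 2, 2, 2))    # ties share one value
#' @export
normalize_confidence <- function(values) {
  if (length(values) == 0L) stop("cannot normalize an empty confidence vector")
  if (!is.numeric(values) || anyNA(values) || any(!is.finite(values)))
    stop("confidence values must be finite numbers")
  # midpoint ECDF == (average rank - 1/2) / n
  (rank(values, ties.method = "average") - 0.5) / length(values)
}

#' Add normalized confidence columns to a trial table
#'
#' Applies [normalize_confidence()] to the 4-level perceptual confidence and
#' the continuous causal confidence, by default separately per subject and
#' per confidence type (matching per-participant normalization); `pool =
#' TRUE` normalizes across all subjects at once. Causal confidence exists
#' only on audiovisual trials; unisensory rows keep `NA`.
#'
#' @param trials a trial-record tibble.
#' @param pool normalize across subjects instead of per subject?
#' @return `trials` with `perceptual_confidence_norm` and
#'   `causal_confidence_norm` columns added.
#' @export
add_normalized_confidence <- function(trials, pool = FALSE) {
  need <- c("subject", "perceptual_confidence_level", "causal_confidence_report")
  miss <- setdiff(need, names(trials))
  if (length(miss))
    stop("trial table lacks column(s): ", paste(miss, collapse = ", "))
  grp <- if (pool) character(0) else "subject"
  out <- dplyr::group_by(trials, dplyr::across(dplyr::all_of(grp)))
  out <- dplyr::mutate(out,
    perceptual_confidence_norm =
      normalize_confidence(.data$perceptual_confidence_level),
    causal_confidence_norm = {
      cc <- .data$causal_confidence_report
      ok <- !is.na(cc)
      res <- rep(NA_real_, length(cc))
      if (any(ok)) res[ok] <- normalize_confidence(cc[ok])
      res
    })
  dplyr::ungroup(out)
}
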