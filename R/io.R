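# column dictionary of the trial-table file format: name -> readr type
TRIAL_COLUMNS <- c(
  subject = "c", block = "i", trial = "i", phase = "c", modality = "c",
  condition = "c", consonant = "c", vowel = "c", place_class = "c",
  voicing = "c", mcgurk = "l", auditory_consonant = "c",
  visual_consonant = "c", xA = "d", xV = "d", percept_place = "c",
  percept_voicing = "c", perceptual_confidence_latent = "d", p_c1 = "d",
  lapse = "l", response_consonant = "c", causal_response = "c",
  causal_confidence_report = "d", perceptual_confidence_level = "i"
)

#' Write a trial table to delimited text
#'
#' Comma-separated, one header row, UTF-8, `"."` decimal separator, missing
#' values as empty fields — the package's on-disk trial-table format.
#'
#' @param trials a trial-record tibble.
#' @param path output file path.
#' @return `trials`, invisibly.
#' @export
write_trials <- function(trials, path) {
  readr::write_csv(trials, path, na = "")
  invisible(trials)
}

#' Read a trial table from delimited text
#'
#' Reads a file written by [write_trials()] (or hand-prepared in the same
#' column dictionary), restores column types, and validates the structural
#' invariants: mandatory columns present, causal fields present if and only
#' if the trial is audiovisual, confidence level in 1..4, causal confidence
#' in `[0, 1]`. Unknown extra columns are preserved.
#'
#' @param path input file path.
#' @param validate raise an error on invariant violations? If `FALSE`, the
#'   violations are attached as attribute `validation`.
#' @return A trial-record tibble.
#' @export
read_trials <- function(path, validate = TRUE) {
  if (!file.exists(path)) stop("no such trial table: ", path)
  hdr <- names(readr::read_csv(path, n_max = 0, col_types = readr::cols(),
                               show_col_types = FALSE))
  mandatory <- c("subject", "modality", "response_consonant",
                 "perceptual_confidence_level", "causal_response",
                 "causal_confidence_report")
  miss <- setdiff(mandatory, hdr)
  if (length(miss))
    stop("trial table is missing mandatory column(s): ",
         paste(miss, collapse = ", "))
  spec <- paste(vapply(hdr, function(h) {
    if (h %in% names(TRIAL_COLUMNS)) TRIAL_COLUMNS[[h]] else "?"
  }, character(1)), collapse = "")
  out <- readr::read_csv(path, col_types = spec, na = "",
                         show_col_types = FALSE, progress = FALSE)
  probs <- readr::problems(out)
  if (nrow(probs) > 0)
    stop("malformed trial table row(s): ",
         paste(utils::head(probs$row, 5), collapse = ", "))
  viol <- validate_trials(out)
  if (length(viol)) {
    if (validate) stop("trial table invariant violations:\n  ",
                       paste(viol, collapse = "\n  "))
    attr(out, "validation") <- viol
  }
  out
}

#' Validate trial-table invariants
#'
#' @param trials a trial-record tibble.
#' @return Character vector of violation messages (empty when clean).
#' @export
validate_trials <- function(trials) {
  viol <- character(0)
  row_msg <- function(rows, what) {
    sprintf("%s (row%s %s)", what, if (length(rows) > 1) "s" else "",
            paste(utils::head(rows, 5), collapse = ", "))
  }
  if (nrow(trials) == 0L) return(viol)
  uni <- trials$modality %in% c("A", "V")
  bad <- which(uni & (!is.na(trials$causal_response) |
                        !is.na(trials$causal_confidence_report)))
  if (length(bad))
    viol <- c(viol, row_msg(bad, "causal fields on unisensory trials"))
  bad <- which(!uni & (is.na(trials$causal_response) |
                         is.na(trials$causal_confidence_report)))
  if (length(bad))
    viol <- c(viol, row_msg(bad, "missing causal fields on audiovisual trials"))
  bad <- which(!trials$perceptual_confidence_level %in% 1:4)
  if (length(bad))
    viol <- c(viol, row_msg(bad, "perceptual confidence level outside 1..4"))
  cc <- trials$causal_confidence_report
  bad <- which(!is.na(cc) & (cc < 0 | cc > 1))
  if (length(bad))
    viol <- c(viol, row_msg(bad, "causal confidence outside [0, 1]"))
  viol
}

# observer_params / design_spec from a plain named list (YAML config)
.params_from_config <- function(cfg) {
  obs <- cfg$observer %||% list()
  allowed <- names(formals(observer_params))
  bad <- setdiff(names(obs), allowed)
  if (length(bad)) stop("unknown observer config field(s): ",
                        paste(bad, collapse = ", "))
  do.call(observer_params, obs)
}

.design_from_config <- function(cfg) {
  des <- cfg$design %||% list()
  allowed <- names(formals(design_spec))
  bad <- setdiff(names(des), allowed)
  if (length(bad)) stop("unknown design config field(s): ",
                        paste(bad, collapse = ", "))
  do.call(design_spec, des)
}

#' Read a pipeline configuration file
#'
#' YAML with two optional top-level maps, `observer` (fields of
#' [observer_params()]) and `design` (fields of [design_spec()]), plus
#' optional `subjects` (number of simulated subjects) and `fit` (logical:
#' run the parameter fit). The configuration is validated before any stage
#' runs; invalid values (e.g. a lapse rate above 1) are rejected here.
#'
#' @param path YAML file path, or a named list already in config shape.
#' @return A validated config list with `params` and `spec` materialized.
#' @export
read_config <- function(path) {
  cfg <- if (is.character(path)) yaml::read_yaml(path) else path
  list(params = .params_from_config(cfg),
       spec = .design_from_config(cfg),
       subjects = cfg$subjects %||% 3L,
       fit = isTRUE(cfg$fit))
}

#' Run the full analysis pipeline
#'
#' Chains simulate, normalize, summarize (all six summary tables),
#' optionally fit, and the model-illustration panels into a deterministic
#' artifact directory, with a manifest recording the configuration hash, the
#' seed and each completed stage. Rerunning with the same config and seed
#' reproduces identical numeric output; a partial failure leaves the
#' manifest marking the stages that completed.
#'
#' @param config a config list or YAML path (see [read_config()]).
#' @param seed integer master seed; all randomness derives from it.
#' @param out_dir output directory (created if needed).
#' @return The manifest list, invisibly.
#' @export
run_pipeline <- function(config = list(), seed = 1, out_dir) {
  cfg <- read_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(config_hash = rlang::hash(cfg), seed = seed,
                   stages = character(0))
  save_manifest <- function() {
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  on.exit(save_manifest())
  mark <- function(stage) {
    manifest$stages <<- c(manifest$stages, stage)
    save_manifest()
  }

  seeds <- seed + seq_len(cfg$subjects) - 1L
  trials <- simulate_experiment(seeds, cfg$params, cfg$spec)
  write_trials(trials, file.path(out_dir, "trials.csv"))
  mark("simulate")

  trials <- add_normalized_confidence(trials)
  write_trials(trials, file.path(out_dir, "trials_normalized.csv"))
  mark("normalize")

  wr <- function(tab, name) readr::write_csv(tab, file.path(out_dir, name),
                                             na = "")
  wr(accuracy_and_confidence_by_modality(trials),
     "summary_accuracy_confidence_by_modality.csv")
  wr(percept_fractions(trials, "mcgurk"), "summary_percepts_mcgurk.csv")
  wr(percept_fractions(trials, "auditory_bp"),
     "summary_percepts_auditory_bp.csv")
  wr(percept_fractions(trials, "visual_gk"), "summary_percepts_visual_gk.csv")
  wr(causal_fractions_and_confidence(trials, "correctness"),
     "summary_causal_by_correctness.csv")
  wr(causal_fractions_and_confidence(trials, "percept"),
     "summary_causal_by_percept.csv")
  wr(median_split_by_causal_confidence(trials), "summary_median_split.csv")
  wr(suppressWarnings(select_metamers(trials)), "summary_metamers.csv")
  wr(voicing_accuracy(trials), "summary_voicing_accuracy.csv")
  mark("summarize")

  if (cfg$fit) {
    fit <- fit_observer(dplyr::filter(trials, .data$phase == "main"),
                        base_params = cfg$params, seed = seed)
    jsonlite::write_json(
      list(estimates = as.list(fit$estimates), loglik = fit$loglik,
           converged = fit$converged, n_trials = fit$n_trials,
           n_mc = fit$n_mc),
      file.path(out_dir, "fit.json"), auto_unbox = TRUE, digits = NA)
    mark("fit")
  }

  pairs <- figure8_pairs()
  for (i in seq_len(nrow(pairs))) {
    panel <- figure8_panel(pairs$xA[i], pairs$xV[i], cfg$params)
    grid <- panel$grid
    grid$p_c1 <- panel$p_c1
    grid$mass_bp <- panel$category_posterior[["B/P"]]
    grid$mass_dt <- panel$category_posterior[["D/T"]]
    grid$mass_gk <- panel$category_posterior[["G/K"]]
    readr::write_csv(grid,
                     file.path(out_dir,
                               sprintf("figure8_panel_%s.csv", pairs$panel[i])))
  }
  mark("figure8")

  invisible(manifest)
}
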