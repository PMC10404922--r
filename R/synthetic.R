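# run code under a seed without disturbing the caller's RNG stream
with_seed_local <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

CONSONANTS <- c("B", "D", "G", "P", "T", "K")
VOWELS <- c("a", "e", "i")

.place_of <- function(consonant) {
  c(B = "B/P", P = "B/P", D = "D/T", T = "D/T", G = "G/K", K = "G/K")[consonant]
}
.voicing_of <- function(consonant) {
  c(B = "voiced", D = "voiced", G = "voiced",
    P = "unvoiced", T = "unvoiced", K = "unvoiced")[consonant]
}
.consonant_of <- function(place, voicing) {
  key <- paste(place, voicing)
  c("B/P voiced" = "B", "B/P unvoiced" = "P",
    "D/T voiced" = "D", "D/T unvoiced" = "T",
    "G/K voiced" = "G", "G/K unvoiced" = "K")[key]
}
.coord_of <- function(place) c("B/P" = -1, "D/T" = 0, "G/K" = 1)[place]

#' The stimulus inventory of the dual-report McGurk design
#'
#' 18 congruent syllables (6 consonants x 3 vowels) and 6 McGurk identities
#' built by cross-dubbing an auditory labial onto a visual guttural of the
#' same voicing class and vowel: auditory B + visual G and auditory P +
#' visual K, for vowels a, e, i.
#'
#' @return A tibble, one row per stimulus identity, with columns `consonant`,
#'   `vowel`, `place_class`, `voicing`, `mcgurk`, `auditory_consonant`,
#'   `visual_consonant`.
#' @export
stimulus_set <- function() {
  cong <- tidyr::expand_grid(consonant = CONSONANTS, vowel = VOWELS)
  cong <- dplyr::mutate(cong,
    place_class = .place_of(.data$consonant),
    voicing = .voicing_of(.data$consonant),
    mcgurk = FALSE,
    auditory_consonant = .data$consonant,
    visual_consonant = .data$consonant)
  mcg <- tidyr::expand_grid(auditory_consonant = c("B", "P"), vowel = VOWELS)
  mcg <- dplyr::mutate(mcg,
    visual_consonant = c(B = "G", P = "K")[.data$auditory_consonant],
    consonant = .data$auditory_consonant,
    place_class = .place_of(.data$auditory_consonant),
    voicing = .voicing_of(.data$auditory_consonant),
    mcgurk = TRUE)
  dplyr::bind_rows(cong, mcg[names(cong)])
}

#' Specification of the experimental design
#'
#' Defaults mirror the dual-report study design: 16 main blocks of 144 trials
#' (36 visual-only, 36 auditory-only, 36 audiovisual-congruent — two
#' repetitions of each of the 18 syllables — and 36 McGurk trials — six
#' repetitions of each of the 6 identities), preceded by a 54-trial
#' familiarization block (18 congruent, then 18 A-only, then 18 V-only).
#'
#' @param n_blocks number of main blocks.
#' @param n_v,n_a,n_avc per-block visual-only / auditory-only / congruent
#'   trial counts; must be multiples of 18.
#' @param n_mcgurk per-block McGurk trial count; must be a multiple of 6.
#' @param familiarization include the familiarization block?
#' @return A `design_spec` list.
#' @export
design_spec <- function(n_blocks = 16, n_v = 36, n_a = 36, n_avc = 36,
                        n_mcgurk = 36, familiarization = TRUE) {
  if (n_blocks < 1) stop("configuration error: n_blocks must be >= 1")
  if (n_v %% 18 || n_a %% 18 || n_avc %% 18)
    stop("configuration error: unisensory and congruent counts must be multiples of 18")
  if (n_mcgurk %% 6)
    stop("configuration error: McGurk count must be a multiple of 6")
  structure(list(n_blocks = n_blocks, n_v = n_v, n_a = n_a, n_avc = n_avc,
                 n_mcgurk = n_mcgurk, familiarization = familiarization),
            class = "design_spec")
}

.rep_stimuli <- function(stim, n_rep) {
  stim[rep(seq_len(nrow(stim)), n_rep), ]
}

#' Build the ordered trial list of one simulated session set
#'
#' Congruent and McGurk trials are randomly interleaved within each block;
#' unisensory trials are presented in separate 18-trial mini-blocks whose
#' position within the block is randomized. The familiarization block runs
#' congruent, then auditory-only, then visual-only, each syllable once.
#' Ordering is reproducible from the seed; counts are exact by construction.
#'
#' @param spec a [design_spec()].
#' @param seed integer seed controlling the interleaving.
#' @return A tibble, one row per trial: `block`, `trial`, `phase`,
#'   `modality`, `condition`, stimulus identity columns.
#' @examples
#' d <- build_design(design_spec(), seed = 1)
#' table(d$condition[d$phase == "main"]) / 16
#' @export
build_design <- function(spec = design_spec(), seed = 1) {
  stim <- stimulus_set()
  cong <- stim[!stim$mcgurk, ]
  mcg <- stim[stim$mcgurk, ]
  with_seed_local(seed, {
    blocks <- list()
    if (spec$familiarization) {
      fam <- dplyr::bind_rows(
        dplyr::mutate(cong[sample(18L), ], modality = "AV", condition = "AVc"),
        dplyr::mutate(cong[sample(18L), ], modality = "A", condition = "A"),
        dplyr::mutate(cong[sample(18L), ], modality = "V", condition = "V"))
      fam$block <- 0L
      fam$phase <- "familiarization"
      blocks[[1]] <- fam
    }
    for (b in seq_len(spec$n_blocks)) {
      av <- dplyr::bind_rows(
        dplyr::mutate(.rep_stimuli(cong, spec$n_avc / 18L),
                      modality = "AV", condition = "AVc"),
        dplyr::mutate(.rep_stimuli(mcg, spec$n_mcgurk / 6L),
                      modality = "AV", condition = "McGurk"))
      av <- av[sample(nrow(av)), ]
      # segments: the interleaved AV run plus shuffled 18-trial unisensory
      # mini-blocks, in random order within the block
      segs <- list(av)
      for (i in seq_len(spec$n_a / 18L))
        segs <- c(segs, list(dplyr::mutate(cong[sample(18L), ],
                                           modality = "A", condition = "A")))
      for (i in seq_len(spec$n_v / 18L))
        segs <- c(segs, list(dplyr::mutate(cong[sample(18L), ],
                                           modality = "V", condition = "V")))
      blk <- dplyr::bind_rows(segs[sample(length(segs))])
      blk$block <- b
      blk$phase <- "main"
      blocks[[length(blocks) + 1L]] <- blk
    }
    out <- dplyr::bind_rows(blocks)
    out <- dplyr::group_by(out, .data$block)
    out <- dplyr::mutate(out, trial = dplyr::row_number())
    out <- dplyr::ungroup(out)
    dplyr::select(out, "block", "trial", "phase", "modality", "condition",
                  "consonant", "vowel", "place_class", "voicing", "mcgurk",
                  "auditory_consonant", "visual_consonant")
  })
}

#' Draw noisy internal signals for a trial list
#'
#' Each present modality's signal is drawn around the place coordinate of its
#' stimulus component: congruent and unisensory stimuli around the single
#' class coordinate, McGurk stimuli with the auditory signal around the
#' labial coordinate (-1) and the visual signal around the guttural
#' coordinate (+1). Visual-only trials carry no auditory signal and vice
#' versa (`NA`).
#'
#' @param trials a trial tibble from [build_design()].
#' @param params an [observer_params()] supplying the noise variances.
#' @param seed integer seed.
#' @return `trials` with `xA` and `xV` columns appended.
#' @export
sample_signals <- function(trials, params = observer_params(), seed = 1) {
  n <- nrow(trials)
  muA <- .coord_of(.place_of(trials$auditory_consonant))
  muV <- .coord_of(.place_of(trials$visual_consonant))
  with_seed_local(seed, {
    xA <- stats::rnorm(n, muA, sqrt(params$sigma2_A))
    xV <- stats::rnorm(n, muV, sqrt(params$sigma2_V))
  })
  trials$xA <- ifelse(trials$modality %in% c("A", "AV"), xA, NA_real_)
  trials$xV <- ifelse(trials$modality %in% c("V", "AV"), xV, NA_real_)
  trials
}

# MAP voicing decision from two independent Bernoulli channels; on conflict
# the more accurate channel wins, exact ties go to the auditory vote
.voicing_decide <- function(voteA, voteV, accA, accV) {
  winner <- if (accV > accA) voteV else voteA  # conflict: reliable channel wins
  out <- ifelse(is.na(voteA), voteV,
                ifelse(is.na(voteV), voteA,
                       ifelse(voteA == voteV, voteA, winner)))
  out
}

.flip_voicing <- function(v) ifelse(v == "voiced", "unvoiced", "voiced")

#' Simulate an observer's reports for a trial list
#'
#' Runs the causal-inference observer over every trial: signals are drawn
#' from the generative model, place percepts and causal reports come from the
#' model-averaged posterior, voicing percepts from the independent two-channel
#' voicing model, and the response consonant combines the place and voicing
#' percepts. With probability `lapse_rate` a trial is a lapse: the response
#' consonant, confidence level and (on audiovisual trials) the causal report
#' and causal confidence are uniform random. The 4-level perceptual
#' confidence discretizes the latent confidence at the subject's empirical
#' quartiles over non-lapse trials, so each level occupies about a quarter of
#' the reports.
#'
#' @param trials a trial tibble from [build_design()].
#' @param params an [observer_params()].
#' @param seed integer seed (signals, lapses, voicing channels).
#' @param subject subject identifier stored in the output.
#' @return A trial-record tibble: the design columns plus `xA`, `xV`,
#'   `percept_place`, `percept_voicing`, `response_consonant`,
#'   `perceptual_confidence_latent`, `perceptual_confidence_level`,
#'   `causal_response`, `causal_confidence_report`, `p_c1`, `lapse`.
#' @examples
#' tr <- simulate_observer(build_design(design_spec(n_blocks = 1), 1), seed = 1)
#' table(tr$percept_place[tr$condition == "McGurk"])
#' @export
simulate_observer <- function(trials, params = observer_params(), seed = 1,
                              subject = paste0("S", seed)) {
  validate_observer_params(params)
  trials <- sample_signals(trials, params, seed = seed)
  n <- nrow(trials)
  av <- trials$modality == "AV"
  aon <- trials$modality == "A"
  von <- trials$modality == "V"

  percept <- character(n)
  conf <- numeric(n)
  p_c1 <- rep(NA_real_, n)
  if (any(av)) {
    batch <- .av_batch(trials$xA[av], trials$xV[av], params)
    dec <- .decide_batch(batch$bp, batch$dt, batch$gk, params$confidence_rule)
    percept[av] <- dec$percept
    conf[av] <- dec$confidence
    p_c1[av] <- batch$p_c1
  }
  if (any(aon)) {
    m <- .cat_mass_batch(trials$xA[aon], params$sigma2_A, params)
    dec <- .decide_batch(m$bp, m$dt, m$gk, params$confidence_rule)
    percept[aon] <- dec$percept
    conf[aon] <- dec$confidence
  }
  if (any(von)) {
    m <- .cat_mass_batch(trials$xV[von], params$sigma2_V, params)
    dec <- .decide_batch(m$bp, m$dt, m$gk, params$confidence_rule)
    percept[von] <- dec$percept
    conf[von] <- dec$confidence
  }

  with_seed_local(seed + 1L, {
    # independent two-channel voicing model
    voteA <- ifelse(stats::runif(n) < params$voicing_acc_A,
                    trials$voicing, .flip_voicing(trials$voicing))
    voteV <- ifelse(stats::runif(n) < params$voicing_acc_V,
                    trials$voicing, .flip_voicing(trials$voicing))
    voteA[von] <- NA_character_
    voteV[aon] <- NA_character_
    voicing <- .voicing_decide(voteA, voteV,
                               params$voicing_acc_A, params$voicing_acc_V)
    lapse <- stats::runif(n) < params$lapse_rate
    lapse_consonant <- sample(CONSONANTS, n, replace = TRUE)
    lapse_level <- sample(1:4, n, replace = TRUE)
    lapse_causal <- sample(c("C=1", "C=2"), n, replace = TRUE)
    lapse_cconf <- stats::runif(n)
  })

  out <- trials
  out$subject <- subject
  out$percept_place <- percept
  out$percept_voicing <- voicing
  out$perceptual_confidence_latent <- conf
  out$p_c1 <- p_c1
  out$lapse <- lapse
  out$response_consonant <- unname(.consonant_of(percept, voicing))
  out$causal_response <- ifelse(av, ifelse(p_c1 >= 0.5, "C=1", "C=2"),
                                NA_character_)
  out$causal_confidence_report <- ifelse(av, abs(2 * p_c1 - 1), NA_real_)

  # quartile discretization of latent confidence over non-lapse trials
  lvl <- integer(n)
  nl <- which(!lapse)
  r <- rank(conf[nl], ties.method = "first")
  lvl[nl] <- ceiling(4 * r / length(nl))
  out$perceptual_confidence_level <- lvl

  # lapses overwrite every report with a uniform draw
  out$response_consonant[lapse] <- lapse_consonant[lapse]
  out$percept_place[lapse] <- unname(.place_of(lapse_consonant[lapse]))
  out$percept_voicing[lapse] <- unname(.voicing_of(lapse_consonant[lapse]))
  out$perceptual_confidence_level[lapse] <- lapse_level[lapse]
  la <- lapse & av
  out$causal_response[la] <- lapse_causal[la]
  out$causal_confidence_report[la] <- lapse_cconf[la]

  dplyr::relocate(out, "subject")
}

#' Simulate a multi-subject experiment
#'
#' One simulated subject per seed; each subject gets a fresh trial ordering
#' and fresh sensory noise.
#'
#' @param seeds integer vector, one seed per subject.
#' @param params an [observer_params()] shared across subjects.
#' @param spec a [design_spec()].
#' @return Row-bound trial records for all subjects.
#' @export
simulate_experiment <- function(seeds = 1:12, params = observer_params(),
                                spec = design_spec()) {
  dplyr::bind_rows(lapply(seeds, function(s) {
    simulate_observer(build_design(spec, seed = s), params,
                      seed = s, subject = sprintf("S%02d", s))
  }))
}
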