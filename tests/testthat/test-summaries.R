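test_that("summaries refuse trial tables without normalized confidence", {
  raw <- make_toy_trials()
  expect_error(accuracy_and_confidence_by_modality(raw),
               "add_normalized_confidence")
  expect_error(percept_fractions(raw, "mcgurk"), "add_normalized_confidence")
  expect_error(causal_fractions_and_confidence(raw), "add_normalized_confidence")
})

test_that("accuracy and confidence by modality handle toy tables", {
  tr <- toy_normalized()
  tab <- accuracy_and_confidence_by_modality(tr)
  # congruent only (McGurk rows have no 6-way correct response)
  expect_identical(sum(tab$n), 5L)
  expect_equal(tab$accuracy, 4 / 5)
  expect_equal(tab$accuracy_place, 4 / 5)

  # all-correct table: accuracy 1 everywhere, incorrect stratum empty
  allc <- tr
  allc$response_consonant <- allc$consonant
  allc$percept_place <- allc$place_class
  t2 <- accuracy_and_confidence_by_modality(allc)
  expect_equal(t2$accuracy, 1)
  expect_identical(t2$n_incorrect, 0L)
  expect_true(is.na(t2$mean_confidence_incorrect))

  # shuffling rows leaves every summary unchanged (order invariance)
  set.seed(1)
  shuf <- tr[sample(nrow(tr)), ]
  expect_equal(accuracy_and_confidence_by_modality(shuf), tab)
})

test_that("percept fractions count and partition correctly", {
  tr <- toy_normalized()
  tab <- percept_fractions(tr, "mcgurk")
  expect_equal(tab$fraction[match(c("B/P", "D/T", "G/K"), tab$percept_place)],
               c(0.2, 0.4, 0.4))
  expect_equal(sum(tab$fraction), 1, tolerance = 1e-9)
  expect_identical(sum(tab$n), 5L)

  # empty selection warns and returns an empty table, not an error
  expect_warning(out <- percept_fractions(tr, "visual_gk"), "no trials")
  expect_identical(nrow(out), 0L)

  # a 10-trial toy with 5 G/K, 3 D/T, 2 B/P gives (0.2, 0.3, 0.5)
  t10 <- tr[rep(1, 10), ]
  t10$mcgurk <- TRUE
  t10$percept_place <- c(rep("G/K", 5), rep("D/T", 3), rep("B/P", 2))
  tab10 <- percept_fractions(t10, "mcgurk")
  expect_equal(tab10$fraction[match(c("B/P", "D/T", "G/K"),
                                    tab10$percept_place)], c(0.2, 0.3, 0.5))
})

test_that("causal fractions stratify by correctness and by percept", {
  tr <- toy_normalized()
  byc <- causal_fractions_and_confidence(tr, "correctness")
  # congruent toy: 4 correct (3 C=1, 1 C=1? rows 1,2,3 correct C=1; row 5 correct C=1)
  cor1 <- byc[byc$level == "correct" & byc$causal_response == "C=1", ]
  expect_equal(cor1$fraction, 1)
  inc <- byc[byc$level == "incorrect", ]
  expect_equal(sum(inc$fraction), 1, tolerance = 1e-9)

  byp <- causal_fractions_and_confidence(tr, "percept")
  expect_true(all(tapply(byp$fraction, byp$level, sum) == 1))
  # missing cells are flagged with n = 0 and NA confidence
  expect_true(any(byp$n == 0 & is.na(byp$mean_causal_confidence)))

  # all-C=2 table: C=1 fractions are zero everywhere
  t2 <- tr
  t2$causal_response <- "C=2"
  b2 <- causal_fractions_and_confidence(t2, "correctness")
  expect_true(all(b2$fraction[b2$causal_response == "C=1"] == 0))
})

test_that("median split assigns ties to the low stratum", {
  tr <- toy_normalized()
  # hand-check one category: S1 x McGurk x C=1 confidences
  ms <- median_split_by_causal_confidence(tr)
  expect_true(all(ms$n[ms$stratum == "low"] >= 1))
  # McGurk C=1 has 3 trials -> defined; the single-trial AVc C=2 cell is not
  expect_true(all(ms$defined[ms$stimulus == "McGurk" &
                               ms$causal_response == "C=1"]))
  expect_false(any(ms$defined[ms$stimulus == "AVc" &
                                ms$causal_response == "C=2"]))

  # {0.1, 0.4, 0.6, 0.9} -> low {0.1, 0.4}, high {0.6, 0.9}
  t4 <- tr[1:4, ]
  t4$causal_response <- "C=1"
  t4$mcgurk <- FALSE
  t4$condition <- "AVc"
  t4$causal_confidence_report <- c(0.1, 0.4, 0.6, 0.9)
  t4 <- add_normalized_confidence(t4)
  m4 <- median_split_by_causal_confidence(t4)
  expect_identical(m4$n[m4$stratum == "low"], 2L)
  expect_identical(m4$n[m4$stratum == "high"], 2L)

  # all-tied confidences: everything lands in the low stratum
  t4$causal_confidence_report <- rep(0.5, 4)
  t4 <- add_normalized_confidence(t4)
  mt <- median_split_by_causal_confidence(t4)
  expect_identical(mt$stratum, "low")
  expect_identical(mt$n, 4L)

  # a category with fewer than two trials is flagged undefined
  t1 <- add_normalized_confidence(tr[1, ])
  m1 <- median_split_by_causal_confidence(t1)
  expect_false(any(m1$defined))
})

test_that("metamer selection keeps only matched C=1 outcomes", {
  tr <- toy_normalized()
  sel <- suppressWarnings(select_metamers(tr))
  # selection contract: never any C=2-response trial in either subset
  expect_true(all(sel$n[sel$source == "congruent"] >= 0))
  # congruent subset = correct syllable + C=1 (rows 1, 2, 3, 5)
  expect_identical(sum(sel$n[sel$source == "congruent"]), 4L)
  # McGurk subset = correct voicing + C=1 (rows 6, 7, 8)
  expect_identical(sum(sel$n[sel$source == "mcgurk"]), 3L)
  # fractions partition within each subject x class x source cell
  sums <- tapply(sel$fraction, paste(sel$subject, sel$percept_place,
                                     sel$source), sum)
  expect_true(all(is.na(sums) | abs(sums - 1) < 1e-9))

  # identical subsets yield identical paired statistics
  t0 <- tr[tr$condition == "AVc" & tr$causal_response == "C=1" &
             tr$response_consonant == tr$consonant, ]
  tm <- t0
  tm$mcgurk <- TRUE
  tm$condition <- "McGurk"
  tm$visual_consonant <- "G"
  both <- add_normalized_confidence(dplyr::bind_rows(t0, tm))
  selb <- suppressWarnings(select_metamers(both))
  wide <- tidyr::pivot_wider(
    selb[, c("subject", "percept_place", "source",
             "perceptual_confidence_level", "fraction")],
    names_from = "source", values_from = "fraction")
  expect_equal(wide$congruent, wide$mcgurk)
})

test_that("voicing accuracy is scored against the auditory component", {
  tr <- make_toy_trials()
  va <- voicing_accuracy(tr)
  expect_equal(va$accuracy, rep(1, nrow(va)))  # toy: all voicing correct

  # perfectly informative channels give accuracy 1 in simulation
  p1 <- observer_params(voicing_acc_A = 1, voicing_acc_V = 1, lapse_rate = 0)
  d <- build_design(design_spec(n_blocks = 1), seed = 1)
  s1 <- simulate_observer(d, p1, seed = 1)
  expect_equal(voicing_accuracy(s1)$accuracy, rep(1, 4))

  # one wrong voicing report halves a two-trial cell
  tr2 <- tr[1:2, ]
  tr2$percept_voicing <- c("voiced", "unvoiced")
  expect_equal(voicing_accuracy(tr2)$accuracy, 0.5)
})

test_that("across-subject aggregation averages subject-level values first", {
  tr <- dplyr::bind_rows(
    toy_normalized(),
    dplyr::mutate(toy_normalized(), subject = "S2",
                  response_consonant = consonant))
  tab <- accuracy_and_confidence_by_modality(tr)
  agg <- aggregate_subjects(tab, "accuracy", keys = "modality")
  expect_identical(agg$n_subjects, 2L)
  expect_equal(agg$mean, mean(c(0.8, 1)))
  expect_equal(agg$min, 0.8)
  expect_equal(agg$max, 1)
})
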