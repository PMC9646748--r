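test_that("argmax labeling follows the fixed tie-break order", {
  expect_equal(argmax_label(prow(multiple = 0.7, death = 0.1,
                                 empty = 0.1)), "Multiple")
  expect_equal(argmax_label(c(Single = 0.25, Multiple = 0.25,
                              Death = 0.25, Empty = 0.25)), "Single")
  expect_equal(argmax_label(c(Single = 0.1, Multiple = 0.4,
                              Death = 0.4, Empty = 0.1)), "Multiple")

  # brute force over random vectors
  set.seed(8)
  P <- matrix(stats::runif(4e4), ncol = 4)
  P <- P / rowSums(P)
  colnames(P) <- CLS
  want <- apply(P, 1, function(r) CLS[which(r == max(r))[1]])
  expect_equal(argmax_label(P), unname(want))
})

test_that("initial-state vote implements the caption's rules", {
  expect_equal(classify_initial_state(c("Empty", "Empty", "Empty")), "NoCell")
  expect_equal(classify_initial_state(c("Single", "Multiple", "Single")),
               "MultipleAtStart")
  expect_equal(classify_initial_state(c("Single", "Death", "Empty")),
               "DeadAtStart")
  expect_equal(classify_initial_state(c("Single", "Single", "Single")),
               "SingleCell")
  expect_equal(classify_initial_state(c("Single", "Empty", "Single")),
               "Ambiguous")
  # Multiple outranks Death in the vote
  expect_equal(classify_initial_state(c("Death", "Multiple", "Empty")),
               "MultipleAtStart")
  expect_error(classify_initial_state(c("Single", "Single")), "exactly 3")
})

test_that("division rule needs two qualifying frames, one above the high bar", {
  base <- lapply(1:12, function(i) prow())
  s1 <- base
  s1[[6]] <- prow(multiple = 0.95)
  s1[[10]] <- prow(multiple = 0.995)
  p <- pmat(s1)
  expect_equal(detect_division(p), attr(p, "times_min")[10])

  # two 0.95 frames, none above 0.99: no division
  s2 <- base
  s2[[6]] <- prow(multiple = 0.95)
  s2[[10]] <- prow(multiple = 0.95)
  expect_true(is.na(detect_division(pmat(s2))))

  # one 0.995 frame alone is not enough
  s3 <- base
  s3[[6]] <- prow(multiple = 0.995)
  expect_true(is.na(detect_division(pmat(s3))))

  # high frame first, low frame later: event at the completing frame
  s4 <- base
  s4[[4]] <- prow(multiple = 0.995)
  s4[[9]] <- prow(multiple = 0.95)
  p4 <- pmat(s4)
  expect_equal(detect_division(p4), attr(p4, "times_min")[9])
})

test_that("death rule fires on the earliest strict crossing", {
  base <- lapply(1:10, function(i) prow())
  s <- base
  s[[8]] <- prow(death = 0.6)
  p <- pmat(s)
  expect_equal(detect_death(p), attr(p, "times_min")[8])

  # boundary: exactly 0.5 never fires
  s2 <- lapply(1:10, function(i) prow(death = 0.5))
  expect_true(is.na(detect_death(pmat(s2))))

  # linear-scan oracle on random sequences
  set.seed(9)
  for (i in 1:200) {
    p <- random_pmat(n = sample(3:15, 1))
    t_got <- detect_death(p)
    hits <- which(p[, "Death"] > 0.5)
    t_want <- if (length(hits)) attr(p, "times_min")[hits[1]] else NA_real_
    expect_identical(t_got, t_want)
  }
})

test_that("track_well applies the vote, precedence and error contract", {
  # all one-hot Single: living non-dividing cell
  quiet <- pmat(lapply(1:8, function(i) prow()))
  r <- track_well(quiet)
  expect_equal(r$initial_state, "SingleCell")
  expect_equal(r$outcome, "AliveQuiescent")
  expect_true(is.na(r$event_time_min))

  # division signature after a Single start
  s <- lapply(1:10, function(i) prow())
  s[[6]] <- prow(multiple = 0.95)
  s[[8]] <- prow(multiple = 0.995)
  r <- track_well(pmat(s))
  expect_equal(r$outcome, "Divided")

  # both signatures: division wins even when death occurs first
  s2 <- lapply(1:12, function(i) prow())
  s2[[4]] <- prow(death = 0.9)
  s2[[8]] <- prow(multiple = 0.95)
  s2[[10]] <- prow(multiple = 0.995)
  p2 <- pmat(s2)
  r2 <- track_well(p2)
  expect_equal(r2$outcome, "Divided")
  expect_equal(r2$event_time_min, attr(p2, "times_min")[10])

  # non-single starts are not tracked
  multi <- pmat(c(list(prow(multiple = 1)),
                  lapply(1:5, function(i) prow())))
  r3 <- track_well(multi)
  expect_equal(r3$initial_state, "MultipleAtStart")
  expect_equal(r3$outcome, "NotTracked")

  expect_error(track_well(pmat(lapply(1:2, function(i) prow()))),
               "at least 3")
})

test_that("raising thresholds never creates additional event calls", {
  set.seed(10)
  seqs <- lapply(1:150, function(i) random_pmat(n = 14))
  base <- fate_rule_params()
  stricter <- list(fate_rule_params(p_multiple_lo = 0.95),
                   fate_rule_params(p_multiple_hi = 0.995),
                   fate_rule_params(p_death = 0.7))
  for (params in stricter) {
    for (p in seqs) {
      if (!is.na(detect_division(p, params = params)))
        expect_false(is.na(detect_division(p, params = base)))
      if (!is.na(detect_death(p, params = params)))
        expect_false(is.na(detect_death(p, params = base)))
    }
  }
})

test_that("one-hot oracle traces recover simulated fates exactly", {
  k <- cohort_kinetics(150, frac_single_at_start = 1, frame_interval_min = 80,
                       duration_h = 96, seed = 12L)
  co <- simulate_cohort(k)
  truth <- cohort_truth_records(co)
  probs <- cohort_oracle_probabilities(co, confidence = 1)
  got <- track_cohort(probs)
  n_frames <- 96 * 60 / 80 + 1
  for (i in seq_len(nrow(truth))) {
    ev_frame <- truth$event_time_min[i] / 80
    if (truth$outcome[i] == "Divided" && ev_frame <= n_frames - 2 &&
        ev_frame >= 3) {
      # two Multiple frames available and a clean Single start
      expect_equal(got$outcome[i], "Divided", info = paste("well", i))
      expect_equal(got$event_time_min[i],
                   truth$event_time_min[i] + 80)   # second Multiple frame
    }
    if (truth$outcome[i] == "Died" && !is.na(ev_frame) && ev_frame >= 3) {
      expect_equal(got$outcome[i], "Died", info = paste("well", i))
      expect_equal(got$event_time_min[i], truth$event_time_min[i])
    }
    if (truth$outcome[i] == "AliveQuiescent")
      expect_equal(got$outcome[i], "AliveQuiescent", info = paste("well", i))
  }
})
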