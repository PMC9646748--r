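test_that("render_well is seeded-deterministic and respects content", {
  s <- well_scene_spec(content = "single", seed = 3L)
  i1 <- render_well(s)
  i2 <- render_well(s)
  expect_identical(unclass(i1)[, ], unclass(i2)[, ])
  expect_true(all(i1 >= 0 & i1 <= 65535))

  # empty well: no non-border foreground at the ideal threshold
  e <- render_well(well_scene_spec(content = "empty", seed = 5L))
  expect_equal(ideal_object_count(e), 0)

  # oversized cell radius rejected
  expect_error(well_scene_spec(content = "single", cell_radii_um = 150),
               "radius larger")
  expect_error(render_well(well_scene_spec(content = "single",
                                           cell_radii_um = 85, seed = 1L)),
               "radius larger")
})

test_that("rendered disk area matches the analytic circle area", {
  s <- well_scene_spec(content = "single", cell_radii_um = 8,
                       pixel_size_um = 1, seed = 11L)
  img <- render_well(s)
  objs <- Filter(function(o) !o$touches_border,
                 segment_objects(img, IDEAL_THR, 2))
  areas <- vapply(objs, function(o) o$area_px, numeric(1))
  expect_length(areas, 1)
  expect_lt(abs(max(areas) - pi * 8^2) / (pi * 8^2), 0.10)
})

test_that("ideal-threshold object count equals ground-truth cell count", {
  for (seed in 1:8) {
    for (content in c("empty", "single", "multiple", "dead")) {
      img <- render_well(well_scene_spec(content = content, seed = seed))
      truth_n <- switch(content, empty = 0L, single = 1L, dead = 1L,
                        multiple = nrow(attr(img, "scene")$centers_px))
      expect_equal(ideal_object_count(img), truth_n,
                   info = sprintf("%s seed %d", content, seed))
    }
  }
})

test_that("render_timelapse encodes events at the snapped frame", {
  # no event: every frame Single
  r <- render_timelapse(well_scene_spec(content = "single", seed = 2L),
                        n_frames = 10, frame_interval_min = 40,
                        render = FALSE)
  expect_equal(r$truth$frame_classes, rep("Single", 10))
  expect_equal(r$truth$outcome, "AliveQuiescent")
  expect_equal(r$timelapse$times_min, seq(0, 360, by = 40))

  # division at 600 min, 40-min interval: two blobs from frame index 15 on
  r <- render_timelapse(well_scene_spec(content = "single",
                                        cell_radii_um = 9, seed = 4L),
                        event = list(type = "division", time_min = 600),
                        n_frames = 18, frame_interval_min = 40)
  expect_equal(r$truth$outcome, "Divided")
  expect_equal(r$truth$event_time_min, 600)
  counts <- vapply(r$timelapse$frames, ideal_object_count, numeric(1))
  expect_equal(counts, c(rep(1, 15), rep(2, 3)))

  # off-grid event time snaps to the next frame
  r <- render_timelapse(well_scene_spec(content = "single", seed = 4L),
                        event = list(type = "death", time_min = 130),
                        n_frames = 10, frame_interval_min = 40,
                        render = FALSE)
  expect_equal(r$truth$event_time_min, 160)
  expect_equal(r$truth$frame_classes[4:5], c("Single", "Death"))

  # death at t = 0: dead from the first frame, outcome DeadAtStart
  r <- render_timelapse(well_scene_spec(content = "single", seed = 6L),
                        event = list(type = "death", time_min = 0),
                        n_frames = 5, frame_interval_min = 40,
                        render = FALSE)
  expect_equal(r$truth$initial_class, "Death")
  expect_equal(r$truth$outcome, "DeadAtStart")
})

test_that("cohort kinetics are validated and realized fractions converge", {
  expect_error(cohort_kinetics(10, division_fraction_96h = 0.6,
                               death_fraction_96h = 0.5), "<= 1")
  # 2 frames only: initial vote impossible
  expect_error(cohort_kinetics(10, frame_interval_min = 60 * 96,
                               duration_h = 96), ">= 3 frames")

  # no events => every single well quiescent
  co <- simulate_cohort(cohort_kinetics(60, division_fraction_96h = 0,
                                        death_fraction_96h = 0, seed = 8L))
  rec <- cohort_truth_records(co)
  singles <- rec[rec$initial_state == "SingleCell", ]
  expect_gt(nrow(singles), 0)
  expect_true(all(singles$outcome == "AliveQuiescent"))

  # realized event fractions within 3 binomial SE over >= 1000 wells
  k <- cohort_kinetics(1200, frac_single_at_start = 1,
                       division_fraction_96h = 0.17,
                       death_fraction_96h = 0.38, seed = 33L)
  rec <- cohort_truth_records(simulate_cohort(k))
  n <- nrow(rec)
  for (ev in c(Divided = 0.17, Died = 0.38)) NULL
  for (i in 1:2) {
    p <- c(0.17, 0.38)[i]
    out <- c("Divided", "Died")[i]
    phat <- mean(rec$outcome == out)
    expect_lt(abs(phat - p), 3 * sqrt(p * (1 - p) / n))
  }
})

test_that("oracle probabilities put the stated mass on the true class", {
  r <- render_timelapse(well_scene_spec(content = "single", seed = 2L),
                        event = list(type = "division", time_min = 200),
                        n_frames = 8, frame_interval_min = 40,
                        render = FALSE)
  P1 <- oracle_probabilities(r$truth, confidence = 1)
  expect_true(all(P1 %in% c(0, 1)))
  expect_equal(argmax_label(P1), r$truth$frame_classes)

  P7 <- oracle_probabilities(r$truth, confidence = 0.7)
  expect_equal(sort(unique(as.numeric(P7))), c(0.1, 0.7))
  expect_equal(rowSums(P7), rep(1, 8))

  expect_error(oracle_probabilities(r$truth, confidence = 0.2), "0.25")

  # normalization under jitter, many draws
  set.seed(1)
  for (i in 1:50) {
    P <- oracle_probabilities(r$truth, confidence = 0.8, jitter_sd = 0.1,
                              seed = i)
    expect_true(all(abs(rowSums(P) - 1) < 1e-9))
    expect_true(all(P >= 0))
  }
})

test_that("classification datasets honor exact class counts and seeding", {
  d <- make_classification_dataset(rep(10, 4), seed = 5L,
                                   keep_images = FALSE)
  expect_equal(nrow(d$manifest), 40)
  expect_equal(as.vector(table(factor(d$manifest$label, levels = CLS))),
               rep(10L, 4))

  # the annotated-cohort imbalance at one-tenth scale
  d1 <- make_classification_dataset(c(287, 461, 80, 909), seed = 9L,
                                    keep_images = FALSE)
  expect_equal(as.vector(table(factor(d1$manifest$label, levels = CLS))),
               c(287L, 461L, 80L, 909L))
  d2 <- make_classification_dataset(c(287, 461, 80, 909), seed = 9L,
                                    keep_images = FALSE)
  expect_identical(d1$manifest, d2$manifest)
})
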