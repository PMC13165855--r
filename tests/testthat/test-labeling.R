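test_that("local reaction time is response minus onset", {
  s <- session_events(c(0, 30), c(0.7, 31.5))
  expect_equal(compute_lrt(s), c(0.7, 1.5))
  expect_equal(compute_lrt(session_events(10, 10)), 0)
  expect_length(compute_lrt(session_events(numeric(0), numeric(0))), 0)
  expect_error(session_events(c(0, 30), c(0.7, 29.9)), "event\\(s\\) 2")
  expect_error(session_events(c(10, 5), c(11, 6)), "strictly increasing")
})

test_that("global reaction time averages the qualifying 90 s look-back set", {
  s <- session_events(c(0, 30, 60, 100), c(1, 32, 63, 104))
  grt <- compute_grt(s, lrt = c(1, 2, 3, 4))
  # event 4: events at 30 and 60 qualify; the event at 0 is 100 s back
  expect_equal(grt[4], 2.5)
  expect_true(is.na(grt[1]))

  s2 <- session_events(c(0, 100), c(1, 101))
  expect_true(all(is.na(compute_grt(s2, lrt = c(1, 1)))))

  s3 <- session_events(c(0, 10, 20), c(1, 11, 21))
  expect_equal(compute_grt(s3, lrt = c(1, 1, 1))[3], 1)

  # locality: perturbing an event more than 90 s before event i leaves
  # grt[i] unchanged
  deps <- c(0, 95, 120, 150, 200)
  lrts <- c(9, 1, 2, 3, 4)
  g1 <- compute_grt(session_events(deps, deps + lrts), lrts)
  lrts2 <- c(0.1, 1, 2, 3, 4)
  g2 <- compute_grt(session_events(deps, deps + lrts2), lrts2)
  expect_equal(g1[3:5], g2[3:5])
})

test_that("alert threshold is the interpolated 95th percentile", {
  expect_equal(compute_art(rep(1, 4)), 1)
  expect_equal(compute_art(0:100), 95)
  expect_equal(compute_art(2.3), 2.3)
  expect_error(compute_art(numeric(0)), "empty")
})

test_that("reaction-time label rule partitions events with strict boundaries", {
  expect_equal(label_rt_event(3, 2.6, 1), "fatigued")
  expect_equal(label_rt_event(1.0, 1.2, 1), "alert")
  expect_equal(label_rt_event(2.0, 3.0, 1), "discard")
  expect_equal(label_rt_event(3, NA, 1), "discard")
  # boundary values are strict: exactly 1.5*art or 2.5*art -> discard
  expect_equal(label_rt_event(1.5, 1.0, 1), "discard")
  expect_equal(label_rt_event(2.5, 3.0, 1), "discard")

  # partition + monotonicity over a grid
  art <- 1
  grid <- expand.grid(lrt = seq(0, 4, by = 0.25), grt = seq(0, 4, by = 0.25))
  lab <- label_rt_event(grid$lrt, grid$grt, art)
  expect_true(all(lab %in% c("alert", "fatigued", "discard")))
  # increasing lrt with grt fixed above 2.5*art never flips fatigued->alert
  for (g in c(2.6, 3.5)) {
    labs <- label_rt_event(seq(0, 5, by = 0.1), rep(g, 51), art)
    expect_false(any(labs == "alert"))
    first_fat <- match("fatigued", labs)
    expect_true(all(labs[first_fat:51] == "fatigued"))
  }
})

test_that("subject retention requires both class counts at threshold", {
  counts <- data.frame(subject_id = c("s1", "s2", "s3"),
                       n_fatigued = c(60, 49, 50),
                       n_alert = c(60, 80, 50))
  expect_equal(filter_retained_subjects(counts), c("s1", "s3"))
  zero <- data.frame(subject_id = "z", n_fatigued = 0, n_alert = 0)
  expect_length(filter_retained_subjects(zero), 0)
  # a 51/51 subject is retained at the 50-per-class rule
  expect_equal(filter_retained_subjects(
    data.frame(subject_id = "s7", n_fatigued = 51, n_alert = 51)), "s7")
})

test_that("PERCLOS ratio and threshold labeling", {
  expect_equal(compute_perclos(0.5, 2, 0.5, 1), 0.25)
  expect_equal(compute_perclos(0, 0, 0, 4), 1)
  expect_equal(compute_perclos(0, 4, 0, 0), 0)
  expect_true(is.na(compute_perclos(0, 0, 0, 0)))
  expect_error(compute_perclos(-1, 0, 0, 1), "non-negative")
  # scale invariance
  expect_equal(compute_perclos(0.3, 1.2, 0.1, 0.9),
               compute_perclos(3, 12, 1, 9))

  expect_equal(label_perclos(0.75), "fatigued")
  expect_equal(label_perclos(0.25), "alert")
  expect_equal(label_perclos(0.5), "alert")   # strict inequality
  expect_true(is.na(label_perclos(NA_real_)))
  expect_error(label_perclos(1.2), "\\[0, 1\\]")
})

test_that("labeling pipeline recovers generator intent on simulated sessions", {
  # all-alert trajectory: nothing labeled fatigued
  sim <- simulate_deviation_session(100, 0L, seed = 11)
  lab <- label_rt_session(sim$session)
  expect_equal(sum(lab$label == "fatigued"), 0)

  # sparse fatigued tail block: its late events (dense fatigued history in
  # the look-back window) are labeled fatigued
  sim2 <- simulate_deviation_session(200, rep(c(0L, 1L), c(190, 10)),
                                     seed = 12, fatigued_rt = c(6, 8))
  lab2 <- label_rt_session(sim2$session)
  expect_true(all(lab2$label[196:200] == "fatigued"))
  expect_true(all(lab2$label[sim2$intent == 0L] != "fatigued"))

  # events spaced beyond the window: GRT undefined everywhere -> discard
  wide <- session_events(seq(0, by = 120, length.out = 10),
                         seq(0, by = 120, length.out = 10) + 1)
  lab3 <- label_rt_session(wide, art = 1)
  expect_true(all(lab3$label == "discard"))
})
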