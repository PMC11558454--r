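test_that("proportional differences follow the Weber-scaling definition", {
  expect_equal(proportional_difference(10, 5), 0.5)
  expect_equal(proportional_difference(5, 10), 0.5)
  expect_equal(proportional_difference(3, 3), 0)
  expect_equal(proportional_difference(0, 0), 0)
  expect_equal(proportional_difference(7, 0), 1)
  # invariance to a common rescaling, which absolute differences lack
  a <- c(1, 4, 2.5); b <- c(3, 2, 2.5)
  expect_equal(proportional_difference(10 * a, 10 * b),
               proportional_difference(a, b))
})

test_that("overlap counting matches the interval-intersection definition", {
  disjoint <- as_interaction(alternating_events(10, period = 5, dur = 0.4))
  expect_identical(overlap_rate(disjoint), c(n_overlapping = 0L, n_total = 10L))

  onset <- seq(0, 20, by = 5)
  sim_ev <- data.frame(
    male_id = rep(c("A", "B"), each = 5),
    onset = rep(onset, 2), offset = rep(onset + 1, 2), n_chucks = 0L)
  sim <- as_interaction(sim_ev[order(sim_ev$onset, sim_ev$male_id), ])
  expect_identical(overlap_rate(sim), c(n_overlapping = 10L, n_total = 10L))

  # touching endpoints (half-open intervals) do not overlap
  touch <- as_interaction(data.frame(
    male_id = c("A", "B", "A", "B"), onset = c(0, 1, 10, 11.5),
    offset = c(1, 2, 11, 12.5), n_chucks = 0L))
  expect_identical(unname(overlap_rate(touch)[1]), 0L)

  # 6-call toy with 2 crossing pairs -> 4 of 6 calls overlap
  toy <- as_interaction(data.frame(
    male_id = c("A", "B", "A", "B", "A", "B"),
    onset = c(0, 0.5, 4, 4.5, 10, 15),
    offset = c(1, 1.5, 5, 5.5, 11, 16), n_chucks = 0L))
  expect_identical(overlap_rate(toy), c(n_overlapping = 4L, n_total = 6L))
  expect_identical(unname(overlap_rate(toy)), brute_overlap(toy$events))
})

test_that("overlap counting matches the brute-force oracle on random inputs", {
  for (s in 101:140) {
    ev <- random_events(s)
    if (nrow(ev) < 2 || length(unique(ev$male_id)) < 2) next
    itx <- as_interaction(ev)
    expect_identical(unname(overlap_rate(itx)), brute_overlap(itx$events))
  }
})

test_that("call rate and complexity are the advertised ratios", {
  # 30 calls of male A inside a 60 s interaction -> 30 calls/min
  onsets_a <- seq(0, 58, by = 2)
  ev <- rbind(
    data.frame(male_id = "A", onset = onsets_a, offset = onsets_a + 0.4,
               n_chucks = rep(c(0L, 1L, 2L), 10)),
    data.frame(male_id = "B", onset = 59.1, offset = 60, n_chucks = 0L))
  ev <- ev[order(ev$onset), ]
  itx <- as_interaction(ev)
  expect_equal(itx$length, 60)
  m <- male_metrics(itx, "A")
  expect_equal(m$call_rate, 30)
  expect_equal(m$complexity, 1)
  expect_identical(m$n_calls, 30L)
  expect_error(male_metrics(itx, "Z"), "no call")
})

test_that("amplitude calls are the loudest eligible ones, matching exhaustive search", {
  # 10 calls of A every 2 s, one overlapped by B, known loudness ranks
  onsets_a <- seq(0, 18, by = 2)
  ev <- rbind(
    data.frame(male_id = "A", onset = onsets_a, offset = onsets_a + 0.4,
               n_chucks = 0L, raw_p2p = c(1, 2, 10, 9, 3, 8, 7, 4, 5, 6)),
    data.frame(male_id = "B", onset = 8.2, offset = 8.5, n_chucks = 0L,
               raw_p2p = 1))  # overlaps A's 5th call (onset 8, loudness 3)
  ev <- ev[order(ev$onset), ]
  ev$rms <- ev$raw_p2p / (2 * sqrt(2))
  ev$p2p <- ev$raw_p2p
  itx <- as_interaction(ev)
  m <- male_metrics(itx, "A")
  want <- brute_amp_selection(itx$events, "A")
  expect_identical(m$amp_call_idx, want)
  expect_equal(m$whine_p2p, mean(itx$events$p2p[want]))
  expect_equal(m$whine_rms, mean(itx$events$rms[want]))
  # the overlapped call and the first/last 3 calls of A are never selected
  expect_false(any(itx$events$onset[m$amp_call_idx] %in%
                     c(onsets_a[1:3], onsets_a[8:10], 8)))
})

test_that("amplitude selection matches the exhaustive oracle on random inputs", {
  for (s in 201:230) {
    ev <- random_events(s)
    if (nrow(ev) < 2 || length(unique(ev$male_id)) < 2) next
    set.seed(s)
    ev$raw_p2p <- runif(nrow(ev), 0.1, 1)
    itx <- as_interaction(ev)
    for (id in c("A", "B")) {
      expect_identical(male_metrics(itx, id)$amp_call_idx,
                       brute_amp_selection(itx$events, id))
    }
  }
})

test_that("calls without eligible amplitude measurements are flagged, not faked", {
  itx <- as_interaction(alternating_events(8, period = 2, dur = 0.4))
  m <- male_metrics(itx, "A")  # no raw_p2p column at all
  expect_false(m$has_amplitude)
  expect_true(is.na(m$whine_rms))
  short <- as_interaction(alternating_events(8, period = 2, dur = 0.4))
  short$events$raw_p2p <- 1
  m2 <- male_metrics(short, "A")  # 4 calls of A: all within first/last 3
  expect_false(m2$has_amplitude)
})

test_that("pair metrics combine means and rival differences symmetrically", {
  itx <- as_interaction(alternating_events(12, period = 5, dur = 0.4))
  ma <- male_metrics(itx, "A"); mb <- male_metrics(itx, "B")
  ma$whine_rms <- 10; mb$whine_rms <- 5
  ma$whine_p2p <- 28; mb$whine_p2p <- 14
  pm <- pair_metrics(itx, ma, mb)
  pm_sw <- pair_metrics(itx, mb, ma)
  expect_equal(pm$whine_rms_mean, 7.5)
  expect_equal(pm$whine_rms_absdiff, 5)
  expect_equal(pm$whine_rms_propdiff, 0.5)
  for (col in grep("_(mean|absdiff|propdiff)$", names(pm), value = TRUE)) {
    expect_equal(pm[[col]], pm_sw[[col]])
  }
  expect_equal(pm$interaction_length, itx$length)
  # equal rivals -> zero differences
  pm_eq <- pair_metrics(itx, ma, ma)
  expect_equal(pm_eq$whine_rms_absdiff, 0)
  expect_equal(pm_eq$whine_rms_propdiff, 0)
})

test_that("model transforms are appended, never applied in place", {
  itx <- as_interaction(alternating_events(12, period = 5, dur = 0.4))
  ma <- male_metrics(itx, "A"); mb <- male_metrics(itx, "B")
  pm <- add_model_transforms(pair_metrics(itx, ma, mb))
  expect_equal(pm$log_interaction_length, log(pm$interaction_length))
  expect_equal(pm$sqrt_call_rate_propdiff, sqrt(pm$call_rate_propdiff))
  expect_true(all(c("interaction_length", "call_rate_propdiff") %in% names(pm)))
})
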