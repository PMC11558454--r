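test_that("a continuous duet forms a single interaction spanning all calls", {
  ev <- alternating_events(13, period = 5, dur = 0.4)  # calls at 0, 5, ..., 60
  itx <- segment_interactions(ev)
  expect_length(itx, 1)
  expect_equal(itx[[1]]$length, 60.4)
  expect_identical(nrow(itx[[1]]$events), 13L)
  expect_identical(interactions_signature(itx),
                   bouts_signature(brute_bouts(ev)))
})

test_that("a single-male timeline yields no interaction", {
  ev <- alternating_events(13)
  ev$male_id <- "A"
  expect_length(segment_interactions(ev), 0)
})

test_that("a long pause splits a duet and short bouts are dropped", {
  # duet with a 10.5 s dyad silence: calls at 0..30 then 41..61
  ev <- rbind(alternating_events(7, period = 5, dur = 0.5),
              alternating_events(5, period = 5, dur = 0.5, t0 = 41))
  itx <- segment_interactions(ev, max_pause = 10, min_length = 20)
  expect_identical(interactions_signature(itx),
                   bouts_signature(brute_bouts(ev, 10, 20)))
  expect_length(itx, 2)
  # shrink the second bout below 20 s: it must be dropped
  ev2 <- rbind(alternating_events(7, period = 5, dur = 0.5),
               alternating_events(4, period = 5, dur = 0.5, t0 = 41))
  itx2 <- segment_interactions(ev2, max_pause = 10, min_length = 20)
  expect_length(itx2, 1)
  expect_equal(itx2[[1]]$start, 0)
})

test_that("a pause of exactly max_pause does not end an interaction", {
  ev <- data.frame(male_id = c("A", "B", "A", "B"),
                   onset = c(0, 5, 15.5, 21), offset = c(0.5, 5.5, 16, 21.5),
                   n_chucks = 0L)
  expect_length(segment_interactions(ev, max_pause = 10, min_length = 20), 1)
  ev$onset[3] <- 15.5 + 0.01 + 1e-9  # nudge the gap just over 10 s
  ev$offset[3] <- ev$onset[3] + 0.5
  expect_length(segment_interactions(ev, max_pause = 10, min_length = 20), 0)
})

test_that("malformed event tables are rejected", {
  ev <- alternating_events(6)
  expect_error(segment_interactions(ev[c(2, 1, 3:6), ]), "sorted")
  bad <- ev; bad$offset[1] <- bad$onset[1]
  expect_error(segment_interactions(bad), "offset > onset")
  overlapping <- ev
  overlapping$offset[1] <- overlapping$onset[3] + 1  # male A overlaps itself
  expect_error(segment_interactions(overlapping), "overlap")
  expect_error(segment_interactions(ev, max_pause = 0), "max_pause")
})

test_that("segmentation matches the brute-force bout finder on random inputs", {
  for (s in 1:150) {
    ev <- random_events(s)
    if (nrow(ev) == 0) next
    got <- interactions_signature(segment_interactions(ev, 10, 20))
    want <- bouts_signature(brute_bouts(ev, 10, 20))
    expect_identical(got, want)
  }
})

test_that("re-segmenting an interaction's events returns that interaction", {
  for (s in 1:40) {
    ev <- random_events(s)
    if (nrow(ev) == 0) next
    for (itx in segment_interactions(ev, 10, 20)) {
      again <- segment_interactions(itx$events, 10, 20)
      expect_length(again, 1)
      expect_equal(again[[1]]$start, itx$start)
      expect_equal(again[[1]]$end, itx$end)
      expect_identical(nrow(again[[1]]$events), nrow(itx$events))
    }
  }
})

test_that("raising max_pause never shrinks the events covered by interactions", {
  covered <- function(ev, mp) {
    sum(vapply(segment_interactions(ev, mp, 20), function(x) nrow(x$events),
               integer(1)))
  }
  for (s in 1:40) {
    ev <- random_events(s)
    if (nrow(ev) == 0) next
    expect_true(covered(ev, 5) <= covered(ev, 10))
    expect_true(covered(ev, 10) <= covered(ev, 15))
  }
})

mk_itx_at <- function(t0, len) {
  # duet of span ~len s (calls every 5 s) starting at t0
  as_interaction(alternating_events(round(len / 5) + 1, period = 5,
                                    dur = 0.4, t0 = t0))
}

test_that("the longest interaction after the exclusion window is selected", {
  itx <- list(mk_itx_at(30, 40), mk_itx_at(200, 25))
  sel <- select_longest(itx, session_start = 0, exclusion = 120)
  expect_equal(sel$start, 200)          # 40 s one starts inside the excluded 2 min
  expect_null(select_longest(list(mk_itx_at(30, 40)), 0, 120))
  expect_null(select_longest(list(), 0, 120))
  # ties break toward the earlier start
  tie <- list(mk_itx_at(250, 30), mk_itx_at(150, 30))
  expect_equal(select_longest(tie, 0, 120)$start, 150)
  # the exclusion window is anchored at session_start
  expect_equal(select_longest(itx, session_start = -100, exclusion = 120)$start, 30)
})

with_rms_db <- function(itx, db) {
  itx$events$rms_db <- db
  itx
}

test_that("rival pairs with few or quiet calls are excluded with machine-readable reasons", {
  loud <- with_rms_db(as_interaction(alternating_events(12, period = 3)), 75)
  few <- with_rms_db(as_interaction(alternating_events(7, period = 3)), 75)
  quiet <- with_rms_db(as_interaction(alternating_events(12, period = 3)), 59.9)

  expect_identical(exclude_pair(few, loud), list(keep = FALSE, reasons = "min_calls"))
  expect_identical(exclude_pair(loud, quiet), list(keep = FALSE, reasons = "min_rms"))
  expect_identical(exclude_pair(few, quiet),
                   list(keep = FALSE, reasons = c("min_calls", "min_rms")))

  # boundaries are inclusive: exactly 8 calls and exactly 60.0 dB are kept
  boundary <- with_rms_db(as_interaction(alternating_events(8, period = 3)), 60)
  expect_true(exclude_pair(boundary, boundary)$keep)

  no_amp <- as_interaction(alternating_events(12, period = 3))
  expect_error(exclude_pair(no_amp, loud), "amplitude")
})

test_that("dyad silences are the pooled no-calling gaps", {
  ev <- data.frame(male_id = c("A", "B", "A", "B"),
                   onset = c(0, 2, 14, 30), offset = c(3, 6, 15, 31),
                   n_chucks = 0L)
  sil <- dyad_silences(ev, min_gap = 5)
  expect_equal(sil$start, c(6, 15))
  expect_equal(sil$end, c(14, 30))
  expect_equal(sil$duration, c(8, 15))
  # overlapping calls: silence measured from the running maximum offset
  expect_identical(nrow(dyad_silences(ev, min_gap = 20)), 0L)
})
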