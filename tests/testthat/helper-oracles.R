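# brute-force oracles and fixture builders, independent of the package's
# segmentation / overlap / eligibility implementations

# enumerate every contiguous subsequence of the onset-sorted pooled events
# and keep those that are maximal pause-free runs with both males and
# sufficient span — the definition of an interaction applied literally
brute_bouts <- function(events, max_pause = 10, min_length = 20) {
  ev <- events[order(events$onset), , drop = FALSE]
  n <- nrow(ev)
  gap_at <- function(i, from) {
    # dyad silence before event i, given the run started at `from`
    if (i == from) return(Inf)
    ev$onset[i] - max(ev$offset[from:(i - 1L)])
  }
  global_gap <- function(i) {
    if (i == 1L) return(Inf)
    ev$onset[i] - max(ev$offset[1:(i - 1L)])
  }
  out <- list()
  for (i in seq_len(n)) {
    if (!(global_gap(i) > max_pause)) next       # run must start after a long silence
    for (j in i:n) {
      gaps_ok <- TRUE
      for (k in seq(i, j)) {
        if (k > i && !(gap_at(k, i) <= max_pause)) { gaps_ok <- FALSE; break }
      }
      if (!gaps_ok) break
      ends_run <- j == n || ev$onset[j + 1L] - max(ev$offset[i:j]) > max_pause
      if (ends_run) {
        span <- max(ev$offset[i:j]) - ev$onset[i]
        if (length(unique(ev$male_id[i:j])) >= 2L && span >= min_length) {
          out[[length(out) + 1L]] <- list(start = ev$onset[i],
                                          end = max(ev$offset[i:j]),
                                          n_events = j - i + 1L)
        }
        break
      }
    }
  }
  out
}

bouts_signature <- function(bouts) {
  if (length(bouts) == 0L) return(data.frame(start = numeric(), end = numeric(),
                                             n_events = integer()))
  do.call(rbind, lapply(bouts, function(b) {
    data.frame(start = b$start, end = b$end, n_events = b$n_events)
  }))
}

interactions_signature <- function(itx) {
  if (length(itx) == 0L) return(data.frame(start = numeric(), end = numeric(),
                                           n_events = integer()))
  do.call(rbind, lapply(itx, function(x) {
    data.frame(start = x$start, end = x$end, n_events = nrow(x$events))
  }))
}

# random two-male event set, <= n_max pooled events, with irregular gaps so
# bout boundaries and sub-threshold bouts both occur
random_events <- function(seed, n_max = 30) {
  set.seed(seed)
  mk <- function(id) {
    k <- sample(0:(n_max %/% 2), 1)
    if (k == 0) return(NULL)
    gaps <- sample(c(stats::runif(k, 0.1, 6), stats::runif(k, 8, 16)), k)
    durs <- stats::runif(k, 0.2, 1.5)
    onset <- cumsum(gaps + c(0, durs[-k]))
    data.frame(male_id = id, onset = onset, offset = onset + durs,
               n_chucks = sample(0:3, k, replace = TRUE),
               stringsAsFactors = FALSE)
  }
  ev <- rbind(mk("A"), mk("B"))
  if (is.null(ev) || nrow(ev) == 0) return(empty_toy_events())
  ev <- ev[order(ev$onset), , drop = FALSE]
  rownames(ev) <- NULL
  ev
}

empty_toy_events <- function() {
  data.frame(male_id = character(), onset = numeric(), offset = numeric(),
             n_chucks = integer(), stringsAsFactors = FALSE)
}

# strictly alternating A/B duet: calls of duration `dur` every `period` s
alternating_events <- function(n, period = 5, dur = 0.4, t0 = 0) {
  onset <- t0 + period * (seq_len(n) - 1)
  data.frame(male_id = rep(c("A", "B"), length.out = n),
             onset = onset, offset = onset + dur,
             n_chucks = 0L, stringsAsFactors = FALSE)
}

# wrap an event table as a single interaction (permissive thresholds)
as_interaction <- function(events, pair_id = "p1", condition = "forest") {
  itx <- segment_interactions(events, max_pause = 1e9, min_length = 1e-6,
                              pair_id = pair_id, condition = condition)
  stopifnot(length(itx) == 1L)
  itx[[1L]]
}

# pairwise interval-intersection overlap count (half-open intervals)
brute_overlap <- function(events) {
  n <- nrow(events)
  overl <- logical(n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (events$male_id[i] == events$male_id[j]) next
      if (events$onset[i] < events$offset[j] &&
          events$onset[j] < events$offset[i]) overl[i] <- TRUE
    }
  }
  c(sum(overl), n)
}

# exhaustive amplitude-call eligibility: every call of the male checked
# against the rules one by one
brute_amp_selection <- function(events, male_id, n_amp = 3, min_flank = 0.1,
                                edge = 3, loudness_col = "raw_p2p") {
  own <- which(events$male_id == male_id)
  ok <- integer()
  for (r in seq_along(own)) {
    if (r <= edge || r > length(own) - edge) next
    i <- own[r]
    clear <- TRUE
    for (j in seq_len(nrow(events))) {
      if (j == i) next
      if (!(events$offset[j] <= events$onset[i] - min_flank ||
            events$onset[j] >= events$offset[i] + min_flank)) clear <- FALSE
    }
    if (clear) ok <- c(ok, i)
  }
  ok <- ok[order(-events[[loudness_col]][ok])]
  sort(ok[seq_len(min(n_amp, length(ok)))])
}

# duet fixture: continuous calling over [0, len] with optional dyad
# silences (gaps in the pooled timeline) inserted at given positions
duet_with_silences <- function(len, silences = NULL, period = 2, dur = 0.4) {
  onset <- seq(0, len - dur, by = period)
  if (!is.null(silences)) {
    for (s in seq_len(nrow(silences))) {
      st <- silences$start[s]; en <- silences$end[s]
      onset <- onset[onset + dur <= st | onset >= en]
      # pin calls to both silence edges so the dyad silence is exactly [st, en]
      onset <- c(onset, st - dur, en)
    }
  }
  onset <- sort(unique(round(onset, 9)))
  ev <- data.frame(male_id = rep(c("A", "B"), length.out = length(onset)),
                   onset = onset, offset = onset + dur, n_chucks = 0L)
  # pin both endpoints so the interaction spans exactly [0, len]
  ev$onset[1] <- 0
  ev$offset[nrow(ev)] <- len
  as_interaction(ev)
}

duet_fix <- function(len, sil = NULL, sil2 = NULL) {
  s <- rbind(
    if (!is.null(sil)) data.frame(start = sil[1], end = sil[2]),
    if (!is.null(sil2)) data.frame(start = sil2[1], end = sil2[2]))
  duet_with_silences(len, s)
}

# acceptance band for a Monte-Carlo quantile of a discrete pmf: the
# interpolated empirical quantile at level p must fall between the exact
# inverse-CDF quantiles at p -/+ 4 binomial standard errors
mc_quantile_band <- function(pmf, p, n_sims) {
  se <- sqrt(p * (1 - p) / n_sims)
  c(pmf_quantile(pmf, max(p - 4 * se, 0)),
    pmf_quantile(pmf, min(p + 4 * se, 1)))
}
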