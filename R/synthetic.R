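#' Simulation configuration
#'
#' Bundles every tunable of the synthetic-data generator: per-male calling
#' parameters, the shared pause (dyad silence) model, and the choice model
#' linking proportional call-rate differences to female choices. All
#' randomness in the generator flows from the single `seed`; the documented
#' stream order is: pause schedule, then male "A" in full, then male "B"
#' (see [gen_call_timeline()]).
#'
#' Calling is a gamma renewal process on call onsets: successive onsets are
#' separated by gamma(`interval_shape`, mean = `mean_interval`) seconds
#' (floored so calls of one male never overlap). `interval_shape = 1` gives a
#' Poisson process, larger values increasingly regular calling. Shared quiet
#' periods — during which neither male starts a call — recur with
#' gamma-distributed gaps (mean `pause_every`) and last
#' gamma(`pause_shape`, mean = `pause_mean`) seconds, so dyad silences long
#' enough to split interactions occur with positive probability.
#'
#' When `condition != origin` (frogs tested in the unfamiliar sensory
#' environment), calling is attenuated: mean onset interval is divided by
#' `condition_rate_mismatch` (< 1 slows calling) and call amplitude shifted
#' by `condition_amp_mismatch_db` dB, emulating less intense interactions
#' under mismatched conditions.
#'
#' @param seed integer seed; fixed seed gives byte-identical output.
#' @param session_duration session length in seconds (>= 0).
#' @param condition,origin sensory treatment and population of origin,
#'   `"forest"` or `"urban"`.
#' @param mean_interval mean call onset-to-onset interval (s).
#' @param interval_shape gamma shape of the onset interval distribution.
#' @param whine_duration duration of the whine component (s).
#' @param chuck_duration added duration per chuck (s).
#' @param chuck_probs probabilities of 0, 1, 2, 3 chucks per call.
#' @param mean_amplitude mean linear peak call amplitude (full scale = 1).
#' @param amplitude_cv coefficient of variation of call amplitude
#'   (lognormal across calls).
#' @param pause_every mean gap between shared quiet periods (s).
#' @param pause_mean,pause_shape mean (s) and gamma shape of quiet-period
#'   duration.
#' @param alternation_offset start offset of male "B" relative to "A" (s),
#'   a crude stand-in for antiphonal alternation.
#' @param choice_baseline female choice probability at zero rival
#'   difference (fair coin, 0.5).
#' @param choice_slope logistic slope linking proportional call-rate
#'   difference to the probability of choosing the faster-calling male.
#' @param trials_per_stimulus phonotaxis trials generated per stimulus.
#' @param no_choice_prob probability a trial ends without a choice.
#'
#' @return an object of class `sim_config` (a validated named list).
#' @seealso [gen_call_timeline()], [gen_waveform()], [gen_choices()]
#' @export
#' @examples
#' cfg <- sim_config(seed = 7, session_duration = 120)
#' ev <- gen_call_timeline(cfg)
#' head(ev)
sim_config <- function(seed = 1L,
                       session_duration = 300,
                       condition = c("forest", "urban"),
                       origin = c("forest", "urban"),
                       mean_interval = 2,
                       interval_shape = 4,
                       whine_duration = 0.35,
                       chuck_duration = 0.03,
                       chuck_probs = c(0.25, 0.35, 0.25, 0.15),
                       mean_amplitude = 0.1,
                       amplitude_cv = 0.2,
                       pause_every = 45,
                       pause_mean = 15,
                       pause_shape = 2,
                       alternation_offset = 1,
                       choice_baseline = 0.5,
                       choice_slope = 2,
                       trials_per_stimulus = 10,
                       no_choice_prob = 0) {
  condition <- match.arg(condition)
  origin <- match.arg(origin)
  if (length(seed) != 1L || !is.finite(seed) || seed != round(seed)) {
    stop_config("seed", "must be a single integer")
  }
  if (!is.finite(session_duration) || session_duration < 0) {
    stop_config("session_duration", "must be a non-negative number of seconds")
  }
  pos <- c(
    mean_interval = mean_interval, interval_shape = interval_shape,
    whine_duration = whine_duration, chuck_duration = chuck_duration,
    mean_amplitude = mean_amplitude, pause_every = pause_every,
    pause_mean = pause_mean, pause_shape = pause_shape
  )
  for (f in names(pos)) {
    if (!is.finite(pos[[f]]) || pos[[f]] <= 0) stop_config(f, "must be > 0")
  }
  if (!is.finite(amplitude_cv) || amplitude_cv < 0) {
    stop_config("amplitude_cv", "must be >= 0")
  }
  if (length(chuck_probs) != 4L || any(!is.finite(chuck_probs)) ||
      any(chuck_probs < 0) || abs(sum(chuck_probs) - 1) > 1e-8) {
    stop_config("chuck_probs", "must be 4 non-negative probabilities summing to 1")
  }
  if (!is.finite(alternation_offset) || alternation_offset < 0) {
    stop_config("alternation_offset", "must be >= 0")
  }
  if (!is.finite(choice_baseline) || choice_baseline <= 0 || choice_baseline >= 1) {
    stop_config("choice_baseline", "must be in (0, 1)")
  }
  if (!is.finite(choice_slope)) stop_config("choice_slope", "must be finite")
  if (!is.finite(trials_per_stimulus) || trials_per_stimulus < 1 ||
      trials_per_stimulus != round(trials_per_stimulus)) {
    stop_config("trials_per_stimulus", "must be a positive integer")
  }
  if (!is.finite(no_choice_prob) || no_choice_prob < 0 || no_choice_prob > 1) {
    stop_config("no_choice_prob", "must be a probability in [0, 1]")
  }
  structure(
    list(
      seed = as.integer(seed), session_duration = session_duration,
      condition = condition, origin = origin,
      mean_interval = mean_interval, interval_shape = interval_shape,
      whine_duration = whine_duration, chuck_duration = chuck_duration,
      chuck_probs = chuck_probs, mean_amplitude = mean_amplitude,
      amplitude_cv = amplitude_cv, pause_every = pause_every,
      pause_mean = pause_mean, pause_shape = pause_shape,
      alternation_offset = alternation_offset,
      choice_baseline = choice_baseline, choice_slope = choice_slope,
      trials_per_stimulus = trials_per_stimulus,
      no_choice_prob = no_choice_prob,
      condition_rate_mismatch = 0.85,
      condition_amp_mismatch_db = -1.5
    ),
    class = "sim_config"
  )
}

#' Generate a two-male antiphonal call timeline
#'
#' Simulates the call-event tables of two rival males sharing one recording
#' session. Each male is a gamma renewal process on call onsets; both males
#' respect a shared schedule of quiet periods during which no call starts,
#' so dyad silences long enough to bound interactions (> 10 s) occur. Calls
#' carry a chuck count (0-3) and a true peak amplitude drawn lognormally.
#'
#' Stream order under the single seed: quiet-period schedule, then all calls
#' of male "A", then all calls of male "B". The caller's RNG state is left
#' untouched.
#'
#' @param config a [sim_config()].
#' @return data frame of pooled call events sorted by onset, with columns
#'   `male_id` ("A"/"B"), `onset`, `offset` (s), `n_chucks`, `amp` (true
#'   linear peak amplitude).
#' @export
gen_call_timeline <- function(config) {
  if (!inherits(config, "sim_config")) stop("config must be a sim_config", call. = FALSE)
  if (config$session_duration == 0) return(empty_events())
  withr::local_seed(config$seed)

  mismatch <- config$condition != config$origin
  mean_int <- config$mean_interval /
    (if (mismatch) config$condition_rate_mismatch else 1)
  amp_mean <- config$mean_amplitude *
    (if (mismatch) 10^(config$condition_amp_mismatch_db / 20) else 1)

  # shared quiet periods: renewal gaps ~ gamma(2, mean pause_every),
  # durations ~ gamma(pause_shape, mean pause_mean)
  pauses <- matrix(numeric(0), ncol = 2)
  t <- 0
  while (t < config$session_duration) {
    t <- t + stats::rgamma(1, shape = 2, scale = config$pause_every / 2)
    d <- stats::rgamma(1, shape = config$pause_shape,
                       scale = config$pause_mean / config$pause_shape)
    if (t < config$session_duration) pauses <- rbind(pauses, c(t, t + d))
    t <- t + d
  }

  defer_past_pauses <- function(onset) {
    if (nrow(pauses) == 0L) return(onset)
    repeat {
      hit <- which(onset > pauses[, 1] & onset < pauses[, 2])
      if (length(hit) == 0L) return(onset)
      onset <- pauses[hit[1L], 2]
    }
  }

  sdlog <- sqrt(log(1 + config$amplitude_cv^2))
  meanlog <- log(amp_mean) - sdlog^2 / 2

  gen_male <- function(id, t0) {
    onset <- numeric(0); offset <- numeric(0); nch <- integer(0); amp <- numeric(0)
    t <- t0
    prev_dur <- 0
    repeat {
      gap <- stats::rgamma(1, shape = config$interval_shape,
                           scale = mean_int / config$interval_shape)
      k <- sample.int(4L, 1L, prob = config$chuck_probs) - 1L
      dur <- config$whine_duration + k * config$chuck_duration
      a <- stats::rlnorm(1, meanlog, sdlog)
      on <- defer_past_pauses(t + max(gap, prev_dur + 0.05))
      off <- on + dur
      if (off > config$session_duration) break
      onset <- c(onset, on); offset <- c(offset, off)
      nch <- c(nch, k); amp <- c(amp, a)
      t <- on
      prev_dur <- dur
    }
    data.frame(male_id = rep(id, length(onset)), onset = onset, offset = offset,
               n_chucks = nch, amp = amp, stringsAsFactors = FALSE)
  }

  ev <- rbind(gen_male("A", 0), gen_male("B", config$alternation_offset))
  ev <- ev[order(ev$onset, ev$male_id), , drop = FALSE]
  rownames(ev) <- NULL
  ev
}

#' Synthesize a mono waveform from a call timeline
#'
#' Renders each call as a downward frequency sweep (900 to 400 Hz) for the
#' whine, followed by one short 2.6 kHz burst per chuck, at the call's peak
#' amplitude with a trapezoidal envelope. Samples are quantized to the given
#' PCM bit depth, Gaussian background noise of the requested RMS is added,
#' and the result re-quantized — emulating a mono PCM recording. The returned
#' ground-truth table holds each call's true RMS and peak-to-peak amplitude
#' measured on the clean (pre-noise) quantized samples, the reference for
#' round-trip testing of [measure_call()].
#'
#' @param events call-event table (`male_id`, `onset`, `offset`, `n_chucks`,
#'   `amp`), e.g. from [gen_call_timeline()]. All events of one male, or a
#'   pooled table for a single-channel mix.
#' @param sample_rate sampling rate in Hz (>= 8000).
#' @param duration waveform duration (s); defaults to the last offset plus
#'   0.2 s. Events extending past `duration` are an error.
#' @param background_rms linear RMS of added Gaussian background noise.
#' @param chuck_duration duration of one chuck burst (s); must match the
#'   value used when the timeline was generated.
#' @param bit_depth PCM bit depth used for quantization.
#' @param seed optional seed for the background noise draw.
#' @return list of class `sim_wave`: `wave` (numeric vector in [-1, 1]),
#'   `sample_rate`, `truth` (data frame `male_id`, `onset`, `offset`,
#'   `true_rms`, `true_p2p`), `background_rms`.
#' @export
gen_waveform <- function(events, sample_rate = 22050, duration = NULL,
                         background_rms = 0, chuck_duration = 0.03,
                         bit_depth = 16L, seed = NULL) {
  validate_events(events, require_pooled_sorted = FALSE)
  if (sample_rate < 8000) stop("sample_rate must be >= 8000 Hz", call. = FALSE)
  if (is.null(duration)) {
    duration <- if (nrow(events)) max(events$offset) + 0.2 else 1
  }
  if (nrow(events) && any(events$offset > duration + 1e-9)) {
    stop("events exceed the waveform duration", call. = FALSE)
  }
  ns <- as.integer(ceiling(duration * sample_rate))
  q <- 2^(bit_depth - 1L) - 1L
  quantize <- function(x) round(x * q) / q

  wave <- numeric(ns)
  truth <- events[, c("male_id", "onset", "offset"), drop = FALSE]
  truth$true_rms <- rep(NA_real_, nrow(truth))
  truth$true_p2p <- rep(NA_real_, nrow(truth))

  for (i in seq_len(nrow(events))) {
    on <- events$onset[i]; off <- events$offset[i]
    nch <- events$n_chucks[i] %||% 0L
    a <- events$amp[i]
    whine_dur <- (off - on) - nch * chuck_duration
    if (whine_dur <= 0) stop("event duration shorter than its chuck train", call. = FALSE)
    i1 <- floor(on * sample_rate) + 1L
    i2 <- min(ns, floor(off * sample_rate))
    tt <- (seq.int(i1, i2) - 1) / sample_rate - on
    x <- numeric(length(tt))
    # whine: linear downward sweep 900 -> 400 Hz, 10% trapezoid ramps
    w <- tt < whine_dur
    tw <- tt[w]
    env <- pmin(1, tw / (0.1 * whine_dur), (whine_dur - tw) / (0.1 * whine_dur))
    phase <- 2 * pi * (900 * tw - (500 / (2 * whine_dur)) * tw^2)
    x[w] <- a * env * sin(phase)
    # chucks: short high-frequency bursts, slightly louder than the whine
    if (nch > 0L) {
      for (ci in seq_len(nch)) {
        c0 <- whine_dur + (ci - 1L) * chuck_duration
        inw <- tt >= c0 & tt < c0 + chuck_duration
        tc <- tt[inw] - c0
        x[inw] <- 1.2 * a * sin(pi * tc / chuck_duration) *
          sin(2 * pi * 2600 * tc)
      }
    }
    x <- quantize(pmax(-1, pmin(1, x)))
    wave[i1:i2] <- wave[i1:i2] + x
    truth$true_rms[i] <- sqrt(mean(x^2))
    truth$true_p2p[i] <- max(x) - min(x)
  }

  if (background_rms > 0) {
    withr::local_seed(seed %||% 1L)
    wave <- wave + stats::rnorm(ns, 0, background_rms)
  }
  wave <- quantize(pmax(-1, pmin(1, wave)))
  structure(
    list(wave = wave, sample_rate = sample_rate, truth = truth,
         background_rms = background_rms),
    class = "sim_wave"
  )
}

#' Generate female choice trials for a set of stimuli
#'
#' Draws Bernoulli two-alternative choices whose bias toward the
#' faster-calling male is a logistic function of the stimulus's proportional
#' call-rate difference: `P(choose faster) = plogis(qlogis(baseline) +
#' slope * prop_diff)`. With `choice_slope = 0` every choice is a fair coin.
#' Trials may end without a choice with probability `no_choice_prob`.
#'
#' @param stimuli data frame with one row per stimulus: `stimulus_id`,
#'   `prop_diff` (proportional call-rate difference in [0, 1]), `faster`
#'   ("A"/"B", the male with the higher call rate), and optionally
#'   `rival_pair_id`, `male_origin`, `male_treatment` (carried through).
#' @param config a [sim_config()]; uses `choice_slope`, `choice_baseline`,
#'   `trials_per_stimulus`, `no_choice_prob`, `origin`, `condition`, `seed`.
#' @return data frame of choice trials: `female_id`, `female_origin`,
#'   `female_treatment`, `stimulus_id`, `rival_pair_id`, `male_origin`,
#'   `male_treatment`, `chosen` ("A"/"B"/"none"), `latency_s`.
#' @export
gen_choices <- function(stimuli, config) {
  if (!inherits(config, "sim_config")) stop("config must be a sim_config", call. = FALSE)
  need <- c("stimulus_id", "prop_diff", "faster")
  miss <- setdiff(need, names(stimuli))
  if (length(miss)) stop("stimuli lack column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  if (any(stimuli$prop_diff < 0 | stimuli$prop_diff > 1, na.rm = TRUE)) {
    stop("prop_diff must lie in [0, 1]", call. = FALSE)
  }
  withr::local_seed(config$seed)
  m <- config$trials_per_stimulus
  rows <- vector("list", nrow(stimuli))
  for (i in seq_len(nrow(stimuli))) {
    p_fast <- stats::plogis(stats::qlogis(config$choice_baseline) +
                              config$choice_slope * stimuli$prop_diff[i])
    fast <- stimuli$faster[i]
    slow <- if (fast == "A") "B" else "A"
    none <- stats::runif(m) < config$no_choice_prob
    pick_fast <- stats::runif(m) < p_fast
    chosen <- ifelse(none, "none", ifelse(pick_fast, fast, slow))
    rows[[i]] <- data.frame(
      female_id = sprintf("F%03d", (i - 1L) * m + seq_len(m)),
      female_origin = config$origin,
      female_treatment = config$condition,
      stimulus_id = stimuli$stimulus_id[i],
      rival_pair_id = (stimuli$rival_pair_id %||% stimuli$stimulus_id)[i],
      male_origin = (stimuli$male_origin %||% rep(NA_character_, nrow(stimuli)))[i],
      male_treatment = (stimuli$male_treatment %||% rep(NA_character_, nrow(stimuli)))[i],
      chosen = chosen,
      latency_s = round(stats::rlnorm(m, log(60), 0.4), 1),
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
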