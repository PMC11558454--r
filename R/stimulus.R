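#' Check playback-stimulus eligibility rules for one interaction
#'
#' An interaction qualifies as a phonotaxis stimulus when (1) it lasts at
#' least `min_length` s, (2) it shows no disqualifying pattern of long dyad
#' silences, and (3) it lasts at most `max_length` s (longer interactions
#' risk females deciding before hearing a complete interaction). The
#' silence rule: considering maximal dyad silences longer than
#' `max_silence` s, none may intersect the first or last `edge_window` s of
#' the interaction, and no two may begin within `repeat_window` s of each
#' other.
#'
#' @param interaction an `interaction` object with its events.
#' @param min_length,max_length length bounds (s); both boundaries
#'   inclusive (exactly 30 s and exactly 150 s are kept).
#' @param max_silence dyad-silence duration threshold (s).
#' @param edge_window length of the protected first/last windows (s).
#' @param repeat_window window within which two long silences disqualify (s).
#' @return character vector of violated rule identifiers among
#'   `"min_length"`, `"silence_rule"`, `"max_length"`; empty when eligible.
#' @seealso [filter_pairs()]
#' @export
check_stimulus <- function(interaction, min_length = 30, max_length = 150,
                           max_silence = 5, edge_window = 30,
                           repeat_window = 30) {
  violated <- character()
  if (interaction$length < min_length) violated <- c(violated, "min_length")
  if (interaction$length > max_length) violated <- c(violated, "max_length")
  sil <- dyad_silences(interaction$events, min_gap = max_silence)
  if (nrow(sil)) {
    head_w <- c(interaction$start, interaction$start + edge_window)
    tail_w <- c(interaction$end - edge_window, interaction$end)
    edge_hit <-
      any(sil$end > head_w[1L] & sil$start < head_w[2L]) ||
      any(sil$end > tail_w[1L] & sil$start < tail_w[2L])
    onsets <- sort(sil$start)
    repeat_hit <- length(onsets) >= 2L && any(diff(onsets) <= repeat_window)
    if (edge_hit || repeat_hit) violated <- c(violated, "silence_rule")
  }
  violated
}

#' Stimulus decisions for a set of interactions
#'
#' Applies [check_stimulus()] to each interaction and tabulates the result.
#'
#' @param interactions list of `interaction` objects carrying `pair_id` and
#'   `condition`.
#' @param ... thresholds forwarded to [check_stimulus()].
#' @return data frame: `pair_id`, `condition`, `eligible`, `reasons`
#'   (rule identifiers joined by `";"`, `""` when eligible).
#' @export
stimulus_decisions <- function(interactions, ...) {
  if (length(interactions) == 0L) {
    return(data.frame(pair_id = character(), condition = character(),
                      eligible = logical(), reasons = character(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, lapply(interactions, function(x) {
    v <- check_stimulus(x, ...)
    data.frame(pair_id = x$pair_id, condition = x$condition,
               eligible = length(v) == 0L,
               reasons = paste(v, collapse = ";"),
               stringsAsFactors = FALSE)
  }))
}

#' Keep rival pairs whose interactions qualify in both conditions
#'
#' A rival pair contributes stimuli only when its longest interaction in
#' each of the two sensory conditions passes every stimulus rule; a pair
#' with a decision missing for either condition is an error.
#'
#' @param decisions data frame from [stimulus_decisions()] with one row per
#'   pair x condition.
#' @param conditions the two required condition labels.
#' @return list with `eligible_pairs` (character vector of pair ids) and
#'   `manifest` (data frame of eligible stimuli: `stimulus_id` =
#'   `pair_id x condition`, `pair_id`, `condition`).
#' @export
filter_pairs <- function(decisions, conditions = c("forest", "urban")) {
  need <- c("pair_id", "condition", "eligible")
  miss <- setdiff(need, names(decisions))
  if (length(miss)) stop("decisions lack column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  pairs <- unique(decisions$pair_id)
  keep <- character()
  for (p in pairs) {
    rows <- decisions[decisions$pair_id == p, , drop = FALSE]
    have <- conditions %in% rows$condition
    if (!all(have)) {
      stop(sprintf("pair '%s' lacks a decision for condition(s): %s",
                   p, paste(conditions[!have], collapse = ", ")), call. = FALSE)
    }
    if (all(rows$eligible[rows$condition %in% conditions])) keep <- c(keep, p)
  }
  manifest <- if (length(keep)) {
    expand <- expand.grid(pair_id = keep, condition = conditions,
                          stringsAsFactors = FALSE)
    expand <- expand[order(expand$pair_id, expand$condition), , drop = FALSE]
    data.frame(stimulus_id = paste(expand$pair_id, expand$condition, sep = "_"),
               pair_id = expand$pair_id, condition = expand$condition,
               stringsAsFactors = FALSE)
  } else {
    data.frame(stimulus_id = character(), pair_id = character(),
               condition = character(), stringsAsFactors = FALSE)
  }
  rownames(manifest) <- NULL
  list(eligible_pairs = keep, manifest = manifest)
}

#' Deterministic stimulus export transform
#'
#' Prepares an eligible interaction for playback as an event-timeline
#' transform (the audio-editor steps done by hand in the original
#' workflow): call amplitudes are normalized by the channel's calibration
#' tone RMS so microphone differences cancel, and 10 s of silence is
#' appended after the interaction.
#'
#' @param interaction an `interaction` whose events carry an `amp` (or
#'   `rms`) linear amplitude column.
#' @param cal a [calibration_record()].
#' @param pad_silence silence appended after the last offset (s).
#' @return list with `events` (times rebased to interaction start,
#'   normalized `amp_norm` column) and `total_duration` (s).
#' @export
export_stimulus <- function(interaction, cal, pad_silence = 10) {
  if (!inherits(cal, "calibration_record")) {
    stop("a calibration_record is required", call. = FALSE)
  }
  ev <- interaction$events
  amp_col <- if ("amp" %in% names(ev)) "amp" else if ("rms" %in% names(ev)) "rms" else
    stop("events carry no linear amplitude column", call. = FALSE)
  ev$onset <- ev$onset - interaction$start
  ev$offset <- ev$offset - interaction$start
  ev$amp_norm <- ev[[amp_col]] / cal$tone_rms
  list(events = ev, total_duration = interaction$length + pad_silence)
}
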