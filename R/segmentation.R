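new_interaction <- function(events, pair_id = NA_character_,
                            condition = NA_character_) {
  start <- events$onset[1L]
  end <- max(events$offset)
  structure(
    list(
      pair_id = pair_id, condition = condition,
      start = start, end = end, length = end - start,
      events = events,
      n_calls = table(factor(events$male_id))
    ),
    class = "interaction"
  )
}

#' @export
print.interaction <- function(x, ...) {
  cat(sprintf(
    "<interaction%s%s> %.1f-%.1f s (length %.1f s), %d calls (%s)\n",
    if (is.na(x$pair_id)) "" else paste0(" ", x$pair_id),
    if (is.na(x$condition)) "" else paste0("/", x$condition),
    x$start, x$end, x$length, nrow(x$events),
    paste(sprintf("%s: %d", names(x$n_calls), as.integer(x$n_calls)),
          collapse = ", ")))
  invisible(x)
}

#' Segment qualifying rival interactions from a two-male call timeline
#'
#' An interaction is a maximal bout of joint calling: a run of pooled calls
#' of both males in which no dyad silence (gap from the latest offset so far
#' to the next onset, pooled across males) exceeds `max_pause`, spanning at
#' least `min_length` seconds from the onset of its first call to the offset
#' of its last call, and containing at least one call of each male. The
#' first and last calls of the bout are included. Bouts are delimited by
#' dyad silences strictly longer than `max_pause` (a pause of exactly
#' `max_pause` does not end a bout); the both-males and minimum-length rules
#' filter bouts, they do not trim them.
#'
#' @param events pooled call-event table of the two males, sorted by onset
#'   (see [validate_events()]); unsorted input is an error.
#' @param max_pause longest dyad silence allowed inside an interaction (s).
#' @param min_length minimum interaction span (s).
#' @param pair_id,condition identifiers attached to returned interactions.
#' @return list of `interaction` objects, disjoint and in time order
#'   (possibly empty).
#' @seealso [select_longest()], [dyad_silences()]
#' @export
#' @examples
#' ev <- data.frame(
#'   male_id = rep(c("A", "B"), 6),
#'   onset = seq(0, 55, by = 5), offset = seq(0, 55, by = 5) + 0.4,
#'   n_chucks = 0L)
#' segment_interactions(ev)
segment_interactions <- function(events, max_pause = 10, min_length = 20,
                                 pair_id = NA_character_,
                                 condition = NA_character_) {
  if (!is.finite(max_pause) || max_pause <= 0) stop("max_pause must be > 0", call. = FALSE)
  if (!is.finite(min_length) || min_length <= 0) stop("min_length must be > 0", call. = FALSE)
  validate_events(events)
  n <- nrow(events)
  if (n == 0L) return(list())
  cm_off <- cummax(events$offset)
  gap_before <- c(Inf, events$onset[-1L] - cm_off[-n])
  bout_id <- cumsum(gap_before > max_pause)
  out <- list()
  for (idx in split(seq_len(n), bout_id)) {
    sub <- events[idx, , drop = FALSE]
    rownames(sub) <- NULL
    span <- max(sub$offset) - sub$onset[1L]
    if (length(unique(sub$male_id)) >= 2L && span >= min_length) {
      out[[length(out) + 1L]] <- new_interaction(sub, pair_id, condition)
    }
  }
  out
}

#' Select the longest interaction after an exclusion window
#'
#' Returns the longest interaction starting at or after
#' `session_start + exclusion` — by default discarding the first 2 min in
#' which the pair could interact, to minimize carry-over from previous
#' interactions. Ties are broken in favour of the earlier start.
#'
#' @param interactions list of `interaction` objects from one session.
#' @param session_start moment the pair could first interact (s); defaults
#'   to recording start.
#' @param exclusion exclusion window length (s).
#' @return the selected `interaction`, or `NULL` if none qualifies.
#' @export
select_longest <- function(interactions, session_start = 0, exclusion = 120) {
  if (length(interactions) == 0L) return(NULL)
  starts <- vapply(interactions, `[[`, numeric(1), "start")
  lens <- vapply(interactions, `[[`, numeric(1), "length")
  ok <- which(starts >= session_start + exclusion)
  if (length(ok) == 0L) return(NULL)
  best <- ok[order(-lens[ok], starts[ok])][1L]
  interactions[[best]]
}

#' Apply the few-calls / low-amplitude rival-pair exclusion
#'
#' A rival pair is excluded from analysis when either of its two longest
#' interactions (one per sensory condition) has very few calls or low
#' whine amplitude. "Few" is fewer than `min_calls` calls in total over both
#' males of the interaction; "low amplitude" is a mean measured whine RMS
#' below `min_rms_db` dB. Both thresholds are exclusive, so an interaction
#' with exactly 8 calls and exactly 60.0 dB is kept.
#'
#' @param interaction_a,interaction_b the pair's longest interaction in each
#'   of the two sensory conditions. Their event tables must carry a
#'   `rms_db` column (calibrated whine RMS; `NA` for unmeasured calls).
#' @param min_calls exclusion threshold on the pair-total call count.
#' @param min_rms_db exclusion threshold on mean whine RMS (dB).
#' @return list with `keep` (logical) and `reasons` (character vector among
#'   `"min_calls"`, `"min_rms"`; empty when kept).
#' @export
exclude_pair <- function(interaction_a, interaction_b,
                         min_calls = 8, min_rms_db = 60) {
  reasons <- character()
  for (itx in list(interaction_a, interaction_b)) {
    if (!inherits(itx, "interaction")) stop("interactions required", call. = FALSE)
    ev <- itx$events
    if (!"rms_db" %in% names(ev) || all(is.na(ev$rms_db))) {
      stop("amplitude data (rms_db) required for pair exclusion", call. = FALSE)
    }
    if (nrow(ev) < min_calls) reasons <- c(reasons, "min_calls")
    if (mean(ev$rms_db, na.rm = TRUE) < min_rms_db) reasons <- c(reasons, "min_rms")
  }
  reasons <- unique(reasons)
  list(keep = length(reasons) == 0L, reasons = reasons)
}

#' Dyad silences in a call timeline
#'
#' Maximal intervals during which neither male is calling, i.e. gaps between
#' the running maximum offset and the next onset in the pooled timeline,
#' longer than `min_gap`.
#'
#' @param events pooled call-event table (sorted internally).
#' @param min_gap report only silences strictly longer than this (s).
#' @return data frame with `start`, `end`, `duration` (s).
#' @export
dyad_silences <- function(events, min_gap = 5) {
  validate_events(events, require_pooled_sorted = FALSE)
  if (nrow(events) < 2L) {
    return(data.frame(start = numeric(), end = numeric(), duration = numeric()))
  }
  ev <- events[order(events$onset), , drop = FALSE]
  n <- nrow(ev)
  cm_off <- cummax(ev$offset)
  gap <- ev$onset[-1L] - cm_off[-n]
  keep <- which(gap > min_gap)
  data.frame(
    start = cm_off[keep], end = ev$onset[keep + 1L],
    duration = gap[keep]
  )
}

#' Summarize a list of interactions as a table
#'
#' @param interactions list of `interaction` objects.
#' @return data frame with one row per interaction: `pair_id`, `condition`,
#'   `start_s`, `end_s`, `length_s`, and per-male call counts
#'   `n_calls_A`, `n_calls_B`.
#' @export
interactions_table <- function(interactions) {
  if (length(interactions) == 0L) {
    return(data.frame(
      pair_id = character(), condition = character(), start_s = numeric(),
      end_s = numeric(), length_s = numeric(),
      n_calls_A = integer(), n_calls_B = integer()))
  }
  do.call(rbind, lapply(interactions, function(x) {
    ids <- sort(unique(x$events$male_id))
    data.frame(
      pair_id = x$pair_id, condition = x$condition,
      start_s = x$start, end_s = x$end, length_s = x$length,
      n_calls_A = sum(x$events$male_id == ids[1L]),
      n_calls_B = if (length(ids) > 1L) sum(x$events$male_id == ids[2L]) else 0L,
      stringsAsFactors = FALSE)
  }))
}
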