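# internal helpers shared across modules

`%||%` <- function(x, y) if (is.null(x)) y else x

stop_config <- function(field, msg) {
  stop(sprintf("invalid configuration field '%s': %s", field, msg), call. = FALSE)
}

#' Validate a call-event table
#'
#' Checks the event-table contract used throughout the package: required
#' columns `male_id`, `onset`, `offset` (seconds), optional `n_chucks` and
#' amplitude columns; `offset > onset` for every call; calls of one male
#' non-overlapping and sorted by onset.
#'
#' @param events data frame of call events.
#' @param require_pooled_sorted error if the pooled table is not sorted by
#'   onset (the contract segmentation relies on).
#' @return `events`, invisibly.
#' @export
validate_events <- function(events, require_pooled_sorted = TRUE) {
  if (!is.data.frame(events)) stop("events must be a data frame", call. = FALSE)
  need <- c("male_id", "onset", "offset")
  miss <- setdiff(need, names(events))
  if (length(miss)) {
    stop("events table lacks column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  }
  if (nrow(events) == 0L) return(invisible(events))
  if (any(!is.finite(events$onset)) || any(!is.finite(events$offset))) {
    stop("event onsets/offsets must be finite", call. = FALSE)
  }
  if (any(events$offset <= events$onset)) {
    stop("every call must satisfy offset > onset", call. = FALSE)
  }
  if (require_pooled_sorted && is.unsorted(events$onset)) {
    stop("events must be sorted by onset", call. = FALSE)
  }
  for (id in unique(events$male_id)) {
    own <- events[events$male_id == id, , drop = FALSE]
    if (is.unsorted(own$onset)) {
      stop(sprintf("calls of male '%s' are not sorted by onset", id), call. = FALSE)
    }
    if (nrow(own) > 1L && any(own$onset[-1L] < own$offset[-nrow(own)])) {
      stop(sprintf("calls of male '%s' overlap each other", id), call. = FALSE)
    }
  }
  invisible(events)
}

# empty event table with the standard columns
empty_events <- function(amp = TRUE) {
  out <- data.frame(
    male_id = character(), onset = numeric(), offset = numeric(),
    n_chucks = integer(), stringsAsFactors = FALSE
  )
  if (amp) out$amp <- numeric()
  out
}
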