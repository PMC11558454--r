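#' Proportional (Weber-scaled) rival difference
#'
#' The absolute difference between two rivals' trait values divided by the
#' larger of the two — the proportional difference presumed relevant to
#' perceptual discrimination (Weber's law). Defined as 0 when both values
#' are 0.
#'
#' @param a,b non-negative trait values of the two rivals (vectorized).
#' @return proportional difference in [0, 1].
#' @export
#' @examples
#' proportional_difference(10, 5)  # 0.5
proportional_difference <- function(a, b) {
  m <- pmax(a, b)
  out <- ifelse(m > 0, abs(a - b) / m, 0)
  as.numeric(out)
}

#' Count overlapping calls in an interaction
#'
#' A call counts as overlapping when its half-open interval
#' `[onset, offset)` intersects any call interval of the other male;
#' touching endpoints do not overlap. The count is the response used for
#' binomial overlap-rate models (overlapping vs. non-overlapping calls).
#'
#' @param interaction an `interaction` object.
#' @return named vector `c(n_overlapping, n_total)` over both males' calls.
#' @export
overlap_rate <- function(interaction) {
  ev <- interaction$events
  n <- nrow(ev)
  overl <- logical(n)
  for (i in seq_len(n)) {
    other <- ev[ev$male_id != ev$male_id[i], , drop = FALSE]
    overl[i] <- any(ev$onset[i] < other$offset & other$onset < ev$offset[i])
  }
  c(n_overlapping = sum(overl), n_total = n)
}

# eligibility of each call of `male_id` for amplitude measurement:
# not among the male's first or last `edge_exclude` calls, no call of either
# male within `min_flank` s before the onset or after the offset (which also
# rules out overlap with the rival)
amplitude_eligible <- function(events, male_id, min_flank = 0.1,
                               edge_exclude = 3L) {
  own_idx <- which(events$male_id == male_id)
  k <- length(own_idx)
  elig <- rep(FALSE, k)
  pos_ok <- seq_len(k) > edge_exclude & seq_len(k) <= k - edge_exclude
  for (j in which(pos_ok)) {
    i <- own_idx[j]
    others <- events[-i, , drop = FALSE]
    clear <- all(others$offset <= events$onset[i] - min_flank |
                   others$onset >= events$offset[i] + min_flank)
    elig[j] <- clear
  }
  own_idx[elig]
}

#' Per-male calling metrics within an interaction
#'
#' Computes, for one male of an interaction: call rate (calls/min over the
#' interaction length), call complexity (mean chucks/call), and whine
#' amplitude as the mean over up to `n_amp_calls` selected calls. Amplitude
#' calls are chosen from the loudest calls (ranked by the raw peak-to-peak
#' column `loudness_col`, descending) that are non-overlapping, have at
#' least `min_flank` s of silence of both males before and after, and are
#' not among that male's first or last `edge_exclude` calls of the
#' interaction.
#'
#' Amplitude columns recognized on the event table: `loudness_col` for
#' ranking, and any of `rms`, `p2p` (corrected linear), `rms_db`, `p2p_db`
#' for the reported means. When no call is eligible (or no loudness column
#' is present) the amplitude fields are `NA` and `has_amplitude` is
#' `FALSE`.
#'
#' @param interaction an `interaction` object.
#' @param male_id which male.
#' @param n_amp_calls maximum number of calls used for amplitude (3).
#' @param min_flank required flanking silence (s).
#' @param edge_exclude number of first/last calls never used (3).
#' @param loudness_col event column used to rank loudness.
#' @return list of class `male_metrics`: `male_id`, `n_calls`, `call_rate`
#'   (calls/min), `complexity` (chucks/call), `whine_rms`, `whine_p2p`
#'   (linear), `rms_db`, `p2p_db`, `amp_call_idx` (row indices into the
#'   interaction's event table), `has_amplitude`.
#' @export
male_metrics <- function(interaction, male_id, n_amp_calls = 3L,
                         min_flank = 0.1, edge_exclude = 3L,
                         loudness_col = "raw_p2p") {
  ev <- interaction$events
  own <- which(ev$male_id == male_id)
  if (length(own) == 0L) {
    stop(sprintf("male '%s' has no call in the interaction", male_id), call. = FALSE)
  }
  res <- list(
    male_id = male_id,
    n_calls = length(own),
    call_rate = 60 * length(own) / interaction$length,
    complexity = mean(ev$n_chucks[own]),
    whine_rms = NA_real_, whine_p2p = NA_real_,
    rms_db = NA_real_, p2p_db = NA_real_,
    amp_call_idx = integer(), has_amplitude = FALSE
  )
  if (loudness_col %in% names(ev)) {
    cand <- amplitude_eligible(ev, male_id, min_flank, edge_exclude)
    cand <- cand[!is.na(ev[[loudness_col]][cand])]
    if (length(cand)) {
      sel <- cand[order(-ev[[loudness_col]][cand])]
      sel <- sel[seq_len(min(n_amp_calls, length(sel)))]
      res$amp_call_idx <- sort(sel)
      res$has_amplitude <- TRUE
      amp_cols <- c(whine_rms = "rms", whine_p2p = "p2p",
                    rms_db = "rms_db", p2p_db = "p2p_db")
      for (nm in names(amp_cols)) {
        col <- amp_cols[[nm]]
        if (col %in% names(ev)) res[[nm]] <- mean(ev[[col]][sel], na.rm = TRUE)
      }
    }
  }
  structure(res, class = "male_metrics")
}

#' Pair-level metrics: means and rival differences
#'
#' For each calling trait (call rate, complexity, whine RMS and P2P
#' amplitude), computes the mean of the two rivals, their absolute
#' difference, and their proportional difference (absolute difference
#' divided by the higher value, [proportional_difference()]). Also reports
#' the interaction length, total call count, and overlap count.
#'
#' @param interaction the `interaction` the metrics were computed on.
#' @param metrics_a,metrics_b [male_metrics()] of the two rivals.
#' @return one-row data frame with `pair_id`, `condition`,
#'   `interaction_length`, `n_calls`, `n_overlapping`, and for each trait
#'   `<trait>_mean`, `<trait>_absdiff`, `<trait>_propdiff`.
#' @export
pair_metrics <- function(interaction, metrics_a, metrics_b) {
  ov <- overlap_rate(interaction)
  out <- data.frame(
    pair_id = interaction$pair_id, condition = interaction$condition,
    interaction_length = interaction$length,
    n_calls = unname(ov["n_total"]),
    n_overlapping = unname(ov["n_overlapping"]),
    stringsAsFactors = FALSE
  )
  for (tr in c("call_rate", "complexity", "whine_rms", "whine_p2p")) {
    a <- metrics_a[[tr]]; b <- metrics_b[[tr]]
    out[[paste0(tr, "_mean")]] <- (a + b) / 2
    out[[paste0(tr, "_absdiff")]] <- abs(a - b)
    out[[paste0(tr, "_propdiff")]] <-
      if (is.na(a) || is.na(b)) NA_real_ else proportional_difference(a, b)
  }
  out
}

#' Model-ready transforms of pair metrics
#'
#' Appends (never replaces) the variance-stabilizing transforms used for
#' Gaussian models on these metrics: log interaction length and square-root
#' absolute differences in whine RMS, call rate, and complexity, plus
#' square-root proportional differences in call rate and complexity.
#'
#' @param metrics data frame of [pair_metrics()] rows.
#' @return `metrics` with `log_interaction_length` and `sqrt_*` columns
#'   added where the source columns exist.
#' @export
add_model_transforms <- function(metrics) {
  if ("interaction_length" %in% names(metrics)) {
    metrics$log_interaction_length <- log(metrics$interaction_length)
  }
  for (col in c("whine_rms_absdiff", "call_rate_absdiff", "complexity_absdiff",
                "call_rate_propdiff", "complexity_propdiff")) {
    if (col %in% names(metrics)) metrics[[paste0("sqrt_", col)]] <- sqrt(metrics[[col]])
  }
  metrics
}
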