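#' Equal-choice point of a cell of n choices
#'
#' For an even number of choices the equal-choice point is `n/2`; for an odd
#' number it is set to the first possible number of choices above 50%,
#' `(n + 1) / 2` — so 2 of 3 choices (67%) counts as no deviation from
#' equality. Both cases equal `ceiling(n / 2)`.
#'
#' @param n number of choices (vectorized).
#' @return equal-choice point(s).
#' @export
equal_choice_point <- function(n) ceiling(n / 2)

#' Preference strength of a collated choice cell
#'
#' Preference strength in [0, 1] measures the deviation of a set of
#' two-alternative choices from an equal split:
#' `ps = (k - e) / (n - e)` where `n` is the number of choices, `k` the
#' number for the majority rival, and `e` the equal-choice point
#' ([equal_choice_point()]). 0 means equal choices for each rival (e.g. 5
#' of 10, or 2 of 3 under the odd-n rule), 1 means all choices for one
#' rival (e.g. 10 of 10). Cells with a single choice are excluded from
#' analysis, so `n >= 2` is required.
#'
#' @param n number of choices per cell (>= 2, vectorized).
#' @param k majority count per cell, `ceiling(n/2) <= k <= n`.
#' @return preference strength(s) in [0, 1].
#' @export
#' @examples
#' preference_strength(10, 10)  # 1
#' preference_strength(10, 5)   # 0
#' preference_strength(3, 2)    # 0
preference_strength <- function(n, k) {
  if (length(k) != length(n)) {
    rec <- max(length(n), length(k))
    n <- rep_len(n, rec); k <- rep_len(k, rec)
  }
  if (any(n < 2)) {
    stop("cells with fewer than 2 choices are excluded from preference analysis",
         call. = FALSE)
  }
  if (any(k > n)) stop("majority count k cannot exceed n", call. = FALSE)
  if (any(k < ceiling(n / 2))) {
    stop("k must be the majority count (k >= ceiling(n/2)); pass max(count_A, count_B)",
         call. = FALSE)
  }
  e <- equal_choice_point(n)
  (k - e) / (n - e)
}

#' Binomial response coding of a preference cell
#'
#' The response pair used for binomial preference models: successes are the
#' recorded choices deviating from equal choices (`k - e`), trials the
#' maximum possible deviation (`n - e`). The ratio reproduces the
#' preference strength exactly.
#'
#' @inheritParams preference_strength
#' @return data frame with `successes` and `trials`.
#' @export
#' @examples
#' binomial_response(10, 8)  # successes 3, trials 5; ps = 0.6
binomial_response <- function(n, k) {
  ps <- preference_strength(n, k)  # validates
  e <- equal_choice_point(n)
  data.frame(successes = k - e, trials = n - e)
}

#' Collate choice trials into preference cells
#'
#' Groups two-alternative choice trials under one of two collation schemes
#' and computes each cell's preference statistics. `"per_stimulus"` collates
#' per female origin and female treatment for each stimulus (used for
#' direct-effect analyses); `"per_pair"` collates per male sensory
#' treatment for each rival pair (indirect effects). Trials scored
#' `chosen = "none"` never enter cells but are counted; cells containing
#' only one choice are excluded from the cell table and listed separately.
#'
#' @param trials data frame of choice trials with columns `chosen`
#'   ("A"/"B"/"none") and the grouping columns of the chosen scheme
#'   (`stimulus_id`, `female_origin`, `female_treatment` or
#'   `rival_pair_id`, `male_treatment`).
#' @param scheme collation scheme.
#' @return list with `cells` (grouping columns plus `n`, `k`, `e`,
#'   `deviation`, `max_deviation`, `ps`), `exclusions` (single-choice
#'   cells), and `n_no_choice`.
#' @export
collate_choices <- function(trials, scheme = c("per_stimulus", "per_pair")) {
  scheme <- match.arg(scheme)
  key <- switch(scheme,
    per_stimulus = c("stimulus_id", "female_origin", "female_treatment"),
    per_pair = c("rival_pair_id", "male_treatment"))
  miss <- setdiff(c(key, "chosen"), names(trials))
  if (length(miss)) stop("trials lack column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  bad <- setdiff(unique(trials$chosen), c("A", "B", "none"))
  if (length(bad)) stop("chosen must be 'A', 'B' or 'none'", call. = FALSE)

  chose <- trials[trials$chosen %in% c("A", "B"), , drop = FALSE]
  n_no_choice <- sum(trials$chosen == "none")
  if (nrow(chose) == 0L) {
    empty <- cbind(
      stats::setNames(as.data.frame(replicate(length(key), character(),
                                              simplify = FALSE)), key),
      data.frame(n = integer(), k = integer(), e = numeric(),
                 deviation = numeric(), max_deviation = numeric(),
                 ps = numeric()))
    return(list(cells = empty, exclusions = empty, n_no_choice = n_no_choice))
  }

  grp <- interaction(chose[key], drop = TRUE, sep = "\r")
  cells <- do.call(rbind, lapply(split(chose, grp), function(d) {
    nA <- sum(d$chosen == "A"); nB <- sum(d$chosen == "B")
    out <- d[1L, key, drop = FALSE]
    out$n <- nA + nB
    out$k <- max(nA, nB)
    out
  }))
  rownames(cells) <- NULL
  cells <- cells[do.call(order, cells[key]), , drop = FALSE]
  cells$e <- equal_choice_point(cells$n)
  cells$deviation <- cells$k - cells$e
  cells$max_deviation <- cells$n - cells$e
  one <- cells$n < 2L
  cells$ps <- NA_real_
  if (any(!one)) cells$ps[!one] <- preference_strength(cells$n[!one], cells$k[!one])
  exclusions <- cells[one, , drop = FALSE]
  cells <- cells[!one, , drop = FALSE]
  rownames(cells) <- rownames(exclusions) <- NULL
  list(cells = cells, exclusions = exclusions, n_no_choice = n_no_choice)
}

#' Mean preference strength across cells
#'
#' Arithmetic mean of cell preference strengths, either unweighted or
#' weighted by the number of choices per cell.
#'
#' @param cells cell table from [collate_choices()] (needs `ps` and, for
#'   weighting, `n`).
#' @param weighting `"unweighted"` or `"by_n"`.
#' @return mean preference strength.
#' @export
mean_preference <- function(cells, weighting = c("unweighted", "by_n")) {
  weighting <- match.arg(weighting)
  if (!is.data.frame(cells) || nrow(cells) == 0L) {
    stop("at least one preference cell is required", call. = FALSE)
  }
  if (weighting == "unweighted") mean(cells$ps)
  else stats::weighted.mean(cells$ps, cells$n)
}
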