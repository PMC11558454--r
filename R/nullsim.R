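# pmf of the preference strength of a single cell of n fair-coin choices:
# X ~ Binomial(n, 1/2), majority k = max(X, n - X), ps = (k - e)/(n - e)
cell_ps_pmf <- function(n) {
  if (n < 2) stop("cells need n >= 2", call. = FALSE)
  x <- 0:n
  p <- stats::dbinom(x, n, 0.5)
  k <- pmax(x, n - x)
  e <- equal_choice_point(n)
  ps <- (k - e) / (n - e)
  agg <- tapply(p, factor(round(ps, 12)), sum)
  list(x = as.numeric(names(agg)), p = as.numeric(agg))
}

#' Exact random-choice null distribution of mean preference strength
#'
#' Enumerates, exactly, the distribution of the (weighted) mean preference
#' strength across cells when every choice is an independent fair coin,
#' conditioned on the observed cell sizes. Each cell's preference strength
#' has `floor(n/2) + 1` support points under Binomial(n, 1/2) majorities;
#' the cell distributions are convolved into the distribution of the mean.
#' Serves as the analytic oracle for [simulate_null()] and provides exact
#' tail probabilities in [compare_observed()].
#'
#' @param cell_sizes integer vector of choices per cell (all >= 2).
#' @param weighting `"unweighted"` or `"by_n"` mean across cells.
#' @param max_support refuse (with an error) configurations whose running
#'   support would exceed this many points; fall back to Monte-Carlo
#'   ([simulate_null()]) for such cases.
#' @return object of class `ps_pmf`: list with sorted support `x`,
#'   probabilities `p`, `cell_sizes`, `weighting`.
#' @export
#' @examples
#' exact_null(2)           # ps 0 or 1, each 1/2
#' pmf_mean(exact_null(10))  # 0.24609375
exact_null <- function(cell_sizes, weighting = c("unweighted", "by_n"),
                       max_support = 1e6) {
  weighting <- match.arg(weighting)
  if (length(cell_sizes) == 0L) stop("cell_sizes must be non-empty", call. = FALSE)
  if (any(cell_sizes < 2)) stop("all cell sizes must be >= 2", call. = FALSE)
  m <- length(cell_sizes)
  w <- if (weighting == "unweighted") rep(1 / m, m) else cell_sizes / sum(cell_sizes)
  x <- 0; p <- 1
  for (j in seq_len(m)) {
    cj <- cell_ps_pmf(cell_sizes[j])
    xs <- outer(x, w[j] * cj$x, `+`)
    ps <- outer(p, cj$p, `*`)
    key <- factor(round(as.numeric(xs), 12))
    p <- as.numeric(tapply(as.numeric(ps), key, sum))
    x <- as.numeric(levels(key))
    if (length(x) > max_support) {
      stop("exact enumeration support too large; use simulate_null()", call. = FALSE)
    }
  }
  ord <- order(x)
  structure(list(x = x[ord], p = p[ord], cell_sizes = cell_sizes,
                 weighting = weighting),
            class = "ps_pmf")
}

#' Moments and quantiles of an exact null distribution
#'
#' `pmf_mean()` is the exact expectation; `pmf_quantile()` the inverse CDF
#' (smallest support point whose cumulative probability reaches `probs`);
#' `pmf_tail_prob()` the upper tail `P(X >= q)`.
#'
#' @param pmf a `ps_pmf` from [exact_null()].
#' @param probs,q probabilities / quantile point.
#' @name pmf-summaries
#' @export
pmf_mean <- function(pmf) sum(pmf$x * pmf$p)

#' @rdname pmf-summaries
#' @export
pmf_quantile <- function(pmf, probs) {
  cdf <- cumsum(pmf$p)
  vapply(probs, function(pr) {
    pmf$x[which(cdf >= pr - 1e-12)[1L]]
  }, numeric(1))
}

#' @rdname pmf-summaries
#' @export
pmf_tail_prob <- function(pmf, q) sum(pmf$p[pmf$x >= q - 1e-12])

#' Monte-Carlo random-choice null of mean preference strength
#'
#' Simulates the reference distribution of the mean preference strength
#' under random (fair coin) choices, conditioned on the observed cell
#' sizes. Each replicate draws every cell's majority count from
#' Binomial(n, 1/2), computes the cell preference strengths, and averages
#' them (unweighted or weighted by n). The 95% interval is the empirical
#' 2.5th and 97.5th percentile with linear interpolation
#' (`quantile(type = 7)`). Replicates are drawn cell by cell (all
#' replicates of cell 1, then cell 2, ...) from the single seed, so a fixed
#' seed gives byte-identical output.
#'
#' @param cell_sizes integer vector of choices per cell (all >= 2).
#' @param n_sims number of simulations (1000 by default).
#' @param seed optional seed; the caller's RNG state is preserved.
#' @param weighting `"unweighted"` or `"by_n"`.
#' @return object of class `null_sim`: `means` (simulated mean ps),
#'   `ci_low`, `ci_high`, `n_sims`, `seed`, `cell_sizes`, `weighting`.
#' @export
simulate_null <- function(cell_sizes, n_sims = 1000, seed = NULL,
                          weighting = c("unweighted", "by_n")) {
  weighting <- match.arg(weighting)
  if (length(cell_sizes) == 0L) stop("cell_sizes must be non-empty", call. = FALSE)
  if (any(cell_sizes < 2)) stop("all cell sizes must be >= 2", call. = FALSE)
  if (!is.null(seed)) withr::local_seed(seed)
  m <- length(cell_sizes)
  ps <- matrix(0, nrow = n_sims, ncol = m)
  for (j in seq_len(m)) {
    nj <- cell_sizes[j]
    xj <- stats::rbinom(n_sims, nj, 0.5)
    kj <- pmax(xj, nj - xj)
    ps[, j] <- (kj - equal_choice_point(nj)) / (nj - equal_choice_point(nj))
  }
  w <- if (weighting == "unweighted") rep(1 / m, m) else cell_sizes / sum(cell_sizes)
  means <- as.numeric(ps %*% w)
  ci <- unname(stats::quantile(means, c(0.025, 0.975), type = 7))
  structure(
    list(means = means, ci_low = ci[1L], ci_high = ci[2L], n_sims = n_sims,
         seed = seed, cell_sizes = cell_sizes, weighting = weighting),
    class = "null_sim"
  )
}

#' Compare an observed mean preference strength against the null
#'
#' Flags whether the observed mean preference strength exceeds the upper
#' bound of the random-choice 95% interval. When the exact enumeration is
#' supplied it must match the simulation's cell sizes and weighting, and an
#' exact upper-tail probability is reported alongside.
#'
#' @param observed observed mean preference strength.
#' @param null a `null_sim` from [simulate_null()].
#' @param exact optional `ps_pmf` from [exact_null()] on the same cells.
#' @return object of class `null_result`: `observed_mean_ps`, `ci_low`,
#'   `ci_high`, `exceeds_null`, `exact_tail_p` (or `NA`), `n_sims`,
#'   `seed`, `cell_sizes`, `weighting`.
#' @export
compare_observed <- function(observed, null, exact = NULL) {
  if (!inherits(null, "null_sim")) stop("null must come from simulate_null()", call. = FALSE)
  if (!is.finite(observed) || observed < 0 || observed > 1) {
    stop("observed mean preference strength must lie in [0, 1]", call. = FALSE)
  }
  tail_p <- NA_real_
  if (!is.null(exact)) {
    if (!inherits(exact, "ps_pmf")) stop("exact must come from exact_null()", call. = FALSE)
    if (!identical(as.integer(exact$cell_sizes), as.integer(null$cell_sizes)) ||
        !identical(exact$weighting, null$weighting)) {
      stop("exact null does not match the simulation's cell sizes/weighting",
           call. = FALSE)
    }
    tail_p <- pmf_tail_prob(exact, observed)
  }
  structure(
    list(observed_mean_ps = observed, ci_low = null$ci_low,
         ci_high = null$ci_high, exceeds_null = observed > null$ci_high,
         exact_tail_p = tail_p, n_sims = null$n_sims, seed = null$seed,
         cell_sizes = null$cell_sizes, weighting = null$weighting),
    class = "null_result"
  )
}

#' @export
print.null_result <- function(x, ...) {
  cat(sprintf(
    "Mean preference strength %.3f vs random choices [%.2f; %.2f] (%d sims, %d cells)\n",
    x$observed_mean_ps, x$ci_low, x$ci_high, x$n_sims, length(x$cell_sizes)))
  cat(if (x$exceeds_null) "  -> above the random-choice 95% interval\n"
      else "  -> not above the random-choice 95% interval\n")
  if (!is.na(x$exact_tail_p)) {
    cat(sprintf("  exact P(mean ps >= observed | random) = %.4g\n", x$exact_tail_p))
  }
  invisible(x)
}
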