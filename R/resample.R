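#' Monte Carlo null distribution of summed per-cell population counts
#'
#' Tests whether invasion localities sit in unusually populous cells: the
#' observed statistic is the sum of population counts over the invaded
#' cells; the null distribution is built by repeatedly drawing the same
#' number of distinct masked cells uniformly at random and summing their
#' counts. The empirical p-value is the fraction of draws whose sum
#' strictly exceeds the observed sum (ties do not count against the
#' observation, and no small-sample correction is applied).
#'
#' @param g A [population_grid].
#' @param sites Invasion sites (see [validate_sites()]); duplicated cells
#'   collapse to one site.
#' @param n_draws Number of random draws (default 10000).
#' @param seed Integer seed; required for reproducibility.
#' @param keep_null Keep the full vector of null sums (default `TRUE`;
#'   needed for histograms).
#' @return An object of class `resample_null`: list with `k`,
#'   `observed_sum`, `count_exceeding`, `p_empirical`, `n_draws`, `seed`,
#'   a five-number `null_summary` and (optionally) the full `null_sums`.
#' @export
resample_null <- function(g, sites, n_draws = 10000, seed = NULL,
                          keep_null = TRUE) {
  stopifnot(inherits(g, "population_grid"))
  sites <- validate_sites(g, sites)
  k <- nrow(sites)
  if (k < 1) abort("need at least one invasion site")
  if (n_draws < 1) abort("n_draws must be >= 1")
  counts <- g$values[g$mask]
  if (k > length(counts)) abort("more sites than masked cells")
  observed_sum <- sum(g$values[cbind(sites$row, sites$col)])
  null_sums <- with_seed(seed, {
    vapply(seq_len(n_draws),
           function(i) sum(counts[sample.int(length(counts), k)]),
           numeric(1))
  })
  count_exceeding <- sum(null_sums > observed_sum)
  structure(list(k = k, observed_sum = observed_sum,
                 count_exceeding = count_exceeding,
                 p_empirical = count_exceeding / n_draws,
                 n_draws = n_draws, seed = seed,
                 null_summary = stats::fivenum(null_sums),
                 null_sums = if (keep_null) null_sums else NULL),
            class = "resample_null")
}

#' @export
print.resample_null <- function(x, ...) {
  cat(sprintf(paste0("Resampling null of summed population counts\n",
                     "k = %d sites, observed sum = %.6g\n",
                     "%d of %d null sums exceed the observation ",
                     "(p = %.4g)\n"),
              x$k, x$observed_sum, x$count_exceeding, x$n_draws,
              x$p_empirical))
  invisible(x)
}

#' @describeIn resample_null Null sums as a tibble (`draw`, `null_sum`).
#' @param x,object A `resample_null`.
#' @param ... Unused.
#' @method tidy resample_null
#' @export
tidy.resample_null <- function(x, ...) {
  if (is.null(x$null_sums)) abort("null sums were not kept")
  tibble::tibble(draw = seq_along(x$null_sums), null_sum = x$null_sums)
}

#' @describeIn resample_null One-row summary of the test.
#' @method glance resample_null
#' @export
glance.resample_null <- function(x, ...) {
  tibble::tibble(k = x$k, observed_sum = x$observed_sum,
                 count_exceeding = x$count_exceeding,
                 p_empirical = x$p_empirical, n_draws = x$n_draws)
}

#' @describeIn resample_null Histogram of the null sums with the observed
#'   sum marked (the classic randomization-test figure). The shaded region
#'   covers the lower 95% of the null distribution.
#' @param bins Number of histogram bins (default 50).
#' @method autoplot resample_null
#' @export
autoplot.resample_null <- function(object, bins = 50, ...) {
  df <- tidy(object)
  q95 <- quantile(df$null_sum, 0.95)
  ggplot2::ggplot(df, ggplot2::aes(.data$null_sum)) +
    ggplot2::geom_histogram(
      ggplot2::aes(fill = ifelse(.data$null_sum <= q95, "lower 95%", "upper 5%")),
      bins = bins, show.legend = FALSE) +
    ggplot2::scale_fill_manual(values = c("lower 95%" = "grey70",
                                          "upper 5%" = "grey35")) +
    ggplot2::geom_vline(xintercept = object$observed_sum, colour = "red") +
    ggplot2::labs(x = "summed population count of random cell sets",
                  y = "frequency",
                  title = sprintf("observed sum %.4g, p = %.4g",
                                  object$observed_sum, object$p_empirical))
}

#' Rejection-rate curve of the randomization test under biased placement
#'
#' Validation harness for the randomization test: for each placement bias
#' `beta`, places `k` invasion sites with probability proportional to
#' `(count + 1)^beta` (see [place_invasions()]), runs [resample_null()],
#' and reports the fraction of replicates rejecting at `alpha`. `beta = 0`
#' is uniform placement, so the rejection rate estimates the test's size;
#' increasing `beta` traces its power.
#'
#' @param g A [population_grid].
#' @param k Number of sites per replicate.
#' @param betas Numeric vector of bias exponents (>= 0).
#' @param n_reps Replicates per beta.
#' @param n_draws Draws per [resample_null()] run.
#' @param seed Integer seed.
#' @param alpha Rejection level (default 0.05).
#' @return A tibble: `beta`, `n_reps`, `rejection_rate`, `mean_p`.
#' @export
power_curve <- function(g, k, betas, n_reps, n_draws = 1000, seed = NULL,
                        alpha = 0.05) {
  if (any(betas < 0)) abort("betas must be >= 0")
  if (n_reps == 0) {
    return(tibble::tibble(beta = numeric(0), n_reps = integer(0),
                          rejection_rate = numeric(0), mean_p = numeric(0)))
  }
  seeds <- matrix(derive_seeds(if (is.null(seed)) 0L else seed,
                               2 * length(betas) * n_reps),
                  nrow = 2)
  si <- 0L
  out <- lapply(seq_along(betas), function(bi) {
    ps <- vapply(seq_len(n_reps), function(r) {
      si <<- si + 1L
      sites <- place_invasions(g, k, beta = betas[bi], seed = seeds[1, si])
      resample_null(g, sites, n_draws = n_draws, seed = seeds[2, si],
                    keep_null = FALSE)$p_empirical
    }, numeric(1))
    tibble::tibble(beta = betas[bi], n_reps = n_reps,
                   rejection_rate = mean(ps <= alpha), mean_p = mean(ps))
  })
  dplyr::bind_rows(out)
}
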