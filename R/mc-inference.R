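#' Build a large simulated degree population with a known exponent
#'
#' Generates a fixed population of degrees from a discrete power law, the
#' reference object for Monte-Carlo inference about complete networks: its
#' size should greatly exceed any sample drawn from it so the central limit
#' theorem applies to the sampling distribution of the exponent estimator.
#'
#' @param alpha_pop Generating exponent.
#' @param size Population size (default 10,000).
#' @param kmin,kmax Support; `kmax` defaults to `size`.
#' @param seed Integer seed.
#' @return Integer degree vector with attribute `alpha_pop`.
#' @export
build_population <- function(alpha_pop, size = 10000, kmin = 1, kmax = size,
                             seed) {
  if (missing(seed)) stop("build_population requires an explicit seed")
  pop <- rpowerlaw(size, powerlaw_model(alpha_pop, kmin = kmin, kmax = kmax),
                   seed = seed)
  attr(pop, "alpha_pop") <- alpha_pop
  pop
}

# sample skewness and excess kurtosis (moment estimators)
moment_shape <- function(x) {
  m <- mean(x)
  s2 <- mean((x - m)^2)
  c(skewness = mean((x - m)^3) / s2^1.5,
    kurtosis = mean((x - m)^4) / s2^2 - 3)
}

#' Monte-Carlo sampling distribution of the exponent estimator
#'
#' Draws `r` samples of `sample_size` degrees from a population (with
#' replacement by default), refits each with the full maximum-likelihood /
#' minimum-degree-selection stack, and summarizes the resulting exponent
#' estimates: standard deviation, skewness, excess kurtosis and a
#' Shapiro-Wilk normality p-value. Samples on which no fit is possible
#' (e.g. a single distinct degree value) are excluded and counted, never
#' silently re-drawn.
#'
#' @param population Degree vector, e.g. from [build_population()].
#' @param sample_size Nodes per sample (e.g. the number of TFs in a genome).
#' @param r Number of replicates (>= 100 recommended; default 1000).
#' @param seed Integer seed.
#' @param replace Sample with replacement (default). `replace = FALSE` with
#'   `sample_size == length(population)` is a census: every estimate is
#'   identical and the SD is 0.
#' @param tail_floor,method Passed to [fit_power_law()].
#' @return Object of class `sampling_distribution`: list with `estimates`,
#'   `mean`, `sd`, `skewness`, `kurtosis`, `shapiro_p`, `n_excluded`,
#'   `sample_size`, `r` and `alpha_pop` (if the population carries it).
#' @export
sampling_distribution <- function(population, sample_size, r = 1000, seed,
                                  replace = TRUE, tail_floor = 10,
                                  method = "exact") {
  stopifnot(sample_size >= 2, r >= 2)
  if (missing(seed)) stop("sampling_distribution requires an explicit seed")
  set.seed(seed)
  est <- vapply(seq_len(r), function(i) {
    s <- sample(population, sample_size, replace = replace)
    f <- tryCatch(
      suppressWarnings(fit_power_law(s, tail_floor = tail_floor,
                                     method = method)),
      error = function(e) NULL)
    if (is.null(f)) NA_real_ else f$alpha
  }, numeric(1))
  ok <- est[!is.na(est)]
  if (length(ok) < 2) stop("fewer than 2 usable replicate fits")
  shape <- moment_shape(ok)
  shp <- if (stats::sd(ok) == 0) NA_real_ else
    stats::shapiro.test(if (length(ok) > 5000) sample(ok, 5000) else ok)$p.value
  structure(
    list(estimates = ok, mean = mean(ok), sd = stats::sd(ok),
         skewness = unname(shape["skewness"]),
         kurtosis = unname(shape["kurtosis"]),
         shapiro_p = shp, n_excluded = sum(is.na(est)),
         sample_size = sample_size, r = r,
         alpha_pop = attr(population, "alpha_pop")),
    class = "sampling_distribution"
  )
}

#' @export
print.sampling_distribution <- function(x, ...) {
  cat(sprintf(
    "Sampling distribution of the exponent (r = %d, sample size = %d)\n  mean = %.3f  sd = %.4f  skew = %.2f  ex.kurt = %.2f  shapiro p = %s  excluded = %d\n",
    x$r, x$sample_size, x$mean, x$sd, x$skewness, x$kurtosis,
    format.pval(x$shapiro_p), x$n_excluded))
  invisible(x)
}

#' Prediction interval for the exponent of a complete network
#'
#' Builds the interval expected to contain the exponent of the complete
#' (fully observed) network around an observed exponent, using the
#' Monte-Carlo sampling distribution computed at the genome-wide TF count:
#' either `center +/- z * SD` (normal approximation, default, z = 1.96 at
#' the 95% level) or the central `level`-mass of the replicate deviations
#' from their mean (percentile method). Both bounds are reported; `method`
#' selects which pair fills `lower`/`upper`.
#'
#' @param dist A [sampling_distribution()] at the genome TF count.
#' @param center Observed exponent the interval is anchored on.
#' @param level Coverage level in (0, 1); default 0.95.
#' @param method `"normal_sd"` (default) or `"percentile"`.
#' @return Object of class `prediction_interval`: list with `lower`,
#'   `center`, `upper`, `level`, `method`, `sd` and the alternative bounds
#'   `normal` and `percentile`.
#' @export
prediction_interval <- function(dist, center, level = 0.95,
                                method = c("normal_sd", "percentile")) {
  stopifnot(inherits(dist, "sampling_distribution"),
            level > 0, level < 1)
  method <- match.arg(method)
  z <- stats::qnorm(1 - (1 - level) / 2)
  normal <- c(center - z * dist$sd, center + z * dist$sd)
  dev <- dist$estimates - dist$mean
  qs <- stats::quantile(dev, c((1 - level) / 2, 1 - (1 - level) / 2),
                        names = FALSE, type = 7)
  pct <- c(center + qs[1], center + qs[2])
  if (dist$sd == 0) {
    warning("degenerate sampling distribution (sd = 0); interval collapses")
    normal <- pct <- c(center, center)
  }
  b <- if (method == "normal_sd") normal else pct
  structure(list(lower = b[1], center = center, upper = b[2], level = level,
                 method = method, sd = dist$sd,
                 normal = normal, percentile = pct),
            class = "prediction_interval")
}

#' @export
print.prediction_interval <- function(x, ...) {
  cat(sprintf("%d%% prediction interval (%s): {%.2f - %.2f} around %.2f (sd %.4f)\n",
              round(100 * x$level), x$method, x$lower, x$upper, x$center,
              x$sd))
  invisible(x)
}

#' Estimate the total interaction count of a complete network
#'
#' Treats the observed out-degrees as a random sample from the degree
#' population of all `n_genome_tfs` TFs in the genome, and simulates that
#' population semiparametrically: each of the N degrees is drawn from the
#' empirical below-`kmin` values with probability `(n - n_tail)/n` and from
#' the fitted power-law tail otherwise (capped at `max_degree`, e.g. the
#' genome gene count). The per-replicate sum estimates the complete
#' interaction count; mean and SD over `r` replicates are reported, and a
#' Z-test against an observed count (see [ztest_observed()]) validates the
#' scheme when N equals the observed TF count.
#'
#' @param fit A `pl_fit` of the observed out-degrees.
#' @param degrees The observed out-degrees themselves.
#' @param n_genome_tfs N, the genome-wide TF count (>= number observed).
#' @param r Replicates (default 1000).
#' @param seed Integer seed.
#' @param max_degree Cap on simulated tail degrees; biologically the number
#'   of genes in the genome.
#' @param gof_p Optional goodness-of-fit p-value of `fit`; values <= 0.1
#'   abort unless `force = TRUE`, since the estimator presumes a plausible
#'   power-law fit.
#' @param force Override the goodness-of-fit guard.
#' @return Object of class `interaction_estimate`: list with `mean_pdis`,
#'   `sd_pdis`, `n_tfs_used`, `replicates`, `observed_pdis` (sum of the
#'   observed degrees) and `ztest_p` (against the observed sum when
#'   `n_genome_tfs` equals the observed TF count, else `NA`).
#' @export
estimate_interactions <- function(fit, degrees, n_genome_tfs, r = 1000, seed,
                                  max_degree = Inf, gof_p = NULL,
                                  force = FALSE) {
  stopifnot(inherits(fit, "pl_fit"))
  if (missing(seed)) stop("estimate_interactions requires an explicit seed")
  if (!is.null(gof_p) && gof_p <= 0.1 && !force) {
    stop("power-law fit not plausible (gof_p <= 0.1); ",
         "pass force = TRUE to proceed anyway")
  }
  k <- as.integer(degrees)
  n <- length(k)
  if (n_genome_tfs < n) stop("n_genome_tfs is below the observed TF count")
  below <- k[k < fit$kmin]
  p_tail <- fit$n_tail / n
  mdl <- powerlaw_model(fit$alpha, kmin = fit$kmin,
                        kmax = if (is.finite(max_degree)) max_degree else fit$kmax)
  set.seed(seed)
  sums <- vapply(seq_len(r), function(i) {
    from_tail <- stats::runif(n_genome_tfs) < p_tail
    tot <- 0
    if (any(from_tail)) {
      tot <- tot + sum(qpowerlaw(stats::runif(sum(from_tail)), mdl))
    }
    if (any(!from_tail)) {
      tot <- tot + sum(sample(below, sum(!from_tail), replace = TRUE))
    }
    tot
  }, numeric(1))
  est <- structure(
    list(mean_pdis = mean(sums), sd_pdis = stats::sd(sums),
         n_tfs_used = n_genome_tfs, r = r, replicates = sums,
         observed_pdis = sum(k), ztest_p = NA_real_),
    class = "interaction_estimate"
  )
  if (n_genome_tfs == n) est$ztest_p <- ztest_observed(est, sum(k))
  est
}

#' @export
print.interaction_estimate <- function(x, ...) {
  cat(sprintf("Simulated interaction count (N = %d TFs, r = %d): %.0f +/- %.0f\n",
              x$n_tfs_used, x$r, x$mean_pdis, x$sd_pdis))
  if (!is.na(x$ztest_p)) {
    cat(sprintf("  Z-test vs observed %d: p = %.3f\n", x$observed_pdis,
                x$ztest_p))
  }
  invisible(x)
}

#' Two-sided Z-test of an observed interaction count against the simulation
#'
#' Computes the two-sided normal p-value for
#' \eqn{Z = (observed - mean) / SD} of an [estimate_interactions()] result.
#' A non-significant p-value means the simulation scheme reproduces the
#' observed network's interaction count.
#'
#' @param estimate An `interaction_estimate`.
#' @param observed_count The observed interaction (PDI) count.
#' @return The p-value, or `NA` with a warning when the simulation SD is 0.
#' @export
ztest_observed <- function(estimate, observed_count) {
  stopifnot(inherits(estimate, "interaction_estimate"))
  if (is.na(estimate$sd_pdis) || estimate$sd_pdis == 0) {
    warning("simulation SD is 0; Z-test undefined")
    return(NA_real_)
  }
  z <- (observed_count - estimate$mean_pdis) / estimate$sd_pdis
  2 * stats::pnorm(-abs(z))
}
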