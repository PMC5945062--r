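#' Lorenz curve of TF-target binding
#'
#' Ranks TFs by increasing out-degree and plots the cumulative proportion of
#' bound target-gene degree mass against the cumulative proportion of TFs.
#' Perfectly egalitarian binding (every TF binds the same number of targets)
#' gives the diagonal "line of equality"; hub-dominated ("capitalistic")
#' networks sag below it.
#'
#' @param degrees Positive degrees, one per TF.
#' @return Object of class `lorenz_curve`: a `data.frame` with columns
#'   `tf_fraction` and `target_share`, starting at (0, 0) and ending at
#'   (1, 1).
#' @examples
#' lorenz_curve(c(1, 1, 1, 1, 6))
#' @export
lorenz_curve <- function(degrees) {
  d <- sort(as.numeric(degrees))
  if (length(d) < 1 || sum(d) <= 0) stop("need at least one positive degree")
  n <- length(d)
  out <- data.frame(tf_fraction = c(0, seq_len(n) / n),
                    target_share = c(0, cumsum(d) / sum(d)))
  class(out) <- c("lorenz_curve", "data.frame")
  out
}

#' Share of target-gene mass bound by the top fraction of TFs
#'
#' Reads off the Lorenz curve the proportion of all TF-target interactions
#' accounted for by the top `fraction` of TFs (those with the most
#' targets): \eqn{1 - L(1 - fraction)}, with linear interpolation between
#' curve points. Under egalitarian binding the top 20% of TFs bind 20% of
#' the targets; smaller exponents push this share up.
#'
#' @param curve A [lorenz_curve()].
#' @param fraction Top fraction of TFs, in (0, 1).
#' @return The share, in \[0, 1\].
#' @export
top_share <- function(curve, fraction) {
  stopifnot(inherits(curve, "lorenz_curve"))
  if (fraction <= 0 || fraction >= 1) stop("fraction must be in (0, 1)")
  1 - stats::approx(curve$tf_fraction, curve$target_share,
                    xout = 1 - fraction, ties = "ordered")$y
}

#' Gini coefficient of a Lorenz curve
#'
#' One minus twice the trapezoidal area under the curve: 0 for perfect
#' equality, approaching 1 when a single TF holds all the degree mass.
#'
#' @param curve A [lorenz_curve()].
#' @return The coefficient, in \[0, 1\].
#' @export
gini <- function(curve) {
  stopifnot(inherits(curve, "lorenz_curve"))
  x <- curve$tf_fraction
  y <- curve$target_share
  area <- sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
  1 - 2 * area
}

#' Average Lorenz curve of simulated power-law degrees
#'
#' Draws `reps` degree sequences of size `n` from a discrete power law with
#' the given exponent and averages their Lorenz curves pointwise (all
#' replicates share the same rank grid). Larger exponents concentrate mass
#' near `kmin` and pull the curve toward the diagonal, which is the
#' "socialistic" end of the topology spectrum.
#'
#' @param alpha Power-law exponent (> 1).
#' @param n Number of TFs per replicate (>= 100).
#' @param seed Integer seed.
#' @param reps Number of averaged replicates.
#' @param kmin,kmax Support of the sampling model; `kmax` defaults to `n`,
#'   mirroring a network in which a TF cannot bind more genes than exist.
#' @return A `lorenz_curve`.
#' @export
simulated_lorenz <- function(alpha, n, seed, reps = 10, kmin = 1, kmax = n) {
  stopifnot(n >= 100, reps >= 1)
  if (missing(seed)) stop("simulated_lorenz requires an explicit seed")
  mdl <- powerlaw_model(alpha, kmin = kmin, kmax = kmax)
  set.seed(seed)
  shares <- vapply(seq_len(reps), function(i) {
    d <- sort(qpowerlaw(stats::runif(n), mdl))
    c(0, cumsum(d) / sum(d))
  }, numeric(n + 1))
  out <- data.frame(tf_fraction = c(0, seq_len(n) / n),
                    target_share = rowMeans(shares))
  class(out) <- c("lorenz_curve", "data.frame")
  out
}
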