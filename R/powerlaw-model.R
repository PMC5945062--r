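#' Discrete power-law model
#'
#' Defines the probability model \eqn{P(k) = C k^{-\alpha}} on the integer
#' support \code{\{kmin, ..., kmax\}}, where the constant \eqn{C} is the
#' reciprocal of a (generalized, possibly truncated) zeta sum so that the
#' probabilities add to one. This is the degree model underlying all
#' scale-free statistics in the package: in a gene regulatory network the
#' out-degree of a transcription factor (TF) is the number of target genes it
#' binds, and a scale-free network has out-degrees following this law.
#'
#' @param alpha Scaling exponent. Must exceed 1 when `kmax` is infinite
#'   (otherwise the distribution is not normalizable); any positive value is
#'   allowed on a finite support.
#' @param kmin Minimum degree of the support (positive integer).
#' @param kmax Maximum degree of the support; `Inf` for an unbounded tail.
#'   A biologically natural choice is the number of genes in the genome,
#'   since a TF cannot bind more genes than exist.
#' @return An object of class `powerlaw_model` with fields `alpha`, `kmin`,
#'   `kmax` and `normalizer` (the zeta sum \eqn{1/C}).
#' @examples
#' m <- powerlaw_model(2.5, kmin = 1)
#' sum(dpowerlaw(1:1000, m)) # close to 1
#' @seealso [dpowerlaw()], [rpowerlaw()], [fit_power_law()]
#' @export
powerlaw_model <- function(alpha, kmin = 1, kmax = Inf) {
  stopifnot(length(alpha) == 1L, is.finite(alpha), alpha > 0)
  kmin <- as.integer(kmin)
  stopifnot(kmin >= 1L)
  if (!is.infinite(kmax)) {
    kmax <- as.integer(kmax)
    if (kmax < kmin) stop("kmax must be >= kmin")
  }
  if (is.infinite(kmax) && alpha <= 1) {
    stop("alpha <= 1 with unbounded kmax is non-normalizable; ",
         "supply alpha > 1 or a finite kmax")
  }
  structure(
    list(alpha = alpha, kmin = kmin, kmax = kmax,
         normalizer = zeta_range(alpha, kmin, kmax)),
    class = "powerlaw_model"
  )
}

#' @export
print.powerlaw_model <- function(x, ...) {
  cat(sprintf("Discrete power law: alpha = %.4g, support {%d..%s}, C = %.6g\n",
              x$alpha, x$kmin,
              if (is.infinite(x$kmax)) "Inf" else format(x$kmax),
              1 / x$normalizer))
  invisible(x)
}

#' Density, distribution function, quantiles and sampling for the discrete
#' power law
#'
#' `dpowerlaw()` gives the probability mass function, `ppowerlaw()` the
#' cumulative distribution \eqn{P(K \le k)}, `qpowerlaw()` the smallest `k`
#' with CDF at least `p`, and `rpowerlaw()` draws random degrees by inversion
#' of the exact (zeta-normalized) CDF — not a rounded continuous
#' approximation, so samples and the maximum-likelihood estimator share the
#' same discrete family.
#'
#' @param k,q Integer degree values (values outside the support get mass 0).
#' @param p Probabilities.
#' @param n Number of degrees to draw.
#' @param model A [powerlaw_model()].
#' @param seed Integer seed; required so every stochastic step in a pipeline
#'   is reproducible.
#' @return `dpowerlaw`/`ppowerlaw` numeric vectors; `qpowerlaw`/`rpowerlaw`
#'   integer degree vectors.
#' @examples
#' m <- powerlaw_model(2, kmin = 1, kmax = 1000)
#' k <- rpowerlaw(500, m, seed = 1)
#' @export
dpowerlaw <- function(k, model) {
  stopifnot(inherits(model, "powerlaw_model"))
  out <- numeric(length(k))
  ok <- k >= model$kmin & k <= model$kmax & k == floor(k)
  out[ok] <- k[ok]^(-model$alpha) / model$normalizer
  out
}

#' @rdname dpowerlaw
#' @export
ppowerlaw <- function(q, model) {
  stopifnot(inherits(model, "powerlaw_model"))
  q <- floor(q)
  out <- numeric(length(q))
  out[q >= model$kmax] <- 1
  mid <- q >= model$kmin & q < model$kmax
  if (any(mid)) {
    if (model$alpha > 1) {
      # P(K <= q) = [zeta(a, kmin) - zeta(a, q + 1)] / Z, valid for kmax = Inf
      upper <- if (is.infinite(model$kmax)) 0 else
        hurwitz_zeta(model$alpha, model$kmax + 1)
      out[mid] <- (hurwitz_zeta(model$alpha, model$kmin) -
                     hurwitz_zeta(model$alpha, q[mid] + 1)) /
        (hurwitz_zeta(model$alpha, model$kmin) - upper)
    } else {
      pm <- cumsum(dpowerlaw(seq.int(model$kmin, model$kmax), model))
      out[mid] <- pm[q[mid] - model$kmin + 1]
    }
  }
  pmin(pmax(out, 0), 1)
}

#' @rdname dpowerlaw
#' @export
qpowerlaw <- function(p, model) {
  stopifnot(inherits(model, "powerlaw_model"), all(p >= 0 & p <= 1))
  # Precompute the CDF over an initial block; invert the zeta CDF by binary
  # search for the (rare) quantiles beyond it.
  block_max <- min(model$kmax, model$kmin + 65535)
  supp <- seq.int(model$kmin, block_max)
  cdf <- ppowerlaw(supp, model) # same pathway as the CDF, so ties invert exactly
  idx <- findInterval(p, cdf, left.open = TRUE) # smallest k with cdf >= p
  out <- model$kmin + idx
  high <- idx >= length(supp) & p > cdf[length(cdf)]
  if (any(high)) {
    out[high] <- vapply(p[high], function(pp) {
      lo <- block_max
      hi <- 2 * lo
      while (ppowerlaw(hi, model) < pp) {
        lo <- hi
        hi <- 2 * hi
        if (hi > 2^52) break
      }
      while (hi - lo > 1) {
        mid <- floor((lo + hi) / 2)
        if (ppowerlaw(mid, model) >= pp) hi <- mid else lo <- mid
      }
      hi
    }, numeric(1))
  }
  out[p == 0] <- model$kmin
  out
}

#' @rdname dpowerlaw
#' @export
rpowerlaw <- function(n, model, seed) {
  stopifnot(inherits(model, "powerlaw_model"), n >= 1)
  if (missing(seed)) stop("rpowerlaw requires an explicit seed")
  set.seed(seed)
  qpowerlaw(stats::runif(n), model)
}
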