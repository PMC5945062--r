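#' Sample a subnetwork by drawing edges from a GRN
#'
#' Mimics the experimental construction of a GRN, in which interactions
#' (edges) rather than genes (nodes) are discovered: a fixed proportion `p`
#' of edges is chosen uniformly at random without replacement, and the
#' subnetwork consists of those edges with their incident nodes. Edge
#' sampling never produces singleton nodes, and a node's chance of
#' inclusion grows linearly with its degree — the property that preserves
#' scale-freeness in subnetworks.
#'
#' @param grn Directed [igraph::igraph] graph.
#' @param p Proportion of edges to sample, in (0, 1]. The drawn count is
#'   `p * |E|` rounded half-up and must be at least 1.
#' @param seed Integer seed.
#' @param mode `"exact"` (default) draws exactly the rounded count;
#'   `"bernoulli"` keeps each edge independently with probability `p`.
#' @return The sampled subnetwork as an igraph graph (vertices without
#'   sampled edges are dropped).
#' @export
sample_edges <- function(grn, p, seed, mode = c("exact", "bernoulli")) {
  mode <- match.arg(mode)
  stopifnot(igraph::is_igraph(grn), p > 0, p <= 1)
  if (missing(seed)) stop("sample_edges requires an explicit seed")
  m <- igraph::gsize(grn)
  set.seed(seed)
  idx <- if (mode == "exact") {
    n_draw <- floor(p * m + 0.5) # round half-up
    if (n_draw < 1) stop("p * |E| rounds below 1 edge")
    if (n_draw == m) seq_len(m) else sample.int(m, n_draw)
  } else {
    which(stats::runif(m) < p)
  }
  igraph::subgraph_from_edges(grn, idx, delete.vertices = TRUE)
}

#' Exponent distributions of edge-sampled subnetworks across sizes
#'
#' For each proportion in `proportions`, draws `r` independent edge-sampled
#' subnetworks, fits the out-degree power law of each with the full
#' minimum-degree-selection stack, and optionally attaches a bootstrap
#' goodness-of-fit p-value. The long-format result supports the two
#' downstream summaries of interest: how the spread (SD) of subnetwork
#' exponents grows as the sampled fraction shrinks, and what fraction of
#' subnetworks retain a plausible power law.
#'
#' @param grn Directed [igraph::igraph] graph.
#' @param proportions Vector of edge proportions in (0, 1].
#' @param r Replicates per proportion (default 1000).
#' @param seed Integer seed.
#' @param n_boot Bootstrap replicates for the per-subnetwork GOF p-value;
#'   0 (default) skips the bootstrap and reports `NA`, which is much
#'   cheaper when only exponents are needed.
#' @param tail_floor,method Passed to [fit_power_law()].
#' @return `data.frame` with columns `proportion`, `replicate`, `alpha`,
#'   `kmin`, `gof_p`, `n_edges`, `n_nodes`; failed fits appear as `NA`
#'   rows rather than aborting the scan.
#' @seealso [summarize_subnets()], [knee_point()]
#' @export
subnet_exponents <- function(grn, proportions, r = 1000, seed, n_boot = 0,
                             tail_floor = 10, method = "exact") {
  stopifnot(all(proportions > 0), all(proportions <= 1))
  if (missing(seed)) stop("subnet_exponents requires an explicit seed")
  set.seed(seed)
  sub_seeds <- matrix(
    sample.int(.Machine$integer.max, length(proportions) * r),
    nrow = length(proportions))
  rows <- vector("list", length(proportions) * r)
  i <- 0L
  for (pi in seq_along(proportions)) {
    p <- proportions[pi]
    for (j in seq_len(r)) {
      i <- i + 1L
      sg <- sample_edges(grn, p, seed = sub_seeds[pi, j])
      deg <- degree_sequence(sg, "out")
      f <- tryCatch(
        suppressWarnings(fit_power_law(deg, tail_floor = tail_floor,
                                       method = method)),
        error = function(e) NULL)
      gof <- NA_real_
      if (!is.null(f) && n_boot > 0) {
        gof <- gof_pvalue(f, deg, n_boot = n_boot,
                          seed = sub_seeds[pi, j] %% 1000003L + 1L,
                          tail_floor = tail_floor)
      }
      rows[[i]] <- data.frame(
        proportion = p, replicate = j,
        alpha = if (is.null(f)) NA_real_ else f$alpha,
        kmin = if (is.null(f)) NA_integer_ else f$kmin,
        gof_p = gof,
        n_edges = igraph::gsize(sg), n_nodes = igraph::vcount(sg))
    }
  }
  do.call(rbind, rows)
}

#' Per-proportion summary of subnetwork exponent fits
#'
#' @param records Output of [subnet_exponents()].
#' @param gof_threshold Plausibility cutoff on the GOF p-value.
#' @return `data.frame` with one row per proportion: mean and SD of the
#'   fitted exponents, number of failed fits, and the fraction of
#'   subnetworks with `gof_p` above the threshold (`NA` when the bootstrap
#'   was skipped).
#' @export
summarize_subnets <- function(records, gof_threshold = 0.1) {
  sp <- split(records, records$proportion)
  out <- do.call(rbind, lapply(sp, function(d) {
    data.frame(
      proportion = d$proportion[1],
      mean_alpha = mean(d$alpha, na.rm = TRUE),
      sd_alpha = stats::sd(d$alpha[!is.na(d$alpha)]),
      n_failed = sum(is.na(d$alpha)),
      frac_gof_pass = if (all(is.na(d$gof_p))) NA_real_ else
        mean(d$gof_p > gof_threshold, na.rm = TRUE))
  }))
  rownames(out) <- NULL
  out[order(out$proportion), ]
}

#' Knee-point detection by two-segment line fitting
#'
#' Finds the x-value at which a curve bends: at every interior bisection
#' point a least-squares line is fitted to the points on each side, and the
#' knee is the bisection minimizing the total sum of squared errors of the
#' two fits (ties going to the smaller x). Applied here to the
#' SD-of-subnetwork-exponents versus sampled-proportion curve, it locates
#' the subnetwork size below which the scale-free exponent can no longer be
#' determined reliably.
#'
#' @param x Ordered predictor values (>= 5 points).
#' @param y Response values, same length.
#' @return List with `knee` (x-value, `NA` when the data are collinear and
#'   no knee exists), `index`, `sse` (per-bisection error profile) and
#'   `collinear`.
#' @examples
#' knee_point(1:10, c(1:5, rep(5, 5)))$knee # 5
#' @export
knee_point <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 5, !is.unsorted(x))
  n <- length(x)
  sse_line <- function(ix) {
    if (length(ix) < 2) return(0)
    r <- stats::lm.fit(cbind(1, x[ix]), y[ix])$residuals
    sum(r^2)
  }
  total <- sse_line(seq_len(n))
  scale_ref <- max(total, sum((y - mean(y))^2))
  if (total <= 1e-12 * max(scale_ref, 1)) {
    return(list(knee = NA_real_, index = NA_integer_, sse = NULL,
                collinear = TRUE))
  }
  idx <- 2:(n - 1)
  sse <- vapply(idx, function(i) {
    sse_line(seq_len(i)) + sse_line(i:n)
  }, numeric(1))
  best <- idx[which.min(sse)] # first minimum = smaller x on ties
  list(knee = x[best], index = best,
       sse = data.frame(x = x[idx], sse = sse), collinear = FALSE)
}
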