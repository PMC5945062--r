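#' Configuration for an in-silico gene regulatory network
#'
#' Bundles and validates the parameters of the synthetic GRN generator:
#' target out-degree exponent, edge (PDI) count, node (gene) count, and the
#' fraction of nodes permitted to have out-going edges — by default 5%,
#' roughly the fraction of genes encoding transcription factors in the
#' genomes this kind of analysis is applied to.
#'
#' @param target_exponent Out-degree power-law exponent the generated
#'   network should exhibit (> 1).
#' @param n_edges Number of directed edges (PDIs).
#' @param n_nodes Number of genes (nodes).
#' @param tf_fraction Fraction of nodes allowed out-going edges, in (0, 1].
#' @param seed Integer seed for the generator.
#' @return Object of class `grn_config`.
#' @export
grn_config <- function(target_exponent, n_edges, n_nodes,
                       tf_fraction = 0.05, seed) {
  stopifnot(target_exponent > 1, n_edges >= 1, n_nodes >= 2,
            tf_fraction > 0, tf_fraction <= 1)
  if (missing(seed)) stop("grn_config requires an explicit seed")
  n_tf <- max(1L, floor(tf_fraction * n_nodes))
  if (n_edges > n_tf * n_nodes) {
    stop("infeasible edge count: ", n_edges, " > ", n_tf, " TFs x ",
         n_nodes, " possible targets")
  }
  structure(list(target_exponent = target_exponent,
                 n_edges = as.integer(n_edges),
                 n_nodes = as.integer(n_nodes),
                 tf_fraction = tf_fraction, n_tf = n_tf,
                 seed = as.integer(seed)),
            class = "grn_config")
}

#' Generate an in-silico GRN with power-law out-degrees
#'
#' Static-fitness construction of a directed network: the designated TF
#' nodes receive Zipf-type out-fitness \eqn{f_j \propto j^{-1/(\alpha - 1)}}
#' and each edge draws its source TF with probability proportional to
#' fitness and its target uniformly among all nodes. Duplicate (TF, target)
#' pairs are rejected and the deficit re-drawn until the network holds
#' exactly `n_edges` distinct edges, so the out-degree sum is exact. The
#' duplicate rejection doubles as a biological ceiling: a hub TF cannot
#' accumulate more targets than there are genes, and mass rejected at
#' saturated hubs is redistributed fitness-proportionally over the
#' remaining TFs. Only the `tf_fraction` of nodes designated as TFs ever
#' gain out-going edges; the realized out-degree distribution follows a
#' power law with the configured exponent.
#'
#' @param config A [grn_config()].
#' @return Directed [igraph::igraph] graph with exactly `config$n_edges`
#'   edges and vertex attribute `is_tf` marking the out-edge-capable nodes.
#' @examples
#' g <- simulate_grn(grn_config(2, n_edges = 500, n_nodes = 400, seed = 1))
#' @export
simulate_grn <- function(config) {
  stopifnot(inherits(config, "grn_config"))
  set.seed(config$seed)
  n_tf <- config$n_tf
  alpha <- config$target_exponent
  fitness <- seq_len(n_tf)^(-1 / (alpha - 1))
  fitness <- fitness / sum(fitness)

  m <- config$n_edges
  seen <- character(0)
  src <- integer(0)
  tgt <- integer(0)
  deficit <- m
  while (deficit > 0) {
    s <- sample.int(n_tf, deficit, replace = TRUE, prob = fitness)
    t <- sample.int(config$n_nodes, deficit, replace = TRUE)
    key <- paste(s, t)
    fresh <- !(key %in% seen) & !duplicated(key)
    seen <- c(seen, key[fresh])
    src <- c(src, s[fresh])
    tgt <- c(tgt, t[fresh])
    deficit <- m - length(src)
  }
  el <- cbind(src, tgt)
  g <- igraph::graph_from_edgelist(el, directed = TRUE)
  g <- igraph::add_vertices(g, max(0L, config$n_nodes - igraph::vcount(g)))
  igraph::V(g)$name <- sprintf("g%05d", seq_len(config$n_nodes))
  igraph::V(g)$is_tf <- seq_len(config$n_nodes) <= n_tf
  g
}

#' Write a GRN as a two-column PDI fixture table
#'
#' Serializes the edge list of a GRN as the tab-separated format read by
#' [read_pdi_table()]: a `tf<TAB>target` header followed by one edge per
#' line, UTF-8. A write/read round trip reproduces the same graph.
#'
#' @param grn Directed [igraph::igraph] graph.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_pdi_table <- function(grn, path) {
  stopifnot(igraph::is_igraph(grn))
  if (igraph::gsize(grn) == 0) stop("refusing to write an empty GRN")
  el <- igraph::as_edgelist(grn, names = TRUE)
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines("tf\ttarget", con)
  writeLines(paste(el[, 1], el[, 2], sep = "\t"), con)
  invisible(path)
}
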