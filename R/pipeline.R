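#' Pipeline run configuration
#'
#' Collects everything a full analysis run needs: the input edge list,
#' organism-scale constants (genome-wide TF and gene counts, which govern
#' complete-network inference), fitting, Monte-Carlo and subnetwork-sampling
#' options, and a master seed from which every stage derives its own. The
#' configuration round-trips losslessly through JSON.
#'
#' @param edge_list Path to a PDI edge-list file (see [read_pdi_table()]).
#' @param n_tfs_genome,n_genes_genome Genome-wide TF and gene counts.
#' @param seed Master integer seed.
#' @param n_boot Bootstrap replicates for goodness-of-fit (default 1000).
#' @param tail_floor Minimum tail size during minimum-degree selection.
#' @param population_size Monte-Carlo population size (default 10,000).
#' @param r Monte-Carlo replicates (default 1000).
#' @param pi_level,pi_method Prediction-interval level and method.
#' @param proportions Edge proportions for subnetwork sampling.
#' @param subnet_r Replicates per proportion.
#' @param min_target_coverage Minimum fraction of the genome's genes that
#'   must appear as targets before complete-network inference is attempted
#'   (default 0.5). Networks below it — sparsely sampled out-degrees, as
#'   with predominantly gene-centered assays — make the observed exponent
#'   an unreliable anchor and the predict stage refuses them.
#' @param out_dir Optional output directory for written reports.
#' @return Object of class `run_config` (a validated list).
#' @export
run_config <- function(edge_list, n_tfs_genome, n_genes_genome, seed,
                       n_boot = 1000, tail_floor = 10,
                       population_size = 10000, r = 1000,
                       pi_level = 0.95, pi_method = "normal_sd",
                       proportions = c(0.02, 0.1, 0.5, 0.9),
                       subnet_r = 200, min_target_coverage = 0.5,
                       out_dir = NULL) {
  stopifnot(n_tfs_genome >= 1, n_genes_genome >= 1, pi_level > 0,
            pi_level < 1, all(proportions > 0), all(proportions <= 1),
            min_target_coverage >= 0, min_target_coverage <= 1)
  if (missing(seed)) stop("run_config requires an explicit master seed")
  cfg <- list(edge_list = edge_list,
              n_tfs_genome = as.integer(n_tfs_genome),
              n_genes_genome = as.integer(n_genes_genome),
              seed = as.integer(seed), n_boot = n_boot,
              tail_floor = tail_floor, population_size = population_size,
              r = r, pi_level = pi_level, pi_method = pi_method,
              proportions = proportions, subnet_r = subnet_r,
              min_target_coverage = min_target_coverage,
              out_dir = out_dir)
  class(cfg) <- "run_config"
  cfg
}

config_hash <- function(config) {
  f <- tempfile(fileext = ".json")
  on.exit(unlink(f))
  jsonlite::write_json(unclass(config), f, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(f))
}

# per-stage seeds derived deterministically from the master seed
stage_seeds <- function(config, n = 8) {
  set.seed(config$seed)
  sample.int(.Machine$integer.max, n)
}

write_report <- function(report, config, name) {
  if (is.null(config$out_dir)) return(invisible(NULL))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  path <- file.path(config$out_dir, paste0(name, ".json"))
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Fit stage: scale-free testing of an observed GRN
#'
#' Reads the configured edge list, assembles the GRN, fits the out-degree
#' power law (with minimum-degree selection), runs the bootstrap
#' goodness-of-fit, fits the Poisson and exponential alternatives on the
#' same tail, and performs the Vuong model-selection tests. When `out_dir`
#' is set, the report is written as JSON, stamped with the configuration
#' hash and seed.
#'
#' @param config A [run_config()].
#' @return Report list with the graph summary, the `pl_fit`, the GOF
#'   p-value, and one Vuong block per alternative.
#' @export
pipeline_fit <- function(config) {
  stopifnot(inherits(config, "run_config"))
  seeds <- stage_seeds(config)
  records <- read_pdi_table(config$edge_list)
  grn <- build_grn(records)
  deg <- degree_sequence(grn, "out")
  fit <- fit_power_law(deg, tail_floor = config$tail_floor)
  gof <- gof_pvalue(fit, deg, n_boot = config$n_boot, seed = seeds[1],
                    tail_floor = config$tail_floor)
  alts <- lapply(c("poisson", "exponential"), function(fam) {
    af <- fit_alternative(deg, fam, kmin = fit$kmin)
    vt <- vuong_test(fit, af, deg)
    list(family = fam, parameters = as.list(af$parameters),
         loglik = af$loglik, vuong_stat = vt$statistic,
         vuong_p = vt$pvalue, favored = vt$favored)
  })
  n_targets <- sum(igraph::degree(grn, mode = "in") > 0)
  report <- list(
    config_hash = config_hash(config), seed = config$seed,
    n_nodes = igraph::vcount(grn), n_edges = igraph::gsize(grn),
    n_tfs = sum(igraph::V(grn)$is_tf),
    n_targets = n_targets,
    target_coverage = n_targets / config$n_genes_genome,
    alpha = fit$alpha, kmin = fit$kmin, D = fit$ks_D, p = gof,
    n_tail = fit$n_tail, loglik = fit$loglik, alternatives = alts)
  write_report(report, config, "fit")
  c(report, list(fit = fit, grn = grn, degrees = deg))
}

#' Predict stage: complete-network exponent interval and interaction count
#'
#' Runs the Monte-Carlo machinery at the configured genome scale: builds a
#' degree population at the observed exponent, derives the sampling
#' distribution of the estimator at the genome TF count, forms the
#' prediction interval, and estimates the complete network's interaction
#' count (capped at the genome gene count), including the self-consistency
#' Z-test at the observed TF count. Networks whose targets cover less than
#' `min_target_coverage` of the genome's genes are refused: with so few
#' out-degrees sampled, the observed exponent is not a trustworthy anchor
#' for extrapolation.
#'
#' @param config A [run_config()].
#' @param fit_report Optionally, the result of [pipeline_fit()] to reuse.
#' @return Report list with interval bounds, interaction estimates, the
#'   percentage of the complete network already observed, and the maximum
#'   possible interaction count (`n_tfs_genome * n_genes_genome`).
#' @export
pipeline_predict <- function(config, fit_report = NULL) {
  stopifnot(inherits(config, "run_config"))
  seeds <- stage_seeds(config)
  if (is.null(fit_report)) fit_report <- pipeline_fit(config)
  if (fit_report$target_coverage < config$min_target_coverage) {
    stop(sprintf(
      "observed targets cover %.0f%% of genome genes, below the %.0f%% floor: out-degrees are too sparsely sampled for complete-network inference (lower min_target_coverage to override)",
      100 * fit_report$target_coverage,
      100 * config$min_target_coverage))
  }
  fit <- fit_report$fit
  deg <- fit_report$degrees
  pop <- build_population(fit$alpha, size = config$population_size,
                          seed = seeds[2])
  dist <- sampling_distribution(pop, config$n_tfs_genome, r = config$r,
                                seed = seeds[3],
                                tail_floor = config$tail_floor)
  pi <- prediction_interval(dist, fit$alpha, level = config$pi_level,
                            method = config$pi_method)
  est_self <- estimate_interactions(fit, deg, length(deg), r = config$r,
                                    seed = seeds[4],
                                    max_degree = config$n_genes_genome,
                                    gof_p = fit_report$p, force = TRUE)
  est_comp <- estimate_interactions(fit, deg, config$n_tfs_genome,
                                    r = config$r, seed = seeds[5],
                                    max_degree = config$n_genes_genome,
                                    gof_p = fit_report$p, force = TRUE)
  i_obs <- sum(deg)
  max_possible <- as.numeric(config$n_tfs_genome) * config$n_genes_genome
  report <- list(
    config_hash = config_hash(config), seed = config$seed,
    alpha_obs = fit$alpha, gof_p = fit_report$p,
    pi_lower = pi$lower, pi_upper = pi$upper, pi_method = pi$method,
    pi_sd = pi$sd,
    n_tfs_genome = config$n_tfs_genome, i_obs = i_obs,
    i_self_mean = est_self$mean_pdis, i_self_sd = est_self$sd_pdis,
    ztest_p_self = est_self$ztest_p,
    i_comp_mean = est_comp$mean_pdis, i_comp_sd = est_comp$sd_pdis,
    pct_observed = 100 * i_obs / est_comp$mean_pdis,
    max_possible_pdis = max_possible,
    pct_of_max = 100 * est_comp$mean_pdis / max_possible)
  write_report(report, config, "predict")
  c(report, list(interval = pi, distribution = dist))
}

#' Subnetwork stage: exponent stability across sampled sizes
#'
#' Edge-samples subnetworks at the configured proportions, summarizes the
#' exponent spread per proportion, and locates the knee of the
#' SD-versus-proportion curve — the size threshold below which the
#' scale-free exponent degrades.
#'
#' @param config A [run_config()].
#' @param fit_report Optionally, the result of [pipeline_fit()] to reuse.
#' @return Report list with the long-format records, the per-proportion
#'   summary and the knee point (requires at least 5 proportions; `NA`
#'   otherwise).
#' @export
pipeline_subnets <- function(config, fit_report = NULL) {
  stopifnot(inherits(config, "run_config"))
  seeds <- stage_seeds(config)
  if (is.null(fit_report)) fit_report <- pipeline_fit(config)
  recs <- subnet_exponents(fit_report$grn, config$proportions,
                           r = config$subnet_r, seed = seeds[6],
                           tail_floor = config$tail_floor)
  summ <- summarize_subnets(recs)
  knee <- if (nrow(summ) >= 5) {
    knee_point(summ$proportion, summ$sd_alpha)
  } else {
    list(knee = NA_real_, collinear = NA)
  }
  report <- list(config_hash = config_hash(config), seed = config$seed,
                 summary = summ, knee = knee$knee)
  write_report(report, config, "subnets")
  c(report, list(records = recs))
}
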