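# Small fixtures built in code, shared across test files.

# star: one TF binding `n` targets
star_records <- function(n = 10) {
  data.frame(tf = "TF1", target = paste0("G", seq_len(n)))
}

# edge-list file on disk; returns the path
write_edge_file <- function(records, path = tempfile(fileext = ".tsv")) {
  writeLines(
    c("tf\ttarget",
      paste(records$tf, records$target, sep = "\t")),
    path)
  path
}

# moderately sized power-law degree sample
pl_sample <- function(n, alpha, seed, kmin = 1, kmax = 10000) {
  rpowerlaw(n, powerlaw_model(alpha, kmin = kmin, kmax = kmax), seed = seed)
}

# synthetic GRN at a reduced "yeast-like" scale used by several suites
toy_grn <- function(seed = 42, n_edges = 4000, n_nodes = 2000) {
  simulate_grn(grn_config(2.0, n_edges = n_edges, n_nodes = n_nodes,
                          tf_fraction = 0.05, seed = seed))
}
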