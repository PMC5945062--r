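test_that("edge-list reading validates and counts lines", {
  rec <- star_records(5)
  path <- write_edge_file(rec)
  got <- read_pdi_table(path)
  expect_equal(nrow(got), 5)
  expect_named(got, c("tf", "target"))
  # malformed line in strict mode: error naming the line
  writeLines(c("tf\ttarget", "A\tB", "Aonly", "C\tD"), path)
  expect_error(read_pdi_table(path), "row\\(s\\): 3")
  expect_warning(ok <- read_pdi_table(path, strict = FALSE), "malformed")
  expect_equal(nrow(ok), 2)
  expect_error(read_pdi_table(tempfile()), "no such file")
})

test_that("duplicate PDIs collapse to one edge with merged provenance", {
  rec <- data.frame(tf = c("A", "A", "A"), target = c("B", "B", "C"),
                    source = c("chip_seq", "y1h", "y1h"))
  g <- build_grn(rec)
  expect_equal(igraph::gsize(g), 2)
  eattr <- igraph::E(g)$provenance
  expect_true("chip_seq;y1h" %in% eattr)
  # a TF that is also a target is one node flagged is_tf
  g2 <- build_grn(data.frame(tf = c("A", "B"), target = c("B", "C")))
  expect_equal(igraph::vcount(g2), 3)
  expect_true(igraph::V(g2)["B"]$is_tf)
})

test_that("graph assembly is order-independent", {
  rec <- data.frame(tf = rep(paste0("T", 1:8), each = 5),
                    target = paste0("G", sample(1:20, 40, replace = TRUE)))
  rec <- rec[!duplicated(rec), ]
  g1 <- build_grn(rec)
  set.seed(1)
  g2 <- build_grn(rec[sample(nrow(rec)), ])
  expect_identical(igraph::as_edgelist(g1), igraph::as_edgelist(g2))
})

test_that("degree sequences conserve edges and match hand cases", {
  # star: 1 TF -> 10 targets
  g <- build_grn(star_records(10))
  expect_equal(unname(degree_sequence(g, "out")), 10)
  expect_equal(unname(degree_sequence(g, "in")), rep(1, 10))
  # chain A -> B -> C
  gc <- build_grn(data.frame(tf = c("A", "B"), target = c("B", "C")))
  expect_equal(sort(unname(degree_sequence(gc, "out"))), c(1, 1))
  expect_equal(sort(unname(degree_sequence(gc, "in"))), c(1, 1))
  # conservation on a larger random graph
  gr <- toy_grn(seed = 3, n_edges = 1500, n_nodes = 900)
  expect_equal(sum(degree_sequence(gr, "out")), igraph::gsize(gr))
  expect_equal(sum(degree_sequence(gr, "in")), igraph::gsize(gr))
})

test_that("provenance filters select exactly the matching records", {
  rec <- data.frame(tf = "A", target = paste0("G", 1:6),
                    source = rep(c("chip_seq", "y1h"), 3),
                    tissue = rep(c("embryo", "adult", "embryo"), 2))
  expect_equal(nrow(filter_pdis(rec, source = "y1h")), 3)
  expect_equal(nrow(filter_pdis(rec, tissue = "embryo")), 4)
  expect_equal(nrow(filter_pdis(rec, source = "chip_seq",
                                tissue = "embryo")), 2)
  expect_error(filter_pdis(rec, source = "chipseq"), "valid labels")
  expect_warning(out <- filter_pdis(rec, tissue = "larva"), "no records")
  expect_equal(nrow(out), 0)
})

test_that("tissue-filtered subnetwork refits end to end", {
  g <- toy_grn(seed = 5, n_edges = 3000, n_nodes = 1500)
  el <- igraph::as_edgelist(g)
  set.seed(8)
  rec <- data.frame(tf = el[, 1], target = el[, 2],
                    source = "chip_seq",
                    tissue = sample(c("embryo", "adult"), nrow(el),
                                    replace = TRUE))
  sub <- filter_pdis(rec, tissue = "embryo")
  f <- fit_power_law(degree_sequence(build_grn(sub), "out"))
  expect_gt(f$alpha, 1)
  expect_true(is.finite(f$ks_D))
})

test_that("peak-to-gene assignment honors the inclusive 2 kb window", {
  genes <- data.frame(gene_id = c("g0", "g2000", "g2500", "gX"),
                      chrom = c("chr1", "chr1", "chr1", "chr2"),
                      tss = c(5000, 7000, 7500, 5000),
                      strand = "+")
  peaks <- data.frame(tf = "TF1", chrom = "chr1", summit = 5000)
  hits <- assign_peaks_to_genes(peaks, genes)
  # distance 0 and exactly 2000 assigned; 2500 and other-chromosome not
  expect_setequal(hits$target, c("g0", "g2000"))
})

test_that("peak assignment agrees with a brute-force all-pairs scan", {
  set.seed(31)
  n <- 400
  peaks <- data.frame(tf = sample(paste0("TF", 1:20), n, replace = TRUE),
                      chrom = sample(c("chr1", "chr2", "chr3"), n, TRUE),
                      summit = sample.int(2e5, n, replace = TRUE))
  genes <- data.frame(gene_id = paste0("g", 1:300),
                      chrom = sample(c("chr1", "chr2", "chr3"), 300, TRUE),
                      tss = sample.int(2e5, 300, replace = TRUE),
                      strand = sample(c("+", "-"), 300, TRUE))
  got <- assign_peaks_to_genes(peaks, genes, window = 2000)
  brute <- do.call(rbind, lapply(seq_len(n), function(i) {
    hit <- genes$chrom == peaks$chrom[i] &
      abs(genes$tss - peaks$summit[i]) <= 2000
    if (!any(hit)) return(NULL)
    data.frame(tf = peaks$tf[i], target = genes$gene_id[hit])
  }))
  brute <- brute[!duplicated(brute), ]
  expect_setequal(paste(got$tf, got$target), paste(brute$tf, brute$target))
})

test_that("chromosome mismatch between files warns with counts", {
  peaks <- data.frame(tf = "T", chrom = "1", summit = 100)
  genes <- data.frame(gene_id = "g", chrom = "chr1", tss = 100, strand = "+")
  expect_warning(assign_peaks_to_genes(peaks, genes), "chromosome")
})

test_that("BED peaks and TSV/GFF3 gene tables load through rtracklayer", {
  bed <- tempfile(fileext = ".bed")
  # BED is 0-based half-open; the 10-wide interval [100, 110) has midpoint 105
  writeLines(c("chr1\t100\t110\tTF1", "chr2\t0\t50\tTF2"), bed)
  pk <- read_peaks(bed)
  expect_equal(pk$summit, c(105, 25))
  expect_equal(pk$tf, c("TF1", "TF2"))

  gff <- tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               "chr1\ttest\tgene\t200\t900\t.\t+\t.\tID=gA",
               "chr1\ttest\tgene\t1000\t2000\t.\t-\t.\tID=gB",
               "chr1\ttest\texon\t200\t300\t.\t+\t.\tID=e1"), gff)
  gt <- read_gene_table(gff, format = "gff3")
  expect_equal(nrow(gt), 2)
  # 5' end: start for + strand, end for - strand
  expect_equal(gt$tss[gt$gene_id == "gA"], 200)
  expect_equal(gt$tss[gt$gene_id == "gB"], 2000)
})
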