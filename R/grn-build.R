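#' Read a protein-DNA interaction (PDI) edge list
#'
#' Reads a delimited text table of TF -> target-gene interactions. The first
#' two columns are interpreted as the TF and target identifiers; optional
#' `source` (assay type) and `tissue` columns are kept as provenance.
#'
#' @param path Path to a delimited text file with a header line.
#' @param sep Field separator (default tab).
#' @param strict If `TRUE` (default), malformed data lines — fewer than two
#'   fields or an empty identifier — abort with an error naming the line
#'   numbers; if `FALSE` they are dropped with a warning.
#' @return A `data.frame` of PDI records with columns `tf`, `target` and,
#'   when present in the file, `source` and `tissue`.
#' @examples
#' f <- tempfile()
#' writeLines(c("tf\ttarget", "TF1\tGENE1", "TF1\tGENE2"), f)
#' read_pdi_table(f)
#' @export
read_pdi_table <- function(path, sep = "\t", strict = TRUE) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          colClasses = "character", quote = "",
                          comment.char = "", fill = TRUE,
                          blank.lines.skip = FALSE)
  if (ncol(df) < 2) stop("edge list needs at least 2 columns (tf, target)")
  if (nrow(df) == 0) stop("empty edge list: ", path)
  names(df)[1:2] <- c("tf", "target")
  bad <- which(is.na(df$tf) | is.na(df$target) |
                 df$tf == "" | df$target == "")
  if (length(bad) > 0) {
    msg <- paste0("malformed line(s) at data row(s): ",
                  paste(utils::head(bad + 1L, 10), collapse = ", "))
    if (strict) stop(msg)
    warning(msg, "; dropped")
    df <- df[-bad, , drop = FALSE]
  }
  keep <- intersect(c("tf", "target", "source", "tissue"), names(df))
  df[, keep, drop = FALSE]
}

#' Filter PDI records by experimental source or tissue
#'
#' Subsets a PDI record table to the rows whose provenance matches the
#' requested assay source and/or tissue, e.g. to refit the exponent of a
#' ChIP-Seq-only or embryo-only subnetwork.
#'
#' @param records PDI `data.frame` from [read_pdi_table()].
#' @param source Optional assay label; one of `"chip_seq"`, `"chip_chip"`,
#'   `"y1h"`, `"dap_seq"`, `"other"`.
#' @param tissue Optional tissue/stage label (matched exactly).
#' @return The matching records; an empty selection triggers a warning.
#' @export
filter_pdis <- function(records, source = NULL, tissue = NULL) {
  valid <- c("chip_seq", "chip_chip", "y1h", "dap_seq", "other")
  keep <- rep(TRUE, nrow(records))
  if (!is.null(source)) {
    if (!source %in% valid) {
      stop("unknown source '", source, "'; valid labels: ",
           paste(valid, collapse = ", "))
    }
    if (is.null(records$source)) stop("records carry no 'source' column")
    keep <- keep & records$source == source
  }
  if (!is.null(tissue)) {
    if (is.null(records$tissue)) stop("records carry no 'tissue' column")
    keep <- keep & records$tissue == tissue
  }
  out <- records[keep, , drop = FALSE]
  if (nrow(out) == 0) warning("no records match the requested filter")
  out
}

#' Assemble a directed gene regulatory network from PDI records
#'
#' Builds the directed graph in which each unique (TF, target) pair is one
#' edge. Duplicate records — the same interaction supported by several
#' assays — are collapsed to a single edge whose `provenance` attribute
#' concatenates the distinct source labels. A TF that is also somebody's
#' target is a single node; self-loops (a TF binding its own gene) are kept.
#'
#' @param records PDI `data.frame` with columns `tf` and `target`.
#' @return An [igraph::igraph] directed graph with logical vertex attribute
#'   `is_tf` (out-degree at least 1) and edge attribute `provenance`.
#' @examples
#' g <- build_grn(data.frame(tf = "A", target = c("B", "C", "A")))
#' igraph::gsize(g)
#' @export
build_grn <- function(records) {
  stopifnot(is.data.frame(records), nrow(records) >= 1)
  key <- paste(records$tf, records$target, sep = "\r")
  first <- !duplicated(key)
  edges <- records[first, c("tf", "target")]
  prov <- if (!is.null(records$source)) {
    vapply(split(records$source, factor(key, levels = key[first])),
           function(s) paste(sort(unique(s)), collapse = ";"), character(1))
  } else {
    rep(NA_character_, nrow(edges))
  }
  # deterministic node order regardless of input row order
  nodes <- sort(unique(c(edges$tf, edges$target)))
  ord <- order(edges$tf, edges$target)
  g <- igraph::graph_from_data_frame(
    cbind(edges[ord, ], provenance = prov[ord]),
    directed = TRUE,
    vertices = data.frame(name = nodes)
  )
  igraph::V(g)$is_tf <- igraph::degree(g, mode = "out") > 0
  g
}

#' Extract the out- or in-degree sequence of a GRN
#'
#' The out-degree of a TF is the number of target genes it binds; the
#' in-degree of a gene is the number of TFs binding it. Nodes with zero
#' degree in the requested direction are excluded (a pure target contributes
#' no out-degree value), so all returned values are at least 1 and the sum
#' equals the edge count in either direction.
#'
#' @param grn Directed [igraph::igraph] graph, e.g. from [build_grn()].
#' @param direction `"out"` (default) or `"in"`.
#' @return Named integer vector of positive degrees.
#' @export
degree_sequence <- function(grn, direction = c("out", "in")) {
  direction <- match.arg(direction)
  stopifnot(igraph::is_igraph(grn), igraph::gsize(grn) >= 1)
  d <- igraph::degree(grn, mode = direction)
  d[d > 0]
}

#' Read ChIP peak locations from a BED file
#'
#' Imports a BED3+name file of binding peaks (the `name` field carries the
#' TF identifier) and reduces every peak to a single summit coordinate, the
#' interval midpoint, in 1-based coordinates.
#'
#' @param path BED file path.
#' @return `data.frame` with columns `tf`, `chrom`, `summit`.
#' @export
read_peaks <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  if (is.null(gr$name)) stop("BED file must carry the TF id in the name field")
  data.frame(
    tf = as.character(gr$name),
    chrom = as.character(GenomicRanges::seqnames(gr)),
    summit = as.integer(floor((GenomicRanges::start(gr) +
                                 GenomicRanges::end(gr)) / 2)),
    stringsAsFactors = FALSE
  )
}

#' Read a gene/TSS annotation table
#'
#' Either a tab-separated table with columns `gene_id`, `chrom`, `tss`,
#' `strand` (1-based TSS coordinates), or a GFF3 file from which the 5' end
#' of every `gene` feature is taken as the TSS.
#'
#' @param path Input file path.
#' @param format `"tsv"` (default) or `"gff3"`.
#' @return `data.frame` with columns `gene_id`, `chrom`, `tss`, `strand`.
#' @export
read_gene_table <- function(path, format = c("tsv", "gff3")) {
  format <- match.arg(format)
  if (format == "tsv") {
    df <- utils::read.table(path, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE)
    need <- c("gene_id", "chrom", "tss", "strand")
    if (!all(need %in% names(df))) {
      stop("gene table must have columns: ", paste(need, collapse = ", "))
    }
    return(df[, need])
  }
  gr <- rtracklayer::import(path, format = "GFF3")
  gr <- gr[gr$type == "gene"]
  strand <- as.character(GenomicRanges::strand(gr))
  ids <- if (!is.null(gr$ID)) as.character(gr$ID) else as.character(gr$Name)
  data.frame(
    gene_id = ids,
    chrom = as.character(GenomicRanges::seqnames(gr)),
    tss = ifelse(strand == "-", GenomicRanges::end(gr),
                 GenomicRanges::start(gr)),
    strand = strand,
    stringsAsFactors = FALSE
  )
}

#' Assign ChIP peaks to genes within a distance window of the TSS
#'
#' Emits one PDI record for every (TF, gene) pair in which the peak summit
#' lies within `window` base pairs of the gene's transcription start site on
#' the same chromosome (inclusive boundary, strand ignored). All qualifying
#' genes are assigned — there is no nearest-gene tie-break — and duplicate
#' (TF, gene) pairs are collapsed.
#'
#' @param peaks `data.frame` with columns `tf`, `chrom`, `summit` (see
#'   [read_peaks()]).
#' @param genes `data.frame` with columns `gene_id`, `chrom`, `tss` (see
#'   [read_gene_table()]).
#' @param window Maximum summit-to-TSS distance in bp (default 2000).
#' @return PDI `data.frame` with columns `tf`, `target`, `source`
#'   (`"chip_seq"`).
#' @export
assign_peaks_to_genes <- function(peaks, genes, window = 2000) {
  stopifnot(all(c("tf", "chrom", "summit") %in% names(peaks)),
            all(c("gene_id", "chrom", "tss") %in% names(genes)))
  shared <- intersect(unique(peaks$chrom), unique(genes$chrom))
  if (length(shared) == 0) {
    warning("no chromosome names shared between peaks (",
            length(unique(peaks$chrom)), ") and genes (",
            length(unique(genes$chrom)), ")")
  }
  pk <- GenomicRanges::GRanges(
    peaks$chrom,
    IRanges::IRanges(start = pmax(1L, peaks$summit - as.integer(window)),
                     end = peaks$summit + as.integer(window))
  )
  tss <- GenomicRanges::GRanges(genes$chrom,
                                IRanges::IRanges(genes$tss, genes$tss))
  hits <- suppressWarnings(GenomicRanges::findOverlaps(pk, tss))
  out <- data.frame(
    tf = peaks$tf[S4Vectors::queryHits(hits)],
    target = genes$gene_id[S4Vectors::subjectHits(hits)],
    source = rep("chip_seq", length(hits)),
    stringsAsFactors = FALSE
  )
  out[!duplicated(paste(out$tf, out$target, sep = "\r")), , drop = FALSE]
}
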