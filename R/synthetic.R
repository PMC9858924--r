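# Synthetic data: a toy genome with planted promoter/enhancer/exon
# structure, and a peak-by-cell matrix with planted cell types, so that
# the whole pipeline can be exercised end to end without downloads.
# Region and peak geometry is chosen so that literal-containment labeling
# is satisfiable (regions narrower than peaks, exon peaks inside exons).

#' Simulation configuration
#'
#' Defaults define the reference synthetic study: 60 genes on one
#' chromosome, 3 cell types of 200 cells, 15 marker genes per type (the
#' remaining 15 genes are housekeeping, active in every type), regulatory
#' peaks of active genes open with probability 0.8 against a background
#' accessibility of 0.05, 2 enhancers per gene.
#'
#' @param n_genes Total genes on the toy chromosome.
#' @param n_celltypes Number of planted cell types.
#' @param cells_per_type Cells per type.
#' @param marker_genes_per_type Marker genes private to each type.
#' @param p_open_active Accessibility probability of an active gene's peaks.
#' @param p_noise Background accessibility probability.
#' @param enhancers_per_gene Enhancer regions per gene.
#' @param seed Integer seed driving all draws.
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(n_genes = 60L, n_celltypes = 3L, cells_per_type = 200L,
                       marker_genes_per_type = 15L, p_open_active = 0.8,
                       p_noise = 0.05, enhancers_per_gene = 2L, seed = 1L) {
  cfg <- list(n_genes = as.integer(n_genes),
              n_celltypes = as.integer(n_celltypes),
              cells_per_type = as.integer(cells_per_type),
              marker_genes_per_type = as.integer(marker_genes_per_type),
              p_open_active = as.numeric(p_open_active),
              p_noise = as.numeric(p_noise),
              enhancers_per_gene = as.integer(enhancers_per_gene),
              seed = as.integer(seed))
  stopifnot(cfg$n_genes > 0, cfg$n_celltypes > 0, cfg$cells_per_type > 0,
            cfg$marker_genes_per_type > 0, cfg$enhancers_per_gene > 0,
            cfg$p_open_active >= 0, cfg$p_open_active <= 1,
            cfg$p_noise >= 0, cfg$p_noise <= 1)
  if (cfg$n_celltypes * cfg$marker_genes_per_type >= cfg$n_genes)
    stop("need at least one housekeeping gene: ",
         "n_genes must exceed n_celltypes * marker_genes_per_type")
  class(cfg) <- "sim_config"
  cfg
}

#' Generate a toy genome annotation
#'
#' Lays `n_genes` genes on one synthetic chromosome in disjoint 100 kb
#' slots: a 10 kb gene body with two exons (1.5 kb at the TSS end, 2 kb at
#' the far end), a 200 bp promoter region 100-300 bp upstream of the TSS,
#' and `enhancers_per_gene` 200 bp enhancer regions 5-13 kb upstream
#' (inside the 30 kb connection window). Strands are drawn at random;
#' all layout is deterministic per seed.
#'
#' @inheritParams sim_config
#' @return A [gene_annotation()]; regions carry a `gene_id` column
#'   recording the planted owner.
#' @export
make_toy_genome <- function(n_genes = 60L, enhancers_per_gene = 2L, seed = 1L) {
  set.seed(seed)
  n_genes <- as.integer(n_genes)
  slot <- 100000
  chrom <- "chrS"
  ids <- sprintf("SG%02d", seq_len(n_genes))
  strand <- sample(c("+", "-"), n_genes, replace = TRUE)
  slot0 <- (seq_len(n_genes) - 1) * slot
  b_start0 <- slot0 + 45000   # 0-based half-open body [b_start0, b_end0)
  b_end0 <- b_start0 + 10000
  genes <- GenomicRanges::GRanges(chrom,
                                  IRanges::IRanges(b_start0 + 1, b_end0),
                                  strand = strand)
  genes$gene_id <- ids
  genes$gene_name <- ids
  genes$biotype <- "protein_coding"
  exl <- lapply(seq_len(n_genes), function(i) {
    GenomicRanges::GRanges(chrom, IRanges::IRanges(
      start = c(b_start0[i] + 1, b_start0[i] + 8000 + 1),
      end = c(b_start0[i] + 1500, b_start0[i] + 10000)),
      strand = strand[i])
  })
  exons <- GenomicRanges::GRangesList(exl)
  names(exons) <- ids
  # regulatory regions, placed transcription-upstream of each TSS
  reg <- list()
  for (i in seq_len(n_genes)) {
    tss0 <- if (strand[i] == "+") b_start0[i] else b_end0[i] - 1
    updir <- if (strand[i] == "+") -1 else 1
    prom_center <- tss0 + updir * 200
    enh_d <- 5000 + (seq_len(enhancers_per_gene) - 1) * 3000 +
      round(stats::runif(enhancers_per_gene, 0, 1000))
    centers <- c(prom_center, tss0 + updir * enh_d)
    reg[[i]] <- GenomicRanges::GRanges(chrom, IRanges::IRanges(
      start = centers - 100 + 1, end = centers + 100))
    reg[[i]]$label <- c("promoter", rep("enhancer_distal", enhancers_per_gene))
    reg[[i]]$gene_id <- ids[i]
  }
  regions <- unlist(GenomicRanges::GRangesList(reg))
  gene_annotation(genes, exons, regions)
}

#' Simulate a planted-cell-type peak matrix
#'
#' One 400 bp peak is centered on every promoter, enhancer and exon region
#' of the toy genome. Each cell type activates its private marker genes
#' (and every housekeeping gene): peaks of active genes open with
#' probability `p_open_active`, all other peaks with `p_noise`. Truth
#' connections pair each marker gene's promoter peak with its enhancer
#' peaks at co-accessibility scores drawn uniformly in [0.3, 0.9].
#'
#' @param annotation A [make_toy_genome()] annotation.
#' @param config A [sim_config()] (its `n_genes`/`enhancers_per_gene` must
#'   match the annotation).
#' @return Object of class `synthetic_dataset`: list with `annotation`,
#'   `counts` (sparse binary peaks-by-cells), `peaks` (`GRanges`),
#'   `truth_labels` (0-based types, named by barcode), `truth_gene_sets`
#'   ([gene_set_pair()]), `truth_connections` ([connection_set()]), and
#'   `config`.
#' @export
simulate_peak_matrix <- function(annotation, config = sim_config()) {
  stopifnot(inherits(annotation, "gene_annotation"), inherits(config, "sim_config"))
  if (config$p_open_active <= config$p_noise)
    warning("p_open_active <= p_noise: planted structure is unrecoverable")
  set.seed(config$seed + 1L)
  genes <- annotation$genes
  ids <- genes$gene_id
  if (length(ids) != config$n_genes)
    stop("annotation does not match config$n_genes")
  # peaks: one per regulatory region and per exon, 400 bp, centered
  reg <- annotation$regions
  ex <- unlist(annotation$exons, use.names = FALSE)
  ex_gene <- rep(names(annotation$exons), lengths(annotation$exons))
  centers0 <- c(.peak_center(reg), .peak_center(ex))
  peak_gene <- c(reg$gene_id, ex_gene)
  chrom <- c(as.character(GenomicRanges::seqnames(reg)),
             as.character(GenomicRanges::seqnames(ex)))
  peaks <- GenomicRanges::GRanges(chrom, IRanges::IRanges(
    start = round(centers0) - 200 + 1, end = round(centers0) + 200))
  names(peaks) <- peak_id(peaks)
  if (anyDuplicated(names(peaks))) stop("internal: peak layout collision")
  n_peaks <- length(peaks)

  k <- config$n_celltypes
  m <- config$marker_genes_per_type
  marker_sets <- split(ids[seq_len(k * m)], rep(seq_len(k), each = m))
  hk <- ids[(k * m + 1):length(ids)]
  n_cells <- k * config$cells_per_type
  type <- rep(seq_len(k) - 1L, each = config$cells_per_type)
  barcodes <- sprintf("CELL-%04d", seq_len(n_cells))

  active_by_type <- lapply(seq_len(k), function(t) {
    peak_gene %in% c(marker_sets[[t]], hk)
  })
  prob <- matrix(config$p_noise, n_peaks, n_cells)
  for (t in seq_len(k)) {
    cols <- which(type == t - 1L)
    prob[active_by_type[[t]], cols] <- config$p_open_active
  }
  draws <- stats::rbinom(length(prob), 1L, as.vector(prob))
  D <- Matrix::Matrix(matrix(draws, n_peaks, n_cells), sparse = TRUE)
  dimnames(D) <- list(names(peaks), barcodes)

  # truth connections: marker prom peak <-> its enhancer peaks
  conn <- list()
  reg_idx <- seq_along(reg)
  for (g in unlist(marker_sets)) {
    pr <- reg_idx[reg$gene_id == g & reg$label == "promoter"]
    en <- reg_idx[reg$gene_id == g & reg$label == "enhancer_distal"]
    for (e in en) {
      conn[[length(conn) + 1L]] <- data.frame(
        p1 = names(peaks)[pr], p2 = names(peaks)[e],
        ca = stats::runif(1, 0.3, 0.9),
        d = abs(.peak_center(peaks[pr]) - .peak_center(peaks[e])),
        stringsAsFactors = FALSE)
    }
  }
  truth_connections <- connection_set(do.call(rbind, conn))
  structure(list(annotation = annotation, counts = D, peaks = peaks,
                 truth_labels = setNames(type, barcodes),
                 truth_gene_sets = gene_set_pair(unlist(marker_sets), hk),
                 truth_connections = truth_connections,
                 config = config),
            class = "synthetic_dataset")
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat(sprintf("synthetic_dataset: %d peaks x %d cells, %d genes, %d cell types\n",
              nrow(x$counts), ncol(x$counts), length(x$annotation$genes),
              length(unique(x$truth_labels))))
  invisible(x)
}

#' The hand-derived worked example
#'
#' A deterministic 2-gene / 7-peak / 3-cell dataset shipped with the
#' package, whose peak labels, association maps and component matrices
#' were derived by hand and stored alongside the inputs. It covers the two
#' delicate promoter cases: a gene with no promoter-track signature whose
#' TSS-covering peak rescues it into the matrix, and two divergent genes
#' near a shared promoter signature, disambiguated by TSS coverage.
#'
#' @return List with `annotation`, `counts`, `peaks`, `connections`, and
#'   `expected` (list: `labels`, named character; `entries`, data.frame
#'   `component`/`row`/`col`/`value` of all nonzero entries of GP, PE, GI,
#'   P, C, E and the combined matrix, pre-normalization, weights (1,1,1)).
#' @export
worked_example <- function() {
  dir <- system.file("extdata", "worked-example", package = "gagam",
                     mustWork = TRUE)
  gm <- load_gene_annotation(file.path(dir, "genes.gtf"), format = "gtf")
  rr <- load_regulatory_tracks(file.path(dir, "ccres.bed"), label_column = 7L)
  annotation <- gene_annotation(gm$genes, gm$exons, rr)
  counts <- read_peak_matrix(file.path(dir, "matrix.mtx"),
                             file.path(dir, "peaks.bed"),
                             file.path(dir, "barcodes.tsv"))
  connections <- read_connections(file.path(dir, "connections.csv"))
  labels <- utils::read.table(file.path(dir, "expected_labels.tsv"),
                              header = TRUE, sep = "\t",
                              stringsAsFactors = FALSE)
  entries <- utils::read.table(file.path(dir, "expected_entries.tsv"),
                               header = TRUE, sep = "\t",
                               stringsAsFactors = FALSE)
  list(annotation = annotation, counts = counts,
       peaks = parse_peak_ids(rownames(counts)),
       connections = connections,
       expected = list(labels = setNames(labels$label, labels$peak),
                       entries = entries))
}
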