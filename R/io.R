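# Readers and writers for the on-disk formats: the 10x-style MatrixMarket
# triplet (matrix.mtx + peaks.bed + barcodes.tsv), gene activity output,
# and a minimal GTF writer for the simulator.

#' Read a peak-by-cell matrix triplet
#'
#' 10x cellranger-atac layout: MatrixMarket sparse matrix with one row per
#' peak (BED3 sidecar) and one column per barcode. Entries are binarized
#' (any positive count counts as accessible).
#'
#' @param matrix Path to the `.mtx` file.
#' @param peaks Path to the BED3 peak file (row order).
#' @param barcodes Path to the barcode list (column order).
#' @return Sparse binary `Matrix` with peak-id rownames and barcode
#'   colnames.
#' @export
read_peak_matrix <- function(matrix, peaks, barcodes) {
  D <- Matrix::readMM(matrix)
  pk <- read_peaks_bed(peaks)
  bc <- readLines(barcodes)
  bc <- bc[nzchar(bc)]
  if (nrow(D) != length(pk))
    stop("matrix has ", nrow(D), " rows but ", length(pk), " peaks")
  if (ncol(D) != length(bc))
    stop("matrix has ", ncol(D), " columns but ", length(bc), " barcodes")
  dimnames(D) <- list(names(pk), bc)
  .as_binary_matrix(D)
}

#' Write a gene activity matrix to a directory
#'
#' Emits `gagam.mtx`, `genes.tsv` (row ids), `barcodes.tsv` (column ids),
#' and optionally the three component matrices.
#'
#' @param g A `gagam` object (or a bare genes-by-cells matrix).
#' @param dir Output directory (created if needed).
#' @param components Also write `P.mtx`, `C.mtx`, `E.mtx`.
#' @return `dir`, invisibly.
#' @export
write_gam <- function(g, dir, components = FALSE) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  m <- if (inherits(g, "gagam")) g$gam else g
  Matrix::writeMM(as(m, "CsparseMatrix"), file.path(dir, "gagam.mtx"))
  writeLines(rownames(m), file.path(dir, "genes.tsv"))
  writeLines(colnames(m), file.path(dir, "barcodes.tsv"))
  if (components && inherits(g, "gagam")) {
    for (nm in names(g$components))
      Matrix::writeMM(as(g$components[[nm]], "CsparseMatrix"),
                      file.path(dir, paste0(nm, ".mtx")))
  }
  invisible(dir)
}

#' Read a gene activity matrix written by [write_gam()]
#'
#' @param dir Directory with `gagam.mtx`, `genes.tsv`, `barcodes.tsv`.
#' @return Sparse genes-by-cells `Matrix`.
#' @export
read_gam <- function(dir) {
  m <- Matrix::readMM(file.path(dir, "gagam.mtx"))
  rn <- readLines(file.path(dir, "genes.tsv"))
  cn <- readLines(file.path(dir, "barcodes.tsv"))
  dimnames(m) <- list(rn[nzchar(rn)], cn[nzchar(cn)])
  as(m, "CsparseMatrix")
}

#' Write a gene annotation as GTF
#'
#' Minimal GTF (gene and exon features, with `gene_id`, `transcript_id`,
#' `gene_name`, `gene_biotype` attributes), sufficient to round-trip
#' through [load_gene_annotation()].
#'
#' @param annotation A [gene_annotation()] (or list with `genes`/`exons`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gtf <- function(annotation, path) {
  genes <- annotation$genes
  exons <- annotation$exons[genes$gene_id]
  attr_of <- function(i, id) {
    sprintf('gene_id "%s"; transcript_id "%s.t1"; gene_name "%s"; gene_biotype "%s";',
            id, id, genes$gene_name[i], genes$biotype[i])
  }
  lines <- character(0)
  for (i in seq_along(genes)) {
    g <- genes[i]
    id <- g$gene_id
    chrom <- as.character(GenomicRanges::seqnames(g))
    st <- as.character(GenomicRanges::strand(g))
    lines <- c(lines,
               paste(chrom, "toy", "gene", GenomicRanges::start(g),
                     GenomicRanges::end(g), ".", st, ".", attr_of(i, id),
                     sep = "\t"))
    e <- sort(exons[[i]])
    lines <- c(lines,
               paste(chrom, "toy", "exon", GenomicRanges::start(e),
                     GenomicRanges::end(e), ".", st, ".", attr_of(i, id),
                     sep = "\t"))
  }
  writeLines(lines, path)
  invisible(path)
}
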