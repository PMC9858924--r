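# Configuration object and file-level pipeline entry points
# (run_label / run_build / run_eval / run_simulate). A thin command-line
# wrapper over these lives in inst/cli/gagam.R.

#' Pipeline configuration
#'
#' All tunable parameters of the construction, validated on creation.
#' Defaults are the reference settings: 500 bp promoter-window extension,
#' 5000 bp exon decay scale, 30,000 bp connection distance threshold,
#' 2-base TSS, binary weights (1,1,1), literal-containment overlap
#' semantics, per-cell size-factor normalization.
#'
#' @param upstream_bp Promoter-window extension upstream of the TSS (bp).
#' @param decay_scale Exon-weight decay scale (bp).
#' @param d_th Connection distance threshold (bp).
#' @param tss_width TSS region width (bp).
#' @param weights Binary `(wp, wc, we)`.
#' @param overlap_mode `"literal_containment"` or `"any_overlap"`.
#' @param normalization `"cell_total"`, `"log_cell_total"` or `"none"`.
#' @param strand_aware Strand-aware TSS and promoter window (default TRUE).
#' @param cam_include_negatives Average negative scores into cam.
#' @param binarize_promoter Clip the promoter matrix to {0,1}.
#' @param coaccess_window_bp Candidate-pair window of the built-in
#'   co-accessibility estimator (bp).
#' @param seed Integer seed for the stochastic stages (clustering).
#' @return Object of class `gagam_config` (a validated named list).
#' @export
gagam_config <- function(upstream_bp = 500L, decay_scale = 5000,
                         d_th = 30000, tss_width = 2L,
                         weights = c(1, 1, 1),
                         overlap_mode = c("literal_containment", "any_overlap"),
                         normalization = c("cell_total", "log_cell_total", "none"),
                         strand_aware = TRUE,
                         cam_include_negatives = FALSE,
                         binarize_promoter = TRUE,
                         coaccess_window_bp = 500000,
                         seed = 1L) {
  cfg <- list(upstream_bp = as.integer(upstream_bp),
              decay_scale = as.numeric(decay_scale),
              d_th = as.numeric(d_th),
              tss_width = as.integer(tss_width),
              weights = as.numeric(weights),
              overlap_mode = match.arg(overlap_mode),
              normalization = match.arg(normalization),
              strand_aware = isTRUE(strand_aware),
              cam_include_negatives = isTRUE(cam_include_negatives),
              binarize_promoter = isTRUE(binarize_promoter),
              coaccess_window_bp = as.numeric(coaccess_window_bp),
              seed = as.integer(seed))
  class(cfg) <- "gagam_config"
  validate_config(cfg)
}

#' Validate a pipeline configuration
#'
#' @param config A `gagam_config` or a plain named list with the same
#'   fields (unknown fields are rejected).
#' @return The validated `gagam_config`.
#' @export
validate_config <- function(config) {
  fields <- names(formals(gagam_config))
  unknown <- setdiff(names(config), fields)
  if (length(unknown)) stop("unknown config fields: ",
                            paste(unknown, collapse = ", "))
  missing <- setdiff(fields, names(config))
  if (length(missing)) stop("missing config fields: ",
                            paste(missing, collapse = ", "))
  stopifnot(config$upstream_bp >= 0, config$decay_scale > 0,
            config$d_th >= 0, config$tss_width >= 1,
            length(config$weights) == 3, all(config$weights %in% c(0, 1)),
            config$overlap_mode %in% c("literal_containment", "any_overlap"),
            config$normalization %in% c("cell_total", "log_cell_total", "none"),
            is.logical(config$strand_aware),
            is.logical(config$cam_include_negatives),
            is.logical(config$binarize_promoter),
            config$coaccess_window_bp > 0,
            is.numeric(config$seed) || is.integer(config$seed))
  cfg <- config[fields]
  class(cfg) <- "gagam_config"
  cfg
}

#' @export
print.gagam_config <- function(x, ...) {
  cat("gagam_config:\n")
  for (nm in names(unclass(x)))
    cat(sprintf("  %-22s %s\n", nm, paste(x[[nm]], collapse = ",")))
  invisible(x)
}

#' Write / read a configuration file
#'
#' Flat YAML serialization; `read_config(write_config(cfg, f))` returns an
#' identical configuration.
#'
#' @param config A `gagam_config`.
#' @param path File path.
#' @return `write_config`: `path`, invisibly. `read_config`: the
#'   validated `gagam_config`.
#' @export
write_config <- function(config, path) {
  config <- validate_config(config)
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  raw$upstream_bp <- as.integer(raw$upstream_bp)
  raw$tss_width <- as.integer(raw$tss_width)
  raw$seed <- as.integer(raw$seed)
  raw$weights <- as.numeric(raw$weights)
  validate_config(structure(raw, class = "gagam_config"))
}

#' Label peaks from files
#'
#' File-level wrapper: reads peaks (BED3), gene annotation and regulatory
#' track, labels the peaks and writes a labeled BED plus a per-label count
#' summary.
#'
#' @param peaks Path to BED3 peak file.
#' @param genes Path to the gene annotation.
#' @param ccres Path to the labeled regulatory BED track.
#' @param out Output path for the labeled BED.
#' @param config A [gagam_config()].
#' @param genes_format `"gtf"` or `"bed12"`.
#' @param label_column Label column of the regulatory track.
#' @return The `labeled_peaks` object, invisibly; the summary is printed.
#' @export
run_label <- function(peaks, genes, ccres, out = NULL,
                      config = gagam_config(), genes_format = "gtf",
                      label_column = 7L) {
  config <- validate_config(config)
  pk <- read_peaks_bed(peaks)
  gm <- load_gene_annotation(genes, format = genes_format)
  rr <- load_regulatory_tracks(ccres, label_column = label_column)
  ann <- gene_annotation(gm$genes, gm$exons, rr)
  lps <- label_peaks(pk, ann, mode = config$overlap_mode,
                     tss_width = config$tss_width,
                     strand_aware = config$strand_aware)
  if (!is.null(out)) write_labeled_peaks(lps, out)
  print(label_summary(lps))
  invisible(lps)
}

#' Build a gene activity matrix from files
#'
#' File-level wrapper around [gagam()]: reads the peak-by-cell matrix
#' (MatrixMarket + peaks BED3 + barcodes), the gene annotation and
#' regulatory track, optionally a connections CSV, builds the matrix and
#' writes `gagam.mtx`, `genes.tsv`, `barcodes.tsv` and a provenance JSON
#' into `outdir`.
#'
#' @param matrix,peaks,barcodes Paths of the 10x-style matrix triplet.
#' @param genes,ccres Annotation paths (see [run_label()]).
#' @param connections Optional connections CSV; the built-in estimator
#'   runs when `NULL`.
#' @param outdir Output directory (created if needed).
#' @param config A [gagam_config()].
#' @param genes_format,label_column As in [run_label()].
#' @param write_components Also write `P.mtx`, `C.mtx`, `E.mtx`.
#' @return The `gagam` object, invisibly.
#' @export
run_build <- function(matrix, peaks, barcodes, genes, ccres,
                      connections = NULL, outdir = ".",
                      config = gagam_config(), genes_format = "gtf",
                      label_column = 7L, write_components = FALSE) {
  config <- validate_config(config)
  D <- read_peak_matrix(matrix, peaks, barcodes)
  gm <- load_gene_annotation(genes, format = genes_format)
  rr <- load_regulatory_tracks(ccres, label_column = label_column)
  ann <- gene_annotation(gm$genes, gm$exons, rr)
  cs <- if (!is.null(connections)) read_connections(connections, d_th = config$d_th)
  g <- gagam(D, ann, connections = cs, config = config)
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  write_gam(g, outdir, components = write_components)
  prov <- list(config = unclass(config),
               inputs = .input_checksums(c(matrix = matrix, peaks = peaks,
                                           barcodes = barcodes, genes = genes,
                                           ccres = ccres,
                                           connections = connections)),
               cam = g$connections$cam,
               n_genes = nrow(g$gam), n_cells = ncol(g$gam),
               label_counts = as.list(label_summary(g$labels)))
  jsonlite::write_json(prov, file.path(outdir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(g)
}

.input_checksums <- function(paths) {
  paths <- paths[!vapply(paths, is.null, logical(1))]
  lapply(paths, function(p) unname(tools::md5sum(p)))
}

#' Evaluate a gene activity matrix from files
#'
#' Embeds the matrix with LSI, clusters the cells, and computes whatever
#' metrics the supplied references allow: ARI/AMI against `truth_labels`
#' when given, RAGI when `markers` and `housekeeping` gene lists are
#' given, and always a per-cluster differential-activity table. Results
#' are written as JSON when `out` is given.
#'
#' @param gam_dir Directory holding `gagam.mtx`, `genes.tsv`,
#'   `barcodes.tsv` (as written by [run_build()]), or a `gagam` object.
#' @param k Number of clusters for k-means (`NULL` with `truth_labels`
#'   present uses the number of truth classes).
#' @param truth_labels Optional two-column TSV (barcode, cluster).
#' @param markers,housekeeping Optional gene-list files (one symbol per
#'   line).
#' @param out Optional JSON output path.
#' @param n_components,drop_first LSI settings, see [lsi_embed()].
#' @param method Clustering method, see [cluster_cells()].
#' @param seed Integer seed for clustering.
#' @param top_n Genes per cluster in the differential-activity table.
#' @return List with `clusters` and the computed metrics, invisibly.
#' @export
run_eval <- function(gam_dir, k = NULL, truth_labels = NULL, markers = NULL,
                     housekeeping = NULL, out = NULL, n_components = 30L,
                     drop_first = TRUE, method = "kmeans", seed = 1L,
                     top_n = 10L) {
  M <- if (inherits(gam_dir, "gagam")) gam_dir$gam else read_gam(gam_dir)
  truth <- NULL
  if (!is.null(truth_labels)) {
    tl <- utils::read.table(truth_labels, header = FALSE, sep = "\t",
                            stringsAsFactors = FALSE)
    truth <- setNames(as.integer(factor(tl[[2]])) - 1L, tl[[1]])
    truth <- truth[colnames(M)]
    if (anyNA(truth)) stop("truth labels missing for some cells")
  }
  if (is.null(k)) {
    if (is.null(truth)) stop("supply k or truth_labels")
    k <- length(unique(truth))
  }
  ncomp <- max(2L, min(as.integer(n_components), min(dim(M)) - 1L))
  emb <- lsi_embed(M, n_components = ncomp, drop_first = drop_first)
  cl <- cluster_cells(emb, method = method, param = k, seed = seed)
  res <- list(clusters = cl, k = k, seed = seed)
  if (!is.null(truth)) {
    res$ari <- ari(cl, truth)
    res$ami <- ami(cl, truth)
  }
  if (!is.null(markers) && !is.null(housekeeping)) {
    sets <- gene_set_pair(readLines(markers), readLines(housekeeping))
    rg <- ragi(M, cl, sets)
    res$ragi <- rg$ragi
    res$ragi_p <- rg$p
    res$per_gene_gini <- rg$per_gene_gini
  } else if (is.null(truth)) {
    warning("neither truth labels nor gene sets supplied; ",
            "only the differential-activity table is computed")
  }
  res$differential_activity <- rank_differential_activity(M, cl, top_n = top_n)
  if (!is.null(out)) {
    payload <- res[setdiff(names(res), c("clusters", "per_gene_gini",
                                         "differential_activity"))]
    payload$cluster_sizes <- as.integer(table(res$clusters))
    jsonlite::write_json(payload, out, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  invisible(res)
}

#' Write a synthetic dataset to disk
#'
#' Generates a toy genome plus a planted-cell-type accessibility matrix
#' (see [simulate_peak_matrix()]) and writes every file the pipeline
#' reads: `genes.gtf`, `ccres.bed`, `peaks.bed`, `matrix.mtx`,
#' `barcodes.tsv`, `connections.csv`, `truth_labels.tsv`, `markers.txt`,
#' `housekeeping.txt`, plus the `config.yaml` used.
#'
#' @param outdir Output directory.
#' @param config A [sim_config()].
#' @param force Overwrite an existing non-empty directory.
#' @return The `synthetic_dataset`, invisibly.
#' @export
run_simulate <- function(outdir, config = sim_config(), force = FALSE) {
  if (dir.exists(outdir) && length(dir(outdir)) && !force)
    stop("output directory exists and is not empty (use force = TRUE)")
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  ann <- make_toy_genome(n_genes = config$n_genes,
                         enhancers_per_gene = config$enhancers_per_gene,
                         seed = config$seed)
  ds <- simulate_peak_matrix(ann, config)
  write_gtf(ds$annotation, file.path(outdir, "genes.gtf"))
  .write_regions_bed(ds$annotation$regions, file.path(outdir, "ccres.bed"))
  p <- ds$peaks
  writeLines(paste(as.character(GenomicRanges::seqnames(p)),
                   GenomicRanges::start(p) - 1L, GenomicRanges::end(p),
                   sep = "\t"),
             file.path(outdir, "peaks.bed"))
  Matrix::writeMM(ds$counts, file.path(outdir, "matrix.mtx"))
  writeLines(colnames(ds$counts), file.path(outdir, "barcodes.tsv"))
  write_connections(ds$truth_connections, file.path(outdir, "connections.csv"))
  utils::write.table(data.frame(barcode = names(ds$truth_labels),
                                cluster = ds$truth_labels),
                     file.path(outdir, "truth_labels.tsv"),
                     sep = "\t", row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  writeLines(ds$truth_gene_sets$markers, file.path(outdir, "markers.txt"))
  writeLines(ds$truth_gene_sets$housekeeping, file.path(outdir, "housekeeping.txt"))
  yaml::write_yaml(unclass(config), file.path(outdir, "config.yaml"))
  invisible(ds)
}

.write_regions_bed <- function(regions, path) {
  inv <- c(promoter = "prom", enhancer_distal = "enhD", other = "other")
  writeLines(paste(as.character(GenomicRanges::seqnames(regions)),
                   GenomicRanges::start(regions) - 1L,
                   GenomicRanges::end(regions),
                   sprintf("R%d", seq_along(regions)), 0L, ".",
                   inv[regions$label],
                   sep = "\t"),
             path)
  invisible(path)
}
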