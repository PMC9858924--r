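# The central constructor: from a binary peak-by-cell matrix plus a genome
# annotation to a normalized gene activity matrix, via peak labeling,
# promoter/enhancer/exon association maps, and the weighted combination.

#' Build a genomic-annotated gene activity matrix
#'
#' Runs the full construction: (1) label peaks `prom`/`enhD`/`exon`/`empty`
#' against the annotation; (2) associate promoter peaks with genes
#' (TSS-first, then promoter-window; golden rule: genes without a promoter
#' peak are excluded); (3) obtain co-accessibility connections (from
#' `connections`, or the windowed-correlation estimator when absent),
#' threshold them at `cam` (mean positive score) and `d_th`, and keep
#' prom-enhD pairs; (4) weight exon peaks by `exp(-d/decay_scale)` from the
#' TSS; (5) combine `wp*P + wc*C + we*E` and normalize per cell.
#'
#' @param counts Binary peaks-by-cells matrix (sparse `Matrix` or base
#'   matrix). Row names must be peak ids (`chr:start-end`, BED
#'   coordinates) unless `peaks` is given; column names are cell barcodes.
#' @param annotation A [gene_annotation()].
#' @param connections Optional [connection_set()] (or data.frame accepted
#'   by it) of co-accessibility scores; estimated from `counts` when `NULL`.
#' @param peaks Optional `GRanges` of peak intervals in row order.
#' @param config A [gagam_config()]; individual arguments below override
#'   nothing — set them through the config.
#' @return An object of class `gagam`: list with
#'   \describe{
#'     \item{gam}{normalized genes-by-cells sparse matrix (rows = Gp)}
#'     \item{components}{the unnormalized `P`, `C`, `E` matrices}
#'     \item{raw}{the unnormalized combined matrix}
#'     \item{weights, normalized}{the combination weights and method}
#'     \item{labels}{the `labeled_peaks` object}
#'     \item{maps}{`GP`, `PE`, `GI` association maps}
#'     \item{connections}{the filtered `connection_set` (with `cam`)}
#'     \item{config}{the configuration snapshot}
#'   }
#' @examples
#' ds <- worked_example()
#' g <- gagam(ds$counts, ds$annotation, connections = ds$connections)
#' summary(g)
#' @export
gagam <- function(counts, annotation, connections = NULL, peaks = NULL,
                  config = gagam_config()) {
  stopifnot(inherits(annotation, "gene_annotation"))
  config <- validate_config(config)
  D <- .as_binary_matrix(counts)
  if (is.null(peaks)) {
    if (is.null(rownames(D))) stop("counts needs peak-id rownames or 'peaks'")
    peaks <- parse_peak_ids(rownames(D))
  } else {
    if (is.null(names(peaks))) names(peaks) <- peak_id(peaks)
    if (is.null(rownames(D))) rownames(D) <- names(peaks)
  }
  stopifnot(length(peaks) == nrow(D))
  if (is.null(colnames(D))) colnames(D) <- sprintf("cell%d", seq_len(ncol(D)))

  lps <- label_peaks(peaks, annotation, mode = config$overlap_mode,
                     tss_width = config$tss_width,
                     strand_aware = config$strand_aware)

  GP <- build_gene_promoter_map(lps, annotation,
                                upstream_bp = config$upstream_bp,
                                strand_aware = config$strand_aware)
  if (nrow(GP$matrix) == 0L)
    stop("no gene passes the golden rule (no promoter peak associated with any gene)")

  if (is.null(connections)) {
    connections <- estimate_coaccessibility(D, peaks,
                                            window_bp = config$coaccess_window_bp,
                                            d_th = config$d_th)
  } else if (is.data.frame(connections)) {
    connections <- connection_set(connections, d_th = config$d_th)
  }
  stopifnot(inherits(connections, "connection_set"))
  fcs <- if (nrow(connections$connections) == 0L) {
    cs <- connections; cs$filtered <- TRUE; cs$cam <- NA_real_; cs
  } else {
    tryCatch(
      filter_connections(connections, lps, d_th = config$d_th,
                         cam_include_negatives = config$cam_include_negatives),
      error = function(e) {
        warning("co-accessibility contribution empty: ", conditionMessage(e))
        cs <- connections
        cs$connections <- cs$connections[0, , drop = FALSE]
        cs$filtered <- TRUE
        cs
      })
  }
  PE <- build_connection_map(fcs, lps)
  GI <- build_exon_map(lps, annotation, gene_ids = rownames(GP$matrix),
                       decay_scale = config$decay_scale,
                       mode = config$overlap_mode,
                       strand_aware = config$strand_aware)

  P <- build_promoter_matrix(GP, D, binarize = config$binarize_promoter)
  C <- build_coaccessibility_matrix(GP, PE, D)
  E <- build_exon_matrix(GI, D)

  out <- combine_activity(P, C, E, weights = config$weights)
  out$raw <- out$gam
  out <- normalize_gam(out, method = config$normalization)
  out$labels <- lps
  out$maps <- list(GP = GP, PE = PE, GI = GI)
  out$connections <- fcs
  out$config <- config
  out
}

#' @export
print.gagam <- function(x, ...) {
  cat(sprintf("gagam: %d genes x %d cells (weights wp=%g wc=%g we=%g, normalization: %s)\n",
              nrow(x$gam), ncol(x$gam),
              x$weights["wp"], x$weights["wc"], x$weights["we"], x$normalized))
  if (!is.null(x$labels)) {
    s <- label_summary(x$labels)
    cat(sprintf("peaks: %d total (%d prom, %d enhD, %d exon, %d empty)\n",
                s[["total"]], s[["prom"]], s[["enhD"]], s[["exon"]], s[["empty"]]))
  }
  if (!is.null(x$connections) && !is.na(x$connections$cam))
    cat(sprintf("connections: %d retained (cam = %.4g, d_th = %g bp)\n",
                nrow(x$connections$connections), x$connections$cam,
                x$connections$d_th))
  invisible(x)
}

#' @export
summary.gagam <- function(object, ...) {
  s <- if (!is.null(object$labels)) label_summary(object$labels) else NULL
  act <- object$gam@x
  out <- list(
    n_genes = nrow(object$gam),
    n_cells = ncol(object$gam),
    labels = s,
    weights = object$weights,
    normalized = object$normalized,
    cam = if (!is.null(object$connections)) object$connections$cam else NA_real_,
    n_connections = if (!is.null(object$connections))
      nrow(object$connections$connections) else NA_integer_,
    sparsity = 1 - length(act) / prod(dim(object$gam)),
    mean_nonzero_activity = if (length(act)) mean(act) else 0)
  class(out) <- "summary.gagam"
  out
}

#' @export
print.summary.gagam <- function(x, ...) {
  cat(sprintf("gene activity matrix: %d genes x %d cells\n", x$n_genes, x$n_cells))
  if (!is.null(x$labels)) {
    cat("peak labels: ")
    cat(paste(sprintf("%s=%d", names(x$labels), x$labels), collapse = ", "), "\n")
  }
  cat(sprintf("weights: wp=%g wc=%g we=%g; normalization: %s\n",
              x$weights["wp"], x$weights["wc"], x$weights["we"], x$normalized))
  if (!is.na(x$cam))
    cat(sprintf("retained connections: %d (cam = %.4g)\n", x$n_connections, x$cam))
  cat(sprintf("sparsity: %.1f%%; mean nonzero activity: %.4g\n",
              100 * x$sparsity, x$mean_nonzero_activity))
  invisible(x)
}

#' @export
dim.gagam <- function(x) dim(x$gam)

#' @export
as.matrix.gagam <- function(x, ...) as.matrix(x$gam)

#' Extract the activity matrix
#'
#' @param x A `gagam` object.
#' @param component `"gam"` (default, the normalized combined matrix),
#'   `"raw"` (pre-normalization), or one of `"P"`, `"C"`, `"E"`.
#' @return Sparse genes-by-cells matrix.
#' @export
activity <- function(x, component = c("gam", "raw", "P", "C", "E")) {
  stopifnot(inherits(x, "gagam"))
  component <- match.arg(component)
  switch(component, gam = x$gam, raw = x$raw, x$components[[component]])
}
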