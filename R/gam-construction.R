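# Assembly of the gene activity matrix from labeled peaks:
#   P = binarize(GP x D_p)      promoter contribution (binary)
#   C = GP x PE x D_e           promoter-enhancer co-accessibility
#   E = GI x D_i                exon contribution, exp(-d/scale) weighted
#   GAM = wp*P + wc*C + we*E    binary weights, then per-cell normalization
#
# The golden rule: a gene enters the matrix only if it has at least one
# associated promoter peak; everything downstream is restricted to that
# gene set (Gp).

#' Associate promoter peaks with genes (GP map)
#'
#' A promoter-labeled peak is associated with gene `g` iff it covers `g`'s
#' TSS region, or it covers *no* gene's TSS and intersects `g`'s enlarged
#' gene body ([derive_promoter_window()]). The TSS route takes priority so
#' that, at divergent gene pairs sharing a promoter signature, the peak is
#' attributed to the gene whose TSS it actually covers rather than to the
#' most-overlapping body. Genes with no associated promoter peak are
#' excluded (golden rule); a peak may associate with several genes when it
#' covers several TSSs or windows.
#'
#' @param lps A `labeled_peaks` object.
#' @param annotation A [gene_annotation()].
#' @param upstream_bp Promoter-window extension (default 500 bp).
#' @param strand_aware Window/TSS orientation, see [derive_promoter_window()].
#' @return List of class `gene_peak_map` with `matrix` (sparse binary
#'   genes-by-promoter-peaks, rows = Gp gene ids, cols = prom peak ids in
#'   label order), `kind = "promoter"`, and `n_multi_gene` (count of peaks
#'   associated with more than one gene).
#' @export
build_gene_promoter_map <- function(lps, annotation, upstream_bp = 500L,
                                    strand_aware = TRUE) {
  stopifnot(inherits(lps, "labeled_peaks"), inherits(annotation, "gene_annotation"))
  genes <- annotation$genes
  prom_idx <- which(lps$labels == "prom")
  prom_peaks <- lps$peaks[prom_idx]
  gid <- genes$gene_id
  if (!length(prom_idx) || !length(genes)) {
    m <- Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                              dims = c(0L, length(prom_idx)),
                              dimnames = list(character(0), names(prom_peaks)))
    return(structure(list(matrix = m, kind = "promoter", n_multi_gene = 0L),
                     class = "gene_peak_map"))
  }
  win <- derive_promoter_window(genes, upstream_bp = upstream_bp,
                                strand_aware = strand_aware)
  tss_hits <- lps$tss_hits[prom_idx]
  covers <- lengths(tss_hits) > 0L
  ii <- integer(0); jj <- integer(0)
  if (any(covers)) {
    gi <- match(unlist(tss_hits[covers]), gid)
    jj <- c(jj, rep(which(covers), lengths(tss_hits[covers])))
    ii <- c(ii, gi)
  }
  if (any(!covers)) {
    sub <- which(!covers)
    h <- GenomicRanges::findOverlaps(win, prom_peaks[sub], type = "any",
                                     ignore.strand = TRUE)
    ii <- c(ii, S4Vectors::queryHits(h))
    jj <- c(jj, sub[S4Vectors::subjectHits(h)])
  }
  keep_genes <- sort(unique(ii))
  m <- Matrix::sparseMatrix(i = match(ii, keep_genes), j = jj, x = 1,
                            dims = c(length(keep_genes), length(prom_idx)),
                            dimnames = list(gid[keep_genes], names(prom_peaks)))
  m@x[] <- 1  # duplicate (i,j) pairs sum; force back to binary
  n_multi <- sum(Matrix::colSums(m) > 1)
  structure(list(matrix = m, kind = "promoter", n_multi_gene = as.integer(n_multi)),
            class = "gene_peak_map")
}

#' Promoter contribution matrix P
#'
#' `P = GP x D_p` over the promoter-peak rows of `D`, then binarized to
#' {0,1} by default (a gene with several accessible promoter peaks in a
#' cell still scores 1). `binarize = FALSE` keeps the raw counts.
#'
#' @param GP A `gene_peak_map` of kind `"promoter"`.
#' @param D Binary peaks-by-cells matrix with rownames covering the GP
#'   peak columns.
#' @param binarize Clip entries to {0,1} (default `TRUE`).
#' @return Sparse genes-by-cells matrix.
#' @export
build_promoter_matrix <- function(GP, D, binarize = TRUE) {
  stopifnot(inherits(GP, "gene_peak_map"), GP$kind == "promoter")
  D <- .as_binary_matrix(D)
  pk <- colnames(GP$matrix)
  if (!all(pk %in% rownames(D))) stop("promoter peaks missing from the data matrix")
  P <- GP$matrix %*% D[pk, , drop = FALSE]
  if (binarize) {
    P <- as(P, "CsparseMatrix")
    P@x <- as.numeric(P@x > 0)
    P <- Matrix::drop0(P)
  }
  P
}

#' Promoter-enhancer association matrix PE
#'
#' Sparse promoter-peaks-by-enhancer-peaks matrix whose entries are the
#' retained co-accessibility scores of a *filtered* connection set
#' ([filter_connections()]); 0 elsewhere.
#'
#' @param cs A filtered `connection_set` (orientation prom, enhD).
#' @param lps The `labeled_peaks` object used for filtering.
#' @return List of class `gene_peak_map` with `kind = "connection"`;
#'   rows = prom peak ids, cols = enhD peak ids (label order).
#' @export
build_connection_map <- function(cs, lps) {
  stopifnot(inherits(cs, "connection_set"), inherits(lps, "labeled_peaks"))
  if (!isTRUE(cs$filtered)) stop("connection set must be filtered first")
  prom_ids <- names(lps$peaks)[lps$labels == "prom"]
  enh_ids <- names(lps$peaks)[lps$labels == "enhD"]
  df <- cs$connections
  i <- match(df$p1, prom_ids); j <- match(df$p2, enh_ids)
  ok <- !is.na(i) & !is.na(j)
  m <- Matrix::sparseMatrix(i = i[ok], j = j[ok], x = df$ca[ok],
                            dims = c(length(prom_ids), length(enh_ids)),
                            dimnames = list(prom_ids, enh_ids))
  structure(list(matrix = m, kind = "connection"), class = "gene_peak_map")
}

#' Co-accessibility contribution matrix C
#'
#' `C = GP x PE x D_e`: for each gene and cell, the sum of co-accessibility
#' scores of the gene's promoter peaks with connected enhancer peaks that
#' are accessible in that cell.
#'
#' @param GP Promoter `gene_peak_map`.
#' @param PE Connection `gene_peak_map` from [build_connection_map()].
#' @param D Binary peaks-by-cells matrix.
#' @return Sparse genes-by-cells matrix.
#' @export
build_coaccessibility_matrix <- function(GP, PE, D) {
  stopifnot(inherits(GP, "gene_peak_map"), GP$kind == "promoter",
            inherits(PE, "gene_peak_map"), PE$kind == "connection")
  D <- .as_binary_matrix(D)
  if (!identical(colnames(GP$matrix), rownames(PE$matrix)))
    stop("GP columns and PE rows must list the same promoter peaks")
  ek <- colnames(PE$matrix)
  if (!all(ek %in% rownames(D))) stop("enhancer peaks missing from the data matrix")
  De <- if (length(ek)) D[ek, , drop = FALSE]
        else Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                                  dims = c(0L, ncol(D)),
                                  dimnames = list(character(0), colnames(D)))
  GP$matrix %*% PE$matrix %*% De
}

#' Exponential distance decay for exon peaks
#'
#' `exp(-d / scale)` with `scale = 5000` bp by default: exon peaks near the
#' promoter weigh most, preventing long genes (more exon peaks) from being
#' over-represented.
#'
#' @param d Non-negative distance(s) in bp.
#' @param scale Decay scale in bp.
#' @return Weight(s) in (0, 1].
#' @export
exon_weight <- function(d, scale = 5000) {
  if (any(d < 0)) stop("negative distance")
  stopifnot(scale > 0)
  exp(-d / scale)
}

#' Associate exon peaks with genes (GI map)
#'
#' `GI[g, p] = exon_weight(|center(p) - tss(g)|)` iff peak `p` is
#' exon-labeled and contained in (literal mode) / intersecting (relaxed
#' mode) an exon of `g`, and `g` has a promoter peak (golden rule: genes
#' outside `Gp` receive nothing). Distances are center-of-peak to TSS
#' position in bp.
#'
#' @param lps A `labeled_peaks` object.
#' @param annotation A [gene_annotation()].
#' @param gene_ids Genes in Gp (row universe), e.g. `rownames(GP$matrix)`.
#' @param decay_scale Decay scale in bp (default 5000).
#' @param mode Overlap semantics, as in [label_peaks()].
#' @param strand_aware TSS position orientation.
#' @return List of class `gene_peak_map`, `kind = "exon"`; rows = `gene_ids`,
#'   cols = exon peak ids (label order), entries in (0, 1].
#' @export
build_exon_map <- function(lps, annotation, gene_ids, decay_scale = 5000,
                           mode = c("literal_containment", "any_overlap"),
                           strand_aware = TRUE) {
  mode <- match.arg(mode)
  stopifnot(inherits(lps, "labeled_peaks"), inherits(annotation, "gene_annotation"))
  exon_idx <- which(lps$labels == "exon")
  exon_peaks <- lps$peaks[exon_idx]
  genes <- annotation$genes
  sel <- match(gene_ids, genes$gene_id)
  if (anyNA(sel)) stop("unknown gene ids: ",
                       paste(gene_ids[is.na(sel)], collapse = ", "))
  m <- Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                            dims = c(length(gene_ids), length(exon_idx)),
                            dimnames = list(gene_ids, names(exon_peaks)))
  if (length(exon_idx) && length(gene_ids)) {
    ex <- unlist(annotation$exons[gene_ids], use.names = FALSE)
    ex_gene <- rep(seq_along(gene_ids), lengths(annotation$exons[gene_ids]))
    type <- if (mode == "literal_containment") "within" else "any"
    h <- GenomicRanges::findOverlaps(exon_peaks, ex, type = type,
                                     ignore.strand = TRUE)
    if (length(h)) {
      pj <- S4Vectors::queryHits(h)
      gi <- ex_gene[S4Vectors::subjectHits(h)]
      dup <- duplicated(cbind(gi, pj))
      pj <- pj[!dup]; gi <- gi[!dup]
      tsspos <- .tss_position(genes[sel], strand_aware = strand_aware)
      d <- abs(.peak_center(exon_peaks[pj]) - tsspos[gi])
      m <- Matrix::sparseMatrix(i = gi, j = pj,
                                x = exon_weight(d, scale = decay_scale),
                                dims = dim(m), dimnames = dimnames(m))
    }
  }
  structure(list(matrix = m, kind = "exon"), class = "gene_peak_map")
}

#' Exon contribution matrix E
#'
#' `E = GI x D_i` over the exon-peak rows of `D`: real-valued, an exon peak
#' contributes its decay weight in every cell where it is accessible (even
#' when the gene's promoter peak is closed in that cell).
#'
#' @param GI Exon `gene_peak_map` from [build_exon_map()].
#' @param D Binary peaks-by-cells matrix.
#' @return Sparse genes-by-cells matrix.
#' @export
build_exon_matrix <- function(GI, D) {
  stopifnot(inherits(GI, "gene_peak_map"), GI$kind == "exon")
  D <- .as_binary_matrix(D)
  pk <- colnames(GI$matrix)
  if (!all(pk %in% rownames(D))) stop("exon peaks missing from the data matrix")
  Di <- if (length(pk)) D[pk, , drop = FALSE]
        else Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                                  dims = c(0L, ncol(D)),
                                  dimnames = list(character(0), colnames(D)))
  GI$matrix %*% Di
}

#' Combine the three contributions into a gene activity matrix
#'
#' `GAM = wp*P + wc*C + we*E` with binary weights. The weights are set a
#' priori (never estimated); the two standard presets are `(1,1,1)` (all
#' contributions) and `(1,1,0)` (no exon term).
#'
#' @param P,C,E Genes-by-cells matrices of identical shape.
#' @param weights Numeric length-3 vector `(wp, wc, we)`, each 0 or 1.
#' @return Object of class `gagam` (unnormalized): list with `gam`, the
#'   `components` list, `weights`, `normalized = "none"`.
#' @export
combine_activity <- function(P, C, E, weights = c(1, 1, 1)) {
  stopifnot(length(weights) == 3, all(weights %in% c(0, 1)))
  if (!all(dim(P) == dim(C)) || !all(dim(P) == dim(E)))
    stop("P, C, E must have identical shapes")
  gam <- weights[1] * P + weights[2] * C + weights[3] * E
  structure(list(gam = gam,
                 components = list(P = P, C = C, E = E),
                 weights = setNames(as.numeric(weights), c("wp", "wc", "we")),
                 normalized = "none"),
            class = "gagam")
}

#' Normalize a gene activity matrix per cell
#'
#' `cell_total` (the default) is a size-factor normalization: every nonzero
#' cell column is scaled to the median of the nonzero raw column sums, so
#' that per-cell totals are comparable; all-zero cells stay zero.
#' `log_cell_total` additionally applies `log(1 + x)`. `none` leaves the
#' matrix untouched.
#'
#' @param x A `gagam` object (or a bare genes-by-cells matrix).
#' @param method `"cell_total"`, `"log_cell_total"` or `"none"`.
#' @return The object with `x$gam` normalized and `normalized` set; for a
#'   bare matrix, the normalized matrix.
#' @export
normalize_gam <- function(x, method = c("cell_total", "log_cell_total", "none")) {
  method <- match.arg(method)
  m <- if (inherits(x, "gagam")) x$gam else x
  if (method != "none") {
    cs <- Matrix::colSums(m)
    nz <- cs > 0
    if (any(nz)) {
      med <- stats::median(cs[nz])
      fac <- ifelse(nz, med / cs, 0)
      m <- m %*% Matrix::Diagonal(x = fac, n = length(fac))
      colnames(m) <- colnames(if (inherits(x, "gagam")) x$gam else x)
    }
    if (method == "log_cell_total") m <- log1p(m)
  }
  if (inherits(x, "gagam")) {
    x$gam <- m
    x$normalized <- method
    x
  } else m
}
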