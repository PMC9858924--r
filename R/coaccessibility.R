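# Peak-peak co-accessibility: file reader, windowed-correlation surrogate
# estimator, automatic threshold (cam), and the promoter-enhancer filter.
#
# A connection is an unordered peak pair with a co-accessibility score ca
# (expected in [-1, 1]) and a center-to-center genomic distance d in bp.
# Retained connections must pair one prom peak with one enhD peak, have
# ca >= cam (cam = mean of the positive scores by default) and d <= d_th
# (default 30,000 bp, the usual guideline for direct regulatory links).

#' Construct a connection set
#'
#' @param connections `data.frame` with columns `p1`, `p2` (peak ids),
#'   `ca` (score) and `d` (distance in bp); duplicate unordered pairs are
#'   collapsed keeping the maximum score.
#' @param d_th Distance threshold in bp used at filtering time.
#' @return Object of class `connection_set`: the table plus `cam` (filled
#'   by [compute_ca_threshold()]), `d_th`, `filtered` flag and a `dropped`
#'   counter vector.
#' @export
connection_set <- function(connections, d_th = 30000) {
  stopifnot(is.data.frame(connections),
            all(c("p1", "p2", "ca", "d") %in% names(connections)))
  df <- connections[, c("p1", "p2", "ca", "d")]
  df$p1 <- as.character(df$p1); df$p2 <- as.character(df$p2)
  if (any(df$p1 == df$p2)) stop("self-connections (p1 == p2) are not allowed")
  if (any(df$d < 0, na.rm = TRUE)) stop("negative distances")
  # collapse unordered duplicates, keeping the maximum score
  key <- ifelse(df$p1 < df$p2, paste(df$p1, df$p2), paste(df$p2, df$p1))
  if (anyDuplicated(key)) {
    ord <- order(key, -df$ca)
    df <- df[ord[!duplicated(key[ord])], , drop = FALSE]
  }
  rownames(df) <- NULL
  structure(list(connections = df, cam = NA_real_, d_th = d_th,
                 filtered = FALSE, dropped = c(na_score = 0L, unknown_peak = 0L)),
            class = "connection_set")
}

#' @export
print.connection_set <- function(x, ...) {
  cat(sprintf("connection_set: %d connection(s)%s; cam = %s, d_th = %g bp\n",
              nrow(x$connections), if (x$filtered) " (filtered)" else "",
              if (is.na(x$cam)) "unset" else format(x$cam), x$d_th))
  invisible(x)
}

#' Read a co-accessibility connections table
#'
#' Expects a CSV/TSV with (case-insensitive) columns `Peak1`, `Peak2`,
#' `coaccess`. Peak ids may use either the `chr1:100-600` or the
#' `chr1_100_600` dialect. Distances are computed from the parsed peak
#' centers when no `dist`/`d` column is present. Rows with missing scores
#' are dropped (counted in `dropped["na_score"]`); duplicate unordered
#' pairs keep the maximum score.
#'
#' @param path CSV or TSV file path.
#' @param d_th Distance threshold stored on the result.
#' @return A [connection_set()].
#' @export
read_connections <- function(path, d_th = 30000) {
  if (!file.exists(path)) stop("no such file: ", path)
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  nm <- tolower(names(df))
  i1 <- match("peak1", nm); i2 <- match("peak2", nm); ic <- match("coaccess", nm)
  if (anyNA(c(i1, i2, ic)))
    stop("connections file needs Peak1, Peak2, coaccess columns")
  ca <- suppressWarnings(as.numeric(df[[ic]]))
  keep <- !is.na(ca)
  n_na <- sum(!keep)
  df <- df[keep, , drop = FALSE]; ca <- ca[keep]
  g1 <- parse_peak_ids(as.character(df[[i1]]))
  g2 <- parse_peak_ids(as.character(df[[i2]]))
  id <- match("dist", nm); if (is.na(id)) id <- match("d", nm)
  d <- if (!is.na(id)) as.numeric(df[[id]]) else abs(.peak_center(g1) - .peak_center(g2))
  cs <- connection_set(data.frame(p1 = names(g1), p2 = names(g2),
                                  ca = ca, d = d,
                                  stringsAsFactors = FALSE),
                       d_th = d_th)
  cs$dropped["na_score"] <- n_na
  cs
}

#' Write a connections table
#'
#' Emits `Peak1,Peak2,coaccess,dist` CSV using the underscore peak-id
#' dialect (`chr1_100_600`).
#'
#' @param cs A `connection_set`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_connections <- function(cs, path) {
  stopifnot(inherits(cs, "connection_set"))
  und <- function(ids) gsub("[:-]", "_", ids)
  df <- data.frame(Peak1 = und(cs$connections$p1),
                   Peak2 = und(cs$connections$p2),
                   coaccess = cs$connections$ca,
                   dist = cs$connections$d)
  utils::write.table(df, path, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Windowed-correlation co-accessibility estimator
#'
#' A deterministic, desk-scale surrogate for a full co-accessibility
#' computation: for every peak pair on the same chromosome whose centers
#' lie within `window_bp`, the score is the Pearson correlation of the two
#' binary accessibility vectors across cells. Non-positive scores are
#' dropped; peaks accessible in no cell or in every cell have undefined
#' correlation and their pairs are skipped (counted). This is *not* a
#' regularized-inverse-covariance method; when a connections file from a
#' dedicated co-accessibility tool is available, prefer
#' [read_connections()].
#'
#' @param D Binary peaks-by-cells matrix (`Matrix` sparse or base), rows
#'   named by peak id, or with `peaks` supplying the intervals.
#' @param peaks Optional `GRanges` of peak intervals, in row order of `D`;
#'   parsed from `rownames(D)` when absent.
#' @param window_bp Maximum center-to-center distance considered.
#' @param d_th Distance threshold stored on the result.
#' @return A [connection_set()] (unfiltered, `ca > 0` only).
#' @export
estimate_coaccessibility <- function(D, peaks = NULL, window_bp = 500000,
                                     d_th = 30000) {
  D <- .as_binary_matrix(D)
  if (ncol(D) < 2L) stop("need at least 2 cells")
  if (is.null(peaks)) peaks <- parse_peak_ids(rownames(D))
  stopifnot(length(peaks) == nrow(D))
  ids <- rownames(D)
  centers <- .peak_center(peaks)
  chrom <- as.character(GenomicRanges::seqnames(peaks))
  ncell <- ncol(D)
  rs <- Matrix::rowSums(D)
  degenerate <- rs == 0 | rs == ncell
  out <- list(); skipped <- 0L
  for (ch in unique(chrom)) {
    idx <- which(chrom == ch)
    if (length(idx) < 2L) next
    idx <- idx[order(centers[idx])]
    cmb <- utils::combn(seq_along(idx), 2L)
    i <- idx[cmb[1L, ]]; j <- idx[cmb[2L, ]]
    close_enough <- abs(centers[i] - centers[j]) <= window_bp
    i <- i[close_enough]; j <- j[close_enough]
    if (!length(i)) next
    bad <- degenerate[i] | degenerate[j]
    skipped <- skipped + sum(bad)
    i <- i[!bad]; j <- j[!bad]
    if (!length(i)) next
    X <- as.matrix(D[idx, , drop = FALSE])
    pos <- match(seq_len(nrow(D)), idx)
    cross <- tcrossprod(X)
    sx <- rs[idx]
    num <- ncell * cross - outer(sx, sx)
    den <- sqrt(outer(ncell * sx - sx^2, ncell * sx - sx^2))
    ca <- num[cbind(pos[i], pos[j])] / den[cbind(pos[i], pos[j])]
    keep <- ca > 0
    if (any(keep)) {
      out[[length(out) + 1L]] <- data.frame(
        p1 = ids[i[keep]], p2 = ids[j[keep]], ca = ca[keep],
        d = abs(centers[i[keep]] - centers[j[keep]]),
        stringsAsFactors = FALSE)
    }
  }
  df <- if (length(out)) do.call(rbind, out)
        else data.frame(p1 = character(0), p2 = character(0),
                        ca = numeric(0), d = numeric(0))
  cs <- connection_set(df, d_th = d_th)
  cs$dropped <- c(cs$dropped, degenerate_pair = skipped)
  cs
}

#' Co-accessibility retention threshold (cam)
#'
#' The arithmetic mean of the positive co-accessibility scores (by
#' default). Because scores can be negative and negative scores are
#' treated as non-connections downstream, the mean is taken over `ca > 0`;
#' `include_negatives = TRUE` averages all non-zero scores instead.
#'
#' @param cs A `connection_set`.
#' @param include_negatives Average over `ca != 0` instead of `ca > 0`.
#' @return The threshold (numeric scalar).
#' @export
compute_ca_threshold <- function(cs, include_negatives = FALSE) {
  stopifnot(inherits(cs, "connection_set"))
  ca <- cs$connections$ca
  sel <- if (include_negatives) ca != 0 else ca > 0
  if (!any(sel)) stop("no usable connections: no ",
                      if (include_negatives) "non-zero" else "positive",
                      " co-accessibility scores")
  mean(ca[sel])
}

#' Filter connections to strong promoter-enhancer pairs
#'
#' Retains connections whose endpoints are one `prom`-labeled and one
#' `enhD`-labeled peak, with `ca >= cam` and `d <= d_th`; orientation is
#' normalized to (prom, enhD). Connections referencing peaks absent from
#' the labeled set are dropped and counted. The operation is idempotent.
#'
#' @param cs A `connection_set`.
#' @param lps A `labeled_peaks` object covering the referenced peaks.
#' @param cam Score threshold; computed via [compute_ca_threshold()] when
#'   `NULL` (using `cam_include_negatives`).
#' @param d_th Distance threshold in bp (default taken from `cs`).
#' @param cam_include_negatives See [compute_ca_threshold()].
#' @return The filtered `connection_set` (with `cam` recorded and
#'   `filtered = TRUE`).
#' @export
filter_connections <- function(cs, lps, cam = NULL, d_th = cs$d_th,
                               cam_include_negatives = FALSE) {
  stopifnot(inherits(cs, "connection_set"), inherits(lps, "labeled_peaks"))
  if (is.null(cam)) {
    cam <- if (isTRUE(cs$filtered) && !is.na(cs$cam)) cs$cam
           else compute_ca_threshold(cs, include_negatives = cam_include_negatives)
  }
  lab <- setNames(as.character(lps$labels), names(lps$peaks))
  df <- cs$connections
  l1 <- lab[df$p1]; l2 <- lab[df$p2]
  known <- !is.na(l1) & !is.na(l2)
  n_unknown <- sum(!known)
  pairtype <- (l1 == "prom" & l2 == "enhD") | (l1 == "enhD" & l2 == "prom")
  keep <- known & pairtype & df$ca >= cam & df$d <= d_th
  keep[is.na(keep)] <- FALSE
  df <- df[keep, , drop = FALSE]
  # orient (prom, enhD)
  flip <- lab[df$p1] == "enhD"
  if (any(flip)) {
    tmp <- df$p1[flip]; df$p1[flip] <- df$p2[flip]; df$p2[flip] <- tmp
  }
  rownames(df) <- NULL
  out <- cs
  out$connections <- df
  out$cam <- cam
  out$d_th <- d_th
  out$filtered <- TRUE
  out$dropped["unknown_peak"] <- out$dropped["unknown_peak"] + n_unknown
  out
}

# coerce to a sparse 0/1 Matrix, preserving dimnames
.as_binary_matrix <- function(D) {
  if (!is(D, "Matrix")) D <- Matrix::Matrix(as.matrix(D), sparse = TRUE)
  if (is(D, "nMatrix") || is(D, "lMatrix")) D <- as(D, "dMatrix")
  D <- as(D, "CsparseMatrix")
  if (any(D@x != 0 & D@x != 1)) {
    warning("matrix entries outside {0,1}; binarizing (> 0 -> 1)")
    D@x <- as.numeric(D@x > 0)
    D <- Matrix::drop0(D)
  }
  D
}
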