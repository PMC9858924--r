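# Evaluation toolkit: TF-IDF/LSI embedding, cell clustering, chance-
# corrected partition agreement (ARI, AMI), Gini-based cluster
# informativeness (RAGI), and one-vs-rest differential activity.

#' TF-IDF + truncated SVD (LSI) embedding
#'
#' Term frequency per cell (column) scaled by the log inverse document
#' frequency of each feature (row), followed by a truncated SVD. The first
#' component is strongly correlated with per-cell depth in accessibility
#' data and is dropped by default. Deterministic (LAPACK SVD, no random
#' initialization).
#'
#' @param M Non-negative features-by-cells matrix.
#' @param n_components Number of singular vectors to compute
#'   (`< min(dim(M))`).
#' @param drop_first Drop the first (depth) component.
#' @return Cells-by-components matrix (`V %*% diag(d)`), rows named by
#'   cell.
#' @export
lsi_embed <- function(M, n_components = 30L, drop_first = TRUE) {
  if (!is(M, "Matrix")) M <- Matrix::Matrix(as.matrix(M), sparse = TRUE)
  if (all(M == 0)) stop("all-zero matrix")
  if (any(M < 0)) stop("matrix must be non-negative")
  n_components <- as.integer(n_components)
  if (n_components >= min(dim(M)))
    stop("n_components must be < min(dim(M))")
  cs <- Matrix::colSums(M)
  tf <- M %*% Matrix::Diagonal(x = ifelse(cs > 0, 1 / cs, 0), n = ncol(M))
  df <- Matrix::rowSums(M > 0)
  idf <- log(1 + ncol(M) / pmax(df, 1))
  X <- Matrix::Diagonal(x = idf, n = nrow(M)) %*% tf
  s <- svd(as.matrix(X), nu = 0, nv = n_components)
  emb <- s$v[, seq_len(n_components), drop = FALSE] %*%
    diag(s$d[seq_len(n_components)], n_components)
  rownames(emb) <- colnames(M)
  colnames(emb) <- sprintf("LSI%d", seq_len(n_components))
  if (drop_first && ncol(emb) > 1L) emb <- emb[, -1L, drop = FALSE]
  emb
}

#' Cluster cells on an embedding
#'
#' `kmeans` (with `param` = number of clusters) or Leiden community
#' detection (`param` = resolution) on a k-nearest-neighbour graph of the
#' embedding. Deterministic given `seed`; labels are contiguous integers
#' starting at 0.
#'
#' @param embedding Cells-by-components numeric matrix.
#' @param method `"kmeans"` or `"leiden"`.
#' @param param Cluster count (kmeans) or resolution (leiden).
#' @param seed Integer seed.
#' @param knn Neighbourhood size of the Leiden graph.
#' @return Named integer vector of 0-based cluster labels.
#' @export
cluster_cells <- function(embedding, method = c("kmeans", "leiden"),
                          param = 2, seed = 1L, knn = 15L) {
  method <- match.arg(method)
  embedding <- as.matrix(embedding)
  if (!all(is.finite(embedding))) stop("embedding must be finite")
  n <- nrow(embedding)
  if (method == "kmeans") {
    k <- as.integer(param)
    if (k > n) stop("k exceeds the number of cells")
    set.seed(seed)
    km <- stats::kmeans(embedding, centers = k, nstart = 25L, iter.max = 100L)
    lab <- km$cluster
  } else {
    knn <- min(as.integer(knn), n - 1L)
    d <- as.matrix(stats::dist(embedding))
    diag(d) <- Inf
    nn <- apply(d, 1L, function(row) order(row)[seq_len(knn)])
    edges <- rbind(rep(seq_len(n), each = knn), as.vector(nn))
    gr <- igraph::simplify(igraph::graph_from_edgelist(t(edges), directed = FALSE))
    set.seed(seed)
    cl <- igraph::cluster_leiden(gr, resolution = param,
                                 objective_function = "modularity",
                                 n_iterations = 10L)
    lab <- igraph::membership(cl)
  }
  out <- as.integer(factor(lab, levels = unique(lab))) - 1L
  names(out) <- rownames(embedding)
  out
}

# align two label vectors on a shared cell set
.align_partitions <- function(a, b) {
  if (!is.null(names(a)) && !is.null(names(b))) {
    if (!setequal(names(a), names(b))) stop("partitions cover different cells")
    b <- b[names(a)]
  } else if (length(a) != length(b)) {
    stop("partitions cover different cells")
  }
  list(a = as.integer(factor(a)), b = as.integer(factor(b)))
}

#' Adjusted Rand index
#'
#' Rand index corrected for chance under the permutation model, computed
#' from the contingency table of the two partitions. 1 for identical
#' partitions (up to relabeling), about 0 for independent ones; can be
#' negative for partitions that agree less than chance.
#'
#' @param a,b Cluster label vectors over the same cells (matched by names
#'   when both are named).
#' @return Numeric scalar in `[-1, 1]`.
#' @export
ari <- function(a, b) {
  p <- .align_partitions(a, b)
  tab <- table(p$a, p$b)
  n <- sum(tab)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  max_index <- (sum_a + sum_b) / 2
  if (abs(max_index - expected) < .Machine$double.eps * 4) return(1)
  (sum_ij - expected) / (max_index - expected)
}

#' Adjusted mutual information
#'
#' Mutual information corrected by its expectation under the permutation
#' (hypergeometric) model, normalized by the arithmetic mean of the two
#' partition entropies. Robust for unbalanced cluster sizes. 1 for
#' identical partitions; about 0 for independent ones.
#'
#' @inheritParams ari
#' @return Numeric scalar (at most 1).
#' @export
ami <- function(a, b) {
  p <- .align_partitions(a, b)
  tab <- table(p$a, p$b)
  n <- sum(tab)
  ai <- rowSums(tab); bj <- colSums(tab)
  ha <- .entropy(ai); hb <- .entropy(bj)
  if (ha == 0 && hb == 0) return(1)  # both trivial and identical
  mi <- 0
  for (i in seq_along(ai)) for (j in seq_along(bj)) {
    nij <- tab[i, j]
    if (nij > 0) mi <- mi + (nij / n) * log(n * nij / (ai[i] * bj[j]))
  }
  emi <- .expected_mi(ai, bj, n)
  denom <- (ha + hb) / 2 - emi
  if (abs(denom) < .Machine$double.eps * 4)
    denom <- sign(denom + .Machine$double.eps) * .Machine$double.eps * 4
  unname((mi - emi) / denom)
}

.entropy <- function(counts) {
  p <- counts[counts > 0] / sum(counts)
  -sum(p * log(p))
}

# expected mutual information under the hypergeometric model
.expected_mi <- function(ai, bj, n) {
  emi <- 0
  lgn <- lgamma(n + 1)
  for (a in ai) for (b in bj) {
    lo <- max(1, a + b - n)
    hi <- min(a, b)
    if (hi < lo) next
    for (nij in lo:hi) {
      term <- (nij / n) * log(n * nij / (a * b))
      lp <- lgamma(a + 1) + lgamma(b + 1) + lgamma(n - a + 1) + lgamma(n - b + 1) -
        lgn - lgamma(nij + 1) - lgamma(a - nij + 1) - lgamma(b - nij + 1) -
        lgamma(n - a - b + nij + 1)
      emi <- emi + term * exp(lp)
    }
  }
  emi
}

#' Gini index of a non-negative vector
#'
#' Mean absolute difference between all value pairs, scaled by twice the
#' mean: `G = sum_ij |x_i - x_j| / (2 n^2 mean(x))`. 0 for perfectly even
#' vectors, approaching 1 when a single entry carries everything. An
#' all-zero vector returns 0 by convention.
#'
#' @param values Finite non-negative numeric vector.
#' @return Numeric scalar in `[0, 1]`.
#' @export
gini <- function(values) {
  if (any(!is.finite(values))) stop("values must be finite")
  if (any(values < 0)) stop("values must be non-negative")
  n <- length(values)
  if (n == 0L || all(values == 0)) return(0)
  x <- sort(values)
  # equivalent to the double sum, via the sorted-index identity
  (2 * sum(seq_len(n) * x) / (n * sum(x))) - (n + 1) / n
}

#' Marker / housekeeping gene-set pair
#'
#' @param markers,housekeeping Character vectors of gene symbols; must be
#'   disjoint and non-empty.
#' @return Object of class `gene_set_pair`.
#' @export
gene_set_pair <- function(markers, housekeeping) {
  markers <- unique(as.character(markers))
  housekeeping <- unique(as.character(housekeeping))
  if (!length(markers) || !length(housekeeping))
    stop("both gene sets must be non-empty")
  if (length(intersect(markers, housekeeping)))
    stop("marker and housekeeping sets must be disjoint")
  structure(list(markers = markers, housekeeping = housekeeping),
            class = "gene_set_pair")
}

#' Residual average Gini index (RAGI)
#'
#' For every gene, the mean activity per cluster is computed and its Gini
#' index taken over the cluster means: markers of specific cell types
#' should be uneven across clusters (high Gini), housekeeping genes even
#' (low Gini). RAGI is the difference of the two set means; the p-value
#' comes from a two-sided Mann-Whitney test between the two per-gene Gini
#' samples (`test = "t"` switches to a Welch t-test).
#'
#' @param gam A `gagam` object or a genes-by-cells matrix.
#' @param clusters Cluster labels over the matrix columns (>= 2 clusters).
#' @param sets A [gene_set_pair()]; genes absent from the matrix are
#'   skipped with a warning.
#' @param test `"wilcox"` (default) or `"t"`.
#' @return List with `ragi`, `p`, and `per_gene_gini` (data.frame gene,
#'   set, gini).
#' @export
ragi <- function(gam, clusters, sets, test = c("wilcox", "t")) {
  test <- match.arg(test)
  stopifnot(inherits(sets, "gene_set_pair"))
  M <- if (inherits(gam, "gagam")) gam$gam else gam
  cl <- if (!is.null(names(clusters)) && !is.null(colnames(M)))
    clusters[colnames(M)] else clusters
  if (length(cl) != ncol(M) || anyNA(cl))
    stop("clusters must cover every cell of the matrix")
  if (length(unique(cl)) < 2L) stop("need at least 2 clusters")
  mk <- intersect(sets$markers, rownames(M))
  hk <- intersect(sets$housekeeping, rownames(M))
  if (!length(mk)) stop("no marker genes found in the matrix")
  if (!length(hk)) stop("no housekeeping genes found in the matrix")
  skipped <- (length(sets$markers) - length(mk)) +
    (length(sets$housekeeping) - length(hk))
  if (skipped > 0) warning(skipped, " gene(s) absent from the matrix skipped")
  cluster_means <- function(g) {
    v <- as.numeric(M[g, ])
    tapply(v, cl, mean)
  }
  gmk <- vapply(mk, function(g) gini(cluster_means(g)), numeric(1))
  ghk <- vapply(hk, function(g) gini(cluster_means(g)), numeric(1))
  p <- if (test == "wilcox")
    stats::wilcox.test(gmk, ghk, exact = FALSE)$p.value
  else stats::t.test(gmk, ghk)$p.value
  list(ragi = mean(gmk) - mean(ghk), p = p,
       per_gene_gini = data.frame(
         gene = c(mk, hk),
         set = rep(c("marker", "housekeeping"), c(length(mk), length(hk))),
         gini = c(gmk, ghk), row.names = NULL))
}

#' Per-cluster differential-activity ranking
#'
#' One-vs-rest Wilcoxon rank-sum test per gene and cluster; genes are
#' ranked by effect size (difference of in-cluster vs rest means), with
#' the p-value as tie-break, and the top `top_n` per cluster returned.
#'
#' @param gam A `gagam` object or genes-by-cells matrix.
#' @param clusters Cluster labels over the matrix columns (>= 2 clusters).
#' @param top_n Genes returned per cluster.
#' @return data.frame with columns `cluster`, `rank`, `gene`, `effect`
#'   (mean difference), `p`.
#' @export
rank_differential_activity <- function(gam, clusters, top_n = 10L) {
  M <- if (inherits(gam, "gagam")) gam$gam else gam
  cl <- if (!is.null(names(clusters)) && !is.null(colnames(M)))
    clusters[colnames(M)] else clusters
  if (length(cl) != ncol(M) || anyNA(cl))
    stop("clusters must cover every cell of the matrix")
  ids <- sort(unique(cl))
  if (length(ids) < 2L) stop("need at least 2 clusters")
  Md <- as.matrix(M)
  out <- lapply(ids, function(k) {
    inside <- cl == k
    eff <- rowMeans(Md[, inside, drop = FALSE]) -
      rowMeans(Md[, !inside, drop = FALSE])
    p <- apply(Md, 1L, function(v)
      stats::wilcox.test(v[inside], v[!inside], exact = FALSE)$p.value)
    p[is.na(p)] <- 1  # constant genes
    ord <- order(-eff, p)
    top <- ord[seq_len(min(top_n, length(ord)))]
    data.frame(cluster = k, rank = seq_along(top),
               gene = rownames(Md)[top], effect = eff[top], p = p[top],
               row.names = NULL)
  })
  do.call(rbind, out)
}
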