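# Brute-force oracles, written directly in 0-based half-open arithmetic on
# the plain-list fixtures and independent of the package's GRanges path.

.o_contains <- function(as, ae, ach, bs, be, bch) { # a within b
  ach == bch && as >= bs && ae <= be
}
.o_intersects <- function(as, ae, ach, bs, be, bch) {
  ach == bch && as < be && bs < ae
}

oracle_tss <- function(gene, tss_width = 2, strand_aware = TRUE) {
  if (strand_aware && gene$strand == "-")
    c(gene$end0 - tss_width, gene$end0)
  else c(gene$start0, gene$start0 + tss_width)
}

oracle_window <- function(gene, upstream = 500, strand_aware = TRUE) {
  if (strand_aware && gene$strand == "-")
    c(gene$start0, gene$end0 + upstream)
  else c(max(0, gene$start0 - upstream), gene$end0)
}

# per-peak Eq.-style label with strict precedence prom > enhD > exon
oracle_label <- function(fix, mode = "literal_containment",
                         tss_width = 2, strand_aware = TRUE) {
  literal <- mode == "literal_containment"
  hit_region <- function(p, lab) {
    any(vapply(seq_len(nrow(fix$regions)), function(r) {
      if (fix$regions$label[r] != lab) return(FALSE)
      if (literal)
        .o_contains(fix$regions$start0[r], fix$regions$end0[r], fix$regions$chrom[r],
                    p$start0, p$end0, p$chrom)
      else
        .o_intersects(fix$regions$start0[r], fix$regions$end0[r], fix$regions$chrom[r],
                      p$start0, p$end0, p$chrom)
    }, logical(1)))
  }
  covers_tss <- function(p, gene) {
    t <- oracle_tss(gene, tss_width, strand_aware)
    .o_contains(t[1], t[2], gene$chrom, p$start0, p$end0, p$chrom)
  }
  vapply(seq_len(nrow(fix$peaks)), function(i) {
    p <- fix$peaks[i, ]
    tss_any <- any(vapply(seq_len(nrow(fix$genes)), function(gi)
      covers_tss(p, fix$genes[gi, ]), logical(1)))
    if ((nrow(fix$regions) && hit_region(p, "promoter")) || tss_any) return("prom")
    if (nrow(fix$regions) && hit_region(p, "enhancer_distal")) return("enhD")
    in_exon <- any(vapply(seq_len(nrow(fix$exons)), function(r) {
      if (literal)
        .o_contains(p$start0, p$end0, p$chrom,
                    fix$exons$start0[r], fix$exons$end0[r], fix$exons$chrom[r])
      else
        .o_intersects(p$start0, p$end0, p$chrom,
                      fix$exons$start0[r], fix$exons$end0[r], fix$exons$chrom[r])
    }, logical(1)))
    if (in_exon) "exon" else "empty"
  }, character(1))
}

# gene association of promoter peaks: TSS coverage first, else window
# intersection; returns list(gp = gene x prom-peak 0/1 matrix, Gp ids)
oracle_gp <- function(fix, labels, upstream = 500, tss_width = 2,
                      strand_aware = TRUE) {
  prom <- which(labels == "prom")
  gp <- matrix(0, nrow(fix$genes), length(prom),
               dimnames = list(fix$genes$gene_id, fix$peaks$id[prom]))
  for (j in seq_along(prom)) {
    p <- fix$peaks[prom[j], ]
    tss_genes <- which(vapply(seq_len(nrow(fix$genes)), function(gi) {
      t <- oracle_tss(fix$genes[gi, ], tss_width, strand_aware)
      .o_contains(t[1], t[2], fix$genes$chrom[gi], p$start0, p$end0, p$chrom)
    }, logical(1)))
    assoc <- if (length(tss_genes)) tss_genes
    else which(vapply(seq_len(nrow(fix$genes)), function(gi) {
      w <- oracle_window(fix$genes[gi, ], upstream, strand_aware)
      .o_intersects(w[1], w[2], fix$genes$chrom[gi], p$start0, p$end0, p$chrom)
    }, logical(1)))
    gp[assoc, j] <- 1
  }
  keep <- rowSums(gp) > 0
  list(gp = gp[keep, , drop = FALSE], Gp = fix$genes$gene_id[keep])
}

# full brute-force construction of P, C, E and the combined matrix
oracle_gam <- function(fix, mode = "literal_containment", upstream = 500,
                       scale = 5000, d_th = 30000, tss_width = 2,
                       strand_aware = TRUE, weights = c(1, 1, 1)) {
  labels <- oracle_label(fix, mode, tss_width, strand_aware)
  og <- oracle_gp(fix, labels, upstream, tss_width, strand_aware)
  if (!nrow(og$gp)) return(NULL)
  Gp <- og$Gp
  cells <- colnames(fix$D)
  n_g <- length(Gp); n_c <- length(cells)
  ctr <- (fix$peaks$start0 + fix$peaks$end0) / 2
  gene_row <- match(Gp, fix$genes$gene_id)

  P <- C <- E <- matrix(0, n_g, n_c, dimnames = list(Gp, cells))
  for (gi in seq_len(n_g)) for (ci in seq_len(n_c)) {
    s <- 0
    for (pj in which(labels == "prom")) {
      if (og$gp[Gp[gi], fix$peaks$id[pj]] == 1) s <- s + fix$D[pj, ci]
    }
    P[gi, ci] <- as.numeric(s > 0)
  }
  # filtered connections (cam over positive scores of the raw list)
  if (!is.null(fix$conn) && nrow(fix$conn)) {
    pos <- fix$conn$ca > 0
    if (any(pos)) {
      cam <- mean(fix$conn$ca[pos])
      lab_of <- stats::setNames(labels, fix$peaks$id)
      for (r in seq_len(nrow(fix$conn))) {
        l1 <- lab_of[fix$conn$p1[r]]; l2 <- lab_of[fix$conn$p2[r]]
        if (is.na(l1) || is.na(l2)) next
        ok <- ((l1 == "prom" && l2 == "enhD") || (l1 == "enhD" && l2 == "prom")) &&
          fix$conn$ca[r] >= cam && fix$conn$d[r] <= d_th
        if (!ok) next
        pp <- if (l1 == "prom") fix$conn$p1[r] else fix$conn$p2[r]
        ep <- if (l1 == "prom") fix$conn$p2[r] else fix$conn$p1[r]
        ei <- match(ep, fix$peaks$id)
        for (gi in seq_len(n_g)) {
          if (og$gp[Gp[gi], pp] == 1) {
            for (ci in seq_len(n_c))
              C[gi, ci] <- C[gi, ci] + fix$conn$ca[r] * fix$D[ei, ci]
          }
        }
      }
    }
  }
  literal <- mode == "literal_containment"
  for (gi in seq_len(n_g)) {
    g <- fix$genes[gene_row[gi], ]
    tpos <- if (strand_aware && g$strand == "-") g$end0 - 1 else g$start0
    gex <- fix$exons[fix$exons$gene_id == Gp[gi], , drop = FALSE]
    for (pj in which(labels == "exon")) {
      p <- fix$peaks[pj, ]
      hit <- any(vapply(seq_len(nrow(gex)), function(r) {
        if (literal)
          .o_contains(p$start0, p$end0, p$chrom,
                      gex$start0[r], gex$end0[r], gex$chrom[r])
        else
          .o_intersects(p$start0, p$end0, p$chrom,
                        gex$start0[r], gex$end0[r], gex$chrom[r])
      }, logical(1)))
      if (hit) {
        w <- exp(-abs(ctr[pj] - tpos) / scale)
        for (ci in seq_len(n_c)) E[gi, ci] <- E[gi, ci] + w * fix$D[pj, ci]
      }
    }
  }
  gam <- weights[1] * P + weights[2] * C + weights[3] * E
  list(labels = labels, Gp = Gp, P = P, C = C, E = E, gam = gam)
}

# pair-counting adjusted Rand index (independent of the contingency-table
# implementation in the package)
oracle_ari_paircount <- function(a, b) {
  n <- length(a)
  s_both <- s_a <- s_b <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    sa <- a[i] == a[j]; sb <- b[i] == b[j]
    s_both <- s_both + (sa && sb)
    s_a <- s_a + sa
    s_b <- s_b + sb
  }
  total <- choose(n, 2)
  expected <- s_a * s_b / total
  maxi <- (s_a + s_b) / 2
  if (abs(maxi - expected) < 1e-12) return(1)
  (s_both - expected) / (maxi - expected)
}

# literal double-sum Gini
oracle_gini_pairs <- function(x) {
  n <- length(x)
  if (all(x == 0)) return(0)
  sum(abs(outer(x, x, "-"))) / (2 * n^2 * mean(x))
}
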