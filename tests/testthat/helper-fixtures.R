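# Shared fixtures. Coordinates in the plain-list fixtures are 0-based
# half-open (BED convention); gr0() converts to the 1-based GRanges used
# by the package.

gr0 <- function(chrom, start0, end0, strand = "*", ...) {
  gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start0 + 1, end0),
                               strand = strand)
  mc <- list(...)
  for (nm in names(mc)) S4Vectors::mcols(gr)[[nm]] <- mc[[nm]]
  gr
}

# the recurring toy gene: G1 on '+', body [999,5000), exons [999,1199) and
# [4700,5000); promoter region [700,900); distal enhancer [8000,8300)
toy_annotation <- function() {
  genes <- gr0("chr1", 999, 5000, "+", gene_id = "G1",
               gene_name = "G1", biotype = "protein_coding")
  exons <- GenomicRanges::GRangesList(
    G1 = gr0("chr1", c(999, 4700), c(1199, 5000), "+"))
  regions <- gr0("chr1", c(700, 8000), c(900, 8300),
                 label = c("promoter", "enhancer_distal"))
  gene_annotation(genes, exons, regions)
}

toy_peaks <- function() {
  p <- gr0("chr1", c(650, 990, 7900, 1050, 3000),
           c(950, 1400, 8400, 1150, 3500))
  names(p) <- peak_id(p)
  p
}

# ---- random micro-fixtures (plain 0-based lists) ------------------------

random_micro_fixture <- function(seed) {
  set.seed(seed)
  n_genes <- sample(1:6, 1)
  chroms <- c("c1", "c2")
  genes <- exons <- regions <- peaks <- list()
  for (i in seq_len(n_genes)) {
    chrom <- sample(chroms, 1)
    s0 <- sample(0:50000, 1)
    e0 <- s0 + sample(1500:8000, 1)
    strand <- sample(c("+", "-"), 1)
    genes[[i]] <- data.frame(gene_id = sprintf("g%02d", i), chrom = chrom,
                             start0 = s0, end0 = e0, strand = strand)
    k <- sample(1:3, 1)
    bnd <- sort(sample(seq(s0, e0 - 1), 2 * k))
    for (j in seq_len(k)) {
      es <- bnd[2 * j - 1]; ee <- bnd[2 * j]
      if (ee <= es) ee <- es + 1
      exons[[length(exons) + 1L]] <- data.frame(
        gene_id = genes[[i]]$gene_id, chrom = chrom, start0 = es, end0 = ee)
    }
    tss0 <- if (strand == "+") s0 else e0 - 1
    updir <- if (strand == "+") -1 else 1
    if (stats::runif(1) < 0.7) { # promoter signature near the TSS
      c0 <- tss0 + updir * sample(100:400, 1)
      if (c0 >= 101)
        regions[[length(regions) + 1L]] <- data.frame(
          chrom = chrom, start0 = c0 - 100, end0 = c0 + 100,
          label = "promoter")
    }
    if (stats::runif(1) < 0.8) { # distal enhancer
      c0 <- tss0 + updir * sample(3000:20000, 1)
      if (c0 >= 151)
        regions[[length(regions) + 1L]] <- data.frame(
          chrom = chrom, start0 = c0 - 150, end0 = c0 + 150,
          label = "enhancer_distal")
    }
  }
  # decoy regions, including promoter/enhancer overlaps for precedence
  for (r in seq_len(sample(0:3, 1))) {
    c0 <- sample(0:60000, 1)
    regions[[length(regions) + 1L]] <- data.frame(
      chrom = sample(chroms, 1), start0 = c0, end0 = c0 + sample(100:400, 1),
      label = sample(c("promoter", "enhancer_distal", "other"), 1))
  }
  if (length(regions) && stats::runif(1) < 0.5) {
    base <- regions[[sample(length(regions), 1)]]
    regions[[length(regions) + 1L]] <- data.frame(
      chrom = base$chrom, start0 = max(0, base$start0 - 50),
      end0 = base$end0 + 50,
      label = if (base$label == "promoter") "enhancer_distal" else "promoter")
  }
  regions <- if (length(regions)) do.call(rbind, regions)
             else data.frame(chrom = character(0), start0 = integer(0),
                             end0 = integer(0), label = character(0))
  exons <- do.call(rbind, exons)
  genes <- do.call(rbind, genes)

  add_peak <- function(chrom, s0, e0) {
    s0 <- max(0, s0)
    if (e0 - s0 >= 2)
      peaks[[length(peaks) + 1L]] <<- data.frame(chrom = chrom, start0 = s0,
                                                 end0 = e0)
  }
  for (r in seq_len(nrow(regions))) { # peaks over regions
    u <- stats::runif(1)
    if (u < 0.7) add_peak(regions$chrom[r], regions$start0[r] - sample(20:200, 1),
                          regions$end0[r] + sample(20:200, 1))
    else if (u < 0.9) add_peak(regions$chrom[r],
                               regions$start0[r] + sample(20:80, 1),
                               regions$end0[r] + sample(20:200, 1))
  }
  for (i in seq_len(nrow(genes))) { # TSS-covering peaks
    if (stats::runif(1) < 0.6) {
      tss0 <- if (genes$strand[i] == "+") genes$start0[i] else genes$end0[i] - 1
      add_peak(genes$chrom[i], tss0 - sample(50:300, 1), tss0 + sample(50:300, 1))
    }
  }
  for (r in seq_len(nrow(exons))) { # peaks inside exons
    w <- exons$end0[r] - exons$start0[r]
    if (w >= 40 && stats::runif(1) < 0.6) {
      off <- sample(0:(w - 30), 1)
      add_peak(exons$chrom[r], exons$start0[r] + off,
               min(exons$end0[r], exons$start0[r] + off + sample(20:w, 1)))
    }
  }
  for (r in seq_len(sample(1:4, 1))) { # background peaks
    s0 <- sample(0:60000, 1)
    add_peak(sample(chroms, 1), s0, s0 + sample(100:600, 1))
  }
  peaks <- do.call(rbind, peaks)
  peaks$id <- sprintf("%s:%d-%d", peaks$chrom, peaks$start0, peaks$end0)
  peaks <- peaks[!duplicated(peaks$id), , drop = FALSE]
  if (nrow(peaks) > 30) peaks <- peaks[seq_len(30), , drop = FALSE]
  rownames(peaks) <- NULL

  n_cells <- sample(3:10, 1)
  D <- matrix(stats::rbinom(nrow(peaks) * n_cells, 1, 0.4),
              nrow(peaks), n_cells,
              dimnames = list(peaks$id, sprintf("c%d", seq_len(n_cells))))
  conn <- NULL
  if (nrow(peaks) >= 2) {
    pairs <- utils::combn(nrow(peaks), 2)
    take <- sample(ncol(pairs), min(15, ncol(pairs)))
    ctr <- (peaks$start0 + peaks$end0) / 2
    same <- peaks$chrom[pairs[1, take]] == peaks$chrom[pairs[2, take]]
    take <- take[same]
    if (length(take)) {
      conn <- data.frame(p1 = peaks$id[pairs[1, take]],
                         p2 = peaks$id[pairs[2, take]],
                         ca = round(stats::runif(length(take), -0.3, 0.9), 3),
                         d = abs(ctr[pairs[1, take]] - ctr[pairs[2, take]]))
    }
  }
  list(genes = genes, exons = exons, regions = regions, peaks = peaks,
       D = D, conn = conn)
}

# package objects from a plain fixture
fixture_objects <- function(fix) {
  genes <- gr0(fix$genes$chrom, fix$genes$start0, fix$genes$end0,
               fix$genes$strand, gene_id = fix$genes$gene_id,
               gene_name = fix$genes$gene_id, biotype = "protein_coding")
  exl <- lapply(fix$genes$gene_id, function(g) {
    e <- fix$exons[fix$exons$gene_id == g, , drop = FALSE]
    gr0(e$chrom, e$start0, e$end0)
  })
  exons <- GenomicRanges::GRangesList(exl)
  names(exons) <- fix$genes$gene_id
  regions <- if (nrow(fix$regions))
    gr0(fix$regions$chrom, fix$regions$start0, fix$regions$end0,
        label = fix$regions$label)
  else NULL
  ann <- gene_annotation(genes, exons, regions)
  peaks <- gr0(fix$peaks$chrom, fix$peaks$start0, fix$peaks$end0)
  names(peaks) <- fix$peaks$id
  D <- Matrix::Matrix(fix$D, sparse = TRUE)
  list(annotation = ann, peaks = peaks, D = D)
}
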