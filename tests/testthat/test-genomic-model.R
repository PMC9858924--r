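# Gene/regulatory annotation parsing and the TSS / promoter-window geometry.

test_that("GTF loading keeps only whitelisted biotypes and merges exons", {
  gtf <- tempfile(fileext = ".gtf")
  writeLines(c(
    'chr1\tt\tgene\t1000\t5000\t.\t+\t.\tgene_id "A"; gene_biotype "protein_coding";',
    'chr1\tt\texon\t1000\t1199\t.\t+\t.\tgene_id "A"; transcript_id "A.1"; gene_biotype "protein_coding";',
    'chr1\tt\texon\t1000\t1199\t.\t+\t.\tgene_id "A"; transcript_id "A.2"; gene_biotype "protein_coding";',
    'chr1\tt\texon\t1100\t1400\t.\t+\t.\tgene_id "A"; transcript_id "A.2"; gene_biotype "protein_coding";',
    'chr1\tt\texon\t4000\t5000\t.\t+\t.\tgene_id "A"; transcript_id "A.1"; gene_biotype "protein_coding";',
    'chr1\tt\tgene\t9000\t9900\t.\t-\t.\tgene_id "B"; gene_biotype "lncRNA";',
    'chr1\tt\texon\t9000\t9900\t.\t-\t.\tgene_id "B"; transcript_id "B.1"; gene_biotype "lncRNA";',
    'chr1\tt\tgene\t20000\t21000\t.\t+\t.\tgene_id "C"; gene_biotype "protein_coding";',
    'chr1\tt\texon\t20000\t21000\t.\t+\t.\tgene_id "C"; transcript_id "C.1"; gene_biotype "protein_coding";'
  ), gtf)
  gm <- load_gene_annotation(gtf, format = "gtf")
  expect_setequal(gm$genes$gene_id, c("A", "C"))
  # transcripts A.1/A.2 share [1000,1199]; overlapping exons merge by union
  eA <- gm$exons[["A"]]
  expect_equal(GenomicRanges::start(eA), c(1000, 4000))
  expect_equal(GenomicRanges::end(eA), c(1400, 5000))
  # union of merged exons equals union of input exons (base-set oracle)
  base_oracle <- sort(unique(c(1000:1199, 1000:1199, 1100:1400, 4000:5000)))
  merged <- sort(unique(unlist(mapply(seq, GenomicRanges::start(eA),
                                      GenomicRanges::end(eA)))))
  expect_identical(merged, base_oracle)
})

test_that("gene with zero exon records is skipped with a warning", {
  gtf <- tempfile(fileext = ".gtf")
  writeLines(c(
    'chr1\tt\tgene\t100\t500\t.\t+\t.\tgene_id "A"; gene_biotype "protein_coding";',
    'chr1\tt\texon\t100\t500\t.\t+\t.\tgene_id "A"; transcript_id "A.1"; gene_biotype "protein_coding";',
    'chr1\tt\tgene\t900\t999\t.\t+\t.\tgene_id "B"; gene_biotype "protein_coding";'
  ), gtf)
  expect_warning(gm <- load_gene_annotation(gtf), "without exon")
  expect_identical(gm$genes$gene_id, "A")
})

test_that("BED12 block arithmetic places exons correctly", {
  bed <- tempfile(fileext = ".bed")
  writeLines("chr1\t999\t5000\tG1\t0\t+\t999\t5000\t0\t2\t200,300,\t0,3701,", bed)
  gm <- load_gene_annotation(bed, format = "bed12")
  expect_equal(GenomicRanges::start(gm$genes), 1000)
  expect_equal(GenomicRanges::end(gm$genes), 5000)
  e <- gm$exons[["G1"]]
  # blocks: [999,1199) and [4700,5000) in BED coordinates
  expect_equal(GenomicRanges::start(e) - 1L, c(999, 4700))
  expect_equal(GenomicRanges::end(e), c(1199, 5000))
})

test_that("gene model round-trips through BED12", {
  ann <- toy_annotation()
  path <- tempfile(fileext = ".bed")
  write_gene_bed12(ann, path)
  back <- load_gene_annotation(path, format = "bed12")
  expect_identical(back$genes$gene_id, ann$genes$gene_id)
  expect_equal(GenomicRanges::start(back$genes), GenomicRanges::start(ann$genes))
  expect_equal(GenomicRanges::end(back$genes), GenomicRanges::end(ann$genes))
  expect_equal(as.character(GenomicRanges::strand(back$genes)),
               as.character(GenomicRanges::strand(ann$genes)))
  for (g in ann$genes$gene_id) {
    expect_equal(GenomicRanges::start(back$exons[[g]]),
                 GenomicRanges::start(ann$exons[[g]]))
    expect_equal(GenomicRanges::end(back$exons[[g]]),
                 GenomicRanges::end(ann$exons[[g]]))
  }
})

test_that("TSS derivation is a 2-base region at the transcription start", {
  plus <- gr0("chr1", 999, 5000, "+", gene_id = "P")
  minus <- gr0("chr1", 999, 5000, "-", gene_id = "M")
  tp <- derive_tss(plus)
  expect_equal(c(GenomicRanges::start(tp) - 1L, GenomicRanges::end(tp)),
               c(999, 1001))
  tm <- derive_tss(minus)
  expect_equal(c(GenomicRanges::start(tm) - 1L, GenomicRanges::end(tm)),
               c(4998, 5000))
  # strand-blind mode ignores orientation
  tm0 <- derive_tss(minus, strand_aware = FALSE)
  expect_equal(GenomicRanges::start(tm0) - 1L, 999)
  # a 2-bp gene's TSS is the whole body
  tiny <- gr0("chr1", 10, 12, "+", gene_id = "T")
  tt <- derive_tss(tiny)
  expect_equal(c(GenomicRanges::start(tt), GenomicRanges::end(tt)), c(11, 12))
})

test_that("promoter window extends upstream of the TSS and clips at zero", {
  plus <- gr0("chr1", 999, 5000, "+", gene_id = "P")
  minus <- gr0("chr1", 999, 5000, "-", gene_id = "M")
  wp <- derive_promoter_window(plus, 500)
  expect_equal(c(GenomicRanges::start(wp) - 1L, GenomicRanges::end(wp)),
               c(499, 5000))
  wm <- derive_promoter_window(minus, 500)
  expect_equal(c(GenomicRanges::start(wm) - 1L, GenomicRanges::end(wm)),
               c(999, 5500))
  expect_equal(derive_promoter_window(plus, 0), plus)
  near0 <- gr0("chr1", 100, 900, "+", gene_id = "N")
  wn <- derive_promoter_window(near0, 500)
  expect_equal(GenomicRanges::start(wn), 1)
})

test_that("TSS is always inside the promoter window", {
  for (seed in 1:20) {
    set.seed(seed)
    s0 <- sample(0:10000, 1)
    g <- gr0("chrX", s0, s0 + sample(100:5000, 1),
             sample(c("+", "-"), 1), gene_id = "g")
    tss <- derive_tss(g)
    win <- derive_promoter_window(g)
    expect_true(GenomicRanges::start(tss) >= GenomicRanges::start(win) &&
                  GenomicRanges::end(tss) <= GenomicRanges::end(win))
  }
})

test_that("regulatory track loading maps labels and flags bad input", {
  bed <- tempfile(fileext = ".bed")
  writeLines(c("chr1\t700\t900\tE1\t0\t.\t700\t900\t255,0,0\tprom",
               "chr1\t2000\t2300\tE2\t0\t.\t2000\t2300\t0,0,255\tdELS",
               "chr1\t4000\t4200\tE3\t0\t.\t4000\t4200\t0,0,0\tCTCF-only"),
             bed)
  rr <- load_regulatory_tracks(bed, label_column = 10)
  expect_equal(rr$label, c("promoter", "enhancer_distal", "other"))
  expect_equal(GenomicRanges::start(rr)[1] - 1L, 700)
  expect_error(load_regulatory_tracks(bed, label_column = 15), "label_column")
  bad <- tempfile(fileext = ".bed")
  writeLines("chr1\t900\t700\tE1\t0\t.\tprom", bad)
  expect_error(load_regulatory_tracks(bad, label_column = 7), "line 1")
})
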