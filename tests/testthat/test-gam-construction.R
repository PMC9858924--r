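# Association maps, the three component matrices, the weighted
# combination and the per-cell normalization.

test_that("exon decay weight has the stated closed forms", {
  expect_equal(exon_weight(0), 1)
  expect_equal(exon_weight(5000), exp(-1))
  expect_equal(exon_weight(10000), exp(-2))
  d <- seq(0, 50000, by = 500)
  expect_true(all(diff(exon_weight(d)) < 0))     # strictly decreasing
  expect_error(exon_weight(-1), "negative")
})

test_that("promoter association follows the TSS-first rule", {
  ds <- worked_example()
  lps <- label_peaks(ds$peaks, ds$annotation)
  GP <- build_gene_promoter_map(lps, ds$annotation)
  m <- as.matrix(GP$matrix)
  # divergent-gene case: chrT:900-1100 covers only G1's TSS -> G1 alone,
  # even though it also intersects G2's promoter window
  expect_equal(m["G1", "chrT:900-1100"], 1)
  expect_equal(m["G2", "chrT:900-1100"], 0)
  # no-promoter-signature case: G2 rescued by its TSS-covering peak
  expect_equal(m["G2", "chrT:700-950"], 1)
  expect_setequal(rownames(m), c("G1", "G2"))
})

test_that("window association applies when a prom peak covers no TSS", {
  ann <- toy_annotation()
  lps <- label_peaks(toy_peaks(), ann)
  GP <- build_gene_promoter_map(lps, ann)
  # [650,950) contains the promoter region, covers no TSS, intersects the
  # enlarged window [499,5000) -> associated with G1
  expect_equal(as.matrix(GP$matrix)["G1", "chr1:650-950"], 1)
})

test_that("genes without any promoter peak are excluded (golden rule)", {
  ann <- toy_annotation()
  peaks <- gr0("chr1", c(1050, 3000), c(1150, 3500))  # exon + intronic only
  names(peaks) <- peak_id(peaks)
  lps <- label_peaks(peaks, ann)
  GP <- build_gene_promoter_map(lps, ann)
  expect_equal(nrow(GP$matrix), 0)
  D <- Matrix::Matrix(matrix(1, 2, 3), sparse = TRUE,
                      dimnames = list(names(peaks), sprintf("c%d", 1:3)))
  expect_error(gagam(D, ann), "golden rule")
})

test_that("promoter matrix is binarized across multiple prom peaks", {
  ann <- toy_annotation()
  # two prom-labeled peaks for G1: one contains the region, one covers the TSS
  peaks <- gr0("chr1", c(650, 990), c(950, 1400))
  names(peaks) <- peak_id(peaks)
  lps <- label_peaks(peaks, ann)
  GP <- build_gene_promoter_map(lps, ann)
  D <- Matrix::Matrix(rbind(c(1, 0, 1, 0), c(1, 0, 0, 1)), sparse = TRUE,
                      dimnames = list(names(peaks), sprintf("c%d", 1:4)))
  P <- build_promoter_matrix(GP, D)
  expect_equal(as.numeric(P["G1", ]), c(1, 0, 1, 1))   # clipped to 1 in c1
  Praw <- build_promoter_matrix(GP, D, binarize = FALSE)
  expect_equal(as.numeric(Praw["G1", ]), c(2, 0, 1, 1))
})

test_that("exon map weights by center-to-TSS distance, Gp-gated", {
  ann <- toy_annotation()
  lps <- label_peaks(toy_peaks(), ann)
  GI <- build_exon_map(lps, ann, gene_ids = "G1")
  # exon peak [1050,1150): center 1100, TSS position 999 -> d = 101
  expect_equal(as.matrix(GI$matrix)["G1", "chr1:1050-1150"],
               exp(-101 / 5000), tolerance = 1e-12)
  # a gene outside Gp gets no exon entries
  GI0 <- build_exon_map(lps, ann, gene_ids = character(0))
  expect_equal(dim(GI0$matrix), c(0L, 1L))
})

test_that("component products match hand evaluation on the worked example", {
  ds <- worked_example()
  g <- gagam(ds$counts, ds$annotation, connections = ds$connections)
  P <- as.matrix(g$components$P)
  C <- as.matrix(g$components$C)
  E <- as.matrix(g$components$E)
  expect_equal(P["G1", ], c("CELL-1" = 1, "CELL-2" = 0, "CELL-3" = 1))
  expect_equal(C["G1", ], c("CELL-1" = 0.6, "CELL-2" = 0.6, "CELL-3" = 0))
  expect_equal(C["G2", ], c("CELL-1" = 0, "CELL-2" = 0, "CELL-3" = 0))
  expect_equal(E["G1", "CELL-1"], exp(-100 / 5000), tolerance = 1e-12)
  # exon accessible while the promoter peak is closed still contributes
  expect_equal(P["G2", "CELL-2"], 1)
  expect_equal(E["G2", "CELL-2"], exp(-99 / 5000), tolerance = 1e-12)
  expect_gt(E["G2", "CELL-2"], 0)
})

test_that("combination is linear in the weights", {
  ds <- worked_example()
  full <- gagam(ds$counts, ds$annotation, connections = ds$connections,
                config = gagam_config(normalization = "none"))
  noE <- gagam(ds$counts, ds$annotation, connections = ds$connections,
               config = gagam_config(weights = c(1, 1, 0),
                                     normalization = "none"))
  onlyP <- gagam(ds$counts, ds$annotation, connections = ds$connections,
                 config = gagam_config(weights = c(1, 0, 0),
                                       normalization = "none"))
  expect_equal(as.matrix(full$gam) - as.matrix(full$components$E),
               as.matrix(noE$gam), tolerance = 1e-14)
  expect_equal(as.matrix(onlyP$gam), as.matrix(full$components$P))
  expect_equal(as.matrix(full$gam)["G1", "CELL-1"],
               1 + 0.6 + exp(-100 / 5000), tolerance = 1e-12)
  expect_error(combine_activity(full$components$P, full$components$C,
                                full$components$E, weights = c(1, 2, 0)))
})

test_that("cell-total normalization equalizes nonzero column sums", {
  m <- Matrix::Matrix(rbind(c(1, 3, 0), c(1, 1, 0)), sparse = TRUE,
                      dimnames = list(c("g1", "g2"), c("c1", "c2", "c3")))
  out <- normalize_gam(m)
  cs <- Matrix::colSums(out)
  expect_equal(unname(cs[1:2]), c(3, 3))   # median of (2, 4) is 3
  expect_equal(unname(cs[3]), 0)           # all-zero cell untouched
  expect_equal(as.matrix(normalize_gam(m, method = "none")), as.matrix(m))
  expect_equal(as.matrix(normalize_gam(m, method = "log_cell_total")),
               log1p(as.matrix(normalize_gam(m, method = "cell_total"))))
})

test_that("opening a closed peak never decreases any component entry", {
  for (seed in 301:306) {
    fix <- random_micro_fixture(seed)
    obj <- fixture_objects(fix)
    base <- tryCatch(
      suppressWarnings(gagam(obj$D, obj$annotation, connections = fix$conn,
                             config = gagam_config(normalization = "none"))),
      error = function(e) NULL)
    if (is.null(base)) next
    zeros <- which(as.matrix(obj$D) == 0, arr.ind = TRUE)
    if (!nrow(zeros)) next
    pick <- zeros[sample(nrow(zeros), 1), ]
    D2 <- obj$D
    D2[pick[1], pick[2]] <- 1
    mod <- suppressWarnings(
      gagam(D2, obj$annotation, connections = fix$conn,
            config = gagam_config(normalization = "none")))
    shared <- intersect(rownames(base$gam), rownames(mod$gam))
    for (comp in c("P", "C", "E")) {
      expect_true(all(as.matrix(mod$components[[comp]][shared, , drop = FALSE]) -
                        as.matrix(base$components[[comp]][shared, , drop = FALSE])
                      >= -1e-12),
                  info = sprintf("seed %d comp %s", seed, comp))
    }
  }
})

test_that("vectorized pipeline equals the brute-force oracle on micro-fixtures", {
  n_checked <- 0
  for (seed in 201:230) {
    fix <- random_micro_fixture(seed)
    obj <- fixture_objects(fix)
    oracle <- oracle_gam(fix)
    got <- tryCatch(
      suppressWarnings(gagam(obj$D, obj$annotation, connections = fix$conn,
                             config = gagam_config(normalization = "none"))),
      error = function(e) e)
    if (is.null(oracle)) {
      expect_true(inherits(got, "error"), info = sprintf("seed %d", seed))
      next
    }
    expect_false(inherits(got, "error"), info = sprintf("seed %d", seed))
    ord <- order(rownames(got$gam))
    for (comp in c("P", "C", "E")) {
      expect_equal(as.matrix(got$components[[comp]])[ord, , drop = FALSE],
                   oracle[[comp]][order(rownames(oracle[[comp]])), , drop = FALSE],
                   tolerance = 1e-12, info = sprintf("seed %d %s", seed, comp))
    }
    expect_equal(as.matrix(got$gam)[ord, , drop = FALSE],
                 oracle$gam[order(rownames(oracle$gam)), , drop = FALSE],
                 tolerance = 1e-12, info = sprintf("seed %d gam", seed))
    n_checked <- n_checked + 1
  }
  expect_gt(n_checked, 10)  # most random fixtures must be non-degenerate
})
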