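mk_peaks <- function(chrom, start, end, name = NULL, tf = "TF") {
  tibble::tibble(chrom = chrom, start = as.integer(start), end = as.integer(end),
                 name = name %||% sprintf("pk%d", seq_along(start)),
                 score = 1, strand = ".", tf = tf)
}

mk_tss <- function(chrom, pos, promoter = NULL, gene = NULL) {
  promoter <- promoter %||% sprintf("p%02d", seq_along(pos))
  tibble::tibble(promoter = promoter, chrom = chrom, pos = as.integer(pos),
                 strand = "+", gene = gene %||% toupper(promoter), is_tf = FALSE)
}

test_that("replicate consistency keeps only overlapping peaks", {
  r1 <- mk_peaks("chr1", c(100, 500), c(200, 600))
  expect_equal(nrow(reproducible_peaks(r1, r1)), 2)
  r2 <- mk_peaks("chr1", c(1000, 2000), c(1100, 2100))
  expect_equal(nrow(reproducible_peaks(r1, r2)), 0)
  # half-open arithmetic: [100,200) and [199,300) share exactly 1 bp
  a <- mk_peaks("chr1", 100, 200)
  b <- mk_peaks("chr1", 199, 300)
  kept <- reproducible_peaks(a, b)
  expect_equal(nrow(kept), 1)
  expect_equal(c(kept$start, kept$end), c(100L, 300L))   # merged interval
  # ...while [100,200) and [200,300) are adjacent, not overlapping
  expect_equal(nrow(reproducible_peaks(a, mk_peaks("chr1", 200, 300))), 0)
  expect_warning(reproducible_peaks(a, mk_peaks("chr9", 100, 200)),
                 "chromosomes")
})

test_that("co-binding counts symmetric >= 1 bp overlaps and k-way subsets", {
  A <- mk_peaks("chr1", 100, 200, tf = "A")
  B <- mk_peaks("chr1", 150, 250, tf = "B")
  C <- mk_peaks("chr1", 160, 190, tf = "C")
  far <- mk_peaks("chr1", 9000, 9100, tf = "D")
  cb <- cobinding(list(A = A, B = B, D = far))
  expect_equal(cb$pairwise["A", "B"], 1L)
  expect_equal(cb$pairwise["B", "A"], 1L)
  expect_equal(cb$pairwise["A", "D"], 0L)
  cb3 <- cobinding(list(A = A, B = B, C = C))
  trip <- cb3$subsets[cb3$subsets$subset == "A+B+C", ]
  expect_equal(trip$count, rep(1L, 3))   # nested triple overlap
})

test_that("chromatin-class overlap compares observed and base-share expectation", {
  classes <- tibble::tibble(
    chrom = "chr1",
    start = as.integer(seq(0, 4000, by = 1000)),
    end = as.integer(seq(1000, 5000, by = 1000)),
    class = paste0("C", 1:5))     # equal 1 kb share per class
  pk <- mk_peaks("chr1", seq(2100, 2900, by = 100), seq(2140, 2940, by = 100))
  res <- class_overlap(pk, classes)   # all midpoints inside C3
  c3 <- res$per_class[res$per_class$class == "C3", ]
  expect_equal(c3$fold, 5)
  expect_lt(c3$p_value, 0.01)
  expect_equal(res$fraction_in_open, 1)
  # one class covering everything: fold is 1 by construction
  one <- class_overlap(pk, tibble::tibble(chrom = "chr1", start = 0L,
                                          end = 5000L, class = "C1"))
  expect_equal(one$per_class$fold, 1)
  # peaks outside any class interval
  none <- class_overlap(mk_peaks("chr1", 9e6, 9e6 + 100), classes)
  expect_equal(sum(none$per_class$observed), 0)
  expect_equal(none$fraction_in_open, 0)
})

test_that("peak-to-TSS distance is the midpoint distance to the nearest peak", {
  tss <- mk_tss("chr1", c(10000, 50000))
  # peaks with midpoints at 10000, 9400, 10600 and 50000 + 40000
  pk <- mk_peaks("chr1", c(9900, 9300, 10500, 89900),
                 c(10100, 9500, 10700, 90100))
  d <- peak_tss_distances(pk, tss)
  expect_equal(d$distance[d$promoter == "p01"], 0)
  expect_equal(d$distance[d$promoter == "p02"], 39400)  # 50000 vs midpoint 10600
  # minimum over peaks: +/-600 beats +40000
  d2 <- peak_tss_distances(pk[2:4, ], mk_tss("chr1", 10000))
  expect_equal(d2$distance, 600)
  # promoters on peak-free chromosomes are flagged infinite
  d3 <- peak_tss_distances(pk, mk_tss("chr7", 100))
  expect_identical(d3$distance, Inf)
})

test_that("distance binning reports per-bin direction fractions", {
  de <- tibble::tibble(promoter = paste0("p", 1:6),
                       direction = c("down", "down", "up", "unaffected",
                                     "unaffected", "down"))
  dist <- tibble::tibble(promoter = paste0("p", 1:6),
                         distance = c(100, 900, 2000, 2100, 50000, Inf))
  b <- bin_response(de, dist)
  expect_equal(b$frac_down[b$bin == "[0,1000)"], 1)
  expect_equal(b$frac_up[b$bin == "[1000,5000)"], 0.5)
  expect_equal(b$frac_unaffected[b$bin == "[5000,1e+05)"], 1)
  expect_equal(b$frac_down[b$bin == "[1e+05,Inf)"], 1)   # no-peak promoter
  # fractions in non-empty bins sum to one
  nz <- b[b$n > 0, ]
  expect_equal(nz$frac_up + nz$frac_down + nz$frac_unaffected, rep(1, nrow(nz)))
  # empty bins are NA, not zero
  b2 <- bin_response(de[1, ], dist[1, ])
  expect_true(is.na(b2$frac_down[b2$bin == "[1000,5000)"]))
  expect_error(bin_response(de, dist, bins = c(0, 5, 5)), "increasing")
})

test_that("direct-target calling needs significance, fold and proximity together", {
  de <- tibble::tibble(promoter = paste0("p", 1:4),
                       logFC = c(-1, -1, -0.4, -1),
                       p_value = c(0.01, 0.01, 0.001, 0.2),
                       q_value = NA, mean_expr = 100)
  dist <- tibble::tibble(promoter = paste0("p", 1:4), gene = paste0("G", 1:4),
                         distance = c(10000, 60000, 100, 100),
                         nearest_peak = "pk")
  hit <- call_direct_targets(de, dist, tf = "T")
  expect_equal(hit$promoter, "p1")     # p2 too far, p3 weak fold, p4 not significant
  expect_equal(hit$gene, "G1")
})

test_that("direct calls are monotone in distance and fold thresholds", {
  scen <- synth_scenario(seed = 5, n_promoters = 500, n_samples = 10,
                         n_enriched = 100, n_direct = 25, n_indirect = 5,
                         n_tf_targets = c(4L, 2L))
  kd <- scen$counts[["TF1"]]
  de <- de_analysis(kd$counts, kd$groups)
  d <- peak_tss_distances(scen$peaks[scen$peaks$tf == "TF1", ], scen$tss)
  n_by_dist <- vapply(c(1e3, 1e4, 5e4, 2e5), function(md) {
    nrow(call_direct_targets(de, d, max_dist = md))
  }, numeric(1))
  expect_true(all(diff(n_by_dist) >= 0))
  n_by_fold <- vapply(c(1, 1.5, 2, 4), function(mf) {
    nrow(call_direct_targets(de, d, min_fold = mf))
  }, numeric(1))
  expect_true(all(diff(n_by_fold) <= 0))
})

test_that("core network keeps only enriched TF genes, at gene level", {
  edges <- tibble::tibble(tf = c("A", "A", "A", "B"),
                          promoter = c("p1", "p2", "p3", "p4"),
                          gene = c("G1", "G1", "G2", "G9"),
                          logFC = -1, p_value = c(0.01, 0.001, 0.02, 0.03),
                          nearest_peak = "pk", distance = 100)
  core <- core_trn(edges, enriched_tfs = c("G1", "G9"))
  expect_equal(nrow(core), 2)
  a_g1 <- core[core$source == "A" & core$target == "G1", ]
  expect_equal(a_g1$n_promoters, 2L)      # any-promoter semantics, pooled
  expect_equal(a_g1$best_p, 0.001)
  expect_false("G2" %in% core$target)
  # absence of a reciprocal edge is visible as plain set membership
  expect_true(nrow(core[core$source == "B" & core$target == "G1", ]) == 0)
  empty <- core_trn(edges, enriched_tfs = "ZZZ")
  expect_equal(nrow(empty), 0)
})
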