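test_that("generators are pure functions of parameters and seed", {
  p1 <- generate_panel(100, 10, 10, 20, seed = 1)
  p2 <- generate_panel(100, 10, 10, 20, seed = 1)
  expect_identical(p1$panel$tpm, p2$panel$tpm)
  expect_identical(p1$enriched_genes, p2$enriched_genes)
  p3 <- generate_panel(100, 10, 10, 20, seed = 2)
  expect_false(identical(p1$panel$tpm, p3$panel$tpm))

  tr <- truth_network(tibble::tibble(tf = "T1", target = "p0001",
                                     effect = -1, direct = FALSE))
  k1 <- generate_kd_counts(tr, sprintf("p%04d", 1:20), seed = 5)
  k2 <- generate_kd_counts(tr, sprintf("p%04d", 1:20), seed = 5)
  expect_identical(k1, k2)

  q1 <- generate_qrtpcr(tr, "T1", c("p0001", "p0002"), seed = 3)
  q2 <- generate_qrtpcr(tr, "T1", c("p0001", "p0002"), seed = 3)
  expect_identical(q1, q2)
})

test_that("planted enriched genes are recoverable exactly, and only they", {
  out <- generate_panel(100, 10, 10, 20, seed = 1)
  tpm <- out$panel$tpm
  med_other <- apply(tpm[, -1], 1, median)
  fold <- tpm[, "focal"] / pmax(med_other, .Machine$double.eps)
  expect_identical(sort(rownames(tpm)[fold >= 20]), sort(out$enriched_genes))
  expect_length(out$enriched_genes, 10)
  # a 20-fold planting clears the score-1.25 (~18-fold) TF threshold
  sc <- panel_scores(out$panel)
  expect_true(all(sc$score[sc$id %in% out$enriched_genes] > 1.25))
})

test_that("panel generator validates its arguments", {
  expect_error(generate_panel(0, 10, 1, 20, seed = 1), "n_genes")
  expect_error(generate_panel(10, 10, 10, 20, seed = 1), "n_enriched")
  expect_error(generate_panel(10, 10, 2, 0.5, seed = 1), "enrichment_fold")
})

test_that("planted knock-down effects shift the count means as specified", {
  tr <- truth_network(tibble::tibble(tf = "T1", target = "p0007",
                                     effect = -1, direct = FALSE))
  kd <- generate_kd_counts(tr, sprintf("p%04d", 1:100), n_reps = 50,
                           lib_size = 1e6, dispersion = 0.1, lib_cv = 0,
                           seed = 42)[["T1"]]
  m_kd <- rowMeans(kd$counts[, kd$groups == "kd"])
  m_ct <- rowMeans(kd$counts[, kd$groups == "control"])
  expect_equal(m_kd[["p0007"]] / m_ct[["p0007"]], 0.5, tolerance = 0.05)
  # non-targets share means between groups
  ratios <- m_kd[-7] / m_ct[-7]
  expect_true(all(abs(log2(ratios)) < 0.35))
})

test_that("dispersion zero gives Poisson counts and NB counts fit the stated law", {
  tr <- truth_network(tibble::tibble(tf = "T1", target = "p0001",
                                     effect = -1, direct = FALSE))
  n_prom <- 50
  mu <- 100
  kd <- generate_kd_counts(tr, sprintf("p%04d", 1:n_prom), n_reps = 2500,
                           lib_size = mu * n_prom, dispersion = 0.2,
                           lib_cv = 0, baseline = rep(1, n_prom),
                           seed = 9)[["T1"]]
  x <- kd$counts["p0025", kd$groups == "control"]  # null promoter, known mean
  # chi-square GOF against NB(mu, phi = 0.2), pooling tail bins to exp >= 5
  br <- c(seq(0, 200, by = 10), Inf)
  obs <- table(cut(x, br, right = FALSE))
  pr <- diff(pnbinom(c(br[-length(br)] - 1, Inf), mu = mu, size = 1 / 0.2))
  keep <- pr * length(x) >= 5
  gof <- suppressWarnings(chisq.test(c(obs[keep], sum(obs[!keep])),
                                     p = c(pr[keep], sum(pr[!keep]))))
  expect_gt(gof$p.value, 0.001)

  kd0 <- generate_kd_counts(tr, sprintf("p%04d", 1:n_prom), n_reps = 2500,
                            lib_size = mu * n_prom, dispersion = 0,
                            lib_cv = 0, baseline = rep(1, n_prom),
                            seed = 9)[["T1"]]
  y <- kd0$counts["p0025", kd0$groups == "control"]
  expect_equal(var(y) / mean(y), 1, tolerance = 0.1)  # Poisson index of dispersion
})

test_that("peaks land where the distance law dictates and round-trip as BED", {
  tr <- truth_network(tibble::tibble(
    tf = "T1", target = c("p0001", "p0002", "p0003"),
    effect = -2, direct = TRUE))
  tss <- generate_tss(20, seed = 4)
  pk <- generate_peaks(tr, tss, distance_law = function(n) rep(500, n),
                       n_decoys = 0, seed = 1)
  d <- peak_tss_distances(pk, tss)
  planted <- d[d$promoter %in% tr$edges$target, ]
  expect_true(all(planted$distance < 1000))

  f <- withr::local_tempfile(fileext = ".bed")
  write_bed(pk, f)
  back <- read_bed(f)
  expect_equal(back[, c("chrom", "start", "end", "name", "strand")],
               pk[, c("chrom", "start", "end", "name", "strand")])

  expect_error(
    generate_peaks(tr, tss[tss$promoter != "p0002", ], seed = 1),
    "p0002")
})

test_that("every planted direct edge gets a peak within the calling window", {
  scen <- synth_scenario(seed = 3, n_promoters = 500, n_samples = 10,
                         n_enriched = 100, n_direct = 20, n_indirect = 5,
                         n_tf_targets = c(4L, 2L))
  direct <- scen$truth$edges[scen$truth$edges$direct, ]
  for (tf in scen$chip_tfs) {
    d <- peak_tss_distances(scen$peaks[scen$peaks$tf == tf, ], scen$tss)
    dd <- d$distance[match(direct$target[direct$tf == tf], d$promoter)]
    expect_true(all(dd < 5e4))
  }
})

test_that("noiseless qRT-PCR fold changes equal the planted effects", {
  tr <- truth_network(tibble::tibble(tf = "T1", target = c("A", "B"),
                                     effect = c(1, -1), direct = FALSE))
  q <- generate_qrtpcr(tr, "T1", c("A", "B", "C", "T1"), noise_sd = 0,
                       n_reps = 2, kd_residual = 0.3, seed = 1)
  fc <- function(t) unique(q$fold_change[q$target == t])
  expect_equal(fc("A"), 2)
  expect_equal(fc("B"), 0.5)
  expect_equal(fc("C"), 1)
  expect_equal(fc("T1"), 0.3)  # self cell carries knock-down residual
})

test_that("truth network validates effects and duplicate edges", {
  expect_error(truth_network(tibble::tibble(tf = "T", target = "p",
                                            effect = 0, direct = FALSE)),
               "non-zero")
  expect_error(truth_network(tibble::tibble(tf = c("T", "T"),
                                            target = c("p", "p"),
                                            effect = c(1, 2),
                                            direct = FALSE)),
               "duplicate")
})
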