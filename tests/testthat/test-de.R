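test_that("TMM factors are 1 under pure depth differences", {
  withr::with_seed(5, {
    a <- rnbinom(500, mu = 50, size = 10) + 1
  })
  y <- cbind(a, a)
  expect_equal(tmm_factors(y), c(1, 1))
  y2 <- cbind(a, 2 * a)   # doubled depth, no composition change
  expect_equal(tmm_factors(y2), c(1, 1))
})

test_that("composition bias shrinks the factor of the inflated library", {
  withr::with_seed(6, {
    a <- rnbinom(1000, mu = 100, size = 10) + 1
  })
  b <- a
  top <- order(a, decreasing = TRUE)[1:50]   # inflate top 5% tenfold
  b[top] <- 10 * a[top]
  f <- tmm_factors(cbind(a, b))
  expect_lt(f[2] / f[1], 1)
})

test_that("TMM agrees with an independent implementation of the method", {
  skip_if_not_installed("edgeR")
  withr::with_seed(7, {
    y <- matrix(rnbinom(3000, mu = rep(exp(runif(750, 1, 7)), 4), size = 5),
                ncol = 4)
  })
  y <- y[rowSums(y) > 0, ]
  expect_equal(tmm_factors(y),
               as.numeric(edgeR::calcNormFactors(y, method = "TMM")),
               tolerance = 1e-10)
})

test_that("TMM rejects degenerate input", {
  expect_error(tmm_factors(matrix(1:5, ncol = 1)), "2 libraries")
  expect_error(tmm_factors(cbind(c(1, 2), c(0, 0))), "no counts")
})

test_that("dispersion estimation recovers Poisson and NB truth", {
  withr::with_seed(11, {
    grp <- factor(rep(c("control", "kd"), each = 3), levels = c("control", "kd"))
    y_pois <- matrix(rpois(5000 * 6, 100), ncol = 6)
    y_nb <- matrix(rnbinom(5000 * 6, mu = 100, size = 10), ncol = 6)
  })
  expect_lt(estimate_dispersion(y_pois, grp)$common, 0.02)
  est <- estimate_dispersion(y_nb, grp)$common
  expect_gt(est, 0.05)
  expect_lt(est, 0.2)
})

test_that("zero-variance promoters take the common dispersion", {
  grp <- factor(rep(c("control", "kd"), each = 3), levels = c("control", "kd"))
  y <- rbind(matrix(rep(c(10, 20), each = 3), nrow = 1),   # constant per group
             matrix(rpois(100 * 6, 50), ncol = 6))
  d <- estimate_dispersion(y, grp, factors = rep(1, 6), lib_sizes = rep(300, 6))
  expect_equal(d$tagwise[1], d$common)
})

test_that("dispersion estimation refuses unreplicated designs", {
  y <- matrix(rpois(20, 10), ncol = 2)
  expect_error(estimate_dispersion(y, factor(c("a", "b"))), "replicates")
})

test_that("the exact test is null on perfectly symmetric data", {
  y <- matrix(50, nrow = 3, ncol = 4,
              dimnames = list(paste0("p", 1:3), NULL))
  grp <- factor(c("control", "control", "kd", "kd"), levels = c("control", "kd"))
  res <- nb_exact_test(y, grp, dispersion = 0.1, factors = rep(1, 4))
  expect_equal(res$p_value, rep(1, 3))
  expect_equal(res$logFC, rep(0, 3))
})

test_that("the Poisson limit matches the conditional enumeration oracle", {
  cases <- list(c(30, 60, 2, 2), c(10, 3, 3, 3), c(100, 100, 3, 2),
                c(0, 12, 2, 3), c(77, 123, 4, 4))
  for (cs in cases) {
    got <- trnmapr:::exact_nb_pvalue(cs[1], cs[2], cs[3], cs[4], phi = 0)
    want <- enum_poisson_cond_p(cs[1], cs[2], cs[3], cs[4])
    expect_equal(got, want, tolerance = 1e-6)
  }
})

test_that("the NB conditional pmf matches brute-force convolution", {
  for (phi in c(0.05, 0.2, 1)) {
    for (cs in list(c(5, 20, 2, 2), c(18, 30, 2, 2), c(25, 25, 2, 2),
                    c(0, 40, 2, 2), c(12, 9, 3, 2))) {
      got <- trnmapr:::exact_nb_pvalue(cs[1], cs[2], cs[3], cs[4], phi)
      want <- enum_nb_cond_p(cs[1], cs[2], cs[3], cs[4], phi)
      expect_equal(got, want, tolerance = 1e-9)
    }
  }
})

test_that("swapping group labels negates logFC and keeps p-values", {
  withr::with_seed(13, {
    y <- matrix(rnbinom(200 * 6, mu = 80, size = 10), ncol = 6,
                dimnames = list(paste0("p", 1:200), NULL))
  })
  g1 <- factor(rep(c("control", "kd"), each = 3), levels = c("control", "kd"))
  g2 <- factor(rep(c("kd", "control"), each = 3), levels = c("control", "kd"))
  r1 <- nb_exact_test(y, g1, dispersion = 0.1)
  r2 <- nb_exact_test(y, g2, dispersion = 0.1)
  expect_equal(r1$p_value, r2$p_value)
  expect_equal(r1$logFC, -r2$logFC)
})

test_that("p-values are depth-invariant up to count discreteness", {
  withr::with_seed(14, {
    y <- matrix(rnbinom(300 * 6, mu = 100, size = 10), ncol = 6,
                dimnames = list(paste0("p", 1:300), NULL))
  })
  grp <- factor(rep(c("control", "kd"), each = 3), levels = c("control", "kd"))
  ls1 <- colSums(y)
  r1 <- nb_exact_test(y, grp, dispersion = 0.1, lib_sizes = ls1)
  y2 <- y; y2[, 1] <- 3L * y[, 1]
  ls2 <- ls1; ls2[1] <- 3 * ls1[1]
  r2 <- nb_exact_test(y2, grp, dispersion = 0.1, lib_sizes = ls2)
  # identical up to the discreteness of re-rounded group sums
  expect_lt(stats::median(abs(r1$p_value - r2$p_value)), 0.005)
  expect_lt(max(abs(r1$p_value - r2$p_value)), 0.05)
})

test_that("direction calls honour alpha and the fold filter", {
  de <- tibble::tibble(promoter = c("a", "b", "c", "d"),
                       mean_expr = 100,
                       logFC = c(-1, -3, 1, -0.4),
                       p_value = c(0.01, 0.2, 0.001, 0.001),
                       q_value = c(0.02, 0.3, 0.004, 0.004))
  cd <- call_de(de, alpha = 0.05)
  expect_equal(cd$direction, c("down", "unaffected", "up", "down"))
  cd2 <- call_de(de, alpha = 0.05, min_fold = 1.5)
  expect_equal(cd2$direction[4], "unaffected")   # |logFC| 0.4 < log2(1.5)
})

test_that("recovery power increases with effect size and replication", {
  sim <- function(effect, n_reps) {
    tr <- truth_network(tibble::tibble(
      tf = "T1", target = sprintf("p%04d", 1:100),
      effect = if (effect == 0) -1e-9 else -effect, direct = FALSE))
    kd <- generate_kd_counts(tr, sprintf("p%04d", 1:400), n_reps = n_reps,
                             lib_size = 100 * 400, dispersion = 0.1,
                             baseline = rep(1, 400), seed = 99)[["T1"]]
    de <- de_analysis(kd$counts, kd$groups)
    mean(de$direction[match(sprintf("p%04d", 1:100), de$promoter)] == "down",
         na.rm = TRUE)
  }
  p_small <- sim(0.5, 3)
  p_mid <- sim(1.5, 3)
  p_big <- sim(2.5, 3)
  expect_true(p_small <= p_mid + 0.02 && p_mid <= p_big + 0.02)
  expect_gt(p_big, p_small)
  expect_gte(sim(1.0, 6), sim(1.0, 3) - 0.02)
})

test_that("all-zero promoters are dropped and reported", {
  withr::with_seed(15, {
    y <- rbind(matrix(0L, 5, 6),
               matrix(rpois(100 * 6, 60), ncol = 6))
  })
  rownames(y) <- paste0("p", seq_len(nrow(y)))
  grp <- factor(rep(c("control", "kd"), each = 3), levels = c("control", "kd"))
  de <- de_analysis(y, grp)
  expect_equal(attr(de, "n_dropped"), 5L)
  expect_equal(nrow(de), 100L)
})
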