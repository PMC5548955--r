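# Abundance windows, two-sample K-S test, target-set shift test and the
# random-set resampling null.

test_that("abundance window is a closed interval on base mean", {
  de <- data.frame(gene_id = paste0("g", 1:5),
                   baseMean = c(10, 316.23, 500, 3000, 31623),
                   log2FC = 0, tested = TRUE)
  # 10^2.5 = 316.2278 <= 316.23, 10^4.25 = 17782.8
  expect_identical(abundance_window(de, 2.5, 4.25), c("g2", "g3", "g4"))
  expect_identical(abundance_window(de, -10, 10), de$gene_id)
  expect_warning(w <- abundance_window(de, 8, 9), "no genes")
  expect_identical(w, character())
  expect_error(abundance_window(de, 3, 3), "lo < hi")
  # untested genes excluded
  de$tested[3] <- FALSE
  expect_identical(abundance_window(de, 2.5, 4.25), c("g2", "g4"))
})

test_that("K-S statistic matches the brute-force ECDF supremum", {
  expect_equal(ks_two_sample(c(1, 2, 3), c(1, 2, 3)),
               list(D = 0, p = 1))
  expect_equal(ks_two_sample(c(1, 3), c(2, 4))$D, 0.5)
  expect_equal(ks_two_sample(rnorm(20), rnorm(20) + 100)$D, 1)
  expect_error(ks_two_sample(numeric(), 1:3), "non-empty")

  set.seed(21)
  for (i in 1:200) {
    n <- sample(1:30, 1)
    m <- sample(1:30, 1)
    x <- sample(round(rnorm(n), 1))   # rounding forces ties
    y <- sample(round(rnorm(m, sd = 2), 1))
    expect_equal(ks_two_sample(x, y)$D, oracle_ks_D(x, y))
  }
})

test_that("K-S asymptotic p agrees with stats::ks.test away from ties", {
  set.seed(31)
  for (i in 1:20) {
    x <- rnorm(60)
    y <- rnorm(60, mean = runif(1, 0, 0.8))
    ours <- ks_two_sample(x, y)
    ref <- suppressWarnings(ks.test(x, y))
    expect_equal(ours$D, unname(ref$statistic))
    # same Kolmogorov limit law; the finite-sample correction differs
    # slightly from the exact null distribution ks.test uses
    if (ref$p.value > 1e-4)
      expect_equal(ours$p, ref$p.value, tolerance = 0.2)
  }
})

test_that("shift_test detects a planted downward shift and is order invariant", {
  set.seed(41)
  n_bg <- 4000
  de <- data.frame(
    gene_id = paste0("g", seq_len(n_bg)),
    baseMean = 10^runif(n_bg, 3, 4),
    log2FC = rnorm(n_bg, 0, 0.5),
    tested = TRUE)
  targets <- paste0("g", 1:400)
  de$log2FC[1:400] <- rnorm(400, -0.4, 0.5)
  res <- shift_test(de, targets, c(2.5, 4.25))
  expect_lt(res$p, 1e-6)
  expect_lt(res$median_target, res$median_background)
  expect_identical(res$n_target, 400L)
  expect_identical(res$n_background, as.integer(n_bg))

  # permutation of table rows changes nothing
  perm <- de[sample(n_bg), ]
  res2 <- shift_test(perm, targets, c(2.5, 4.25))
  expect_equal(res2[c("D", "p", "median_target", "fisher_p")],
               res[c("D", "p", "median_target", "fisher_p")])

  # monotone relabeling of gene ids changes nothing
  relab <- de
  relab$gene_id <- paste0("x", de$gene_id)
  res3 <- shift_test(relab, paste0("x", targets), c(2.5, 4.25))
  expect_equal(res3$D, res$D)

  # identity: target set = all window genes
  resid <- shift_test(de, de$gene_id, c(2.5, 4.25))
  expect_equal(resid$D, 0)
  expect_equal(resid$p, 1)
})

test_that("up/down Fisher test flags asymmetric regulation", {
  de <- data.frame(
    gene_id = paste0("g", 1:12800),
    baseMean = 1000,
    log2FC = c(rep(1, 200), rep(-1, 600),        # targets: 200 up, 600 down
               rep(1, 6000), rep(-1, 6000)),     # others balanced
    tested = TRUE)
  res <- shift_test(de, paste0("g", 1:800), c(2, 4))
  expect_identical(unname(res$updown),
                   c(200L, 600L, 6000L, 6000L))
  expect_lt(res$fisher_p, 1e-10)
})

test_that("random sets are reproducible and sized correctly", {
  set.seed(51)
  de <- data.frame(gene_id = paste0("g", 1:500),
                   baseMean = 10^runif(500, 3, 4),
                   log2FC = rnorm(500), tested = TRUE)
  r1 <- random_set_null(de, c(2.5, 4.25), set_size = 50, k = 5, seed = 9)
  r2 <- random_set_null(de, c(2.5, 4.25), set_size = 50, k = 5, seed = 9)
  expect_identical(r1, r2)
  expect_identical(nrow(r1), 5L)
  expect_true(all(r1$D >= 0 & r1$D <= 1))
  expect_error(random_set_null(de, c(2.5, 4.25), set_size = 600),
               "exceeds")
})

test_that("low target coverage in the window is flagged", {
  de <- data.frame(gene_id = paste0("g", 1:100), baseMean = 1000,
                   log2FC = rnorm(100), tested = TRUE)
  expect_warning(res <- shift_test(de, c("g1", "g2"), c(2, 4)),
                 "2 target gene")
  expect_true(res$low_n)
})
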