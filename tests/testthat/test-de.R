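# Dispersion estimation, NB GLM fitting, BH adjustment and the DE stage.

test_that("BH adjustment equals the independent step-up oracle", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  expect_equal(bh_adjust(0.37), 0.37)
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")

  set.seed(71)
  for (i in 1:1000) {
    n <- sample(1:40, 1)
    p <- runif(n)
    if (i %% 7 == 0) p[sample(n, 1)] <- NA
    expect_equal(bh_adjust(p), oracle_bh(p))
  }
})

test_that("NB GLM recovers a known two-group log ratio", {
  # Poisson limit: groups with means 100 and 200 -> coefficient ln 2
  set.seed(81)
  n <- 200
  X <- cbind(1, rep(c(0, 1), each = n / 2))
  colnames(X) <- c("intercept", "genotypeKO")
  y <- matrix(c(rpois(n / 2, 100), rpois(n / 2, 200)), nrow = 1)
  fit <- fit_nb_glm(y, X, rep(1, n), dispersions = 1e-8)
  expect_true(fit$converged)
  expect_equal(unname(fit$beta[1, "genotypeKO"]), log(2), tolerance = 0.05)

  # cross-check coefficients and SEs against stats::glm with the
  # equivalent fixed-dispersion NB family
  skip_if_not_installed("MASS")
  alpha <- 0.1
  set.seed(82)
  y2 <- matrix(rnbinom(24, mu = rep(c(60, 120), each = 12),
                       size = 1 / alpha), nrow = 1)
  X2 <- cbind(1, rep(c(0, 1), each = 12))
  colnames(X2) <- c("intercept", "genotypeKO")
  sf <- runif(24, 0.8, 1.2)
  ours <- fit_nb_glm(y2, X2, sf, alpha)
  ref <- stats::glm(y2[1, ] ~ X2[, 2] + offset(log(sf)),
                    family = MASS::negative.binomial(theta = 1 / alpha))
  expect_equal(unname(ours$beta[1, ]), unname(coef(ref)),
               tolerance = 1e-6)
  # dispersion fixed at 1 in the reference: the NB family's extra
  # variance is already in the family, not a free scale parameter
  expect_equal(unname(ours$se[1, ]),
               unname(summary(ref, dispersion = 1)$coefficients[, "Std. Error"]),
               tolerance = 1e-4)
})

test_that("identical groups give near-zero coefficients and tame Wald stats", {
  set.seed(83)
  G <- 300
  X <- cbind(1, rep(c(0, 1), each = 6))
  colnames(X) <- c("intercept", "genotypeKO")
  y <- matrix(rnbinom(G * 12, mu = 100, size = 1 / 0.05), G, 12)
  fit <- fit_nb_glm(y, X, rep(1, 12), dispersions = 0.05)
  z <- fit$beta[, 2] / fit$se[, 2]
  expect_lt(abs(median(fit$beta[, 2])), 0.05)
  expect_gte(mean(abs(z) < 3), 0.99)
})

test_that("degenerate genes are handled: all zero and rank deficiency", {
  X <- cbind(1, rep(c(0, 1), each = 4))
  y <- matrix(0L, 1, 8)
  # all-zero genes never reach the fitter in run_de; here the fit simply
  # returns a tiny intercept, exercised for robustness
  fit <- fit_nb_glm(y, X, rep(1, 8), 0.1)
  expect_true(all(is.finite(fit$beta[1, 1])))
  Xbad <- cbind(1, 1, rep(c(0, 1), each = 4))
  expect_error(fit_nb_glm(matrix(1L, 1, 8), Xbad, rep(1, 8), 0.1),
               "rank deficient")
})

test_that("dispersion estimation recovers Poisson and NB truths", {
  set.seed(91)
  n <- 24
  X <- cbind(1, rep(c(0, 1), n / 2))
  sf <- rep(1, n)
  # Poisson counts at mu >= 100: final dispersion should be tiny
  y_pois <- matrix(rpois(500 * n, 150), 500, n,
                   dimnames = list(paste0("p", 1:500), NULL))
  # NB alpha = 0.1 genes
  y_nb <- matrix(rnbinom(500 * n, mu = 150, size = 10), 500, n,
                 dimnames = list(paste0("n", 1:500), NULL))
  d_pois <- estimate_dispersions(y_pois, sf, X)
  d_nb <- estimate_dispersions(y_nb, sf, X)
  expect_lte(median(d_pois$final), 0.01)
  expect_gte(median(d_nb$final), 0.05)
  expect_lte(median(d_nb$final), 0.2)
  # constant counts: moment estimate pinned at the floor
  y_const <- matrix(100L, 5, n, dimnames = list(paste0("c", 1:5), NULL))
  y_mix <- rbind(y_const, y_nb)
  d_mix <- estimate_dispersions(y_mix, sf, X)
  expect_true(all(d_mix$mom[1:5] == 1e-8))

  expect_error(estimate_dispersions(y_nb[, 1:3], sf[1:3], X[1:3, ]),
               "residual degrees")
})

test_that("the DE stage recovers planted IP effects and spares the Input", {
  s <- small_sim(seed = 202, n_genes = 2500)
  de_ip <- run_de(s$counts, s$samples, "IP")
  de_in <- run_de(s$counts, s$samples, "Input")
  tr <- s$truth
  planted <- tr$gene_id[tr$in_up | tr$in_down]

  # structure invariants
  expect_true(all(de_ip$padj >= de_ip$pvalue - 1e-12, na.rm = TRUE))
  expect_true(all(de_ip$padj <= 1, na.rm = TRUE))
  idx <- which(de_ip$tested)
  expect_equal(de_ip$stat[idx] * de_ip$lfcSE[idx], de_ip$log2FC[idx],
               tolerance = 1e-9)
  expect_true(all(is.na(de_ip$pvalue[!de_ip$tested])))

  # most planted IP genes found; signs agree with the planted effects
  hit <- de_ip$significant[match(planted, de_ip$gene_id)]
  expect_gte(mean(hit), 0.7)
  sig_up <- de_ip$gene_id[de_ip$significant & de_ip$log2FC > 0]
  expect_gt(mean(sig_up %in% tr$gene_id[tr$in_up]), 0.8)

  # planted IP-only effects leave the Input fraction quiet
  in_lfc <- de_in$log2FC[match(planted, de_in$gene_id)]
  expect_lt(median(abs(in_lfc), na.rm = TRUE), 0.25)
  expect_identical(sum(de_in$significant[match(planted, de_in$gene_id)],
                       na.rm = TRUE), 0L)

  # all-zero genes are not tested
  cz <- s$counts
  cz[1, ] <- 0L
  de_z <- run_de(cz, s$samples, "IP")
  expect_false(de_z$tested[1])
  expect_true(is.na(de_z$padj[1]))
})

test_that("permuting sample order leaves the DE table unchanged", {
  s <- small_sim(seed = 303, n_genes = 400)
  de1 <- run_de(s$counts, s$samples, "IP")
  set.seed(1)
  perm <- sample(ncol(s$counts))
  de2 <- run_de(s$counts[, perm], s$samples, "IP")
  expect_equal(de1$log2FC, de2$log2FC, tolerance = 1e-8)
  expect_equal(de1$pvalue, de2$pvalue, tolerance = 1e-8)
})

test_that("doubling one sample's counts shifts its size factor, not the fold changes", {
  s <- small_sim(seed = 404, n_genes = 400, disp_sdlog = 0)
  de1 <- run_de(s$counts, s$samples, "IP")
  c2 <- s$counts
  j <- which(colnames(c2) == "p1_WT_IP")
  c2[, j] <- c2[, j] * 2L
  de2 <- run_de(c2, s$samples, "IP")
  sf1 <- attr(de1, "size_factors")
  sf2 <- attr(de2, "size_factors")
  # doubling shifts the factor ratio to every other sample by 2 (the
  # geometric-mean reference itself absorbs 2^(1/n))
  expect_equal(unname(sf2[["p1_WT_IP"]] / sf2[["p2_WT_IP"]]),
               2 * unname(sf1[["p1_WT_IP"]] / sf1[["p2_WT_IP"]]),
               tolerance = 1e-9)
  keep <- de1$tested & de2$tested
  expect_equal(de1$log2FC[keep], de2$log2FC[keep], tolerance = 0.02)
})

test_that("unpaired design is available and broadly agrees on strong effects", {
  s <- small_sim(seed = 505, n_genes = 1200)
  de_p <- run_de(s$counts, s$samples, "IP", design = "paired")
  de_u <- run_de(s$counts, s$samples, "IP", design = "unpaired")
  tr <- s$truth
  planted_up <- tr$gene_id[tr$in_up]
  expect_gt(cor(de_p$log2FC[match(planted_up, de_p$gene_id)],
                de_u$log2FC[match(planted_up, de_u$gene_id)]), 0.9)
})
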