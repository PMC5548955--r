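# Paired negative-binomial differential expression: median-of-ratios
# normalization, method-of-moments dispersion estimation with a 1/mu
# trend and empirical-Bayes shrinkage toward it, per-gene NB GLM fitted
# by iteratively reweighted least squares with a log size-factor offset,
# Wald tests and Benjamini-Hochberg adjustment.

#' Estimate per-gene negative-binomial dispersions
#'
#' A two-pass procedure.  First, quick gene-wise estimates come from the
#' method of moments applied to size-factor-normalized counts: the
#' residual variance after an ordinary least-squares fit of the design
#' gives `alpha_mom = max((var - mean) / mean^2, 1e-8)`, and a
#' mean-dispersion trend `alpha(mu) = a1/mu + a0` is fitted to these by
#' iteratively trimmed least squares.  Second, with fitted means from a
#' preliminary GLM pass, each gene's dispersion is re-estimated on the
#' likelihood scale: the gene-wise estimate maximizes the Cox-Reid
#' adjusted negative-binomial profile log-likelihood, and the final value
#' maximizes that likelihood plus a log-normal prior (sd `prior_sdlog` on
#' `ln alpha`) centred on the trend.  Gene-wise likelihood estimates more
#' than `outlier_ratio`-fold above the trend are kept as-is (dispersion
#' outliers are not shrunk down).  Moment estimates alone are too noisy
#' at typical residual degrees of freedom to calibrate the Wald tail;
#' the adjusted-likelihood pass restores calibration (see the package
#' vignette).
#'
#' @param counts count matrix, genes x samples.
#' @param sf size factors (named as the columns of `counts`).
#' @param design design matrix (samples x coefficients, full rank).
#' @param prior_sdlog prior sd on `ln alpha` governing shrinkage strength.
#' @param outlier_ratio gene-wise/trend ratio above which a gene keeps its
#'   gene-wise likelihood estimate.
#' @return A list with per-gene vectors `mom` (moment estimates),
#'   `genewise` (Cox-Reid likelihood estimates), `trend` and `final`
#'   (maximum a posteriori), plus the trend `coef` (`a0`, `a1`) and
#'   `prior_sdlog`.
#' @export
estimate_dispersions <- function(counts, sf, design,
                                 prior_sdlog = 0.5,
                                 outlier_ratio = 10) {
  n <- ncol(counts)
  p <- qr(design)$rank
  if (p < ncol(design)) stop_fmt("design matrix is rank deficient")
  if (n - p < 2L)
    stop_fmt("need at least 2 residual degrees of freedom (n = %d, p = %d)",
             n, p)
  q <- sweep(counts, 2L, sf, "/")
  hat <- design %*% solve(crossprod(design), t(design))
  resid <- q - q %*% t(hat)
  var_q <- rowSums(resid^2) / (n - p)
  mean_q <- rowMeans(q)
  mom <- rep(1e-8, nrow(counts))
  ok <- mean_q > 0
  mom[ok] <- pmax((var_q[ok] - mean_q[ok]) / mean_q[ok]^2, 1e-8)
  genewise <- mom

  # provisional trend from the moment estimates, used only to seed the
  # preliminary GLM pass
  fit_idx <- which(ok & mom > 1e-8 & mean_q >= 1)
  if (length(fit_idx) < 10L)
    stop_fmt("too few genes (%d) with informative dispersion estimates",
             length(fit_idx))
  co0 <- .fit_disp_trend(mom[fit_idx], mean_q[fit_idx])
  trend0 <- pmax(co0[["a0"]] + co0[["a1"]] / pmax(mean_q, 1e-8), 1e-8)

  # likelihood pass: fitted means from a preliminary GLM run with
  # moment-shrunk starting values, then per-gene 1-D optimization of the
  # Cox-Reid adjusted profile log-likelihood in ln(alpha).  The CR term
  # (-1/2 log det X'WX) compensates for the residual degrees of freedom
  # absorbed by the mean fit, which otherwise biases the estimates low.
  s2_samp <- trigamma((n - p) / 2)
  w <- (1 / s2_samp) / (1 / s2_samp + 1 / prior_sdlog^2)
  start <- exp(w * log(pmax(mom, trend0 / 100)) + (1 - w) * log(trend0))
  pre <- fit_nb_glm(counts, design, sf, start)
  mu <- exp(pre$beta %*% t(design) +
              matrix(log(sf), nrow(counts), n, byrow = TRUE))
  mu <- pmax(mu, 1e-10)
  X <- as.matrix(design)
  neg_cr <- function(la, y, m, lt, prior_var) {
    alpha <- exp(la)
    W <- m / (1 + alpha * m)
    v <- -(sum(stats::dnbinom(y, mu = m, size = 1 / alpha, log = TRUE)) -
             0.5 * determinant(crossprod(X * sqrt(W)),
                               logarithm = TRUE)$modulus)
    if (!is.null(prior_var)) v <- v + (la - lt)^2 / (2 * prior_var)
    if (!is.finite(v)) 1e300 else as.numeric(v)
  }
  genewise <- vapply(seq_len(nrow(counts)), function(g) {
    o <- suppressWarnings(stats::optimize(
      neg_cr, c(-12, 3), y = counts[g, ], m = mu[g, ], lt = 0,
      prior_var = NULL))
    exp(o$minimum)
  }, numeric(1L))

  # definitive trend refitted on the likelihood estimates (less noisy
  # and less biased than the moment pass), then the shrinkage prior
  trd_idx <- which(genewise > 1e-5 & mean_q >= 1)
  co <- if (length(trd_idx) >= 10L) {
    .fit_disp_trend(genewise[trd_idx], mean_q[trd_idx])
  } else co0
  trend <- pmax(co[["a0"]] + co[["a1"]] / pmax(mean_q, 1e-8), 1e-8)

  lt <- log(trend)
  prior_var <- prior_sdlog^2
  final <- numeric(nrow(counts))
  for (g in seq_len(nrow(counts))) {
    if (genewise[g] > outlier_ratio * trend[g]) {
      final[g] <- genewise[g]     # dispersion outlier: no shrinkage
    } else {
      o_map <- suppressWarnings(stats::optimize(
        neg_cr, c(-12, 3), y = counts[g, ], m = mu[g, ], lt = lt[g],
        prior_var = prior_var))
      final[g] <- exp(o_map$minimum)
    }
  }
  final <- pmax(final, 1e-8)

  list(mom = mom, genewise = genewise, trend = trend, final = final,
       coef = co, prior_sdlog = prior_sdlog)
}

# Solve trigamma(x) = v for x > 0 (Newton on the monotone decreasing
# trigamma); used to convert the log-dispersion prior variance into
# effective prior degrees of freedom (df = 2x).
.inv_trigamma <- function(v) {
  x <- 0.5 + 1 / v
  for (i in 1:50) {
    delta <- (trigamma(x) - v) / psigamma(x, 2L)
    x <- x - delta
    if (abs(delta) < 1e-10) break
  }
  x
}

# Iteratively trimmed least-squares fit of alpha ~ a0 + a1/mu, trimming
# genes whose estimate/trend ratio falls outside [1e-2, 15] each round.
.fit_disp_trend <- function(alpha, mu) {
  inv_mu <- 1 / mu
  keep <- rep(TRUE, length(alpha))
  co <- c(0.01, 1)
  for (it in seq_len(10L)) {
    fit <- stats::lm.fit(cbind(1, inv_mu[keep]), alpha[keep])
    new_co <- fit$coefficients
    new_co[1L] <- max(new_co[1L], 1e-6)
    new_co[2L] <- max(new_co[2L], 0)
    ratio <- alpha / (new_co[1L] + new_co[2L] * inv_mu)
    new_keep <- ratio > 1e-2 & ratio < 15
    if (max(abs(new_co - co)) < 1e-8 * (1 + max(abs(co))) &&
        identical(new_keep, keep)) {
      co <- new_co
      break
    }
    co <- new_co
    keep <- new_keep
  }
  names(co) <- c("a0", "a1")
  co
}

#' Fit negative-binomial log-linear models to many genes
#'
#' Fits, for each row of `counts`, a negative-binomial GLM with log link,
#' fixed per-gene dispersion, offset `log(sf)`, by iteratively reweighted
#' least squares.  Standard errors come from the inverse expected Fisher
#' information `X' W X` with `W = mu / (1 + alpha mu)`.  Coefficients are
#' on the natural-log scale.
#'
#' @param counts count matrix (genes x samples); a single gene may be
#'   passed as a vector.
#' @param design full-rank design matrix (samples x coefficients).
#' @param sf size factors.
#' @param dispersions per-gene dispersion(s) `alpha` (recycled if length
#'   1).
#' @param tol convergence tolerance on the deviance change.
#' @param max_iter iteration cap; genes not converged by then are flagged.
#' @return A list with matrices `beta` and `se` (genes x coefficients),
#'   logical `converged`, and the per-gene final `deviance`.
#' @export
fit_nb_glm <- function(counts, design, sf, dispersions, tol = 1e-8,
                       max_iter = 50L) {
  if (is.null(dim(counts))) counts <- matrix(counts, nrow = 1L)
  y <- counts
  G <- nrow(y)
  n <- ncol(y)
  X <- as.matrix(design)
  p <- ncol(X)
  if (qr(X)$rank < p) stop_fmt("design matrix is rank deficient")
  if (length(sf) != n) stop_fmt("size factors do not match samples")
  alpha <- rep_len(dispersions, G)
  off <- log(sf)
  offm <- matrix(off, G, n, byrow = TRUE)

  # index pairs for the symmetric p x p normal-equation blocks
  ut <- which(upper.tri(diag(p), diag = TRUE), arr.ind = TRUE)
  M <- X[, ut[, 1L], drop = FALSE] * X[, ut[, 2L], drop = FALSE]

  beta <- matrix(0, G, p, dimnames = list(rownames(y), colnames(X)))
  beta[, 1L] <- log(pmax(rowMeans(sweep(y, 2L, sf, "/")), 1e-8))

  nb_dev <- function(y, mu, alpha) {
    t1 <- ifelse(y > 0, y * log(y / mu), 0)
    t2 <- (y + 1 / alpha) * log((1 + alpha * y) / (1 + alpha * mu))
    2 * rowSums(t1 - t2)
  }

  eta <- beta %*% t(X) + offm
  mu <- pmin(pmax(exp(eta), 1e-10), 1e12)
  dev <- nb_dev(y, mu, alpha)
  converged <- rep(FALSE, G)
  active <- seq_len(G)

  for (it in seq_len(max_iter)) {
    W <- mu / (1 + alpha * mu)
    Z <- (eta - offm) + (y - mu) / mu
    A <- (W %*% M)            # G x p(p+1)/2 stacked X'WX entries
    B <- (W * Z) %*% X        # G x p right-hand sides
    for (g in active) {
      S <- matrix(0, p, p)
      S[cbind(ut[, 1L], ut[, 2L])] <- A[g, ]
      S[cbind(ut[, 2L], ut[, 1L])] <- A[g, ]
      b <- tryCatch(solve(S, B[g, ]), error = function(e) NULL)
      if (is.null(b)) {
        converged[g] <- NA
        next
      }
      step <- b - beta[g, ]
      step[step > 10] <- 10
      step[step < -10] <- -10
      beta[g, ] <- beta[g, ] + step
    }
    active <- active[!is.na(converged[active])]
    eta <- beta %*% t(X) + offm
    mu <- pmin(pmax(exp(eta), 1e-10), 1e12)
    new_dev <- nb_dev(y, mu, alpha)
    done <- abs(new_dev[active] - dev[active]) <
      tol * (abs(new_dev[active]) + 1)
    converged[active[done]] <- TRUE
    dev <- new_dev
    active <- active[!done]
    if (!length(active)) break
  }
  converged[is.na(converged)] <- FALSE

  W <- mu / (1 + alpha * mu)
  A <- W %*% M
  se <- matrix(NA_real_, G, p, dimnames = dimnames(beta))
  for (g in seq_len(G)) {
    S <- matrix(0, p, p)
    S[cbind(ut[, 1L], ut[, 2L])] <- A[g, ]
    S[cbind(ut[, 2L], ut[, 1L])] <- A[g, ]
    v <- tryCatch(diag(solve(S)), error = function(e) rep(NA_real_, p))
    se[g, ] <- sqrt(pmax(v, 0))
  }
  list(beta = beta, se = se, converged = converged, deviance = dev)
}

#' Benjamini-Hochberg adjustment
#'
#' Standard step-up false-discovery-rate adjustment with monotonicity
#' enforcement.  `NA` p values are excluded from the number of tests and
#' propagate as `NA`.
#'
#' @param p numeric vector of p values in `[0, 1]`, `NA` allowed.
#' @return Adjusted p values, same length and order as `p`.
#' @export
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE))
    stop_fmt("p values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Paired negative-binomial differential expression for one fraction
#'
#' Runs the full stage on the samples of a single fraction: size factors,
#' dispersion estimation, per-gene NB GLM with littermate blocking
#' (`~ pair + genotype`; `~ genotype` when `design = "unpaired"`), Wald
#' test of the KO-vs-WT coefficient (two-sided, standard normal) and
#' Benjamini-Hochberg adjustment.  Genes with all-zero counts, or below
#' the base-mean filter, are not tested and carry `NA` statistics.
#'
#' The Wald statistic is referred by default to a t distribution whose
#' degrees of freedom add the dispersion prior's effective information
#' (the inverse-trigamma of the prior variance) to the residual degrees
#' of freedom, the standard plug-in correction for testing with
#' moderated dispersion estimates; `wald_dist = "normal"` gives the
#' plain standard-normal reference (see the package vignette for the
#' calibration measurements behind this default).
#'
#' @param counts count matrix covering all samples.
#' @param samples sample sheet (see [read_sample_sheet()]).
#' @param fraction `"IP"` or `"Input"`; the analysis is restricted to that
#'   fraction's samples.
#' @param design `"paired"` (littermate blocking, default) or
#'   `"unpaired"`.
#' @param fdr FDR threshold used to flag significant genes (default 0.1).
#' @param min_base_mean genes with mean normalized count below this are
#'   not tested; set to 0 to disable.
#' @param wald_dist reference distribution for the Wald statistic:
#'   `"t"` (residual + prior effective df, default) or `"normal"`.
#' @return A `data.frame` of class `trap_de` with columns `gene_id`,
#'   `baseMean`, `log2FC`, `lfcSE`, `stat`, `pvalue`, `padj`, `tested`,
#'   `significant`; size factors and the dispersion fit are attached as
#'   attributes.
#' @export
run_de <- function(counts, samples, fraction = c("IP", "Input"),
                   design = c("paired", "unpaired"), fdr = 0.1,
                   min_base_mean = 0.5, wald_dist = c("t", "normal")) {
  fraction <- match.arg(fraction)
  design <- match.arg(design)
  wald_dist <- match.arg(wald_dist)
  samples <- validate_sample_sheet(samples)
  validate_counts(counts)
  sub <- samples[samples$fraction == fraction, , drop = FALSE]
  if (length(unique(sub$pair_id)) < 2L)
    stop_fmt("need at least two littermate pairs in fraction %s", fraction)
  missing <- setdiff(sub$sample_id, colnames(counts))
  if (length(missing))
    stop_fmt("sample '%s' absent from count matrix", missing[1L])
  cnt <- counts[, sub$sample_id, drop = FALSE]

  genotype <- factor(sub$genotype, levels = .GENOTYPES)
  pair <- factor(sub$pair_id)
  X <- if (design == "paired") {
    stats::model.matrix(~ pair + genotype)
  } else {
    stats::model.matrix(~ genotype)
  }
  coef_name <- "genotypeKO"

  sf <- size_factors(cnt)
  norm <- sweep(cnt, 2L, sf, "/")
  base_mean <- rowMeans(norm)
  tested <- rowSums(cnt) > 0 & base_mean >= min_base_mean

  res <- data.frame(gene_id = rownames(cnt), baseMean = base_mean,
                    log2FC = NA_real_, lfcSE = NA_real_, stat = NA_real_,
                    pvalue = NA_real_, padj = NA_real_, tested = tested,
                    stringsAsFactors = FALSE)
  rownames(res) <- NULL

  if (any(tested)) {
    disp <- estimate_dispersions(cnt[tested, , drop = FALSE], sf, X)
    fit <- fit_nb_glm(cnt[tested, , drop = FALSE], X, sf, disp$final)
    ok <- fit$converged & is.finite(fit$se[, coef_name]) &
      fit$se[, coef_name] > 0
    lfc <- fit$beta[, coef_name] / log(2)
    se <- fit$se[, coef_name] / log(2)
    stat <- ifelse(ok, lfc / se, NA_real_)
    if (wald_dist == "t") {
      df_prior <- .inv_trigamma(disp$prior_sdlog^2) * 2
      df_test <- (nrow(X) - ncol(X)) + df_prior
      pval <- 2 * stats::pt(-abs(stat), df = df_test)
    } else {
      df_test <- Inf
      pval <- 2 * stats::pnorm(-abs(stat))
    }
    idx <- which(tested)
    res$log2FC[idx] <- ifelse(ok, lfc, NA_real_)
    res$lfcSE[idx] <- ifelse(ok, se, NA_real_)
    res$stat[idx] <- stat
    res$pvalue[idx] <- pval
    res$tested[idx] <- ok
    res$padj[idx][ok] <- bh_adjust(pval[ok])
    attr(res, "dispersion_fit") <- disp
  }
  res$significant <- !is.na(res$padj) & res$padj < fdr
  attr(res, "wald_df") <- if (any(tested)) df_test else NA_real_
  attr(res, "size_factors") <- sf
  attr(res, "fraction") <- fraction
  attr(res, "design") <- design
  attr(res, "fdr") <- fdr
  class(res) <- c("trap_de", "data.frame")
  res
}
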