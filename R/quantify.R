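# Normalization and abundance computations: median-of-ratios size
# factors, gene-level TPM, heatmap-style normalization (WT-mean division
# followed by per-gene z-scoring) and qPCR relative quantification.

#' Median-of-ratios size factors
#'
#' Computes per-sample scale factors by the median-of-ratios method: for
#' genes with strictly positive counts in every sample, each sample's
#' factor is the median ratio of its counts to the per-gene geometric
#' means.  No pseudocounts are used; genes with any zero count are
#' excluded from the reference.
#'
#' @param counts count matrix (genes x samples), at least two samples.
#' @return A named numeric vector of positive size factors.
#' @export
size_factors <- function(counts) {
  validate_counts(counts)
  if (ncol(counts) < 2L) stop_fmt("size factors need at least two samples")
  pos <- rowSums(counts > 0) == ncol(counts)
  if (!any(pos))
    stop_fmt("no gene has positive counts in every sample; cannot form a median-of-ratios reference")
  lg <- log(counts[pos, , drop = FALSE])
  geo <- rowMeans(lg)
  sf <- apply(exp(lg - geo), 2L, stats::median)
  if (any(!is.finite(sf) | sf <= 0))
    stop_fmt("non-positive size factor for sample '%s'",
             colnames(counts)[which(!is.finite(sf) | sf <= 0)][1L])
  sf
}

#' Gene-level TPM
#'
#' Transcripts per million computed directly at gene level: the per-gene
#' length-normalized rate `count/length` is rescaled so that every column
#' with any nonzero count sums to one million.
#'
#' @param counts count matrix.
#' @param lengths named vector of effective gene lengths (bases) covering
#'   every gene in `counts`.
#' @return A numeric matrix of TPM values with the dimensions of `counts`.
#' @export
tpm <- function(counts, lengths) {
  validate_counts(counts)
  missing <- setdiff(rownames(counts), names(lengths))
  if (length(missing))
    stop_fmt("no length for gene '%s'", missing[1L])
  len <- lengths[rownames(counts)]
  rate <- counts / len
  denom <- colSums(rate)
  zero <- denom == 0
  if (any(zero)) {
    warn_fmt("%d sample(s) with all-zero counts yield all-zero TPM columns",
             sum(zero))
    denom[zero] <- 1
  }
  sweep(rate, 2L, denom, "/") * 1e6
}

#' Heatmap-style normalization
#'
#' Divides each gene by its mean over the wild-type samples, then centres
#' and scales each gene to zero mean and unit variance across all samples
#' (row scaling, the convention of standard heatmap tools).  Genes whose
#' WT mean is zero, or whose normalized values are constant, are dropped
#' with a warning.
#'
#' @param x TPM (or normalized-count) matrix, genes x samples.
#' @param wt_samples character vector of wild-type sample ids (columns of
#'   `x`).
#' @return The row-scaled matrix restricted to retained genes.
#' @export
heatmap_normalize <- function(x, wt_samples) {
  if (!length(wt_samples)) stop_fmt("wt_samples must be non-empty")
  missing <- setdiff(wt_samples, colnames(x))
  if (length(missing)) stop_fmt("unknown WT sample '%s'", missing[1L])
  wt_mean <- rowMeans(x[, wt_samples, drop = FALSE])
  keep <- wt_mean > 0
  if (!any(keep)) stop_fmt("all genes have zero WT mean; nothing to scale")
  if (any(!keep))
    warn_fmt("%d gene(s) with zero WT mean dropped", sum(!keep))
  y <- x[keep, , drop = FALSE] / wt_mean[keep]
  mu <- rowMeans(y)
  sdv <- apply(y, 1L, stats::sd)
  const <- sdv == 0
  if (any(const)) {
    warn_fmt("%d constant gene(s) dropped (zero variance)", sum(const))
    y <- y[!const, , drop = FALSE]
    mu <- mu[!const]
    sdv <- sdv[!const]
  }
  (y - mu) / sdv
}

#' qPCR relative quantification (delta-delta-Ct)
#'
#' Each target Ct is normalized to the reference gene, and the IP sample
#' is then normalized to its corresponding Input sample:
#' `ddCt = (ct_target_ip - ct_ref_ip) - (ct_target_input - ct_ref_input)`,
#' fold change `2^(-ddCt)` assuming perfect doubling per cycle.
#'
#' @param ct_target_ip,ct_ref_ip,ct_target_input,ct_ref_input finite Ct
#'   values (vectorized).
#' @return Fold change(s), `2^(-ddCt)`.
#' @export
rel_quant <- function(ct_target_ip, ct_ref_ip, ct_target_input,
                      ct_ref_input) {
  vals <- c(ct_target_ip, ct_ref_ip, ct_target_input, ct_ref_input)
  if (any(!is.finite(vals))) stop_fmt("Ct values must be finite")
  ddct <- (ct_target_ip - ct_ref_ip) - (ct_target_input - ct_ref_input)
  2^(-ddct)
}
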