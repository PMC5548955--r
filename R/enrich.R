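# Protein-clan (Pfam-clan) enrichment of a gene list against an
# expressed-gene background, with the list-adjustment and background
# rules of TPM-based expression filtering, and overlap reporting between
# two enriched-clan lists.

#' Expressed-gene background from a TPM table
#'
#' Genes with TPM > 0 in at least one sample.
#'
#' @param tpm_table TPM matrix, genes x samples.
#' @return Character vector of expressed gene ids.
#' @export
expressed_background <- function(tpm_table) {
  rownames(tpm_table)[rowSums(tpm_table > 0) > 0]
}

#' Restrict a gene set to genes detected in IP samples
#'
#' Keeps the genes of a set with TPM > 0 in at least one IP sample;
#' genes absent from the TPM table are dropped.
#'
#' @param genes character vector of gene ids.
#' @param tpm_table TPM matrix.
#' @param ip_samples character vector of IP sample ids (columns of
#'   `tpm_table`).
#' @return The adjusted character vector; empty with a warning if no
#'   gene survives.
#' @export
adjust_target_list <- function(genes, tpm_table, ip_samples) {
  missing <- setdiff(ip_samples, colnames(tpm_table))
  if (length(missing)) stop_fmt("unknown IP sample '%s'", missing[1L])
  sub <- tpm_table[rownames(tpm_table) %in% genes, ip_samples,
                   drop = FALSE]
  kept <- rownames(sub)[rowSums(sub > 0) > 0]
  out <- genes[genes %in% kept]
  if (!length(out))
    warn_fmt("no gene of the set is detected in any IP sample")
  out
}

#' Per-clan Fisher enrichment of a gene list
#'
#' For every clan represented in the list, builds the 2x2 table of clan
#' membership versus list membership over the background and applies the
#' two-sided Fisher exact test.  Background genes without any clan
#' annotation stay in the table (they dilute enrichment).  A clan is
#' flagged enriched when `p < alpha` and its proportion in the list
#' exceeds its proportion in the background.  No multiplicity correction
#' is applied by default (a fixed `p < alpha` rule); `adjust = "BH"`
#' additionally reports BH-adjusted p values and applies the flag to
#' them.
#'
#' @param gene_list character vector of genes, a subset of `background`.
#' @param background character vector of background gene ids.
#' @param clan_map data.frame with `gene_id`, `clan_id` (see
#'   [read_clan_map()]).
#' @param alpha enrichment threshold on the (possibly adjusted) p value.
#' @param adjust `"none"` (default) or `"BH"`.
#' @return A data.frame of class `trap_enrichment`, sorted by p: `clan`,
#'   `a`, `b`, `c`, `d` (list-in-clan, list-not-clan, rest-in-clan,
#'   rest-not-clan), `odds_ratio`, `continuity` (TRUE when the 0.5
#'   correction was applied to the odds ratio), `p`, optionally `padj`,
#'   `enriched`.
#' @export
clan_enrichment <- function(gene_list, background, clan_map, alpha = 0.01,
                            adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  gene_list <- unique(gene_list)
  background <- unique(background)
  if (!length(gene_list) || !length(background))
    stop_fmt("gene list and background must be non-empty")
  outside <- setdiff(gene_list, background)
  if (length(outside))
    stop_fmt("gene '%s' of the list is not in the background", outside[1L])
  map <- clan_map[clan_map$gene_id %in% background, , drop = FALSE]
  sets <- clan_sets(map)
  in_list <- vapply(sets, function(g) sum(gene_list %in% g), integer(1L))
  sets <- sets[in_list > 0L]            # clans absent from the list skipped
  if (!length(sets)) {
    warn_fmt("no clan is represented in the gene list")
    out <- data.frame(clan = character(), a = integer(), b = integer(),
                      c = integer(), d = integer(), odds_ratio = numeric(),
                      continuity = logical(), p = numeric(),
                      enriched = logical(), stringsAsFactors = FALSE)
    class(out) <- c("trap_enrichment", "data.frame")
    return(out)
  }
  n_list <- length(gene_list)
  n_bg <- length(background)
  rows <- lapply(names(sets), function(cl) {
    clan_genes <- intersect(sets[[cl]], background)
    a <- sum(gene_list %in% clan_genes)
    b <- n_list - a
    c_ <- length(clan_genes) - a
    d <- n_bg - n_list - c_
    fe <- fisher_exact(c(a, b, c_, d))
    cont <- any(c(a, b, c_, d) == 0L)
    or <- if (cont) {
      ((a + 0.5) * (d + 0.5)) / ((b + 0.5) * (c_ + 0.5))
    } else fe$odds_ratio
    data.frame(clan = cl, a = a, b = b, c = c_, d = d, odds_ratio = or,
               continuity = cont, p = fe$p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  direction <- out$a / n_list > (out$a + out$c) / n_bg
  if (adjust == "BH") {
    out$padj <- bh_adjust(out$p)
    out$enriched <- out$padj < alpha & direction
  } else {
    out$enriched <- out$p < alpha & direction
  }
  out <- out[order(out$p, out$clan), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "alpha") <- alpha
  attr(out, "n_list") <- n_list
  attr(out, "n_background") <- n_bg
  class(out) <- c("trap_enrichment", "data.frame")
  out
}

#' Overlap between two enriched-clan lists
#'
#' Reports the intersection of the enriched clans of two enrichment
#' tables as an "x out of y" summary, with A's enriched clans as the
#' reference denominator.
#'
#' @param enriched_a,enriched_b `trap_enrichment` tables (or character
#'   vectors of clan ids).
#' @return A list with `shared` (clan ids), `n_shared`, `n_a`, `n_b` and
#'   a formatted `summary` string.
#' @export
overlap_report <- function(enriched_a, enriched_b) {
  as_clans <- function(x) {
    if (is.character(x)) return(unique(x))
    unique(x$clan[x$enriched])
  }
  a <- as_clans(enriched_a)
  b <- as_clans(enriched_b)
  shared <- intersect(a, b)
  list(shared = shared, n_shared = length(shared), n_a = length(a),
       n_b = length(b),
       summary = sprintf("%d out of %d", length(shared), length(a)))
}
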