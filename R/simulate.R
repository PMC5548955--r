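# Synthetic paired TRAP-seq data with planted ground truth.  Counts are
# drawn from a negative binomial with the mean structure the downstream
# model assumes: baseline x library size factor x animal (littermate)
# effect x IP enrichment (IP samples only) x 2^(genotype effect for KO),
# and variance mu + alpha * mu^2 with a dispersion trend alpha(mu) =
# a1/mu + a0 modulated by log-normal gene-level noise.

#' Simulation configuration
#'
#' Builds the configuration object consumed by [simulate_trap()].  The
#' defaults emulate the study design the pipeline targets: six littermate
#' pairs, each animal contributing one Input and one IP library; a planted
#' differential-translation signal of 90 upregulated and 31 downregulated
#' genes (IP fraction only, |log2 fold change| near 1); an 800-gene target
#' set carrying a subtle downward shift (-0.2 log2) in both fractions; and
#' 40 protein clans of which 2 are enriched among the upregulated genes.
#'
#' @param n_pairs number of littermate pairs (each contributes a WT and a
#'   KO animal, and each animal an Input and an IP sample).
#' @param n_genes number of genes.
#' @param seed integer seed; all randomness in [simulate_trap()] derives
#'   from it.
#' @param baseline_meanlog,baseline_sdlog natural-log mean and sd of the
#'   log-normal baseline expression (expected Input counts at size factor
#'   1).
#' @param ip_enrichment_sdlog sd (ln scale) of the per-gene IP enrichment
#'   multiplier; median enrichment is 1 so IP and Input libraries are
#'   comparable in depth.
#' @param libsize_sdlog sd (ln scale) of per-sample library size factors.
#' @param pair_sdlog sd (ln scale) of per-animal littermate multipliers
#'   (shared by that animal's Input and IP samples).
#' @param disp_a0,disp_a1 asymptotic and 1/mu coefficients of the
#'   dispersion trend `alpha(mu) = a1/mu + a0`.
#' @param disp_sdlog sd (ln scale) of gene-level dispersion noise around
#'   the trend.
#' @param n_up,up_lfc_mean,up_lfc_sd size and log2 effect (mean, sd) of the
#'   planted upregulated set, applied in the IP fraction only.
#' @param n_down,down_lfc_mean,down_lfc_sd size and log2 effect of the
#'   planted downregulated set, applied in the IP fraction only.
#' @param n_target,target_lfc_mean,target_lfc_sd size and log2 effect of
#'   the target (e.g. RNA-binding-protein target) set, applied in both
#'   fractions.
#' @param de_abundance_range log10 baseline-mean interval from which the
#'   planted up/down genes are drawn; defaults to the quantifiable range in
#'   which differential genes are observed in bulk data.
#' @param target_abundance_range log10 baseline-mean interval from which
#'   target genes are drawn; target mRNAs skew toward well-expressed genes.
#' @param n_clans number of protein clans.
#' @param n_enriched_clans number of clans over-represented among the
#'   planted upregulated genes.
#' @param clan_prob probability that a gene carries any clan annotation.
#' @param second_clan_prob probability that an annotated gene belongs to a
#'   second clan.
#' @param enriched_clan_prob probability that a planted upregulated gene is
#'   (additionally) assigned to one of the enriched clans.
#' @param length_meanlog,length_sdlog log-normal parameters of gene
#'   effective lengths (bases), centred near 2 kb.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_pairs = 6L,
                       n_genes = 15000L,
                       seed = 1L,
                       baseline_meanlog = log(60),
                       baseline_sdlog = 1.8,
                       ip_enrichment_sdlog = 0.5,
                       libsize_sdlog = 0.15,
                       pair_sdlog = 0.05,
                       disp_a0 = 0.01,
                       disp_a1 = 2,
                       disp_sdlog = 0.25,
                       n_up = 90L,
                       up_lfc_mean = 1.0,
                       up_lfc_sd = 0.1,
                       n_down = 31L,
                       down_lfc_mean = -1.0,
                       down_lfc_sd = 0.1,
                       n_target = 800L,
                       target_lfc_mean = -0.2,
                       target_lfc_sd = 0.05,
                       de_abundance_range = c(2, 4),
                       target_abundance_range = c(2.3, 4.2),
                       n_clans = 40L,
                       n_enriched_clans = 2L,
                       clan_prob = 0.7,
                       second_clan_prob = 0.1,
                       enriched_clan_prob = 0.6,
                       length_meanlog = log(2000),
                       length_sdlog = 0.5) {
  cfg <- list(n_pairs = as.integer(n_pairs), n_genes = as.integer(n_genes),
              seed = as.integer(seed),
              baseline_meanlog = baseline_meanlog,
              baseline_sdlog = baseline_sdlog,
              ip_enrichment_sdlog = ip_enrichment_sdlog,
              libsize_sdlog = libsize_sdlog, pair_sdlog = pair_sdlog,
              disp_a0 = disp_a0, disp_a1 = disp_a1, disp_sdlog = disp_sdlog,
              n_up = as.integer(n_up), up_lfc_mean = up_lfc_mean,
              up_lfc_sd = up_lfc_sd,
              n_down = as.integer(n_down), down_lfc_mean = down_lfc_mean,
              down_lfc_sd = down_lfc_sd,
              n_target = as.integer(n_target),
              target_lfc_mean = target_lfc_mean,
              target_lfc_sd = target_lfc_sd,
              de_abundance_range = de_abundance_range,
              target_abundance_range = target_abundance_range,
              n_clans = as.integer(n_clans),
              n_enriched_clans = as.integer(n_enriched_clans),
              clan_prob = clan_prob, second_clan_prob = second_clan_prob,
              enriched_clan_prob = enriched_clan_prob,
              length_meanlog = length_meanlog, length_sdlog = length_sdlog)
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
}

validate_sim_config <- function(cfg) {
  sds <- c(cfg$baseline_sdlog, cfg$ip_enrichment_sdlog, cfg$libsize_sdlog,
           cfg$pair_sdlog, cfg$disp_sdlog, cfg$up_lfc_sd, cfg$down_lfc_sd,
           cfg$target_lfc_sd, cfg$length_sdlog)
  if (any(sds < 0)) stop_fmt("all sd parameters must be >= 0")
  if (cfg$n_pairs < 1L || cfg$n_genes < 1L)
    stop_fmt("n_pairs and n_genes must be positive")
  if (cfg$n_up + cfg$n_down + cfg$n_target > cfg$n_genes)
    stop_fmt("planted set sizes (%d) exceed n_genes (%d)",
             cfg$n_up + cfg$n_down + cfg$n_target, cfg$n_genes)
  if (cfg$disp_a0 < 0 || cfg$disp_a1 < 0)
    stop_fmt("dispersion trend coefficients must be >= 0")
  cfg
}

#' Remove every planted effect from a configuration
#'
#' Returns a configuration identical to the input except that all planted
#' sets are empty, producing a global-null simulation for false-discovery
#' calibration.  Idempotent.
#'
#' @param cfg a `sim_config`.
#' @return The null `sim_config`.
#' @export
null_config <- function(cfg) {
  cfg$n_up <- 0L
  cfg$n_down <- 0L
  cfg$n_target <- 0L
  validate_sim_config(cfg)
}

# Sample `n` gene indices whose baseline falls in the 10^range window,
# excluding `taken`; falls back to the closest-abundance genes if the
# window holds too few.
.sample_in_range <- function(baseline, n, range, taken) {
  if (n == 0L) return(integer())
  pool <- which(log10(baseline) >= range[1L] & log10(baseline) <= range[2L])
  pool <- setdiff(pool, taken)
  if (length(pool) < n) {
    mid <- mean(range)
    extra <- setdiff(order(abs(log10(baseline) - mid)), c(taken, pool))
    pool <- c(pool, extra[seq_len(n - length(pool))])
  }
  sample(pool, n)
}

#' Generate a synthetic paired TRAP-seq dataset
#'
#' Draws a gene x sample negative-binomial count matrix under the paired
#' IP/Input design together with the matching sample sheet, gene lengths,
#' clan map, gene sets (GMT-style list) and a ground-truth table.  The
#' output is deterministic for a fixed `cfg$seed`.
#'
#' @param cfg a [sim_config()].
#' @return A list with elements `counts` (integer matrix), `samples`
#'   (sample sheet), `lengths` (named vector), `clan_map` (data.frame),
#'   `gene_sets` (named list of character vectors: `up`, `down`, `target`),
#'   and `truth` (per-gene data.frame with planted effects; per-sample true
#'   size factors in `attr(truth, "size_factors")`).
#' @export
simulate_trap <- function(cfg = sim_config()) {
  validate_sim_config(cfg)
  with_seed(derive_seed(cfg$seed, "simulate"), {
    G <- cfg$n_genes
    P <- cfg$n_pairs
    genes <- sprintf("g%05d", seq_len(G))

    samples <- expand.grid(fraction = .FRACTIONS, genotype = .GENOTYPES,
                           pair_id = seq_len(P), stringsAsFactors = FALSE,
                           KEEP.OUT.ATTRS = FALSE)
    samples$animal_id <- paste0("p", samples$pair_id, "_", samples$genotype)
    samples$sample_id <- paste0(samples$animal_id, "_", samples$fraction)
    samples <- samples[, c("sample_id", "fraction", "genotype", "pair_id",
                           "animal_id")]
    n_samp <- nrow(samples)

    baseline <- exp(stats::rnorm(G, cfg$baseline_meanlog, cfg$baseline_sdlog))
    ip_enrich <- exp(stats::rnorm(G, 0, cfg$ip_enrichment_sdlog))
    disp <- (cfg$disp_a1 / baseline + cfg$disp_a0) *
      exp(stats::rnorm(G, 0, cfg$disp_sdlog))
    size_f <- exp(stats::rnorm(n_samp, 0, cfg$libsize_sdlog))
    names(size_f) <- samples$sample_id
    animal_eff <- exp(stats::rnorm(2L * P, 0, cfg$pair_sdlog))
    names(animal_eff) <- unique(samples$animal_id)

    # planted sets are mutually disjoint; up/down genes lie in the
    # quantifiable abundance range, target genes skew well-expressed
    idx_up <- .sample_in_range(baseline, cfg$n_up, cfg$de_abundance_range,
                               integer())
    idx_down <- .sample_in_range(baseline, cfg$n_down,
                                 cfg$de_abundance_range, idx_up)
    idx_target <- .sample_in_range(baseline, cfg$n_target,
                                   cfg$target_abundance_range,
                                   c(idx_up, idx_down))

    lfc_ip <- lfc_input <- numeric(G)
    lfc_ip[idx_up] <- stats::rnorm(cfg$n_up, cfg$up_lfc_mean, cfg$up_lfc_sd)
    lfc_ip[idx_down] <- stats::rnorm(cfg$n_down, cfg$down_lfc_mean,
                                     cfg$down_lfc_sd)
    tgt_shift <- stats::rnorm(cfg$n_target, cfg$target_lfc_mean,
                              cfg$target_lfc_sd)
    lfc_ip[idx_target] <- tgt_shift
    lfc_input[idx_target] <- tgt_shift

    # clan annotation; the enriched clans recruit extra upregulated genes
    clans <- sprintf("CL%03d", seq_len(cfg$n_clans))
    has_clan <- stats::runif(G) < cfg$clan_prob
    clan1 <- ifelse(has_clan, sample(clans, G, replace = TRUE), NA_character_)
    has2 <- has_clan & stats::runif(G) < cfg$second_clan_prob
    clan2 <- ifelse(has2, sample(clans, G, replace = TRUE), NA_character_)
    map <- data.frame(
      gene_id = c(genes[has_clan], genes[has2]),
      clan_id = c(clan1[has_clan], clan2[has2]),
      stringsAsFactors = FALSE)
    if (cfg$n_enriched_clans > 0L && cfg$n_up > 0L) {
      enriched <- clans[seq_len(cfg$n_enriched_clans)]
      recruit <- idx_up[stats::runif(cfg$n_up) < cfg$enriched_clan_prob]
      if (length(recruit))
        map <- rbind(map, data.frame(
          gene_id = genes[recruit],
          clan_id = sample(enriched, length(recruit), replace = TRUE),
          stringsAsFactors = FALSE))
    }
    map <- unique(map)
    map <- map[order(map$gene_id, map$clan_id), , drop = FALSE]
    rownames(map) <- NULL

    lengths <- exp(stats::rnorm(G, cfg$length_meanlog, cfg$length_sdlog))
    names(lengths) <- genes

    is_ip <- samples$fraction == "IP"
    is_ko <- samples$genotype == "KO"
    mu <- matrix(0, G, n_samp, dimnames = list(genes, samples$sample_id))
    for (j in seq_len(n_samp)) {
      m <- baseline * size_f[j] * animal_eff[[samples$animal_id[j]]]
      if (is_ip[j]) m <- m * ip_enrich
      if (is_ko[j]) m <- m * 2^(if (is_ip[j]) lfc_ip else lfc_input)
      mu[, j] <- m
    }
    counts <- matrix(stats::rnbinom(G * n_samp, mu = mu, size = 1 / disp),
                     G, n_samp, dimnames = dimnames(mu))
    storage.mode(counts) <- "double"

    truth <- data.frame(
      gene_id = genes, baseline = baseline, ip_enrichment = ip_enrich,
      log2fc_ip = lfc_ip, log2fc_input = lfc_input, dispersion = disp,
      in_up = seq_len(G) %in% idx_up,
      in_down = seq_len(G) %in% idx_down,
      in_target = seq_len(G) %in% idx_target,
      stringsAsFactors = FALSE)
    attr(truth, "size_factors") <- size_f
    attr(truth, "animal_effects") <- animal_eff

    gene_sets <- list(up = genes[sort(idx_up)],
                      down = genes[sort(idx_down)],
                      target = genes[sort(idx_target)])

    list(counts = counts, samples = samples, lengths = lengths,
         clan_map = map, gene_sets = gene_sets, truth = truth,
         config = cfg)
  })
}

#' Write all simulation outputs to a directory
#'
#' Emits `counts.tsv`, `samples.tsv`, `lengths.tsv`, `clans.tsv`,
#' `sets.gmt` and `truth.tsv`.
#'
#' @param sim result of [simulate_trap()].
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_counts(sim$counts, file.path(dir, "counts.tsv"))
  write_sample_sheet(sim$samples, file.path(dir, "samples.tsv"))
  write_gene_lengths(sim$lengths, file.path(dir, "lengths.tsv"))
  write_clan_map(sim$clan_map, file.path(dir, "clans.tsv"))
  write_gmt(sim$gene_sets, file.path(dir, "sets.gmt"))
  write_results(sim$truth, file.path(dir, "truth.tsv"))
  invisible(dir)
}
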