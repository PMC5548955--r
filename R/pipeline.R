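# End-to-end orchestration: simulate (or load) -> normalize -> paired DE
# per fraction -> target-set shift tests with resampling null -> clan
# enrichment and overlap -> one reproducible report.  All randomness
# derives from the single config seed via per-stage sub-seeds.

.DEFAULT_CONFIG <- list(
  seed = 1L,
  fdr = 0.1,
  clan_alpha = 0.01,
  n_random_sets = 5L,
  window_input = c(2.5, 4.25),
  window_ip = c(2.75, 4.75),
  de_design = "paired",
  min_base_mean = 0.5,
  include_targets_in_background = TRUE,
  counts = NULL, samples = NULL, lengths = NULL, clans = NULL,
  sets = NULL, target_set = "target",
  sim = NULL,
  out_dir = NULL)

parse_window <- function(x) {
  if (is.character(x) && length(x) == 1L)
    x <- as.numeric(strsplit(x, ":", fixed = TRUE)[[1L]])
  x <- as.numeric(x)
  if (length(x) != 2L || anyNA(x) || x[1L] >= x[2L])
    stop_fmt("window must be two increasing log10 exponents, e.g. '2.5:4.25'")
  x
}

#' Validate and resolve a run configuration
#'
#' Reads a YAML file (or takes a list), rejects unknown keys, and fills
#' defaults: FDR 0.1, clan alpha 0.01, abundance windows 2.5:4.25 (Input)
#' and 2.75:4.75 (IP), 5 random sets.  When no input paths are given the
#' run simulates its data with [sim_config()] defaults (any `sim:` keys
#' override individual generator parameters).
#'
#' @param config path to a YAML file, or a named list, or `NULL` for all
#'   defaults.
#' @return A resolved configuration list of class `run_config`.
#' @export
validate_config <- function(config = NULL) {
  if (is.character(config)) {
    config <- yaml::read_yaml(config)
    if (is.null(config)) config <- list()
  }
  config <- config %||% list()
  unknown <- setdiff(names(config), names(.DEFAULT_CONFIG))
  if (length(unknown))
    stop_fmt("unknown configuration key(s): %s",
             paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(.DEFAULT_CONFIG, config, keep.null = TRUE)
  cfg$seed <- as.integer(cfg$seed)
  cfg$window_input <- parse_window(cfg$window_input)
  cfg$window_ip <- parse_window(cfg$window_ip)
  cfg$de_design <- match.arg(cfg$de_design, c("paired", "unpaired"))
  if (cfg$fdr <= 0 || cfg$fdr >= 1) stop_fmt("fdr must be in (0, 1)")
  if (cfg$clan_alpha <= 0 || cfg$clan_alpha >= 1)
    stop_fmt("clan_alpha must be in (0, 1)")
  paths <- c("counts", "samples", "lengths", "clans", "sets")
  given <- !vapply(cfg[paths], is.null, logical(1L))
  if (any(given)) {
    if (!all(given))
      stop_fmt("either all of %s must be given, or none (simulation mode)",
               paste(paths, collapse = ", "))
    for (p in paths)
      if (!file.exists(cfg[[p]]))
        stop_fmt("configured %s file does not exist: %s", p, cfg[[p]])
    cfg$mode <- "files"
  } else {
    sim_args <- cfg$sim %||% list()
    sim_args$seed <- derive_seed(cfg$seed, "simulate")
    cfg$sim <- do.call(sim_config, sim_args)
    cfg$mode <- "simulate"
  }
  class(cfg) <- "run_config"
  cfg
}

#' Run the full pipeline
#'
#' Executes every stage in order and returns a report; with an output
#' directory, every intermediate table is written as TSV (with a header
#' recording version and seed) and the report as JSON.  Stages fail fast
#' with a stage-tagged error message.  The run is deterministic for a
#' fixed config seed.
#'
#' @param config a `run_config` (see [validate_config()]), a path to a
#'   YAML config, or `NULL` for defaults.
#' @param out_dir optional output directory (overrides the config's).
#' @return A list of class `trap_report` with per-stage summaries.
#' @export
run_all <- function(config = NULL, out_dir = NULL) {
  cfg <- if (inherits(config, "run_config")) config else
    validate_config(config)
  out_dir <- out_dir %||% cfg$out_dir
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop_fmt("stage '%s' failed: %s", name, conditionMessage(e)))
  }
  hdr <- c(sprintf("trapshift %s",
                   as.character(utils::packageVersion("trapshift"))),
           sprintf("seed %d", cfg$seed))
  emit <- function(tab, file) {
    if (!is.null(out_dir)) write_results(tab, file.path(out_dir, file), hdr)
  }
  if (!is.null(out_dir))
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  dat <- stage("input", {
    if (cfg$mode == "simulate") {
      simulate_trap(cfg$sim)
    } else {
      samples <- read_sample_sheet(cfg$samples)
      list(counts = read_counts(cfg$counts, samples), samples = samples,
           lengths = read_gene_lengths(cfg$lengths),
           clan_map = read_clan_map(cfg$clans),
           gene_sets = lapply(read_gmt(cfg$sets), `[[`, "genes"),
           truth = NULL)
    }
  })
  if (cfg$mode == "simulate" && !is.null(out_dir))
    write_simulation(dat, file.path(out_dir, "sim"))

  tpm_tab <- stage("quantification", tpm(dat$counts, dat$lengths))

  de_ip <- stage("de_ip", run_de(dat$counts, dat$samples, "IP",
                                 design = cfg$de_design, fdr = cfg$fdr,
                                 min_base_mean = cfg$min_base_mean))
  de_input <- stage("de_input", run_de(dat$counts, dat$samples, "Input",
                                       design = cfg$de_design,
                                       fdr = cfg$fdr,
                                       min_base_mean = cfg$min_base_mean))
  emit(de_ip, "de_ip.tsv")
  emit(de_input, "de_input.tsv")

  target <- dat$gene_sets[[cfg$target_set]]
  if (is.null(target))
    stop_fmt("stage 'shift' failed: gene set '%s' not found", cfg$target_set)
  shift <- stage("shift", {
    lapply(list(IP = list(de = de_ip, win = cfg$window_ip),
                Input = list(de = de_input, win = cfg$window_input)),
           function(s) {
             st <- shift_test(s$de, target, s$win,
                              include_targets = cfg$include_targets_in_background)
             rnd <- random_set_null(s$de, s$win, st$n_target,
                                    k = cfg$n_random_sets,
                                    seed = derive_seed(cfg$seed, "random_sets"))
             list(shift = st, random = rnd)
           })
  })
  emit(shift$IP$random, "random_sets_ip.tsv")
  emit(shift$Input$random, "random_sets_input.tsv")

  enrich <- stage("enrichment", {
    ip_samples <- dat$samples$sample_id[dat$samples$fraction == "IP"]
    background <- expressed_background(tpm_tab)
    de_list <- de_ip$gene_id[de_ip$significant]
    de_list <- intersect(de_list, background)
    adj_target <- adjust_target_list(target, tpm_tab, ip_samples)
    adj_target <- intersect(adj_target, background)
    enr_de <- if (length(de_list))
      clan_enrichment(de_list, background, dat$clan_map,
                      alpha = cfg$clan_alpha) else NULL
    enr_tgt <- if (length(adj_target))
      clan_enrichment(adj_target, background, dat$clan_map,
                      alpha = cfg$clan_alpha) else NULL
    overlap <- if (!is.null(enr_de) && !is.null(enr_tgt))
      overlap_report(enr_de, enr_tgt) else NULL
    list(background_size = length(background), de_list = de_list,
         adjusted_target = adj_target, de = enr_de, target = enr_tgt,
         overlap = overlap)
  })
  if (!is.null(enrich$de)) emit(enrich$de, "enrichment_de.tsv")
  if (!is.null(enrich$target)) emit(enrich$target, "enrichment_target.tsv")

  report <- list(
    version = as.character(utils::packageVersion("trapshift")),
    seed = cfg$seed,
    mode = cfg$mode,
    n_genes = nrow(dat$counts),
    n_samples = ncol(dat$counts),
    n_tested = c(IP = sum(de_ip$tested), Input = sum(de_input$tested)),
    n_significant = c(IP = sum(de_ip$significant),
                      Input = sum(de_input$significant)),
    fdr = cfg$fdr,
    shift = lapply(shift, function(s)
      list(n_target = s$shift$n_target,
           n_background = s$shift$n_background,
           D = s$shift$D, p = s$shift$p,
           median_target = s$shift$median_target,
           median_background = s$shift$median_background,
           fisher_p = s$shift$fisher_p,
           random_set_p = s$random$p)),
    enrichment = list(
      background_size = enrich$background_size,
      n_de_list = length(enrich$de_list),
      n_adjusted_target = length(enrich$adjusted_target),
      enriched_de = if (!is.null(enrich$de))
        enrich$de$clan[enrich$de$enriched] else character(),
      enriched_target = if (!is.null(enrich$target))
        enrich$target$clan[enrich$target$enriched] else character(),
      overlap = enrich$overlap$summary %||% NA_character_))
  if (!is.null(out_dir))
    jsonlite::write_json(report, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  report$tables <- list(de_ip = de_ip, de_input = de_input, shift = shift,
                        enrichment = enrich)
  class(report) <- "trap_report"
  report
}

#' @export
print.trap_report <- function(x, ...) {
  cat(sprintf("trapshift run (seed %d, %s mode): %d genes, %d samples\n",
              x$seed, x$mode, x$n_genes, x$n_samples))
  cat(sprintf("  DE at FDR %g: %d significant (IP), %d significant (Input)\n",
              x$fdr, x$n_significant[["IP"]], x$n_significant[["Input"]]))
  for (fr in names(x$shift)) {
    s <- x$shift[[fr]]
    cat(sprintf("  shift [%s]: %d targets vs %d, K-S D = %.3f, p = %.3g\n",
                fr, s$n_target, s$n_background, s$D, s$p))
  }
  e <- x$enrichment
  cat(sprintf("  enrichment: %d-gene background, %d enriched clans (DE list), %d (target list), overlap %s\n",
              e$background_size, length(e$enriched_de),
              length(e$enriched_target), e$overlap))
  invisible(x)
}
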