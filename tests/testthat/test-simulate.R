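# Synthetic-data generator: determinism, design shape, NB moments,
# ground-truth consistency, null configuration.

test_that("generation is deterministic and has the paired design shape", {
  cfg <- sim_config(n_genes = 300, seed = 5, n_up = 10, n_down = 5,
                    n_target = 30)
  s1 <- simulate_trap(cfg)
  s2 <- simulate_trap(cfg)
  expect_identical(s1$counts, s2$counts)
  expect_identical(s1$truth, s2$truth)
  expect_identical(s1$clan_map, s2$clan_map)

  expect_identical(dim(s1$counts), c(300L, 24L))  # 6 pairs x 2 x 2
  expect_identical(nrow(s1$samples), 24L)
  expect_true(all(s1$counts >= 0))
  expect_true(all(s1$counts == floor(s1$counts)))
  expect_silent(validate_counts(s1$counts))
  expect_true(all(s1$lengths > 0))
})

test_that("truth table and gene-set memberships agree exactly", {
  s <- small_sim()
  tr <- s$truth
  expect_identical(sort(tr$gene_id[tr$in_up]), s$gene_sets$up)
  expect_identical(sort(tr$gene_id[tr$in_down]), s$gene_sets$down)
  expect_identical(sort(tr$gene_id[tr$in_target]), s$gene_sets$target)
  # planted sets are disjoint
  expect_identical(sum(tr$in_up & tr$in_down), 0L)
  expect_identical(sum(tr$in_up & tr$in_target), 0L)
  # effects are exactly zero off the planted sets
  expect_true(all(tr$log2fc_ip[!(tr$in_up | tr$in_down | tr$in_target)] == 0))
  expect_true(all(tr$log2fc_input[!tr$in_target] == 0))
  # IP-only effects: up/down genes carry no Input effect
  expect_true(all(tr$log2fc_input[tr$in_up | tr$in_down] == 0))
})

test_that("negative-binomial sampling matches the mean-variance law", {
  # mu = 100, alpha = 0.1 -> variance 100 + 0.1 * 100^2 = 1100
  set.seed(99)
  draws <- rnbinom(10000, mu = 100, size = 1 / 0.1)
  expect_equal(var(draws), 1100, tolerance = 0.15)
  expect_equal(mean(draws), 100, tolerance = 0.05)
})

test_that("null_config empties every planted set and is idempotent", {
  cfg <- sim_config(n_genes = 2000, n_up = 30, n_down = 10, n_target = 100)
  nul <- null_config(cfg)
  expect_identical(nul$n_up, 0L)
  expect_identical(nul$n_down, 0L)
  expect_identical(nul$n_target, 0L)
  expect_identical(null_config(nul), nul)
  s <- simulate_trap(null_config(sim_config(n_genes = 100, n_up = 5,
                                            n_down = 5, n_target = 10)))
  expect_true(all(s$truth$log2fc_ip == 0))
  expect_identical(length(s$gene_sets$up), 0L)
})

test_that("a zero-effect, zero-noise config gives symmetric KO/WT counts", {
  cfg <- sim_config(n_genes = 15000, seed = 17, n_up = 0, n_down = 0,
                    n_target = 0, libsize_sdlog = 0, pair_sdlog = 0)
  s <- simulate_trap(cfg)
  ip <- s$samples$sample_id[s$samples$fraction == "IP"]
  ko <- ip[grepl("KO", ip)]
  wt <- ip[grepl("WT", ip)]
  mko <- rowMeans(s$counts[, ko])
  mwt <- rowMeans(s$counts[, wt])
  keep <- mko > 0 & mwt > 0
  lfc <- log2(mko[keep] / mwt[keep])
  expect_lt(abs(mean(lfc)), 0.02)
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(n_genes = 100, n_up = 80, n_down = 30,
                          n_target = 0), "exceed")
  expect_error(sim_config(baseline_sdlog = -1), ">= 0")
  expect_error(sim_config(n_pairs = 0), "positive")
})

test_that("simulation outputs round-trip through the writers", {
  s <- simulate_trap(sim_config(n_genes = 120, seed = 8, n_up = 5,
                                n_down = 5, n_target = 20))
  dir <- withr::local_tempdir()
  write_simulation(s, dir)
  sheet <- read_sample_sheet(file.path(dir, "samples.tsv"))
  expect_equal(sheet, s$samples, ignore_attr = TRUE)
  cnt <- read_counts(file.path(dir, "counts.tsv"), sheet)
  expect_equal(cnt, s$counts)
  expect_equal(read_gene_lengths(file.path(dir, "lengths.tsv")),
               s$lengths, tolerance = 1e-6)
  expect_identical(read_clan_map(file.path(dir, "clans.tsv")), s$clan_map)
  gs <- read_gmt(file.path(dir, "sets.gmt"))
  expect_identical(gs$target$genes, s$gene_sets$target)
})
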