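test_that("trait-table simulation honors the guild geometry and the seed", {
  cfg <- sim_config(seed = 5, n_guilds = 3, members_per_guild = 3, n_traits = 10,
                    within_guild_noise = 0)
  sim <- simulate_trait_table(cfg)
  expect_equal(dim(sim$table), c(9L, 10L))
  d <- trait_distance(sim$table)
  guild <- sim$truth$guild
  within <- outer(guild, guild, "==") & upper.tri(d)
  expect_true(all(d[within] == 0))          # noiseless: within-guild distance 0
  expect_true(all(d[!outer(guild, guild, "==")] == 1))  # equidistant centroids

  # determinism: same seed identical, different seed differs (with noise on)
  cfg_n <- sim_config(seed = 5, n_guilds = 3, members_per_guild = 3, n_traits = 10,
                      within_guild_noise = 0.5)
  expect_identical(simulate_trait_table(cfg_n)$table, simulate_trait_table(cfg_n)$table)
  cfg_n2 <- sim_config(seed = 6, n_guilds = 3, members_per_guild = 3, n_traits = 10,
                       within_guild_noise = 0.5)
  expect_false(identical(simulate_trait_table(cfg_n)$table,
                         simulate_trait_table(cfg_n2)$table))

  # metadata respects configured ranges
  expect_true(all(sim$metadata$completeness > 70 & sim$metadata$completeness <= 100))
  expect_true(all(sim$metadata$contamination < 5))
})

test_that("single-guild community has FRed = 1", {
  cfg <- sim_config(seed = 2, n_guilds = 1, members_per_guild = 4, n_traits = 4,
                    within_guild_noise = 0, temperature_effect = 0,
                    season_effect = 0, salinity_effect = 0, abundance_noise = 0,
                    n_per_cell = 1)
  sim <- simulate_community(cfg)
  res <- community_fred(sim$table, sim$abundance)
  expect_true(all(res$FRed == 1))
})

test_that("zero effects give exchangeable MAG abundances; strong effects do not", {
  cfg0 <- sim_config(seed = 1, n_guilds = 4, members_per_guild = 2, n_traits = 8,
                     temperature_effect = 0, season_effect = 0, salinity_effect = 0,
                     abundance_noise = 0.3, n_per_cell = 1)
  tt <- simulate_trait_table(cfg0)
  # mean relative abundance per MAG across replicate worlds ~ uniform (1/8)
  reps <- sapply(1:100, function(s) {
    cfg <- cfg0; cfg$seed <- s
    colMeans(simulate_abundances(cfg, tt$truth)$abundance)
  })
  grand <- rowMeans(reps)
  mc_se <- apply(reps, 1, stats::sd) / sqrt(ncol(reps))
  expect_true(all(abs(grand - 1 / 8) <= 3 * mc_se + 1e-3))

  # extreme positive season slope: responder guild summed abundance higher in
  # summer in every replicate
  for (s in 1:10) {
    cfg <- sim_config(seed = s, n_guilds = 4, members_per_guild = 2, n_traits = 8,
                      temperature_effect = 0, season_effect = 5, salinity_effect = 0,
                      n_per_cell = 1)
    ab <- simulate_abundances(cfg, tt$truth)
    resp <- rowSums(ab$abundance[, tt$truth$guild == 1L, drop = FALSE])
    expect_gt(min(resp[ab$samples$season == "summer"]),
              max(resp[ab$samples$season == "spring"]))
  }
})

test_that("transcript simulation conserves depth and respects pi", {
  cfg <- sim_config(seed = 9, n_guilds = 2, members_per_guild = 2, n_traits = 6,
                    n_per_cell = 1, depth = 5000)
  sim <- simulate_community(cfg)
  totals <- tapply(sim$transcripts$read_count, sim$transcripts$sample_id, sum)
  expect_true(all(totals == 5000))  # read conservation

  # pi = 0: nothing expressed, every sample flagged undefined
  cfg0 <- cfg; cfg0$expression_prob <- 0
  tx0 <- simulate_transcripts(cfg0, sim$table, sim$abundance)
  expect_true(all(tx0$read_count == 0))
  et0 <- expressed_trait_tables(tx0, rownames(sim$table), colnames(sim$table))
  ef0 <- expressed_fred(et0, sim$abundance)
  expect_true(all(is.na(ef0$FRed)))
})

test_that("pi = 1, sigma = 0, equal lengths, even abundances: expressed ~ potential", {
  cfg <- sim_config(seed = 12, n_guilds = 3, members_per_guild = 2, n_traits = 9,
                    within_guild_noise = 0.4, temperature_effect = 0,
                    season_effect = 0, salinity_effect = 0, abundance_noise = 0,
                    n_per_cell = 1, expression_prob = 1, activity_sdlog = 0,
                    depth = 2e6, gene_length_range = c(1000L, 1000L))
  sim <- simulate_community(cfg)
  pot <- community_fred(sim$table, sim$abundance, scale_per_sample = TRUE)
  et <- expressed_trait_tables(sim$transcripts, rownames(sim$table), colnames(sim$table))
  ef <- expressed_fred(et, sim$abundance)
  expect_equal(ef$FRed, pot$FRed, tolerance = 0.02)  # multinomial MC error only
})

test_that("lower expression probability lowers median expressed FRed", {
  meds <- sapply(c(lo = 0.25, hi = 1), function(pi_val) {
    vals <- sapply(1:8, function(s) {
      cfg <- sim_config(seed = s, n_guilds = 3, members_per_guild = 4, n_traits = 12,
                        within_guild_noise = 0, n_per_cell = 1,
                        expression_prob = pi_val, activity_sdlog = 0, depth = 5e4)
      sim <- simulate_community(cfg)
      et <- expressed_trait_tables(sim$transcripts, rownames(sim$table),
                                   colnames(sim$table))
      stats::median(expressed_fred(et, sim$abundance)$FRed, na.rm = TRUE)
    })
    stats::median(vals)
  })
  expect_lte(meds[["lo"]], meds[["hi"]] + 1e-9)
})

test_that("simulation writes and reloads through the IO layer", {
  cfg <- sim_config(seed = 3, n_guilds = 2, members_per_guild = 2, n_traits = 6,
                    n_per_cell = 1, depth = 2000)
  sim <- simulate_community(cfg)
  f <- tempfile(fileext = ".tsv")
  utils::write.table(
    data.frame(sample_id = rownames(sim$abundance), sim$abundance,
               check.names = FALSE),
    f, sep = "\t", quote = FALSE, row.names = FALSE)
  back <- read_abundance_matrix(f)
  expect_equal(back, sim$abundance, tolerance = 1e-12)
})
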