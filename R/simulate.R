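# Seeded synthetic communities with controlled guild-redundancy structure.
# The generator states a world: guilds of functionally identical MAGs whose
# centroids are mutually equidistant (one-hot trait blocks, a simplex), so
# the noiseless guild model has the closed-form FRed = (m-1)/(g*m-1) under
# even abundances. Environmental structure enters through a responder guild
# whose log-abundance tracks temperature, season and salinity.

#' Simulation configuration
#'
#' Defaults state the conditions the analysis assumes at desk scale:
#' 8 guilds x 5 members = 40 MAGs, 60 traits, 24 samples (2 per
#' bay x season x salinity cell), matching the magnitude of an estuarine
#' MAG study while staying sub-second. See the methods vignette for the
#' rationale behind each default.
#'
#' @param seed Integer root seed; per-stage child seeds are derived by fixed
#'   offsets (+1 traits, +2 abundances, +3 transcripts).
#' @param n_guilds,members_per_guild Guild structure (`g * m >= 2`).
#' @param n_traits Number of traits (>= `n_guilds`).
#' @param within_guild_noise Std-dev of trait noise around guild centroids.
#' @param centroid_hits Hit count carried by a guild's block traits.
#' @param completeness_range,contamination_range Uniform ranges for MAG
#'   quality metrics (percent).
#' @param n_per_cell Samples per (bay x season x salinity_class) cell.
#' @param temperature_effect Responder-guild log-abundance slope per degC.
#' @param season_effect Responder-guild summer log-abundance shift.
#' @param salinity_effect Responder-guild log-abundance slope per PSU.
#' @param abundance_noise Lognormal (log-scale sd) MAG x sample noise.
#' @param expression_prob Probability an encoded trait is expressed in a
#'   sample (pi).
#' @param activity_meanlog,activity_sdlog Lognormal expression activity.
#' @param depth Sequencing depth: reads per sample.
#' @param gene_length_range Uniform integer range of gene lengths (bp).
#' @return List of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_guilds = 8L, members_per_guild = 5L, n_traits = 60L,
                       within_guild_noise = 0.3, centroid_hits = 5,
                       completeness_range = c(80, 100),
                       contamination_range = c(0, 5),
                       n_per_cell = 2L,
                       temperature_effect = 0.15,
                       season_effect = 2,
                       salinity_effect = 0.04,
                       abundance_noise = 0.3,
                       expression_prob = 0.7,
                       activity_meanlog = 0, activity_sdlog = 1,
                       depth = 1e5,
                       gene_length_range = c(300L, 3000L)) {
  cfg <- list(seed = as.integer(seed), n_guilds = as.integer(n_guilds),
              members_per_guild = as.integer(members_per_guild),
              n_traits = as.integer(n_traits),
              within_guild_noise = within_guild_noise,
              centroid_hits = centroid_hits,
              completeness_range = completeness_range,
              contamination_range = contamination_range,
              n_per_cell = as.integer(n_per_cell),
              temperature_effect = temperature_effect,
              season_effect = season_effect,
              salinity_effect = salinity_effect,
              abundance_noise = abundance_noise,
              expression_prob = expression_prob,
              activity_meanlog = activity_meanlog,
              activity_sdlog = activity_sdlog,
              depth = depth,
              gene_length_range = gene_length_range)
  stopifnot(cfg$n_guilds >= 1L, cfg$members_per_guild >= 1L,
            cfg$n_guilds * cfg$members_per_guild >= 2L,
            cfg$n_traits >= cfg$n_guilds,
            cfg$within_guild_noise >= 0,
            cfg$completeness_range[1L] > 70, cfg$completeness_range[2L] <= 100,
            cfg$contamination_range[1L] >= 0, cfg$contamination_range[2L] < 100,
            cfg$n_per_cell >= 1L,
            cfg$expression_prob >= 0, cfg$expression_prob <= 1,
            cfg$depth >= 1)
  class(cfg) <- "sim_config"
  cfg
}

#' Simulate a guild-structured MAG trait table
#'
#' Guild centroids occupy disjoint one-hot trait blocks (so all centroid
#' pairs are mutually equidistant; after max-scaling every between-guild
#' distance is exactly 1 and within-guild distances are 0 when
#' `within_guild_noise = 0`). Leftover traits beyond `g * floor(n/g)` are a
#' shared constant "core" across all guilds and do not affect distances.
#' Members are centroid plus truncated Gaussian noise. Completeness and
#' contamination are drawn uniformly; each guild maps to one taxonomic
#' order.
#'
#' @param config A [sim_config()].
#' @return List: `table` (MAG x trait matrix of hit counts), `metadata`
#'   (MAG metadata data frame), `truth` (guild assignment, closed-form
#'   even-abundance FRed, the generating config).
#' @export
simulate_trait_table <- function(config) {
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(config$seed + 1L)
  g <- config$n_guilds; m <- config$members_per_guild
  n_mags <- g * m; nt <- config$n_traits
  block <- nt %/% g
  mag_ids <- sprintf("mag_%03d", seq_len(n_mags))
  trait_ids <- sprintf("trait_%03d", seq_len(nt))
  guild <- rep(seq_len(g), each = m)
  names(guild) <- mag_ids

  centroids <- matrix(0, g, nt)
  for (k in seq_len(g)) centroids[k, ((k - 1L) * block + 1L):(k * block)] <- config$centroid_hits
  if (g * block < nt) centroids[, (g * block + 1L):nt] <- config$centroid_hits / 2

  tab <- centroids[guild, , drop = FALSE]
  if (config$within_guild_noise > 0) {
    tab <- pmax(tab + matrix(stats::rnorm(length(tab), 0, config$within_guild_noise),
                             nrow(tab)), 0)
  }
  dimnames(tab) <- list(mag_ids, trait_ids)

  meta <- data.frame(
    mag_id = mag_ids,
    total_genes = sample(1500:4500, n_mags, replace = TRUE),
    completeness = stats::runif(n_mags, config$completeness_range[1L],
                                config$completeness_range[2L]),
    contamination = stats::runif(n_mags, config$contamination_range[1L],
                                 config$contamination_range[2L]),
    order = sprintf("o__Guild%02d", guild),
    fraction = sample(c("PA", "FL"), n_mags, replace = TRUE),
    stringsAsFactors = FALSE
  )
  truth <- list(guild = guild,
                expected_even_fred = (m - 1) / (g * m - 1),
                config = config)
  list(table = tab, metadata = meta, truth = truth)
}

# Closed-form FRed of the ideal guild model (within-guild d = 0,
# between-guild d = 1, each guild's share split evenly over its m members).
#' Closed-form FRed of a guild-block community
#'
#' @param guild_shares Relative abundance per guild (sums to 1).
#' @param members_per_guild Number of identical members per guild.
#' @return Expected FRed under the noiseless guild model.
#' @export
guild_model_fred <- function(guild_shares, members_per_guild) {
  P2 <- sum(guild_shares^2)
  Q <- 1 - P2
  D <- 1 - P2 / members_per_guild
  1 - Q / D
}

#' Simulate abundance gradients driven by environmental covariates
#'
#' Samples fill a bay x season x salinity-class design with `n_per_cell`
#' replicates. Covariates are drawn per sample (temperature about 14 degC in
#' spring, 26 degC in summer, sd 4; salinity uniform within class bands).
#' The responder guild (guild 1, a "warm-adapted halotolerant" guild) gets a
#' log-abundance shift `temperature_effect * (T - 20) + season_effect *
#' is_summer + salinity_effect * (S - 15)`; all MAGs receive lognormal noise
#' and a per-sample softmax yields relative abundances. Increasing responder
#' dominance raises FRed in the guild model, so the injected effects have a
#' known positive sign on FRed.
#'
#' @param config A [sim_config()].
#' @param truth Truth list from [simulate_trait_table()].
#' @return List: `abundance` (sample x MAG relative abundance matrix),
#'   `samples` (sample metadata), `expected_fred` (noiseless analytic FRed
#'   per sample from the guild shares).
#' @export
simulate_abundances <- function(config, truth) {
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(config$seed + 2L)
  design <- expand.grid(bay = c("Chesapeake", "Delaware"),
                        season = c("spring", "summer"),
                        salinity_class = c("low", "medium", "high"),
                        rep = seq_len(config$n_per_cell),
                        stringsAsFactors = FALSE)
  n_s <- nrow(design)
  sal_band <- list(low = c(2, 8), medium = c(10, 20), high = c(25, 32))
  samples <- data.frame(
    sample_id = sprintf("s_%03d", seq_len(n_s)),
    bay = design$bay, season = design$season,
    salinity_class = design$salinity_class,
    fraction = rep_len(c("PA", "FL"), n_s),
    temperature = stats::rnorm(n_s, ifelse(design$season == "summer", 26, 14), 4),
    salinity = mapply(function(cl) stats::runif(1, sal_band[[cl]][1L], sal_band[[cl]][2L]),
                      design$salinity_class),
    nitrate = stats::rlnorm(n_s, 2, 0.5),
    phosphate = stats::rlnorm(n_s, 0, 0.5),
    silicate = stats::rlnorm(n_s, 1.5, 0.5),
    ammonium = stats::rlnorm(n_s, 0.5, 0.5),
    chlorophyll_a = stats::rlnorm(n_s, 1, 0.6),
    cell_count = stats::rlnorm(n_s, 13, 0.5),
    stringsAsFactors = FALSE
  )
  guild <- truth$guild
  n_mags <- length(guild)
  g <- truth$config$n_guilds
  eta_responder <- config$temperature_effect * (samples$temperature - 20) +
    config$season_effect * (samples$season == "summer") +
    config$salinity_effect * (samples$salinity - 15)
  # log-abundance: responder shift for guild 1, lognormal noise for all
  eta <- outer(eta_responder, as.numeric(guild == 1L)) +
    matrix(stats::rnorm(n_s * n_mags, 0, config$abundance_noise), n_s, n_mags)
  ab <- exp(eta)
  ab <- ab / rowSums(ab)
  dimnames(ab) <- list(samples$sample_id, names(guild))

  expected <- vapply(seq_len(n_s), function(s) {
    shares_mag <- exp(eta_responder[s] * (guild == 1L))
    shares <- vapply(seq_len(g), function(k) sum(shares_mag[guild == k]), numeric(1L))
    guild_model_fred(shares / sum(shares), truth$config$members_per_guild)
  }, numeric(1L))
  list(abundance = ab, samples = samples,
       expected_fred = stats::setNames(expected, samples$sample_id))
}

#' Simulate transcript counts as partially silenced expression
#'
#' Each encoded trait of each MAG is one gene variant with a fixed length
#' drawn uniformly from `gene_length_range`. Per sample, a gene is expressed
#' with probability `expression_prob`; its expected read weight is
#' proportional to `MAG abundance x encoded hit value x lognormal activity x
#' gene length`, and reads are drawn by multinomial sampling at the
#' configured depth (total reads per sample equals `depth` exactly whenever
#' any gene is on).
#'
#' @param config A [sim_config()].
#' @param table MAG x trait matrix from [simulate_trait_table()].
#' @param abundance Sample x MAG matrix from [simulate_abundances()].
#' @return Long transcript count data frame (`sample_id`, `gene_id`,
#'   `mag_id`, `trait_id`, `gene_length`, `read_count`).
#' @export
simulate_transcripts <- function(config, table, abundance) {
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(config$seed + 3L)
  enc <- which(table > 0, arr.ind = TRUE)
  genes <- data.frame(
    mag_id = rownames(table)[enc[, 1L]],
    trait_id = colnames(table)[enc[, 2L]],
    value = table[enc],
    gene_length = sample(config$gene_length_range[1L]:config$gene_length_range[2L],
                         nrow(enc), replace = TRUE),
    stringsAsFactors = FALSE
  )
  genes$gene_id <- paste(genes$mag_id, genes$trait_id, sep = "|")
  n_g <- nrow(genes)
  out <- lapply(rownames(abundance), function(sid) {
    on <- stats::rbinom(n_g, 1L, config$expression_prob)
    act <- stats::rlnorm(n_g, config$activity_meanlog, config$activity_sdlog)
    w <- abundance[sid, genes$mag_id] * genes$value * on * act * genes$gene_length
    counts <- if (sum(w) > 0) {
      as.integer(stats::rmultinom(1L, size = config$depth, prob = w))
    } else {
      integer(n_g)
    }
    data.frame(sample_id = sid, gene_id = genes$gene_id, mag_id = genes$mag_id,
               trait_id = genes$trait_id, gene_length = genes$gene_length,
               read_count = counts, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Simulate a complete synthetic study
#'
#' Convenience wrapper chaining [simulate_trait_table()],
#' [simulate_abundances()] and [simulate_transcripts()].
#'
#' @param config A [sim_config()].
#' @return List with `table`, `metadata`, `truth`, `abundance`, `samples`,
#'   `expected_fred`, `transcripts`.
#' @export
simulate_community <- function(config = sim_config()) {
  tt <- simulate_trait_table(config)
  ab <- simulate_abundances(config, tt$truth)
  tx <- simulate_transcripts(config, tt$table, ab$abundance)
  c(tt, ab, list(transcripts = tx))
}
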