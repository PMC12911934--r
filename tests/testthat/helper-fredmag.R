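# Shared fixtures and independent oracles. Oracles are deliberately naive
# (nested loops, exhaustive pair counts) and never call the code paths they
# check.

# brute-force Rao's quadratic entropy: explicit double loop
oracle_rao_q <- function(p, d) {
  ids <- names(p)
  s <- 0
  for (i in ids) for (j in ids) s <- s + p[[i]] * p[[j]] * d[i, j]
  s
}

# exhaustive all-pairs Cliff's delta
oracle_cliffs_delta <- function(x, y) {
  wins <- 0L; losses <- 0L
  for (xi in x) for (yj in y) {
    if (xi > yj) wins <- wins + 1L
    if (xi < yj) losses <- losses + 1L
  }
  (wins - losses) / (length(x) * length(y))
}

# random valid dissimilarity matrix in [0,1], zero diagonal, symmetric
random_distance <- function(n, ids = sprintf("m%02d", seq_len(n))) {
  d <- matrix(stats::runif(n * n), n, n, dimnames = list(ids, ids))
  d <- (d + t(d)) / 2
  diag(d) <- 0
  d
}

# random positive relative-abundance profile
random_profile <- function(n, ids = sprintf("m%02d", seq_len(n))) {
  p <- stats::rgamma(n, shape = 1) + 1e-6
  stats::setNames(p / sum(p), ids)
}

# ideal guild-block distance matrix: within-guild 0, between-guild 1
guild_distance <- function(g, m) {
  n <- g * m
  ids <- sprintf("m%02d", seq_len(n))
  guild <- rep(seq_len(g), each = m)
  d <- 1 - outer(guild, guild, "==")
  storage.mode(d) <- "double"
  dimnames(d) <- list(ids, ids)
  d
}

# write a data frame / matrix to a temp TSV, returning the path
tmp_tsv <- function(df) {
  path <- tempfile(fileext = ".tsv")
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

# minimal MAG metadata builder
make_meta <- function(mag_id, total_genes = 2000, completeness = 90,
                      contamination = 1, order = "o__A", fraction = "PA") {
  data.frame(mag_id = mag_id, total_genes = total_genes,
             completeness = completeness, contamination = contamination,
             order = order, fraction = fraction, stringsAsFactors = FALSE)
}
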