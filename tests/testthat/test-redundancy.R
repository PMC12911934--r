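test_that("trait distances are max-scaled Euclidean", {
  tab <- matrix(c(0, 0, 3, 0,   # t1
                  0, 0, 0, 4),  # t2
                4, 2, dimnames = list(c("a", "b", "c", "d"), c("t1", "t2")))
  # identical rows a, b -> distance 0
  d <- trait_distance(tab)
  expect_equal(d["a", "b"], 0)
  expect_true(all(abs(d - t(d)) == 0) && all(diag(d) == 0))
  expect_true(all(d >= 0 & d <= 1))
  # rows (0,0), (3,0), (0,4): raw distances 3, 4, 5 scale to 0.6, 0.8, 1
  expect_equal(d["a", "c"], 0.6)
  expect_equal(d["a", "d"], 0.8)
  expect_equal(d["c", "d"], 1.0)

  # permuting MAG order permutes the matrix consistently
  perm <- c("d", "b", "a", "c")
  expect_equal(trait_distance(tab[perm, ]), d[perm, perm])

  expect_equal(max(trait_distance(tab[c("a", "b"), ])), 0)  # all-identical: all-zero
  expect_error(trait_distance(tab[1, , drop = FALSE]), class = "fredmag_validation_error")
})

test_that("relative abundance drops sub-threshold MAGs and renormalizes", {
  p <- relative_abundance(c(m1 = 2, m2 = 2, m3 = 0))
  expect_equal(p, c(m1 = 0.5, m2 = 0.5))
  expect_error(relative_abundance(c(m1 = 1, m2 = 0, m3 = 0)),
               class = "fredmag_undefined_community")
  q <- c(a = 0.25, b = 0.75)
  expect_equal(relative_abundance(q), q)  # idempotent on normalized input
  expect_equal(relative_abundance(c(a = 1, b = 2, c = 0.5), min_abundance = 0.5),
               c(a = 1 / 3, b = 2 / 3))
})

test_that("Gini-Simpson matches its closed forms", {
  expect_equal(gini_simpson(c(a = 0.5, b = 0.5)), 0.5)
  for (n in c(2, 5, 40)) {
    p <- stats::setNames(rep(1 / n, n), sprintf("m%d", 1:n))
    expect_equal(gini_simpson(p), 1 - 1 / n)
  }
  p_dom <- c(a = 1 - 1e-9, b = 1e-9)
  expect_lt(gini_simpson(p_dom), 1e-8)  # dominance limit -> 0
  expect_error(gini_simpson(c(a = 0.4, b = 0.4)), class = "fredmag_validation_error")
})

test_that("Rao's Q matches closed forms and the brute-force oracle", {
  d0 <- guild_distance(1, 3) # all zero
  expect_equal(rao_q(random_profile(3, rownames(d0)), d0), 0)
  d1 <- guild_distance(2, 1) # d12 = 1
  expect_equal(rao_q(c(m01 = 0.5, m02 = 0.5), d1), 0.5)

  set.seed(42)
  for (i in 1:50) {
    n <- sample(2:6, 1)
    d <- random_distance(n)
    p <- random_profile(n)
    expect_equal(rao_q(p, d), oracle_rao_q(p, d), tolerance = 1e-12)
  }
  expect_error(rao_q(c(zz = 0.5, m01 = 0.5), d1), class = "fredmag_validation_error")
})

test_that("fred reproduces the limiting cases and the guild closed form", {
  # all members functionally identical -> FRed = 1
  ident <- fred(c(a = 0.4, b = 0.3, c = 0.3),
                matrix(0, 3, 3, dimnames = list(letters[1:3], letters[1:3])))
  expect_equal(ident$FRed, 1)
  expect_equal(ident$Q, 0)

  # all members maximally distinct (d = 1 everywhere off-diagonal) -> FRed = 0
  dmax <- guild_distance(3, 1)
  distinct <- fred(stats::setNames(rep(1 / 3, 3), rownames(dmax)), dmax)
  expect_equal(distinct$FRed, 0)
  expect_equal(distinct$Q, distinct$D)

  # guild community: g guilds x m members, even abundance -> (m-1)/(gm-1)
  for (g in 2:4) for (m in 2:4) {
    d <- guild_distance(g, m)
    p <- stats::setNames(rep(1 / (g * m), g * m), rownames(d))
    expect_equal(fred(p, d)$FRed, (m - 1) / (g * m - 1), tolerance = 1e-12)
  }
  # g = 2, m = 2 is 1/3 exactly
  d <- guild_distance(2, 2)
  expect_equal(fred(stats::setNames(rep(0.25, 4), rownames(d)), d)$FRed, 1 / 3)
})

test_that("fred is invariant to MAG relabeling", {
  set.seed(7)
  for (i in 1:20) {
    n <- sample(3:8, 1)
    d <- random_distance(n)
    p <- random_profile(n)
    perm <- sample(names(p))
    a <- fred(p, d)
    b <- fred(p[perm], d[perm, perm])
    expect_equal(a$FRed, b$FRed, tolerance = 1e-12)
    expect_equal(a$Q, b$Q, tolerance = 1e-12)
  }
})

test_that("community_fred iterates samples x subsets with flagged undefined rows", {
  tab <- matrix(c(1, 1, 5, 1, 1, 0), 3, 2,
                dimnames = list(c("m1", "m2", "m3"), c("g1", "g2")))
  ab <- matrix(c(0.5, 0.5, 0.3, 0.3, 0.2, 0.2, 0, 1),
               nrow = 4, byrow = TRUE,
               dimnames = list(sprintf("s%d", 1:4), NULL))
  ab <- ab[, 1:2]; colnames(ab) <- c("m1", "m2")
  ab <- cbind(ab, m3 = c(0, 0, 0.6, 0))

  res <- community_fred(tab, ab)
  expect_s3_class(res, "fred_result")
  # s1, s2 communities are {m1, m2} which are identical -> FRed = 1
  expect_equal(res$FRed[res$sample_id == "s1"], 1)
  expect_equal(res$FRed[res$sample_id == "s2"], 1)
  # s4 has a single positive MAG -> flagged NA row, not an abort
  expect_true(is.na(res$FRed[res$sample_id == "s4"]))
  expect_equal(nrow(res), 4L)

  # duplicating a sample row duplicates its result exactly
  ab2 <- rbind(ab, s1b = ab["s1", ])
  res2 <- community_fred(tab, ab2)
  expect_equal(res2[res2$sample_id == "s1b", -1], res2[res2$sample_id == "s1", -1],
               ignore_attr = TRUE)

  # subsetting to a trait on which all MAGs agree -> FRed = 1 everywhere defined
  res_g1 <- community_fred(tab[, "g1", drop = FALSE] * 0 + 1, ab)
  expect_true(all(res_g1$FRed[!is.na(res_g1$FRed)] == 1))
})

test_that("adding a functional duplicate never decreases FRed (spot check)", {
  set.seed(21)
  for (i in 1:25) {
    n <- sample(2:6, 1)
    d <- random_distance(n)
    p <- random_profile(n)
    base <- fred(p, d)$FRed
    # split MAG 1's abundance with an identical twin
    ids2 <- c(names(p), "twin")
    d2 <- rbind(cbind(d, twin = d[, 1]), twin = c(d[1, ], 0))
    dimnames(d2) <- list(ids2, ids2)
    frac <- runif(1, 0.1, 0.9)
    p2 <- c(p, twin = unname(p[1]) * (1 - frac)); p2[1] <- p[1] * frac
    expect_gte(fred(p2, d2)$FRed, base - 1e-12)
  }
})
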