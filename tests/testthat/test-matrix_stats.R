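mat3 <- function(vals, kind = "distance_percent", labels = c("a", "b", "c")) {
  v <- matrix(0, 3, 3, dimnames = list(labels, labels))
  v[upper.tri(v)] <- vals
  v[lower.tri(v)] <- t(v)[lower.tri(v)]
  labeled_matrix(v, kind = kind)
}

test_that("upper-triangle standardization gives unit-variance z-scores", {
  m <- mat3(c(1, 2, 3))
  expect_equal(standardize_upper_triangle(m), c(-1, 0, 1))
  expect_error(standardize_upper_triangle(mat3(c(5, 5, 5))), "degenerate")

  fx <- packaged_fixtures()
  z <- standardize_upper_triangle(similarity_to_distance(fx$ddh_matrix))
  expect_equal(mean(z), 0, tolerance = 1e-12)
  expect_equal(sd(z), 1, tolerance = 1e-12)
})

test_that("Mantel r_M is a Pearson correlation of upper triangles", {
  set.seed(101)
  for (n in 4:6) {
    for (k in 1:10) {
      x <- rand_dist_matrix(n)
      y <- rand_dist_matrix(n)
      r <- mantel(x, y, n_perm = 0)$r_m
      expect_equal(r, oracle_mantel_r(x, y), tolerance = 1e-12)
      # statistic is symmetric in its arguments
      expect_equal(mantel(y, x, n_perm = 0)$r_m, r, tolerance = 1e-15)
    }
  }
})

test_that("r_M is invariant under positive affine transforms, -1 on reversal", {
  set.seed(102)
  x <- rand_dist_matrix(6)
  expect_equal(mantel(x, x, n_perm = 0)$r_m, 1)
  y <- labeled_matrix(3 * x$values + 7 * (1 - diag(6)),
                      kind = "distance_percent", labels = x$labels)
  expect_equal(mantel(x, y, n_perm = 0)$r_m, 1)
  # decreasing affine transform (still a valid non-negative distance)
  yr <- labeled_matrix((200 - x$values) * (1 - diag(6)),
                       kind = "distance_percent", labels = x$labels)
  expect_equal(mantel(x, yr, n_perm = 0)$r_m, -1)
})

test_that("exhaustive permutation p matches direct enumeration and MC", {
  set.seed(103)
  for (n in c(4, 5)) {
    for (k in 1:4) {
      x <- rand_dist_matrix(n)
      y <- rand_dist_matrix(n)
      res <- mantel(x, y, n_perm = factorial(n), seed = 1)
      expect_true(res$exhaustive)
      expect_equal(res$n_perm, factorial(n))
      expect_equal(res$p_value, oracle_exhaustive_p(x, y), tolerance = 1e-12)
    }
  }
  # exhaustive p agrees with a Monte-Carlo estimate within binomial error
  set.seed(104)
  x <- rand_dist_matrix(5)
  y <- rand_dist_matrix(5)
  p_ex <- mantel(x, y, n_perm = 120)$p_value
  ux <- upper_triangle(x)
  mc <- replicate(10000, {
    p <- sample.int(5)
    pv <- y$values[p, p]
    cor(ux, pv[upper.tri(pv)]) >= mantel(x, y, n_perm = 0)$r_m - 1e-12
  })
  expect_lt(abs(mean(mc) - p_ex), 3 * sqrt(p_ex * (1 - p_ex) / 10000) + 1e-6)
})

test_that("label handling is strict and degenerate matrices error", {
  x <- rand_dist_matrix(4, labels = c("a", "b", "c", "d"))
  y <- rand_dist_matrix(4, labels = c("a", "b", "c", "e"))
  expect_error(mantel(x, y, seed = 1), "only in first: d.*only in second: e")
  # reordered labels are reconciled by name, not position
  y2 <- labeled_matrix(x$values[c(2, 1, 4, 3), c(2, 1, 4, 3)],
                       kind = "distance_percent")
  expect_equal(mantel(x, y2, n_perm = 0)$r_m, 1)
  # n = 3: statistic only, no p-value
  res3 <- mantel(mat3(c(1, 2, 3)), mat3(c(2, 4, 6)), n_perm = 999, seed = 1)
  expect_equal(res3$r_m, 1)
  expect_true(is.na(res3$p_value))
  # similarity matrices are refused
  fx <- packaged_fixtures()
  expect_error(mantel(fx$ddh_matrix, fx$ddh_matrix, seed = 1),
               "similarity_to_distance")
})

test_that("sympatry matrices are binary blocks over plate labels", {
  fx <- packaged_fixtures()
  sym <- sympatry_matrix(fx$plates)
  eu <- c("SolV", "Fur", "Rib", "Fdl", "Ice")
  expect_equal(unname(sym$values[eu, eu]), matrix(1, 5, 5))
  non_eu <- setdiff(sym$labels, eu)
  expect_equal(sum(sym$values[non_eu, non_eu]) , length(non_eu))  # diag only
  expect_equal(sum(sym$values[eu, non_eu]), 0)

  # pairwise-distinct plates give an identity-pattern matrix
  solo <- sympatry_matrix(c(a = "p1", b = "p2", c = "p3", d = "p4"))
  expect_equal(unname(solo$values), diag(4))

  expect_error(sympatry_matrix(c(a = "p1", b = NA)), "lack a plate.*b")
})

test_that("Spearman sympatry handles ties and degenerate inputs", {
  labels <- c("a", "b", "c", "d")
  g <- matrix(100, 4, 4, dimnames = list(labels, labels))
  # upper triangle (column-major): ab, ac, bc, ad, bd, cd
  g[upper.tri(g)] <- c(95, 80, 80, 70, 60, 50)
  g[lower.tri(g)] <- t(g)[lower.tri(g)]
  gm <- labeled_matrix(g, kind = "similarity_percent")
  sym <- sympatry_matrix(c(a = "p1", b = "p1", c = "p2", d = "p3"))
  res <- spearman_sympatry(gm, sym, n_perm = 0)
  # frozen tied-rank value: ranks (6, 4.5, 4.5, 3, 2, 1) vs (6, 3, 3, 3, 3, 3)
  expect_equal(res$r_s, 0.6642111641550715, tolerance = 1e-12)
  expect_equal(res$n_pairs, 6)

  # within-plate similarity uniformly higher => positive correlation
  res2 <- spearman_sympatry(gm, sym, n_perm = 1000, seed = 9)
  expect_gt(res2$r_s, 0)
  expect_true(res2$exhaustive)   # n = 4, 24 relabelings

  all_one <- sympatry_matrix(c(a = "p", b = "p", c = "p", d = "p"))
  expect_error(spearman_sympatry(gm, all_one, seed = 1),
               "all pairs sympatric")
})

test_that("r_M agrees with vegan's Mantel statistic", {
  set.seed(110)
  for (k in 1:5) {
    x <- rand_dist_matrix(7)
    y <- rand_dist_matrix(7)
    v <- vegan::mantel(stats::as.dist(x$values), stats::as.dist(y$values),
                       permutations = 0)
    expect_equal(mantel(x, y, n_perm = 0)$r_m, unname(v$statistic),
                 tolerance = 1e-12)
  }
})

test_that("Monte-Carlo null p-values are not anti-conservative (small run)", {
  set.seed(105)
  pvals <- replicate(120, {
    x <- rand_dist_matrix(6)
    y <- rand_dist_matrix(6)
    mantel(x, y, n_perm = 99, seed = sample.int(1e6, 1))$p_value
  })
  expect_true(all(pvals > 0 & pvals <= 1))
  for (t in c(0.05, 0.25, 0.5))
    expect_lte(mean(pvals <= t), t + 3 * sqrt(t * (1 - t) / 120))
})
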