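test_that("70% DDH threshold reproduces the published species groups", {
  fx <- packaged_fixtures()
  six <- c("Fur", "Rib", "Fdl", "Ice", "Yel", "Phi")
  cs6 <- cluster_at_threshold(subset_matrix(fx$ddh_matrix, six), 70)
  expect_length(cs6$partition, 3)
  expect_equal(cs6$partition,
               list(c("Fdl", "Fur", "Ice", "Rib"), "Phi", "Yel"))

  cs9 <- cluster_at_threshold(fx$ddh_matrix, 70)
  expect_length(cs9$partition, 5)
  expect_equal(cs9$partition,
               list(c("Fdl", "Fur", "Ice", "Rib", "SolV"),
                    "Kam1", "Phi", "V4", "Yel"))
  # single and complete linkage agree on this matrix at 70%
  cs9c <- cluster_at_threshold(fx$ddh_matrix, 70, linkage = "complete")
  expect_equal(cs9c$partition, cs9$partition)
})

test_that("threshold extremes give one group or all singletons", {
  fx <- packaged_fixtures()
  expect_length(cluster_at_threshold(fx$ddh_matrix, 0)$partition, 1)
  top <- max(upper_triangle(fx$ddh_matrix))
  set.seed(61)
  m <- rand_sim_matrix(6)
  expect_length(cluster_at_threshold(m, 100)$partition, 6)
  # at 100% only the printed-100 pairs (within the Azores/Ice block) merge
  expect_length(cluster_at_threshold(fx$ddh_matrix, 100)$partition, 6)
  expect_true(top == 100)
})

test_that("raising the threshold only refines the partition", {
  set.seed(62)
  for (k in 1:10) {
    m <- rand_sim_matrix(7)
    prev <- cluster_at_threshold(m, 0)$partition
    for (th in c(20, 40, 60, 80, 99)) {
      cur <- cluster_at_threshold(m, th)$partition
      # every new group must sit inside one old group
      for (g in cur) {
        holders <- Filter(function(old) all(g %in% old), prev)
        expect_length(holders, 1)
      }
      prev <- cur
    }
  }
})

test_that("single linkage equals the transitive-closure oracle", {
  set.seed(63)
  for (k in 1:15) {
    n <- sample(3:8, 1)
    m <- rand_sim_matrix(n)
    th <- runif(1, 0, 100)
    got <- cluster_at_threshold(m, th)$partition
    expect_equal(got, oracle_components(m$values, th))
  }
})

test_that("partition does not depend on input label order", {
  fx <- packaged_fixtures()
  perm <- c("Yel", "Fdl", "Kam1", "SolV", "Phi", "Fur", "V4", "Ice", "Rib")
  shuffled <- subset_matrix(fx$ddh_matrix, perm)
  expect_equal(cluster_at_threshold(shuffled, 70)$partition,
               cluster_at_threshold(fx$ddh_matrix, 70)$partition)
})

test_that("complete linkage refuses chained merges that single accepts", {
  labs <- c("a", "b", "c")
  v <- matrix(c(100, 90, 10, 90, 100, 90, 10, 90, 100), 3, 3,
              dimnames = list(labs, labs))
  m <- labeled_matrix(v, kind = "similarity_percent")
  expect_length(cluster_at_threshold(m, 70, "single")$partition, 1)
  expect_equal(cluster_at_threshold(m, 70, "complete")$partition,
               list(c("a", "b"), "c"))
})

test_that("group extremes report the published clade boundaries", {
  fx <- packaged_fixtures()
  eu <- c("SolV", "Fur", "Rib", "Fdl", "Ice")
  lo <- group_extreme(fx$ddh_matrix, eu)
  expect_equal(lo$value, 88.4)
  expect_setequal(lo$pair, c("Ice", "SolV"))

  hi <- group_extreme(fx$ddh_matrix, c("Phi", "V4"),
                      others = setdiff(fx$ddh_matrix$labels, c("Phi", "V4")),
                      mode = "max")
  expect_equal(hi$value, 21.6)

  yel <- group_extreme(fx$ddh_matrix, "Yel", others = eu, mode = "max")
  expect_equal(yel$value, 61)
  expect_setequal(yel$pair, c("Yel", "Ice"))

  two <- group_extreme(fx$ddh_matrix, c("Kam1", "Yel"))
  expect_equal(two$value, 50.4)
  expect_error(group_extreme(fx$ddh_matrix, "Yel"), "at least 2")
  expect_error(group_extreme(fx$ddh_matrix, "Yel", others = c("Yel", "Ice")),
               "overlap")
})

test_that("pairwise relationship classification follows the decision table", {
  # 16S above the species cutoff but DDH far below it: distinct, flagged
  r <- classify_relationship(99.5, 61)
  expect_equal(r$label, "distinct_species")
  expect_equal(r$flags, "ambiguous_16s")

  expect_equal(classify_relationship(100, 100)$label, "same_species")
  # boundaries are inclusive
  expect_equal(classify_relationship(98.7, 70)$label, "same_species")
  expect_equal(classify_relationship(96, 20)$label, "distinct_species")
  expect_length(classify_relationship(96, 20)$flags, 0)
  # geovar candidates: same species from separated sites
  expect_equal(classify_relationship(100, 88.4, allopatric = TRUE)$label,
               "same_geovar_candidate")
  # 16S-only calls when DDH is unavailable
  expect_equal(classify_relationship(99, NA)$label, "same_species")
  expect_equal(classify_relationship(96.5, NA)$label, "distinct_species")
  expect_equal(classify_relationship(98, NA)$label, "ambiguous")
})
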